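# Synthetic studies: complete drive logs, gaze logs, horn presses and ground
# truth with a known occlusion -> reaction-time effect. The gaze model is a
# three-state process (forward fixation / dashboard glance / hazard pursuit)
# with Poisson glance arrivals; dropout is i.i.d. per sample plus occasional
# multi-second gaps with exponential lengths, emulating the difficulty of
# tracking extra-foveal fixators. Reaction times follow a log-linear response
# model: log RT = subject intercept + eccentricity effect + slope x occlusion
# time + Gaussian noise, coupled to the generated gaze by a monotone fixed
# point (occlusion time up to the press determines the press, and is
# non-decreasing in it).

#' Gaze-behaviour parameters for the synthetic generator
#'
#' @param fixation_jitter_sd Gaussian jitter of fixation, degrees.
#' @param saccade_latency_mean,saccade_latency_sd Seconds before the horn
#'   press at which gaze lands on the hazard (orienting saccade + pursuit).
#' @param dashboard_glance_rate Poisson rate of downward dashboard glances,
#'   per minute.
#' @param glance_duration Glance length, s.
#' @param glance_elevation Gaze elevation during a glance, degrees (negative
#'   = down).
#' @param dropout_prob Per-sample i.i.d. probability of an invalid tracker
#'   sample.
#' @param gap_rate Poisson rate of long tracker gaps, per minute.
#' @param gap_mean Mean gap length, s (exponential).
#' @return A list of class `gaze_behavior_params`.
#' @export
gaze_behavior_params <- function(fixation_jitter_sd = 0.5,
                                 saccade_latency_mean = 0.25,
                                 saccade_latency_sd = 0.05,
                                 dashboard_glance_rate = 6,
                                 glance_duration = 0.7,
                                 glance_elevation = -12,
                                 dropout_prob = 0.08,
                                 gap_rate = 10,
                                 gap_mean = 5) {
  stopifnot(
    fixation_jitter_sd >= 0, dashboard_glance_rate >= 0, glance_duration >= 0,
    dropout_prob >= 0, dropout_prob <= 1, gap_rate >= 0, gap_mean >= 0
  )
  structure(as.list(environment()), class = "gaze_behavior_params")
}

#' Response-model parameters for the synthetic generator
#'
#' Defaults put scotoma-field participants' median reaction times near the
#' low-2-second range and empty-field controls near 1.1-1.2 s, with longer
#' latencies for occluded hazards.
#'
#' @param subject_intercepts Named numeric vector of per-participant
#'   intercepts (log-seconds), or `NULL` to derive defaults from the fields:
#'   `log(2.5)` for participants with scotomas, `log(1.25)` for empty
#'   fields, plus a `N(0, intercept_sd)` subject effect.
#' @param intercept_sd SD of the subject effect when intercepts are derived.
#' @param ecc_effect Log-seconds for large (14 deg) vs small (4 deg)
#'   eccentricity.
#' @param occ_slope Log-seconds of added latency per second of scotoma
#'   occlusion.
#' @param noise_sd Residual SD, log-seconds (> 0).
#' @param detect_prob Probability a pedestrian is detected at all.
#' @return A list of class `response_model_params`.
#' @export
response_model_params <- function(subject_intercepts = NULL,
                                  intercept_sd = 0.15,
                                  ecc_effect = -0.25,
                                  occ_slope = 0.3,
                                  noise_sd = 0.35,
                                  detect_prob = 0.98) {
  stopifnot(noise_sd > 0, detect_prob > 0, detect_prob <= 1, intercept_sd >= 0)
  structure(as.list(environment()), class = "response_model_params")
}

# Per-participant/drive gaze trace at 60 Hz (fixation + glances + dropout).
# Hazard pursuit is spliced in per event once the press time is known.
generate_gaze_trace <- function(duration, gaze) {
  rate <- 60
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  az <- rnorm(n, 0, gaze$fixation_jitter_sd)
  el <- rnorm(n, 0, gaze$fixation_jitter_sd)
  # dashboard glances
  n_gl <- rpois(1, gaze$dashboard_glance_rate * duration / 60)
  if (n_gl > 0) {
    starts <- runif(n_gl, 0, duration)
    for (s in starts) {
      in_gl <- t >= s & t < s + gaze$glance_duration
      el[in_gl] <- gaze$glance_elevation + rnorm(sum(in_gl), 0, gaze$fixation_jitter_sd)
    }
  }
  valid <- runif(n) > gaze$dropout_prob
  n_gap <- rpois(1, gaze$gap_rate * duration / 60)
  if (n_gap > 0) {
    starts <- runif(n_gap, 0, duration)
    lens <- rexp(n_gap, 1 / max(gaze$gap_mean, 1e-9))
    for (g in seq_len(n_gap)) {
      valid[t >= starts[g] & t < starts[g] + lens[g]] <- FALSE
    }
  }
  tibble::tibble(
    t = t,
    gaze_azimuth_deg = az,
    gaze_elevation_deg = el,
    valid = valid
  )
}

#' Generate a complete synthetic hazard-detection study
#'
#' Builds, for each participant, one city and one highway drive whose
#' pedestrian appearances are evenly divided among the configured
#' eccentricities and between the drive types; generates gaze traces;
#' couples reaction times to the occlusion actually produced by the gaze and
#' the participant's visual field; and records every latent quantity in a
#' ground-truth table. Deterministic given `seed`.
#'
#' @param fields List of [visual_field()] objects, one per participant
#'   (empty-polygon fields are normal-vision controls).
#' @param cfg A [scenario_config()]; `n_appearances` is the per-participant
#'   total, which must divide evenly among eccentricity-by-drive-type cells
#'   when both drive types are used.
#' @param gaze A [gaze_behavior_params()].
#' @param resp A [response_model_params()].
#' @param drive_types Drive types to include.
#' @param inter_event_gap Quiet seconds between consecutive event windows.
#' @param seed Integer seed; required (reproducibility is mandatory).
#' @return A list of class `synthetic_study`: `logs` (tibble with
#'   `participant_id`, `drive_type`, list-columns `drive`, `gaze`, and the
#'   `cfg` for that drive), `fields`, `ground_truth` (one row per
#'   appearance with the latent intercept, noise, true occlusion time,
#'   press time), `params`, `seed`.
#' @export
generate_study <- function(fields,
                           cfg = scenario_config("city"),
                           gaze = gaze_behavior_params(),
                           resp = response_model_params(),
                           drive_types = c("city", "highway"),
                           inter_event_gap = 2,
                           seed = NULL) {
  if (is.null(seed)) abort("a seed is required: synthetic studies must be reproducible")
  stopifnot(inherits(cfg, "scenario_config"), inherits(gaze, "gaze_behavior_params"),
            inherits(resp, "response_model_params"))
  if (is.null(names(fields))) names(fields) <- vapply(fields, function(f) f$participant_id, character(1))
  set.seed(as.integer(seed))

  eccs <- cfg$eccentricities
  n_cells <- length(eccs) * length(drive_types)
  if (cfg$n_appearances %% n_cells != 0L) {
    abort("n_appearances must divide evenly among eccentricity-by-drive-type cells")
  }
  per_cell <- cfg$n_appearances %/% n_cells

  intercepts <- resp$subject_intercepts
  if (is.null(intercepts)) {
    base <- vapply(fields, function(f) if (length(f$polygons) > 0) log(2.5) else log(1.25), numeric(1))
    intercepts <- base + rnorm(length(fields), 0, resp$intercept_sd)
    names(intercepts) <- names(fields)
  }

  log_rows <- list()
  gt_rows <- list()
  for (pid in names(fields)) {
    field <- fields[[pid]]
    has_scotoma <- length(field$polygons) > 0
    for (dt in drive_types) {
      dcfg <- scenario_config(
        dt,
        appearance_travel_time = cfg$appearance_travel_time,
        eccentricities = eccs,
        n_appearances = as.integer(per_cell * length(eccs)),
        pedestrian_height = cfg$pedestrian_height,
        deceleration = cfg$deceleration,
        eye_height = cfg$eye_height,
        lane_half_width = cfg$lane_half_width,
        sim_rate = cfg$sim_rate
      )
      sched_ecc <- sample(rep(eccs, per_cell))
      n_ev <- length(sched_ecc)
      period <- dcfg$appearance_travel_time + inter_event_gap
      duration <- n_ev * period + inter_event_gap
      dt_sim <- 1 / dcfg$sim_rate
      tt <- seq(0, duration, by = dt_sim)
      drive <- tibble::tibble(
        t = tt,
        car_along_track_m = dcfg$car_speed * tt,
        car_speed_mps = dcfg$car_speed,
        car_heading_deg = 0,
        ped_id = NA_character_,
        ped_x_m = NA_real_,
        ped_y_m = NA_real_,
        ped_visible = 0L,
        horn = 0L
      )
      gz <- generate_gaze_trace(duration, gaze)

      for (e in seq_len(n_ev)) {
        t_appear <- inter_event_gap + (e - 1) * period
        ev_id <- sprintf("%s_%s_%03d", pid, dt, e)
        ev <- pedestrian_event(ev_id, sched_ecc[e], t_appear, dcfg)
        car_x0 <- dcfg$car_speed * t_appear
        traj <- make_trajectory(dcfg, ev, car_x0 = car_x0)
        idx <- round((traj$t - tt[1]) / dt_sim) + 1L
        keep <- idx >= 1L & idx <= nrow(drive)
        idx <- idx[keep]
        drive$ped_id[idx] <- ev_id
        drive$ped_x_m[idx] <- traj$ped_x[keep]
        drive$ped_y_m[idx] <- traj$ped_y[keep]
        drive$ped_visible[idx] <- 1L

        # response model with occlusion coupling
        mu <- intercepts[pid] +
          resp$ecc_effect * as.numeric(abs(sched_ecc[e]) == max(abs(eccs)))
        noise <- rnorm(1, 0, resp$noise_sd)
        detected <- runif(1) < resp$detect_prob

        ev_drive <- drive[idx, ]
        ang <- project_to_angles(ev_drive$car_along_track_m, ev_drive$ped_x_m,
                                 ev_drive$ped_y_m, dcfg)
        aligned <- align_streams(gz, dplyr::bind_cols(ev_drive[, "t"], ang))
        trace <- occlusion_trace(field, aligned, event_id = ev_id)

        rt <- exp(mu + noise)
        occ <- 0
        if (has_scotoma) {
          for (it in 1:10) {
            occ_new <- occlusion_time(trace, t_appear + rt, dcfg$sim_rate)
            rt_new <- exp(mu + resp$occ_slope * occ_new + noise)
            if (abs(rt_new - rt) < 1e-6 && occ_new == occ) {
              rt <- rt_new; occ <- occ_new; break
            }
            rt <- rt_new; occ <- occ_new
          }
        }
        if (rt > ev$window - dt_sim) detected <- FALSE

        t_press <- NA_real_
        if (detected) {
          # snap the press to the simulator grid
          press_idx <- idx[which.min(abs(ev_drive$t - (t_appear + rt)))]
          t_press <- drive$t[press_idx]
          rt <- t_press - t_appear
          drive$horn[press_idx] <- 1L
          # hazard pursuit: gaze lands on the pedestrian shortly before press
          lead <- max(rnorm(1, gaze$saccade_latency_mean, gaze$saccade_latency_sd), 0)
          in_pursuit <- gz$t >= (t_press - lead) & gz$t <= max(traj$t)
          if (any(in_pursuit)) {
            paz <- approx(ev_drive$t, ang$azimuth, xout = gz$t[in_pursuit], rule = 2)$y
            pel <- approx(ev_drive$t, (ang$elevation_top + ang$elevation_bottom) / 2,
                          xout = gz$t[in_pursuit], rule = 2)$y
            jn <- sum(in_pursuit)
            gz$gaze_azimuth_deg[in_pursuit] <- paz + rnorm(jn, 0, gaze$fixation_jitter_sd)
            gz$gaze_elevation_deg[in_pursuit] <- pel + rnorm(jn, 0, gaze$fixation_jitter_sd)
          }
          # final ground-truth occlusion over the analysed span, post-pursuit
          aligned2 <- align_streams(gz, dplyr::bind_cols(ev_drive[, "t"], ang))
          trace <- occlusion_trace(field, aligned2, event_id = ev_id)
          occ <- occlusion_time(trace, t_press, dcfg$sim_rate)
        } else {
          occ <- occlusion_time(trace, t_appear + ev$window, dcfg$sim_rate)
        }

        gt_rows[[length(gt_rows) + 1L]] <- tibble::tibble(
          event_id = ev_id,
          participant_id = pid,
          drive_type = dt,
          eccentricity = sched_ecc[e],
          t_appear = t_appear,
          detected = detected,
          t_press = t_press,
          reaction_time = if (detected) rt else NA_real_,
          occlusion_time = occ,
          mu = unname(mu),
          noise = noise,
          has_scotoma = has_scotoma
        )
      }
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        participant_id = pid,
        drive_type = dt,
        drive = list(drive),
        gaze = list(gz),
        cfg = list(dcfg)
      )
    }
  }
  structure(
    list(
      logs = dplyr::bind_rows(log_rows),
      fields = fields,
      ground_truth = dplyr::bind_rows(gt_rows),
      params = list(cfg = cfg, gaze = gaze, resp = resp,
                    subject_intercepts = intercepts),
      seed = as.integer(seed)
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d participants, %d drives, %d appearances (seed %d)\n",
    length(x$fields), nrow(x$logs), nrow(x$ground_truth), x$seed
  ))
  invisible(x)
}

#' Score a synthetic study through the full pipeline
#'
#' Runs occlusion scoring and event-table assembly on every drive of a
#' generated study — the same code path used for logged data.
#'
#' @param study A `synthetic_study`.
#' @return An `event_table` over all participants and drives, with a
#'   `group` column (`"CFL"` for participants with scotomas, `"NV"`
#'   otherwise).
#' @export
score_study <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  tabs <- purrr::pmap(study$logs, function(participant_id, drive_type, drive, gaze, cfg) {
    build_event_table(drive, gaze, study$fields[[participant_id]], cfg,
                      participant_id = participant_id)
  })
  out <- dplyr::bind_rows(tabs)
  grp <- vapply(study$fields, function(f) if (length(f$polygons) > 0) "CFL" else "NV", character(1))
  out$group <- unname(grp[out$participant_id])
  class(out) <- c("event_table", class(out))
  out
}

#' Recover response-model parameters from a synthetic study
#'
#' Parameter-recovery harness: scores the study with the standard pipeline,
#' restricts to gaze-usable detected events of scotoma-field participants,
#' and fits the log reaction-time regression. Returns the estimated
#' occlusion slope with its confidence interval and the occlusion-time /
#' reaction-time correlation.
#'
#' @param study A `synthetic_study`.
#' @param events Optionally, a pre-scored `event_table` (avoids re-scoring).
#' @return A list: `fit` (an `occlusion_rt_fit`, or `NULL` when
#'   unidentifiable), `estimates` (tibble: term, estimate, conf_low,
#'   conf_high, true value where known), `correlation` (tibble from
#'   [pearson_r()]), `n_events`.
#' @export
recover_parameters <- function(study, events = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (is.null(events)) events <- score_study(study)
  usable <- events |>
    dplyr::filter(.data$group == "CFL", .data$detected, .data$gaze_usable,
                  !is.na(.data$reaction_time))
  if (nrow(usable) < 10 || sd(usable$occlusion_time) == 0) {
    warn("occlusion slope unidentifiable: too few usable events or no occlusion variance")
    return(list(fit = NULL, estimates = NULL, correlation = NULL, n_events = nrow(usable)))
  }
  fit <- ols_logrt(usable)
  est <- tibble::tibble(
    term = "occ_slope",
    estimate = fit$occ_slope,
    conf_low = fit$occ_slope_ci[1],
    conf_high = fit$occ_slope_ci[2],
    truth = study$params$resp$occ_slope
  )
  corr <- pearson_r(usable$occlusion_time, usable$reaction_time)
  list(fit = fit, estimates = est, correlation = corr, n_events = nrow(usable))
}

#' Parameter-recovery benchmark
#'
#' Repeatedly generates a benchmark study (three superior-scotoma
#' participants, about 300 pedestrian appearances, a known occlusion slope)
#' and runs the full scoring-and-regression pipeline on each replicate. The
#' benchmark generates from exactly the model the pipeline fits (no
#' eccentricity effect, since the regression contains occlusion and subject
#' terms only) at modest residual noise, where the protocol-induced coupling
#' between occlusion-to-press and reaction time is negligible (see the
#' methods vignette).
#'
#' @param replicates Number of replicates.
#' @param occ_slope True occlusion slope, log-seconds per second occluded.
#' @param noise_sd Residual SD, log-seconds.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return A tibble with one row per replicate: `estimate`, `conf_low`,
#'   `conf_high`, `covered` (CI contains the truth), `corr_r`, `n_events`.
#' @export
recovery_benchmark <- function(replicates = 20, occ_slope = 0.3,
                               noise_sd = 0.25, seed = 1L) {
  gaze <- gaze_behavior_params(
    dashboard_glance_rate = 8, glance_duration = 1.2,
    dropout_prob = 0.02, gap_rate = 1, gap_mean = 1
  )
  resp <- response_model_params(
    ecc_effect = 0, occ_slope = occ_slope,
    noise_sd = noise_sd, detect_prob = 0.99
  )
  fields <- lapply(sprintf("CFL%d", 1:3), superior_scotoma_field)
  purrr::map_dfr(seq_len(replicates), function(r) {
    st <- generate_study(fields, scenario_config("city", n_appearances = 104),
                         gaze = gaze, resp = resp, seed = seed + r)
    rec <- recover_parameters(st)
    tibble::tibble(
      replicate = r,
      estimate = rec$estimates$estimate,
      conf_low = rec$estimates$conf_low,
      conf_high = rec$estimates$conf_high,
      covered = rec$estimates$conf_low <= occ_slope & occ_slope <= rec$estimates$conf_high,
      corr_r = rec$correlation$r,
      n_events = rec$n_events
    )
  })
}

#' A typical superior-scotoma visual field
#'
#' Convenience constructor for a convex scotoma above the PRL, the common
#' configuration in juvenile macular degeneration. The default spans about
#' 14 degrees horizontally and sits between 3 and 13 degrees elevation, so
#' that a 12-degree downward dashboard glance lifts an on-road hazard into
#' it.
#'
#' @param participant_id Label.
#' @param half_width Horizontal half-extent, degrees.
#' @param elevation_range Elevation span, degrees.
#' @return A [visual_field()].
#' @export
superior_scotoma_field <- function(participant_id = "CFL",
                                   half_width = 7,
                                   elevation_range = c(3, 13)) {
  lo <- elevation_range[1]; hi <- elevation_range[2]
  mid <- (lo + hi) / 2
  poly <- cbind(
    c(-half_width, -half_width * 0.6, half_width * 0.6, half_width,
      half_width * 0.6, -half_width * 0.6),
    c(mid, lo, lo, mid, hi, hi)
  )
  visual_field(list(poly), participant_id,
               prl_note = "scotoma above PRL (synthetic)")
}
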