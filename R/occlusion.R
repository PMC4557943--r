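# Occlusion scoring: merge the 30 Hz simulator stream with the 60 Hz gaze
# stream, move the pedestrian's angular segment into PRL-centred visual-field
# coordinates given momentary gaze, and measure what fraction of its vertical
# extent falls inside the scotoma union at each sample. Gaze-missing samples
# are scored as not-occluded — a conservative under-estimate of occlusion.

#' Align a 60 Hz gaze log with a 30 Hz drive log
#'
#' For each simulator sample the nearest gaze sample within half a gaze
#' period (±1/60 s) is attached; with synchronised clocks this is exactly the
#' "every other gaze sample" rule. Simulator samples with no valid gaze match
#' are flagged gaze-missing.
#'
#' @param gaze Gaze log: tibble with `t`, `gaze_azimuth_deg`,
#'   `gaze_elevation_deg`, `valid` (0/1 or logical).
#' @param drive Drive log: tibble with at least `t` (30 Hz).
#' @param tol Matching tolerance in seconds (default 1/60 + a small slack).
#' @return The drive log with `gaze_azimuth`, `gaze_elevation`,
#'   `gaze_valid` columns appended.
#' @export
align_streams <- function(gaze, drive, tol = 1 / 60 + 1e-6) {
  stopifnot(is.data.frame(gaze), is.data.frame(drive))
  req <- c("t", "gaze_azimuth_deg", "gaze_elevation_deg", "valid")
  missing_cols <- setdiff(req, names(gaze))
  if (length(missing_cols) > 0) {
    abort(paste0("gaze log is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (min(gaze$t) > max(drive$t) || max(gaze$t) < min(drive$t)) {
    abort("gaze and drive logs cover disjoint time ranges")
  }
  gt <- gaze$t
  idx <- findInterval(drive$t, gt)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(gt))
  d_lo <- abs(drive$t - gt[lo])
  d_hi <- abs(drive$t - gt[hi])
  nearest <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  matched <- dist <= tol
  valid <- as.logical(gaze$valid)[nearest] & matched
  out <- drive
  out$gaze_azimuth <- ifelse(valid, gaze$gaze_azimuth_deg[nearest], NA_real_)
  out$gaze_elevation <- ifelse(valid, gaze$gaze_elevation_deg[nearest], NA_real_)
  out$gaze_valid <- valid
  tibble::as_tibble(out)
}

#' Move a target segment into visual-field (retinal) coordinates
#'
#' Subtracts the momentary gaze direction from the target's head-centred
#' angles, so that the PRL (the visual-field origin) coincides with the gaze
#' direction. A downward dashboard glance therefore raises the target in
#' visual-field coordinates — the mechanism by which a scotoma above the PRL
#' can occlude an on-road hazard.
#'
#' @param segment Tibble with `azimuth`, `elevation_bottom`, `elevation_top`
#'   (degrees, head-centred, relative to car heading).
#' @param gaze_azimuth,gaze_elevation Gaze direction, degrees (same frame);
#'   `NA` propagates.
#' @return A tibble of the same shape in visual-field coordinates.
#' @export
retinal_position <- function(segment, gaze_azimuth, gaze_elevation) {
  tibble::tibble(
    azimuth = segment$azimuth - gaze_azimuth,
    elevation_bottom = segment$elevation_bottom - gaze_elevation,
    elevation_top = segment$elevation_top - gaze_elevation
  )
}

#' Fraction of a vertical segment occluded by the scotoma union
#'
#' When the segment and a scotoma overlap horizontally, the occluded part of
#' the segment is the intersection of the segment's elevation span with the
#' scotoma's vertical chord at that azimuth; with several scotomas the union
#' of the per-polygon intersections is measured. The result is the fraction
#' of the segment's vertical extent inside the scotoma (0 when nothing
#' overlaps horizontally). Touching the boundary counts as inside, but
#' contributes zero length.
#'
#' @param field A [visual_field()] in PRL-centred degrees.
#' @param segment Tibble (any number of rows) with `azimuth`,
#'   `elevation_bottom`, `elevation_top` already in visual-field coordinates.
#' @return Numeric vector of fractions in \[0, 1\]; `NA` rows in, `NA` out.
#' @export
occlusion_fraction <- function(field, segment) {
  stopifnot(inherits(field, "visual_field"))
  az <- segment$azimuth
  bot <- segment$elevation_bottom
  top <- segment$elevation_top
  n <- length(az)
  height <- top - bot
  if (any(height <= 0, na.rm = TRUE)) abort("segment must have elevation_top > elevation_bottom")
  k <- length(field$polygons)
  if (k == 0L) return(ifelse(is.na(az), NA_real_, 0))
  # per-polygon clipped intervals
  lo_mat <- matrix(NA_real_, n, k)
  hi_mat <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    b <- chord_bounds(field$polygons[[j]], az)
    lo <- pmax(b$lower, bot)
    hi <- pmin(b$upper, top)
    keep <- !is.na(lo) & !is.na(hi) & hi > lo
    lo_mat[keep, j] <- lo[keep]
    hi_mat[keep, j] <- hi[keep]
  }
  covered <- if (k == 1L) {
    len <- hi_mat[, 1] - lo_mat[, 1]
    ifelse(is.na(len), 0, len)
  } else {
    interval_union_length(lo_mat, hi_mat)
  }
  out <- covered / height
  out[is.na(az)] <- NA_real_
  pmin(pmax(out, 0), 1)
}

# Total length of the union of k intervals per row; NA intervals are absent.
interval_union_length <- function(lo_mat, hi_mat) {
  n <- nrow(lo_mat)
  out <- numeric(n)
  any_int <- rowSums(!is.na(lo_mat)) > 0
  for (i in which(any_int)) {
    lo <- lo_mat[i, ]
    hi <- hi_mat[i, ]
    ok <- !is.na(lo)
    lo <- lo[ok]; hi <- hi[ok]
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    total <- 0
    cur_lo <- lo[1]; cur_hi <- hi[1]
    for (j in seq_along(lo)[-1]) {
      if (lo[j] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[j])
      } else {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- lo[j]; cur_hi <- hi[j]
      }
    }
    out[i] <- total + (cur_hi - cur_lo)
  }
  out
}

#' Per-sample occlusion trace for one hazard event
#'
#' Projects the pedestrian into visual angles at every simulator sample,
#' moves it into visual-field coordinates given the aligned gaze, and scores
#' the occluded fraction. Samples with missing gaze get fraction 0 and
#' `occluded = FALSE` (conservative); the `gaze_valid` flag is preserved.
#'
#' @param field A [visual_field()].
#' @param aligned Aligned event stream: tibble with `t`, `azimuth`,
#'   `elevation_bottom`, `elevation_top` (head-centred) and `gaze_azimuth`,
#'   `gaze_elevation`, `gaze_valid`.
#' @param event_id Label stored on the trace.
#' @return A tibble of class `occlusion_trace`: `t`, `fraction`, `occluded`,
#'   `gaze_valid`.
#' @export
occlusion_trace <- function(field, aligned, event_id = "event") {
  seg <- retinal_position(
    aligned[, c("azimuth", "elevation_bottom", "elevation_top")],
    aligned$gaze_azimuth, aligned$gaze_elevation
  )
  frac <- occlusion_fraction(field, seg)
  frac[is.na(frac)] <- 0
  out <- tibble::tibble(
    event_id = event_id,
    t = aligned$t,
    fraction = frac,
    occluded = frac > 0,
    gaze_valid = aligned$gaze_valid
  )
  class(out) <- c("occlusion_trace", class(out))
  out
}

#' Cumulative occlusion time of a trace
#'
#' Number of occluded samples up to the analysis end, divided by the sample
#' rate. The analysis span runs from pedestrian appearance to the horn press
#' or, for undetected pedestrians, to disappearance. Gaze-missing samples
#' contribute nothing.
#'
#' @param trace An [occlusion_trace()].
#' @param analysis_end End of the analysis span (s); defaults to the last
#'   sample.
#' @param sim_rate Samples per second.
#' @return Seconds.
#' @export
occlusion_time <- function(trace, analysis_end = Inf, sim_rate = 30) {
  if (nrow(trace) == 0L) {
    warn("empty occlusion trace; occlusion time is 0")
    return(0)
  }
  sum(trace$occluded & trace$t <= analysis_end) / sim_rate
}

#' @export
autoplot.occlusion_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_rug(
      data = dplyr::filter(object, !.data$gaze_valid),
      sides = "b", colour = "red", alpha = 0.5
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "Time (s)", y = "Occluded fraction of pedestrian",
      title = paste("Occlusion trace:", object$event_id[1]),
      caption = "red rug: gaze-missing samples"
    ) +
    ggplot2::theme_minimal()
}

#' Build the per-appearance event table
#'
#' The substrate of every statistic: one row per pedestrian appearance, with
#' detection, reaction time, timeliness (stopping-distance criterion at the
#' instantaneous speed at the press), occlusion time over the analysis span
#' (appearance to press, or to disappearance if undetected), and a
#' gaze-usability flag (at least half the span's samples must carry valid
#' gaze).
#'
#' @param drive Drive log tibble: `t`, `car_along_track_m`, `car_speed_mps`,
#'   `car_heading_deg`, `ped_id`, `ped_x_m`, `ped_y_m`, `ped_visible`,
#'   `horn`.
#' @param gaze Gaze log tibble (see [align_streams()]).
#' @param field A [visual_field()] for the participant.
#' @param cfg A [scenario_config()].
#' @param participant_id Participant label.
#' @param usable_threshold Minimum fraction of valid-gaze samples in the
#'   analysis span for an event to be gaze-usable.
#' @return A tibble of class `event_table`, one row per appearance:
#'   `event_id`, `participant_id`, `drive_type`, `eccentricity`,
#'   `ecc_class` (small/large), `detected`, `reaction_time`, `timely`,
#'   `occlusion_time`, `max_fraction`, `gaze_usable`, `log_rt`.
#' @export
build_event_table <- function(drive, gaze, field, cfg,
                              participant_id = field$participant_id,
                              usable_threshold = 0.5) {
  stopifnot(inherits(field, "visual_field"), inherits(cfg, "scenario_config"))
  aligned <- align_streams(gaze, drive)
  press_times <- drive$t[drive$horn > 0]
  press_used <- rep(FALSE, length(press_times))

  vis <- aligned[aligned$ped_visible > 0 & !is.na(aligned$ped_id), ]
  ids <- unique(vis$ped_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ev <- vis[vis$ped_id == ids[i], ]
    t_appear <- min(ev$t)
    t_gone <- max(ev$t)
    window_end <- t_gone

    ang <- project_to_angles(ev$car_along_track_m, ev$ped_x_m, ev$ped_y_m, cfg)
    open <- !is.na(ang$azimuth)
    ev <- ev[open, ]
    ang <- ang[open, ]
    if (nrow(ev) == 0L) next

    # nominal eccentricity: bearing at appearance snapped to the configured set
    ecc0 <- ang$azimuth[1]
    ecc <- cfg$eccentricities[which.min(abs(cfg$eccentricities - ecc0))]

    # earliest unclaimed press inside the window
    cand <- which(!press_used & press_times >= t_appear & press_times <= window_end)
    if (length(cand) > 0L) {
      pi1 <- cand[which.min(press_times[cand])]
      press_used[pi1] <- TRUE
      t_press <- press_times[pi1]
      detected <- TRUE
      rt <- t_press - t_appear
    } else {
      t_press <- NA_real_
      detected <- FALSE
      rt <- NA_real_
    }
    analysis_end <- if (detected) t_press else t_gone

    stream <- dplyr::bind_cols(
      ev[, c("t", "gaze_azimuth", "gaze_elevation", "gaze_valid")],
      ang
    )
    trace <- occlusion_trace(field, stream, event_id = as.character(ids[i]))
    span <- trace[trace$t <= analysis_end, ]
    occ_t <- occlusion_time(trace, analysis_end, cfg$sim_rate)
    usable <- nrow(span) > 0 && mean(span$gaze_valid) >= usable_threshold

    timely <- NA
    if (detected) {
      k <- which.min(abs(ev$t - t_press))
      remaining <- ev$ped_x_m[k] - ev$car_along_track_m[k]
      timely <- is_timely(remaining, ev$car_speed_mps[k], cfg$deceleration)
    }

    rows[[i]] <- tibble::tibble(
      event_id = as.character(ids[i]),
      participant_id = participant_id,
      drive_type = cfg$drive_type,
      eccentricity = ecc,
      ecc_class = ifelse(abs(ecc) <= 9, "small", "large"),
      detected = detected,
      reaction_time = rt,
      timely = timely,
      occlusion_time = occ_t,
      max_fraction = if (nrow(span) > 0) max(span$fraction) else 0,
      gaze_usable = usable
    )
  }
  out <- dplyr::bind_rows(rows)
  out$log_rt <- log(out$reaction_time)
  out <- out[order(out$event_id), ]
  class(out) <- c("event_table", class(out))
  out
}

#' Gaze-data availability bias check
#'
#' Tests whether tracker dropouts biased which hazard locations retain usable
#' gaze data: counts gaze-usable events per eccentricity and compares them
#' with expected counts by a goodness-of-fit chi-square. Expected counts are
#' proportional to the total appearances per eccentricity
#' (`expectation = "totals"`, the default) or uniform
#' (`expectation = "uniform"`).
#'
#' @param table An `event_table`.
#' @param expectation `"totals"` or `"uniform"`.
#' @return A list with `counts` (tibble: eccentricity, usable, total) and
#'   `test` (tibble: statistic, df, p_value).
#' @export
gaze_availability_check <- function(table, expectation = c("totals", "uniform")) {
  expectation <- match.arg(expectation)
  counts <- table |>
    dplyr::group_by(.data$eccentricity) |>
    dplyr::summarise(
      usable = sum(.data$gaze_usable),
      total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$eccentricity)
  w <- if (expectation == "totals") counts$total else rep(1, nrow(counts))
  test <- chi2_gof(counts$usable, w)
  if (any(counts$usable == 0)) {
    warn("at least one eccentricity has no usable events (gross imbalance)")
  }
  list(counts = counts, test = test)
}
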