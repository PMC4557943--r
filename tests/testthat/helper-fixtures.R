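# Fixtures and independent oracles, built in code.

square_poly <- function(half = 5, cx = 0, cy = 0) {
  cbind(c(cx - half, cx + half, cx + half, cx - half),
        c(cy - half, cy - half, cy + half, cy + half))
}

square_field <- function(half = 5, cx = 0, cy = 0, id = "sq") {
  visual_field(list(square_poly(half, cx, cy)), id)
}

# random convex polygon: convex hull of points on a jittered ellipse
random_convex_poly <- function(n_pts = 12, scale = 5) {
  th <- sort(runif(n_pts, 0, 2 * pi))
  r <- scale * (0.5 + runif(n_pts))
  x <- r * cos(th) + runif(1, -8, 8)
  y <- r * sin(th) + runif(1, -8, 8)
  h <- chull(x, y)
  cbind(x[h], y[h])
}

# independent point-in-convex-polygon test: all cross products one sign
# (closed: boundary counts as inside)
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  inside <- rep(TRUE, length(px))
  for (e in seq_len(n)) {
    cr <- (poly[nxt[e], 1] - poly[e, 1]) * (py - poly[e, 2]) -
      (poly[nxt[e], 2] - poly[e, 2]) * (px - poly[e, 1])
    inside <- inside & cr >= -1e-12
  }
  inside
}

# rasterised occlusion oracle: sample the segment every `step` degrees and
# count points inside any polygon
raster_occlusion <- function(field, azimuth, bottom, top, step = 0.01) {
  ys <- seq(bottom, top, by = step)
  inside <- rep(FALSE, length(ys))
  for (p in field$polygons) {
    m <- as.matrix(p)
    # ensure CCW orientation for the cross-product test
    inside <- inside | point_in_poly(rep(azimuth, length(ys)), ys, m)
  }
  mean(inside)
}

# brute-force Mann-Whitney U1 by pair enumeration
u1_brute <- function(x, y) {
  g <- expand.grid(x = x, y = y)
  sum((g$x > g$y) + 0.5 * (g$x == g$y))
}

# minimal scripted drive: one pedestrian on a collision course, optional
# horn press `rt` seconds after appearance
scripted_drive <- function(cfg, ecc = 4, t_appear = 1, rt = NA, duration = 8) {
  dt <- 1 / cfg$sim_rate
  tt <- seq(0, duration, by = dt)
  drive <- tibble::tibble(
    t = tt,
    car_along_track_m = cfg$car_speed * tt,
    car_speed_mps = cfg$car_speed,
    car_heading_deg = 0,
    ped_id = NA_character_,
    ped_x_m = NA_real_,
    ped_y_m = NA_real_,
    ped_visible = 0L,
    horn = 0L
  )
  ev <- pedestrian_event("ped1", ecc, t_appear, cfg)
  traj <- make_trajectory(cfg, ev, car_x0 = cfg$car_speed * t_appear)
  idx <- round(traj$t / dt) + 1L
  keep <- idx <= nrow(drive)
  drive$ped_id[idx[keep]] <- "ped1"
  drive$ped_x_m[idx[keep]] <- traj$ped_x[keep]
  drive$ped_y_m[idx[keep]] <- traj$ped_y[keep]
  drive$ped_visible[idx[keep]] <- 1L
  if (!is.na(rt)) {
    pi1 <- which.min(abs(tt - (t_appear + rt)))
    drive$horn[pi1] <- 1L
  }
  drive
}

# steady forward-gaze log covering the drive
forward_gaze <- function(duration, valid = TRUE, elevation = 0) {
  t <- seq(0, duration, by = 1 / 60)
  tibble::tibble(
    t = t,
    gaze_azimuth_deg = 0,
    gaze_elevation_deg = elevation,
    valid = valid
  )
}
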