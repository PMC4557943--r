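test_that("stream alignment implements the every-other-sample rule with tolerance", {
  drive <- tibble::tibble(t = seq(0, 1, by = 1 / 30))
  gaze <- tibble::tibble(
    t = seq(0, 1, by = 1 / 60),
    gaze_azimuth_deg = seq_along(t) * 1.0,
    gaze_elevation_deg = 0,
    valid = TRUE
  )
  gaze$gaze_azimuth_deg <- seq_len(nrow(gaze)) * 1.0
  al <- align_streams(gaze, drive)
  # phase-locked: exactly every other gaze sample (1st, 3rd, 5th, ...)
  expect_equal(al$gaze_azimuth, seq(1, nrow(gaze), by = 2))
  expect_true(all(al$gaze_valid))

  # 5 ms clock offset: nearest-neighbour matching, nothing dropped
  gaze_off <- gaze
  gaze_off$t <- gaze$t + 0.005
  al2 <- align_streams(gaze_off, drive)
  expect_true(all(al2$gaze_valid))

  gaze_bad <- gaze
  gaze_bad$valid <- FALSE
  al3 <- align_streams(gaze_bad, drive)
  expect_true(all(!al3$gaze_valid))
  expect_true(all(is.na(al3$gaze_azimuth)))

  gaze_late <- gaze
  gaze_late$t <- gaze$t + 100
  expect_error(align_streams(gaze_late, drive), "disjoint")
})

test_that("retinal position subtracts gaze so the PRL rides the gaze point", {
  seg <- tibble::tibble(azimuth = 14, elevation_bottom = -1, elevation_top = 0.7)
  expect_equal(retinal_position(seg, 0, 0)$azimuth, 14)
  expect_equal(retinal_position(seg, 14, 0)$azimuth, 0)
  # dashboard glance: looking 10 deg down lifts the target 10 deg in field coords
  glanced <- retinal_position(seg, 0, -10)
  expect_equal(glanced$elevation_bottom, 9)
  expect_equal(glanced$elevation_top, 10.7)
  expect_true(is.na(retinal_position(seg, NA, NA)$azimuth))
})

test_that("occlusion fraction is the covered share of the segment", {
  f <- square_field(5)
  seg <- function(az, lo, hi) tibble::tibble(azimuth = az, elevation_bottom = lo, elevation_top = hi)
  expect_equal(occlusion_fraction(f, seg(0, -2, 2)), 1)
  expect_equal(occlusion_fraction(f, seg(10, -2, 2)), 0)
  expect_equal(occlusion_fraction(f, seg(0, -10, 0)), 0.5)
  # empty field: always zero
  nv <- visual_field(list(), "nv")
  expect_equal(occlusion_fraction(nv, seg(c(0, 3), c(-1, -1), c(1, 1))), c(0, 0))
})

test_that("occlusion fraction is translation equivariant and respects union bounds", {
  set.seed(21)
  f2 <- visual_field(list(square_poly(4), square_poly(3, cx = 5, cy = 2)), "two")
  f_a <- visual_field(list(square_poly(4)), "a")
  f_b <- visual_field(list(square_poly(3, cx = 5, cy = 2)), "b")
  for (i in 1:50) {
    az <- runif(1, -10, 10); lo <- runif(1, -8, 2); hi <- lo + runif(1, 0.5, 6)
    seg <- tibble::tibble(azimuth = az, elevation_bottom = lo, elevation_top = hi)
    fu <- occlusion_fraction(f2, seg)
    fa <- occlusion_fraction(f_a, seg)
    fb <- occlusion_fraction(f_b, seg)
    expect_gte(fu + 1e-12, max(fa, fb))
    expect_lte(fu, min(1, fa + fb) + 1e-12)

    # shifting gaze and target together changes nothing
    dg <- runif(2, -5, 5)
    shifted <- retinal_position(
      tibble::tibble(azimuth = az + dg[1], elevation_bottom = lo + dg[2],
                     elevation_top = hi + dg[2]),
      dg[1], dg[2]
    )
    expect_equal(occlusion_fraction(f2, shifted), fu, tolerance = 1e-12)
  }
})

test_that("occlusion fraction agrees with the rasterised oracle on random fields", {
  set.seed(31)
  for (i in 1:40) {
    n_poly <- sample(1:2, 1)
    f <- visual_field(lapply(seq_len(n_poly), function(i) random_convex_poly()), "r")
    az <- runif(1, -15, 15)
    lo <- runif(1, -12, 5); hi <- lo + runif(1, 0.5, 8)
    got <- occlusion_fraction(f, tibble::tibble(
      azimuth = az, elevation_bottom = lo, elevation_top = hi
    ))
    want <- raster_occlusion(f, az, lo, hi)
    expect_lt(abs(got - want), 0.02)
  }
})

test_that("occlusion time counts occluded samples at the simulator rate", {
  tr <- tibble::tibble(
    event_id = "e", t = seq(0, 1, by = 1 / 30)[1:30],
    fraction = c(rep(0.4, 15), rep(0, 15)),
    occluded = c(rep(TRUE, 15), rep(FALSE, 15)),
    gaze_valid = TRUE
  )
  class(tr) <- c("occlusion_trace", class(tr))
  expect_equal(occlusion_time(tr), 0.5)
  expect_equal(occlusion_time(tr, analysis_end = tr$t[10]), 10 / 30)
  # non-decreasing in the analysis end
  ends <- seq(0, 1, by = 0.1)
  occ <- vapply(ends, function(e) occlusion_time(tr, e), numeric(1))
  expect_true(all(diff(occ) >= 0))
  none <- dplyr::mutate(tr, occluded = FALSE)
  expect_equal(occlusion_time(none), 0)
  expect_warning(empty <- occlusion_time(tr[0, ]), "empty")
  expect_equal(empty, 0)
})

test_that("a scripted full-cover scotoma yields the scripted occlusion time", {
  # huge scotoma centred on the PRL: pedestrian occluded whenever gaze valid
  f <- square_field(60)
  cfg <- scenario_config("city")
  drive <- scripted_drive(cfg, ecc = 4, t_appear = 1, rt = 3)
  dur <- max(drive$t)
  gaze <- forward_gaze(dur)
  # gaze valid only during a scripted 1.2 s slice of the event
  gaze$valid <- gaze$t >= 1.5 & gaze$t < 2.7
  ev <- build_event_table(drive, gaze, f, cfg, participant_id = "p")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$occlusion_time, 1.2, tolerance = 1 / 30 + 1e-9)
})

test_that("event tables capture detection, reaction time, and timeliness from logs", {
  cfg <- scenario_config("city")
  f <- visual_field(list(), "nv")
  drive <- scripted_drive(cfg, ecc = 4, t_appear = 1, rt = 1.0)
  gaze <- forward_gaze(max(drive$t))
  ev <- build_event_table(drive, gaze, f, cfg)
  expect_equal(nrow(ev), 1)
  expect_true(ev$detected)
  expect_equal(ev$reaction_time, 1.0, tolerance = 1e-9)
  expect_equal(ev$eccentricity, 4)
  expect_equal(ev$ecc_class, "small")
  expect_true(ev$timely) # city press after 1 s leaves ~53 m > 18 m
  expect_true(ev$gaze_usable)
  expect_equal(ev$occlusion_time, 0)

  # no press inside the window: undetected, no RT, timeliness not applicable
  drive2 <- scripted_drive(cfg, ecc = -14, t_appear = 1, rt = NA)
  ev2 <- build_event_table(drive2, gaze, f, cfg)
  expect_false(ev2$detected)
  expect_true(is.na(ev2$reaction_time))
  expect_true(is.na(ev2$timely))
  expect_equal(ev2$ecc_class, "large")

  # a late press on a highway drive is untimely
  hw <- scenario_config("highway")
  drive3 <- scripted_drive(hw, ecc = 4, t_appear = 1, rt = 4.0, duration = 8)
  gaze3 <- forward_gaze(8)
  ev3 <- build_event_table(drive3, gaze3, f, hw)
  expect_true(ev3$detected)
  expect_false(ev3$timely) # 134 - 26.82*4 = 26.7 m < 71.9 m
})

test_that("gaze availability check reproduces the totals-weighted statistic", {
  tab <- tibble::tibble(
    eccentricity = rep(c(-14, -4, 4, 14), times = c(178, 179, 175, 173)),
    gaze_usable = c(rep(c(TRUE, FALSE), c(66, 112)), rep(c(TRUE, FALSE), c(67, 112)),
                    rep(c(TRUE, FALSE), c(62, 113)), rep(c(TRUE, FALSE), c(65, 108)))
  )
  chk <- gaze_availability_check(tab)
  expect_equal(chk$counts$usable, c(66, 67, 62, 65))
  expect_equal(chk$counts$total, c(178, 179, 175, 173))
  expect_equal(chk$test$statistic, 0.139, tolerance = 1e-3)
  chk_u <- gaze_availability_check(tab, expectation = "uniform")
  expect_equal(chk_u$test$statistic, 0.215, tolerance = 1e-2)

  # perfectly balanced, all usable: statistic 0
  bal <- tibble::tibble(eccentricity = rep(c(-14, -4, 4, 14), 10), gaze_usable = TRUE)
  expect_equal(gaze_availability_check(bal)$test$statistic, 0)

  # one eccentricity fully dropped: gross imbalance warning
  drop1 <- dplyr::mutate(bal, gaze_usable = eccentricity != 4)
  expect_warning(res <- gaze_availability_check(drop1), "imbalance")
  expect_gt(res$test$statistic, 5)
})
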