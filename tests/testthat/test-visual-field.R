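test_that("pixel-to-degree conversion is an arctangent projection with an exact inverse", {
  g <- perimetry_geometry(viewing_distance = 1, pixel_pitch = 0.3,
                          screen_center_px = c(512, 384))
  ctr <- pixels_to_degrees(c(512, 384), g)
  expect_equal(ctr$azimuth, 0)
  expect_equal(ctr$elevation, 0)

  right <- pixels_to_degrees(c(612, 384), g) # 100 px = 30 mm at 1 m
  expect_equal(right$azimuth, atan(0.030 / 1.0) * 180 / pi, tolerance = 1e-10)
  expect_equal(right$azimuth, 1.718, tolerance = 1e-3)

  set.seed(4)
  pts <- cbind(runif(20, -30, 30), runif(20, -20, 20))
  round_trip <- pixels_to_degrees(as.matrix(degrees_to_pixels(pts, g)), g)
  expect_lt(max(abs(as.matrix(round_trip) - pts)), 1e-9)

  expect_error(pixels_to_degrees(c(NA, 1), g), "finite")
  expect_error(perimetry_geometry(viewing_distance = 0), "viewing_distance")
})

test_that("polygon validation enforces convexity, vertex cap, and CCW order", {
  cw_square <- cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)) # clockwise
  p <- validate_polygon(cw_square)
  n <- nrow(p)
  area2 <- sum(p$azimuth * p$elevation[c(2:n, 1)] - p$azimuth[c(2:n, 1)] * p$elevation)
  expect_gt(area2, 0) # reordered counter-clockwise

  dented <- cbind(c(0, 4, 4, 2, 0), c(0, 0, 4, 1, 4)) # (2,1) is a reflex vertex
  expect_error(validate_polygon(dented), "not convex")

  th <- seq(0, 2 * pi, length.out = 102)[1:101]
  expect_error(validate_polygon(cbind(cos(th), sin(th))), "at most 100")
  th100 <- seq(0, 2 * pi, length.out = 101)[1:100]
  expect_s3_class(validate_polygon(cbind(cos(th100), sin(th100))), "scotoma_polygon")

  expect_error(validate_polygon(cbind(0:1, 0:1)), "at least 3")
})

test_that("vertical chord is a single interval, exact at edges and vertices", {
  sq <- validate_polygon(square_poly(5))
  ch <- vertical_chord(sq, 0)
  expect_equal(ch$lower, -5)
  expect_equal(ch$upper, 5)
  expect_true(is.na(vertical_chord(sq, 6)$lower))

  tri <- validate_polygon(cbind(c(0, 4, 0), c(0, 0, 4)))
  ch2 <- vertical_chord(tri, 2)
  expect_equal(ch2$lower, 0)
  expect_equal(ch2$upper, 2)
})

test_that("chord agrees with a dense point-sampling oracle on random convex polygons", {
  set.seed(11)
  for (i in 1:25) {
    poly <- random_convex_poly()
    v <- validate_polygon(poly)
    xs <- runif(40, min(poly[, 1]) - 1, max(poly[, 1]) + 1)
    ch <- vertical_chord(v, xs)
    ys <- seq(min(poly[, 2]) - 1, max(poly[, 2]) + 1, by = 0.01)
    for (j in seq_along(xs)) {
      m <- as.matrix(v)
      inside <- point_in_poly(rep(xs[j], length(ys)), ys, m)
      if (!any(inside)) {
        # oracle can miss a sliver thinner than its grid
        if (!is.na(ch$lower[j])) expect_lt(ch$upper[j] - ch$lower[j], 0.05)
      } else {
        expect_false(is.na(ch$lower[j]))
        expect_lt(abs(ch$lower[j] - min(ys[inside])), 0.02)
        expect_lt(abs(ch$upper[j] - max(ys[inside])), 0.02)
      }
    }
  }
})

test_that("scotoma size is the mean cardinal diameter and is translation invariant", {
  expect_equal(scotoma_size(square_field(5)), 10)

  th <- seq(0, 2 * pi, length.out = 65)[1:64]
  circ <- visual_field(list(cbind(5 * cos(th), 5 * sin(th))), "circ")
  expect_equal(scotoma_size(circ), 10, tolerance = 0.05 / 10)

  rect <- visual_field(list(cbind(c(-4, 4, 4, -4), c(-2, -2, 2, 2))), "rect")
  expect_equal(scotoma_size(rect), 6)

  shifted <- visual_field(list(cbind(c(-4, 4, 4, -4) + 3.7, c(-2, -2, 2, 2) - 8.1)), "rect2")
  expect_equal(scotoma_size(shifted), scotoma_size(rect))

  multi <- visual_field(list(square_poly(5), square_poly(2, cx = 10)), "multi")
  expect_equal(scotoma_size(multi), 10)
  expect_equal(sort(scotoma_size(multi, per_polygon = TRUE)), c(4, 10))

  expect_error(scotoma_size(visual_field(list(), "nv")), "no scotoma")
})

test_that("fixation stability counts samples inside the criterion circle", {
  same <- cbind(rep(1.3, 10), rep(-0.2, 10))
  expect_equal(fixation_stability(same, 2), 100)

  half <- rbind(cbind(rep(0, 5), rep(0, 5)), cbind(rep(10, 5), rep(0, 5)))
  expect_equal(fixation_stability(half, 2, center = "target", target = c(0, 0)), 50)

  th <- seq(0, 2 * pi, length.out = 33)[1:32]
  ring <- cbind(0.5 * cos(th), 0.5 * sin(th))
  expect_equal(fixation_stability(ring, 2), 100)

  # monotone non-decreasing in diameter
  set.seed(2)
  scatter <- cbind(rnorm(200, 0, 1.5), rnorm(200, 0, 1.5))
  stabs <- vapply(c(1, 2, 3, 4, 6), function(d) fixation_stability(scatter, d), numeric(1))
  expect_true(all(diff(stabs) >= 0))

  expect_error(fixation_stability(cbind(NA_real_, NA_real_), 2), "valid")
})

test_that("gaze accuracy is the mean planar deviation from the intended point", {
  pts <- cbind(rep(3, 8), rep(-1, 8))
  expect_equal(gaze_accuracy(pts, c(3, -1)), 0)
  off <- cbind(rep(0.86, 5), rep(0, 5))
  expect_equal(gaze_accuracy(off, c(0, 0)), 0.86)
  two <- rbind(c(1, 0), c(3, 0))
  expect_equal(gaze_accuracy(two, c(0, 0)), 2)
})

test_that("visual-field JSON round-trips", {
  vf <- visual_field(list(square_poly(5), cbind(c(8, 12, 10), c(0, 0, 4))),
                     "CFL5", prl_note = "two scotomas")
  path <- withr::local_tempfile(fileext = ".json")
  write_visual_field(vf, path)
  back <- read_visual_field(path)
  expect_equal(back$participant_id, "CFL5")
  expect_equal(length(back$polygons), 2)
  expect_equal(as.matrix(back$polygons[[1]]), as.matrix(vf$polygons[[1]]))
  expect_equal(back$prl_note, "two scotomas")
})
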