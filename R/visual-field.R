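# Visual fields: binocular scotomas mapped by kinetic perimetry, expressed in
# degrees of visual angle with the preferred retinal locus (PRL) at the origin.
# Each scotoma is a convex polygon (<= 100 vertices); a field holds zero or
# more polygons treated as a union. Boundary points count as inside (closed-set
# convention, used everywhere in the package).

MAX_POLY_VERTICES <- 100L

#' Validate a candidate scotoma polygon
#'
#' Checks that a vertex list describes a convex, non-self-intersecting polygon
#' with at most 100 vertices, and returns it with vertices ordered
#' counter-clockwise. Perimetry-mapped scotomas are modelled as convex
#' polygons; convexity is what makes the vertical-chord geometry of
#' [vertical_chord()] a single interval.
#'
#' @param vertices A two-column matrix or data frame of vertex coordinates:
#'   azimuth (degrees, positive right) and elevation (degrees, positive up).
#'   At least 3 vertices.
#' @return A tibble with columns `azimuth`, `elevation`, vertices in
#'   counter-clockwise order, classed `scotoma_polygon`.
#' @examples
#' sq <- validate_polygon(cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)))
#' scotoma_size_polygon(sq)
#' @export
validate_polygon <- function(vertices) {
  v <- as.matrix(as.data.frame(vertices))
  if (ncol(v) < 2L) abort("polygon vertices need two columns (azimuth, elevation)")
  v <- unname(v[, 1:2, drop = FALSE])
  storage.mode(v) <- "double"
  if (!all(is.finite(v))) abort("polygon vertices must be finite")
  n <- nrow(v)
  if (n < 3L) abort("a polygon needs at least 3 vertices")
  if (n > MAX_POLY_VERTICES) {
    abort(sprintf("polygon has %d vertices; at most %d are allowed", n, MAX_POLY_VERTICES))
  }
  if (any(abs(v[, 1]) > 180) || any(abs(v[, 2]) > 90)) {
    abort("vertex angles out of range: azimuth within [-180, 180], elevation within [-90, 90]")
  }
  # signed area; negative => clockwise input, reorder
  nxt <- c(2:n, 1L)
  area2 <- sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])
  if (abs(area2) < 1e-12) abort("polygon is degenerate (zero area)")
  if (area2 < 0) v <- v[n:1, , drop = FALSE]
  # convexity: every cross product of consecutive edges must be >= 0 (CCW)
  prv <- c(n, 1:(n - 1L))
  nxt <- c(2:n, 1L)
  ex1 <- v[, 1] - v[prv, 1]; ey1 <- v[, 2] - v[prv, 2]
  ex2 <- v[nxt, 1] - v[, 1]; ey2 <- v[nxt, 2] - v[, 2]
  cross <- ex1 * ey2 - ey1 * ex2
  tol <- -1e-9 * max(abs(v))
  bad <- which(cross < tol)
  if (length(bad) > 0L) {
    abort(sprintf(
      "polygon is not convex: reflex angle at vertex %d (azimuth %.3f, elevation %.3f)",
      bad[1], v[bad[1], 1], v[bad[1], 2]
    ))
  }
  out <- tibble::tibble(azimuth = v[, 1], elevation = v[, 2])
  class(out) <- c("scotoma_polygon", class(out))
  out
}

#' Construct a binocular visual field
#'
#' A visual field is a set of convex scotoma polygons in PRL-centred degrees.
#' Multiple scotomas are allowed and treated as a union when scoring
#' occlusion; an empty polygon list represents a normal-vision field.
#'
#' @param polygons List of polygons (each passed through [validate_polygon()]).
#' @param participant_id Participant label.
#' @param prl_note Optional free-text note about the PRL (e.g. scotoma above
#'   or below fixation).
#' @return An object of class `visual_field`.
#' @examples
#' vf <- visual_field(list(cbind(c(-5, 5, 5, -5), c(3, 3, 13, 13))), "CFL1")
#' scotoma_size(vf)
#' @export
visual_field <- function(polygons = list(), participant_id = "unknown", prl_note = NULL) {
  stopifnot(is.list(polygons))
  polys <- lapply(polygons, function(p) {
    if (inherits(p, "scotoma_polygon")) p else validate_polygon(p)
  })
  structure(
    list(
      participant_id = as.character(participant_id),
      polygons = polys,
      prl_note = prl_note
    ),
    class = "visual_field"
  )
}

#' @export
print.visual_field <- function(x, ...) {
  cat(sprintf(
    "<visual_field> participant %s: %d scotoma polygon(s)\n",
    x$participant_id, length(x$polygons)
  ))
  if (length(x$polygons) > 0) {
    sz <- scotoma_size(x)
    cat(sprintf("  size (largest polygon, mean cardinal diameter): %.2f deg\n", sz))
  }
  if (!is.null(x$prl_note)) cat("  PRL note:", x$prl_note, "\n")
  invisible(x)
}

#' Intersection of a vertical line with a convex scotoma polygon
#'
#' For a convex polygon the vertical line at a given azimuth meets the
#' interior in at most one closed elevation interval. This chord is the
#' geometric primitive behind occlusion scoring: a pedestrian is modelled as
#' a vertical angular segment, and the occluded part of that segment is its
#' intersection with the chord.
#'
#' @param poly A `scotoma_polygon`.
#' @param x Azimuth (degrees) of the vertical line. May be a vector.
#' @return A tibble with columns `azimuth`, `lower`, `upper`; rows where the
#'   line misses the polygon have `NA` bounds.
#' @export
vertical_chord <- function(poly, x) {
  if (!inherits(poly, "scotoma_polygon")) poly <- validate_polygon(poly)
  b <- chord_bounds(poly, x)
  tibble::tibble(azimuth = x, lower = b$lower, upper = b$upper)
}

# Vectorised chord computation: for each x return the elevation interval
# [lower, upper] of the vertical line's intersection with the convex polygon,
# NA when the line misses it. Endpoints are exact at vertices (interpolation
# with t in {0,1} is exact).
chord_bounds <- function(poly, x) {
  px <- poly$azimuth
  py <- poly$elevation
  n <- length(px)
  nxt <- c(2:n, 1L)
  x1 <- px; y1 <- py; x2 <- px[nxt]; y2 <- py[nxt]
  m <- length(x)
  lower <- rep(NA_real_, m)
  upper <- rep(NA_real_, m)
  for (e in seq_len(n)) {
    xa <- x1[e]; xb <- x2[e]; ya <- y1[e]; yb <- y2[e]
    if (xa == xb) {
      hit <- !is.na(x) & x == xa
      if (any(hit)) {
        lo <- min(ya, yb); hi <- max(ya, yb)
        lower[hit] <- pmin(lower[hit], lo, na.rm = TRUE)
        upper[hit] <- pmax(upper[hit], hi, na.rm = TRUE)
      }
    } else {
      lo <- pmin(xa, xb); hi <- pmax(xa, xb)
      hit <- !is.na(x) & x >= lo & x <= hi
      if (any(hit)) {
        t <- (x[hit] - xa) / (xb - xa)
        yy <- ya + t * (yb - ya)
        lower[hit] <- pmin(lower[hit], yy, na.rm = TRUE)
        upper[hit] <- pmax(upper[hit], yy, na.rm = TRUE)
      }
    }
  }
  list(lower = lower, upper = upper)
}

# Mean cardinal diameter of one polygon: centre = vertex centroid, diameter =
# mean of the horizontal and vertical chords through the centre.
#' @rdname scotoma_size
#' @export
scotoma_size_polygon <- function(poly) {
  if (!inherits(poly, "scotoma_polygon")) poly <- validate_polygon(poly)
  cx <- mean(poly$azimuth)
  cy <- mean(poly$elevation)
  v <- chord_bounds(poly, cx)
  vlen <- v$upper - v$lower
  # horizontal chord: same computation on the transposed polygon
  tpoly <- poly
  tpoly$azimuth <- poly$elevation
  tpoly$elevation <- poly$azimuth
  h <- chord_bounds(tpoly, cy)
  hlen <- h$upper - h$lower
  if (is.na(vlen) || is.na(hlen)) abort("polygon centroid fell outside the polygon; cannot measure size")
  (vlen + hlen) / 2
}

#' Scotoma size of a visual field
#'
#' Size of one scotoma is the mean of its horizontal and vertical chord
#' lengths through the vertex centroid (the average diameter along the
#' cardinal meridians). For a field with several scotomas the field-level
#' value is the size of the largest polygon; per-polygon sizes are available
#' via `per_polygon = TRUE`.
#'
#' @param field A `visual_field` with at least one polygon.
#' @param per_polygon If `TRUE` return the vector of per-polygon sizes.
#' @return Degrees (scalar, or vector when `per_polygon`).
#' @export
scotoma_size <- function(field, per_polygon = FALSE) {
  stopifnot(inherits(field, "visual_field"))
  if (length(field$polygons) == 0L) abort("visual field has no scotoma polygons")
  sizes <- vapply(field$polygons, scotoma_size_polygon, numeric(1))
  if (per_polygon) sizes else max(sizes)
}

#' Perimetry screen geometry
#'
#' Geometry of the computerised perimetry display used to map scotomas:
#' targets on a screen viewed from a fixed distance, with pixel positions
#' converted to visual angles by arctangent projection. Defaults match a
#' 0.74 deg square target and 1.23 deg fixation cross viewed binocularly
#' from 1 m.
#'
#' @param viewing_distance Metres from eye to screen (> 0).
#' @param pixel_pitch Millimetres per pixel (> 0).
#' @param screen_center_px Length-2 pixel coordinates of the screen centre.
#' @param target_size_deg,fixation_cross_deg Stimulus sizes in degrees.
#' @return A list of class `perimetry_geometry`.
#' @export
perimetry_geometry <- function(viewing_distance = 1.0,
                               pixel_pitch = 0.3,
                               screen_center_px = c(512, 384),
                               target_size_deg = 0.74,
                               fixation_cross_deg = 1.23) {
  if (!is.finite(viewing_distance) || viewing_distance <= 0) abort("viewing_distance must be > 0")
  if (!is.finite(pixel_pitch) || pixel_pitch <= 0) abort("pixel_pitch must be > 0")
  structure(
    list(
      viewing_distance = viewing_distance,
      pixel_pitch = pixel_pitch,
      screen_center_px = as.numeric(screen_center_px),
      target_size_deg = target_size_deg,
      fixation_cross_deg = fixation_cross_deg
    ),
    class = "perimetry_geometry"
  )
}

#' Convert perimetry pixel coordinates to visual angles
#'
#' Arctangent projection of the pixel offset from the screen centre at the
#' viewing distance. Horizontal pixels increase rightwards and vertical
#' pixels increase upwards in this convention. [degrees_to_pixels()] is the
#' exact inverse.
#'
#' @param p Pixel coordinates: a length-2 vector or an n-by-2 matrix /
#'   data frame (columns x, y).
#' @param g A [perimetry_geometry()].
#' @return A tibble with columns `azimuth`, `elevation` in degrees.
#' @examples
#' g <- perimetry_geometry(viewing_distance = 1, pixel_pitch = 0.3)
#' pixels_to_degrees(c(612, 384), g) # 100 px right of centre -> 1.718 deg
#' @export
pixels_to_degrees <- function(p, g) {
  stopifnot(inherits(g, "perimetry_geometry"))
  p <- to_xy_matrix(p)
  if (!all(is.finite(p))) abort("pixel coordinates must be finite")
  dx_m <- (p[, 1] - g$screen_center_px[1]) * g$pixel_pitch / 1000
  dy_m <- (p[, 2] - g$screen_center_px[2]) * g$pixel_pitch / 1000
  tibble::tibble(
    azimuth = atan(dx_m / g$viewing_distance) * 180 / pi,
    elevation = atan(dy_m / g$viewing_distance) * 180 / pi
  )
}

#' @rdname pixels_to_degrees
#' @param a Angular coordinates: length-2 vector or n-by-2 matrix / data
#'   frame (columns azimuth, elevation in degrees).
#' @export
degrees_to_pixels <- function(a, g) {
  stopifnot(inherits(g, "perimetry_geometry"))
  a <- to_xy_matrix(a)
  if (!all(is.finite(a))) abort("angles must be finite")
  dx_m <- tan(a[, 1] * pi / 180) * g$viewing_distance
  dy_m <- tan(a[, 2] * pi / 180) * g$viewing_distance
  tibble::tibble(
    x = g$screen_center_px[1] + dx_m * 1000 / g$pixel_pitch,
    y = g$screen_center_px[2] + dy_m * 1000 / g$pixel_pitch
  )
}

to_xy_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) abort("expected a length-2 coordinate or an n-by-2 table")
    matrix(as.numeric(p), ncol = 2)
  } else {
    m <- as.matrix(as.data.frame(p))[, 1:2, drop = FALSE]
    storage.mode(m) <- "double"
    unname(m)
  }
}

#' Fixation stability
#'
#' Percentage of fixation samples falling within a circle of the given
#' diameter. By default the circle is centred on the sample centroid, which
#' is robust to a constant calibration offset; set `center = "target"` (with
#' `target`) to centre it on the fixation target instead. Points exactly on
#' the circle count as inside.
#'
#' @param samples Data frame / matrix of gaze samples with azimuth and
#'   elevation columns (degrees). Rows with missing values are dropped.
#' @param diameter Criterion circle diameter in degrees (> 0); clinically 2
#'   and 4 degrees are reported.
#' @param center `"centroid"` (default) or `"target"`.
#' @param target Length-2 target location, required when `center = "target"`.
#' @return Percentage in \[0, 100\].
#' @export
fixation_stability <- function(samples, diameter, center = c("centroid", "target"),
                               target = c(0, 0)) {
  center <- match.arg(center)
  if (!is.finite(diameter) || diameter <= 0) abort("diameter must be > 0")
  m <- to_xy_matrix(samples)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L) abort("no valid fixation samples")
  ctr <- if (center == "centroid") colMeans(m) else as.numeric(target)
  r <- sqrt((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2)
  100 * mean(r <= diameter / 2 + 1e-12)
}

#' Gaze-tracking accuracy
#'
#' Mean angular deviation (planar Euclidean, in degrees) of measured gaze
#' samples from the intended gaze point — the conservative accuracy measure
#' used to characterise tracker performance at different screen positions.
#'
#' @param measured Data frame / matrix of measured gaze (azimuth, elevation).
#' @param intended Length-2 intended gaze point.
#' @return Mean deviation in degrees.
#' @export
gaze_accuracy <- function(measured, intended) {
  m <- to_xy_matrix(measured)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) == 0L) abort("no valid gaze samples")
  intended <- as.numeric(intended)
  mean(sqrt((m[, 1] - intended[1])^2 + (m[, 2] - intended[2])^2))
}

#' Read / write visual-field files
#'
#' Visual fields are stored as JSON with fields `participant_id`, `polygons`
#' (a list of lists of `[azimuth_deg, elevation_deg]` vertex pairs) and an
#' optional `prl_note`. The PRL is implicitly the origin.
#'
#' @param path File path.
#' @return `read_visual_field()` returns a `visual_field`.
#' @export
read_visual_field <- function(path) {
  if (!file.exists(path)) abort(sprintf("visual-field file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- j$polygons
  if (is.null(polys)) polys <- list()
  visual_field(
    polygons = lapply(polys, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    }),
    participant_id = j$participant_id %||% "unknown",
    prl_note = j$prl_note
  )
}

#' @rdname read_visual_field
#' @param field A `visual_field`.
#' @export
write_visual_field <- function(field, path) {
  stopifnot(inherits(field, "visual_field"))
  obj <- list(
    participant_id = field$participant_id,
    polygons = lapply(field$polygons, function(p) unname(as.matrix(p)))
  )
  if (!is.null(field$prl_note)) obj$prl_note <- field$prl_note
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a visual field
#'
#' Draws the scotoma polygons on the PRL-centred visual-field plane, the way
#' binocular field plots are conventionally presented (PRL at the origin,
#' azimuth positive rightwards).
#'
#' @param field A `visual_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_visual_field <- function(field, ...) {
  stopifnot(inherits(field, "visual_field"))
  df <- purrr::imap_dfr(field$polygons, function(p, i) {
    tibble::tibble(polygon = factor(i), azimuth = p$azimuth, elevation = p$elevation)
  })
  gg <- ggplot2::ggplot()
  if (nrow(df) > 0) {
    gg <- gg + ggplot2::geom_polygon(
      data = df,
      ggplot2::aes(x = .data$azimuth, y = .data$elevation, group = .data$polygon),
      fill = "grey30", alpha = 0.6, colour = "black"
    )
  }
  gg +
    ggplot2::geom_point(data = tibble::tibble(x = 0, y = 0),
                        ggplot2::aes(x = .data$x, y = .data$y), shape = 3, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Visual field: %s", field$participant_id),
      x = "Azimuth (deg, PRL at origin)", y = "Elevation (deg)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.visual_field <- function(object, ...) plot_visual_field(object, ...)
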