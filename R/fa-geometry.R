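#' Focal adhesion classification by membrane-edge location and orientation
#'
#' FAs are classified relative to the closest edge of the ventral
#' (adherent) plasma membrane, given as a polyline in um coordinates:
#'
#' * orientation: *pointing* when the angle between the FA long axis and
#'   the local edge tangent is within 30 degrees of perpendicular
#'   (90 +- 30), *parallel* when within 30 degrees of parallel
#'   (180 +- 30, equivalently 0 +- 30 under axial symmetry), *other*
#'   otherwise (excluded from orientation analyses);
#' * location: *outer* when no other FA lies between the FA and its
#'   nearest edge point, *inner* when the segment from the FA centroid to
#'   that point crosses another FA's outline.
#'
#' @name fa_classification
NULL

## ---- geometry primitives (2D, um coordinates) ----

# nearest point on segment ab to point p
nearest_on_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  a + t * ab
}

# nearest point on a polyline (n x 2 matrix); returns point, distance and
# the index of the containing segment
nearest_on_polyline <- function(p, poly) {
  best <- NULL
  best_d <- Inf
  best_seg <- NA_integer_
  for (i in seq_len(nrow(poly) - 1)) {
    q <- nearest_on_segment(p, poly[i, ], poly[i + 1, ])
    d <- sqrt(sum((p - q)^2))
    if (d < best_d) {
      best <- q
      best_d <- d
      best_seg <- i
    }
  }
  list(point = best, distance = best_d, segment = best_seg)
}

# do open segments p1-p2 and p3-p4 properly intersect (shared interior pt)?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1)
  d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3)
  d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  FALSE
}

point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2])) {
      xint <- poly[j, 1] + (p[2] - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# does the open segment a-b cross polygon `poly` (closed, n x 2)?
segment_crosses_polygon <- function(a, b, poly) {
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    if (segments_intersect(a, b, poly[i, ], poly[j, ])) return(TRUE)
  }
  # proper-crossing tests miss grazing contacts (a polygon vertex exactly
  # on the segment) and fully-contained segments; sample interior points
  for (t in seq(0.02, 0.98, length.out = 49)) {
    if (point_in_polygon(a + t * (b - a), poly)) return(TRUE)
  }
  FALSE
}

#' Membrane edge polyline
#'
#' @param points An n x 2 matrix or data frame of (x, y) points in um
#'   tracing the ventral membrane edge; at least 2 points.
#' @return An object of class `membrane_edge`.
#' @export
membrane_edge <- function(points) {
  m <- as.matrix(points)
  stopifnot(ncol(m) == 2, nrow(m) >= 2)
  structure(list(points = unname(m)), class = "membrane_edge")
}

# tangent angle (deg, [0, 180)) of the edge segment nearest to p
edge_tangent_angle <- function(edge, p) {
  np <- nearest_on_polyline(p, edge$points)
  seg <- edge$points[np$segment + 1, ] - edge$points[np$segment, ]
  (atan2(seg[2], seg[1]) * 180 / pi) %% 180
}

#' Orientation class of an FA relative to the local membrane edge
#'
#' Folds both the FA long-axis angle and the edge tangent angle to the
#' axial range \[0, 180) and classifies by the absolute angle between
#' them: pointing when within 30 degrees of perpendicular, parallel when
#' within 30 degrees of parallel, other otherwise.
#'
#' @param theta_fa FA long-axis angle(s), degrees.
#' @param theta_edge Local edge tangent angle(s), degrees.
#' @param band Half-width of the classification bands, degrees
#'   (default 30).
#' @return Character vector: `"pointing"`, `"parallel"` or `"other"`.
#' @examples
#' orientation_class(90, 0)  # perpendicular to the edge
#' orientation_class(10, 0)  # parallel band
#' orientation_class(45, 0)  # other
#' @export
orientation_class <- function(theta_fa, theta_edge, band = 30) {
  phi <- (theta_fa - theta_edge) %% 180
  phi <- pmin(phi, 180 - phi)  # acute angle between the undirected axes
  dplyr::case_when(
    abs(phi - 90) <= band ~ "pointing",
    phi <= band ~ "parallel",
    TRUE ~ "other"
  )
}

#' Expected fraction of FAs excluded under random orientation
#'
#' Under a uniform distribution of long-axis angles on \[0, 180), the
#' pointing band covers 60 degrees and the parallel band 60 degrees, so
#' the remaining "other" measure is 60/180 = 1/3.  Optionally confirmed by
#' Monte Carlo through [orientation_class()].
#'
#' @param n_mc If not `NULL`, also estimate the fraction by classifying
#'   `n_mc` uniform random angles.
#' @param band Band half-width in degrees.
#' @param seed Seed for the Monte Carlo draw.
#' @return The analytic fraction, with the Monte Carlo estimate in the
#'   `mc_estimate` attribute when requested.
#' @export
expected_random_exclusion <- function(n_mc = NULL, band = 30, seed = 1) {
  analytic <- max(0, (180 - 4 * band) / 180)
  if (!is.null(n_mc)) {
    set.seed(seed)
    cls <- orientation_class(runif(n_mc, 0, 180), 0, band = band)
    attr(analytic, "mc_estimate") <- mean(cls == "other")
  }
  analytic
}

#' Distal endpoint of an FA long (or relevant) axis
#'
#' Of the two axis endpoints, returns the one closer to the membrane-edge
#' polyline (the distal side); the opposite endpoint is proximal.  Exactly
#' equidistant endpoints are resolved toward the smaller x coordinate and
#' flagged.
#'
#' @param centroid FA centroid (x, y) in um.
#' @param theta_deg Axis angle in degrees.
#' @param length_um Axis length in um.
#' @param edge A [membrane_edge()].
#' @return A list: `distal`, `proximal` (each (x, y)), `tie` (logical).
#' @export
distal_side <- function(centroid, theta_deg, length_um, edge) {
  u <- c(cos(theta_deg * pi / 180), sin(theta_deg * pi / 180))
  e1 <- centroid + u * length_um / 2
  e2 <- centroid - u * length_um / 2
  d1 <- nearest_on_polyline(e1, edge$points)$distance
  d2 <- nearest_on_polyline(e2, edge$points)$distance
  tie <- isTRUE(all.equal(d1, d2))
  if (tie) {
    # deterministic tie-break: smaller x, then smaller y
    first <- e1[1] < e2[1] || (e1[1] == e2[1] && e1[2] <= e2[2])
    if (first) list(distal = e1, proximal = e2, tie = TRUE)
    else list(distal = e2, proximal = e1, tie = TRUE)
  } else if (d1 < d2) {
    list(distal = e1, proximal = e2, tie = FALSE)
  } else {
    list(distal = e2, proximal = e1, tie = FALSE)
  }
}

#' Location class of an FA: outer or inner
#'
#' Constructs the segment from the FA centroid to its nearest point on the
#' membrane edge; the FA is *inner* iff that (open) segment crosses
#' another FA's outline polygon, *outer* otherwise.
#'
#' @param centroid FA centroid (x, y), um.
#' @param edge A [membrane_edge()].
#' @param other_polygons List of n x 2 outline matrices of the other FAs.
#' @return `"outer"` or `"inner"`.
#' @export
location_class <- function(centroid, edge, other_polygons = list()) {
  np <- nearest_on_polyline(centroid, edge$points)
  for (poly in other_polygons) {
    if (segment_crosses_polygon(centroid, np$point, as.matrix(poly))) {
      return("inner")
    }
  }
  "outer"
}

#' Classify a set of FAs by location and orientation
#'
#' Takes FA outlines and a membrane edge, derives each FA's centroid and
#' axes (from the outline polygon), and classifies every FA.
#'
#' @param fas A tibble with columns `fa_id` and `polygon` (list-column of
#'   n x 2 outline matrices in um), or a list of such matrices.  An
#'   optional `theta_deg` column overrides the polygon-derived axis angle.
#' @param edge A [membrane_edge()].
#' @param band Orientation band half-width, degrees.
#' @return A tibble of class `fa_records`: `fa_id`, `centroid_x`,
#'   `centroid_y`, `theta_deg`, `phi_deg` (angle to local edge tangent,
#'   folded to \[0, 90\]), `major_um`, `minor_um`, `orientation`,
#'   `location`, `distal_x`, `distal_y`, `distal_tie`, and the `polygon`
#'   list-column.
#' @export
classify_fas <- function(fas, edge, band = 30) {
  if (!is.data.frame(fas)) {
    fas <- tibble::tibble(fa_id = as.character(seq_along(fas)), polygon = fas)
  }
  stopifnot(all(c("fa_id", "polygon") %in% names(fas)))
  geom <- purrr::map(fas$polygon, polygon_axes)
  out <- fas
  out$centroid_x <- purrr::map_dbl(geom, ~ .x$centroid[1])
  out$centroid_y <- purrr::map_dbl(geom, ~ .x$centroid[2])
  out$theta_deg <- if ("theta_deg" %in% names(fas)) fas$theta_deg else
    purrr::map_dbl(geom, "theta_deg")
  out$major_um <- purrr::map_dbl(geom, "major")
  out$minor_um <- purrr::map_dbl(geom, "minor")

  n <- nrow(out)
  orientation <- character(n)
  location <- character(n)
  phi <- numeric(n)
  distal <- matrix(NA_real_, n, 2)
  tie <- logical(n)
  for (i in seq_len(n)) {
    ctr <- c(out$centroid_x[i], out$centroid_y[i])
    te <- edge_tangent_angle(edge, ctr)
    ph <- (out$theta_deg[i] - te) %% 180
    phi[i] <- min(ph, 180 - ph)
    degenerate <- is.na(out$major_um[i]) || is.na(out$minor_um[i]) ||
      out$major_um[i] <= out$minor_um[i] + 1e-9
    orientation[i] <- if (degenerate) "other" else
      orientation_class(out$theta_deg[i], te, band = band)
    location[i] <- location_class(ctr, edge,
                                  out$polygon[-i])
    axis_theta <- if (identical(orientation[i], "parallel")) {
      (out$theta_deg[i] + 90) %% 180
    } else {
      out$theta_deg[i]
    }
    axis_len <- if (identical(orientation[i], "parallel")) out$minor_um[i]
      else out$major_um[i]
    ds <- distal_side(ctr, axis_theta, axis_len, edge)
    distal[i, ] <- ds$distal
    tie[i] <- ds$tie
  }
  out$phi_deg <- phi
  out$orientation <- orientation
  out$location <- location
  out$distal_x <- distal[, 1]
  out$distal_y <- distal[, 2]
  out$distal_tie <- tie
  class(out) <- c("fa_records", class(out))
  out
}

# centroid, axis lengths and long-axis angle of a polygon outline
polygon_axes <- function(poly) {
  m <- as.matrix(poly)
  # dense resampling of the outline -> area moments via the shoelace-based
  # covariance of the enclosed region (uniform sampling inside the bbox)
  ctr <- polygon_centroid(m)
  cov <- polygon_covariance(m, ctr)
  eig <- eigen(cov, symmetric = TRUE)
  theta <- (atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi) %% 180
  list(centroid = ctr, theta_deg = theta,
       major = 4 * sqrt(max(eig$values[1], 0)),
       minor = 4 * sqrt(max(eig$values[2], 0)))
}

polygon_area_signed <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1)
  sum(m[, 1] * m[j, 2] - m[j, 1] * m[, 2]) / 2
}

polygon_centroid <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1)
  cr <- m[, 1] * m[j, 2] - m[j, 1] * m[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(m))
  c(sum((m[, 1] + m[j, 1]) * cr) / (6 * a),
    sum((m[, 2] + m[j, 2]) * cr) / (6 * a))
}

# exact second-order area moments of a polygon about `ctr`
polygon_covariance <- function(m, ctr) {
  m <- sweep(m, 2, ctr)
  n <- nrow(m)
  j <- c(2:n, 1)
  x0 <- m[, 1]; y0 <- m[, 2]; x1 <- m[j, 1]; y1 <- m[j, 2]
  cr <- x0 * y1 - x1 * y0
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    return(stats::cov(m))
  }
  ixx <- sum(cr * (y0^2 + y0 * y1 + y1^2)) / 12
  iyy <- sum(cr * (x0^2 + x0 * x1 + x1^2)) / 12
  ixy <- sum(cr * (x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0)) / 24
  matrix(c(iyy, ixy, ixy, ixx), 2, 2) / a
}

#' Write an FA classification table as CSV
#'
#' @param records A [classify_fas()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fa_classification <- function(records, path) {
  cols <- c("fa_id", "theta_deg", "phi_deg", "orientation", "location",
            "distal_x", "distal_y")
  write.csv(as.data.frame(records)[, cols], path, row.names = FALSE)
  invisible(path)
}
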