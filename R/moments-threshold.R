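#' Moment-preserving (Tsai) bilevel threshold
#'
#' Computes the classic moment-preserving threshold: the image histogram is
#' replaced by a two-level distribution that preserves its first three
#' moments, and the threshold is placed at the p0-tile of the histogram,
#' where p0 is the below-level fraction of the moment-preserving bilevel
#' fit.  This is the "moments" dynamic threshold of the common
#' image-analysis toolkits, reimplemented on a 256-bin histogram so it
#' applies to arbitrary numeric images.
#'
#' The returned value is the upper edge of the selected histogram bin, so
#' the foreground is `x > threshold`.  Deterministic: identical input gives
#' an identical threshold.
#'
#' @param x Numeric vector, matrix or array of pixel values (NAs dropped).
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value, or `NA` for a constant region (a constant
#'   region has no foreground).
#' @examples
#' moments_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
moments_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) return(NA_real_)  # constant region: all background
  # histogram over [lo, hi]
  idx <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1)
  p <- tabulate(idx + 1L, nbins = n_bins) / length(v)
  mids <- seq_len(n_bins) - 1  # work on the bin index scale
  m1 <- sum(mids * p)
  m2 <- sum(mids^2 * p)
  m3 <- sum(mids^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) return(NA_real_)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  if (z1 == z0) return(NA_real_)
  p0 <- (z1 - m1) / (z1 - z0)  # fraction of pixels at/below threshold
  cum <- cumsum(p)
  bin <- which(cum >= p0 - 1e-12)[1]
  if (is.na(bin)) bin <- n_bins
  # upper edge of the selected bin, mapped back to the data scale
  lo + bin / n_bins * (hi - lo)
}

#' 8-connected component labelling of a binary mask
#'
#' Labels the connected foreground components of a logical matrix using
#' 8-connectivity (the particle-analysis convention: diagonal neighbours
#' belong to the same particle).
#'
#' @param mask Logical matrix.
#' @return An integer matrix of the same shape: 0 for background, 1..k for
#'   the k components.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  mask[is.na(mask)] <- FALSE
  nxt <- 0L
  # flood fill with an explicit stack; images here are small
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      stack <- matrix(c(i, j), ncol = 2)
      lab[i, j] <- nxt
      while (nrow(stack) > 0) {
        cur <- stack[nrow(stack), ]
        stack <- stack[-nrow(stack), , drop = FALSE]
        for (di in -1:1) {
          for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            ii <- cur[1] + di
            jj <- cur[2] + dj
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
            if (mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- nxt
              stack <- rbind(stack, c(ii, jj))
            }
          }
        }
      }
    }
  }
  lab
}

#' Second-order moments of a binary mask: centroid, axes, orientation
#'
#' Fits the equivalent ellipse of a pixel mask from its image moments.
#' Coordinates are in pixel units with x along columns and y along rows
#' (row r, column c maps to x = c, y = r).
#'
#' @param mask Logical matrix.
#' @return A list: `centroid` (x, y in pixels), `theta_deg` (long-axis
#'   angle in \[0, 180) measured counterclockwise from +x), `major`,
#'   `minor` (full axis lengths, pixels), `area_px`.
#' @export
mask_moments <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) {
    return(list(centroid = c(NA, NA), theta_deg = NA_real_, major = NA_real_,
                minor = NA_real_, area_px = 0L))
  }
  x <- idx[, 2]
  y <- idx[, 1]
  cx <- mean(x)
  cy <- mean(y)
  # + 1/12: variance of the unit pixel itself
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  theta <- atan2(2 * mxy, mxx - myy) / 2  # [-pi/2, pi/2]
  theta_deg <- (theta * 180 / pi) %% 180
  list(centroid = c(cx, cy), theta_deg = theta_deg,
       major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)), area_px = n)
}
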