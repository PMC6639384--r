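#' Photoconversion image stack
#'
#' A photoconversion experiment acquires the green and red channel at three
#' time points: before conversion (`t_pre`), immediately after converting a
#' small region with 405 nm light (`t_0`), and three minutes later
#' (`t_post`), with two frames per channel and time point.  Frames are kept
#' unregistered (registration is out of scope) and averaged per time point
#' before any ratio is formed.
#'
#' @param green_pre,red_pre,green_t0,red_t0,green_post,red_post Numeric
#'   h x w matrices (one frame) or h x w x 2 arrays (two frames).
#' @param pixel_size Pixel size in um.
#' @param t_interval Nominal `t_post - t_0` interval in seconds (recorded
#'   metadata; default 180).
#' @return An object of class `photoconv_stack`.
#' @export
photoconv_stack <- function(green_pre, red_pre, green_t0, red_t0,
                            green_post, red_post, pixel_size,
                            t_interval = 180) {
  frames <- list(green_pre = green_pre, red_pre = red_pre,
                 green_t0 = green_t0, red_t0 = red_t0,
                 green_post = green_post, red_post = red_post)
  frames <- lapply(frames, function(f) {
    if (is.matrix(f)) f <- array(f, dim = c(dim(f), 1))
    stopifnot(length(dim(f)) == 3)
    f
  })
  dims <- unique(lapply(frames, function(f) dim(f)[1:2]))
  if (length(dims) != 1) {
    rlang::abort("all frames must be registered to the same shape")
  }
  stopifnot(pixel_size > 0)
  structure(c(frames, list(pixel_size = pixel_size,
                           t_interval = t_interval)),
            class = "photoconv_stack")
}

#' @export
print.photoconv_stack <- function(x, ...) {
  d <- dim(x$green_pre)
  cat("<photoconv_stack>", d[1], "x", d[2], "px,", d[3],
      "frame(s)/timepoint,", x$pixel_size, "um/px\n")
  invisible(x)
}

avg_frames <- function(f) {
  apply(f, c(1, 2), mean)
}

#' Ratio-view image of retained converted signal
#'
#' Forms the per-pixel 'ratio view' (RV) image
#' `RV = I_avg,red,post / I_avg,red,t0` (frames averaged per time point).
#' A high ratio means converted (red) protein was retained over the chase
#' interval, i.e. stably bound protein; a low ratio means the converted
#' protein exchanged with the unconverted pool.  The ratio is only defined
#' on pixels that at `t_pre` in the green channel exceed a
#' background-dependent preselection threshold (background median +
#' `preselect_k` x MAD), which reliably selects FAs; the FA mask itself
#' comes from the moment-preserving threshold of the averaged green
#' `t_pre` image.
#'
#' @param stack A [photoconv_stack()].
#' @param preselect_k MAD multiplier of the green preselection threshold.
#' @param subtract_background If `TRUE`, subtract the red-channel
#'   background median from both ratio terms first (default off; the ratio
#'   is formed on raw red intensities).
#' @param saturation_level Pixels at or above this value in any averaged
#'   channel are treated as saturated and excluded (default `Inf`).
#' @return An object of class `ratio_view`: `ratio` (matrix, `NA` where
#'   undefined), `fa_mask` (logical), `green_threshold`,
#'   `preselect_threshold`, `pixel_size`, and an `audit` list (pixels
#'   excluded for zero denominators or saturation).
#' @export
ratio_view <- function(stack, preselect_k = 6, subtract_background = FALSE,
                       saturation_level = Inf) {
  g_pre <- avg_frames(stack$green_pre)
  r_t0 <- avg_frames(stack$red_t0)
  r_post <- avg_frames(stack$red_post)

  thr <- moments_threshold(g_pre)
  fa_mask <- if (is.na(thr)) {
    matrix(FALSE, nrow(g_pre), ncol(g_pre))
  } else {
    g_pre > thr
  }
  bg_px <- g_pre[!fa_mask]
  pre_thr <- if (length(bg_px) > 1) {
    median(bg_px) + preselect_k * stats::mad(bg_px)
  } else {
    -Inf
  }
  defined <- g_pre > pre_thr

  num <- r_post
  den <- r_t0
  if (subtract_background) {
    r_bg <- median(r_t0[!fa_mask])
    num <- num - r_bg
    den <- den - r_bg
  }
  saturated <- g_pre >= saturation_level | r_t0 >= saturation_level |
    r_post >= saturation_level
  zero_den <- defined & den <= 0
  ok <- defined & !saturated & den > 0
  ratio <- matrix(NA_real_, nrow(g_pre), ncol(g_pre))
  ratio[ok] <- pmax(num[ok] / den[ok], 0)

  structure(
    list(ratio = ratio, fa_mask = fa_mask & ok, green_threshold = thr,
         preselect_threshold = pre_thr, pixel_size = stack$pixel_size,
         audit = list(n_zero_denominator = sum(zero_den),
                      n_saturated = sum(saturated & defined))),
    class = "ratio_view"
  )
}

#' @export
print.ratio_view <- function(x, ...) {
  cat("<ratio_view>", sum(x$fa_mask), "FA pixels,",
      "median ratio", round(median(x$ratio[x$fa_mask]), 3), "\n")
  invisible(x)
}

#' Detect stably bound areas in a ratio-view image
#'
#' Differentiates stably from dynamically bound areas by applying the same
#' dynamic (moment-preserving) threshold to the RV values within the FA
#' mask, grouping above-threshold pixels by 8-connectivity, and keeping
#' components covering at least `min_area` um^2 (inclusive; default
#' 0.05 um^2).  Everything else in the FA is labelled dynamic.
#'
#' Because the moment-preserving rule always splits a histogram, a
#' separation guard decides whether the mask actually contains two ratio
#' populations: the split is accepted only when its between-class variance
#' exceeds `min_separation` of the total variance (Otsu's effectiveness
#' measure).  An effectively unimodal mask - e.g. a chemically fixed
#' control where the converted protein is retained everywhere - is
#' labelled entirely stable.
#'
#' @param rv A [ratio_view()].
#' @param min_area Minimum stable-area size in um^2 (inclusive).
#' @param min_separation Minimum Otsu effectiveness of the RV split in
#'   \[0, 1\]; below it the whole mask is treated as one stable class.
#' @param threshold Optional fixed threshold overriding the recomputed
#'   moments threshold (e.g. to reuse the green-channel level).
#' @return A tibble of class `stable_areas` with one row per stable area:
#'   `area_id`, `n_px`, `area_um2`, `centroid_x`, `centroid_y` (um).
#'   Attributes: `labels` (integer matrix; 0 = background/dynamic),
#'   `threshold`, `split_accepted`, `fa_mask`, `pixel_size`.
#' @export
detect_stable_areas <- function(rv, min_area = 0.05, min_separation = 0.75,
                                threshold = NULL) {
  px2 <- rv$pixel_size^2
  vals <- rv$ratio[rv$fa_mask]
  empty <- tibble::tibble(area_id = integer(0), n_px = integer(0),
                          area_um2 = numeric(0), centroid_x = numeric(0),
                          centroid_y = numeric(0))
  if (length(vals) == 0) {
    out <- empty
    attr(out, "labels") <- matrix(0L, nrow(rv$ratio), ncol(rv$ratio))
    attr(out, "threshold") <- NA_real_
    attr(out, "split_accepted") <- FALSE
    attr(out, "fa_mask") <- rv$fa_mask
    attr(out, "pixel_size") <- rv$pixel_size
    class(out) <- c("stable_areas", class(out))
    return(out)
  }
  thr <- threshold %||% moments_threshold(vals)
  split_accepted <- FALSE
  if (!is.na(thr) && any(vals > thr) && any(vals <= thr)) {
    hi <- vals[vals > thr]
    lo <- vals[vals <= thr]
    w1 <- length(hi) / length(vals)
    w0 <- 1 - w1
    between <- w0 * w1 * (mean(hi) - mean(lo))^2
    total <- stats::var(vals) * (length(vals) - 1) / length(vals)
    split_accepted <- total > 0 && between / total >= min_separation
  }
  stable_mask <- rv$fa_mask
  if (split_accepted) {
    stable_mask <- rv$fa_mask & !is.na(rv$ratio) & rv$ratio > thr
  }
  lab <- label_components(stable_mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * px2 >= min_area - 1e-12)
  relab <- matrix(0L, nrow(lab), ncol(lab))
  rows <- list()
  for (k in seq_along(keep)) {
    px <- which(lab == keep[k], arr.ind = TRUE)
    relab[lab == keep[k]] <- k
    rows[[k]] <- tibble::tibble(
      area_id = k, n_px = nrow(px),
      area_um2 = nrow(px) * px2,
      centroid_x = mean(px[, 2]) * rv$pixel_size,
      centroid_y = mean(px[, 1]) * rv$pixel_size
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  attr(out, "labels") <- relab
  attr(out, "threshold") <- if (split_accepted) thr else NA_real_
  attr(out, "split_accepted") <- split_accepted
  attr(out, "fa_mask") <- rv$fa_mask
  attr(out, "pixel_size") <- rv$pixel_size
  class(out) <- c("stable_areas", class(out))
  out
}

#' Area-weighted centre of the stably bound areas along the FA axis
#'
#' Projects the area-weighted mean of the stable-area centroids onto the
#' FA axis that runs from the distal end (the end nearest the ventral
#' membrane edge, position 0) to the proximal end (position 1): the major
#' axis for pointing FAs, the minor axis for parallel FAs.  Values above
#' 0.5 place the stably bound material in the proximal FA half.
#'
#' @param areas A [detect_stable_areas()] tibble.
#' @param fa An FA record: list or one-row data frame with `centroid_x`,
#'   `centroid_y`, `theta_deg`, `major_um`, `minor_um`, `orientation`
#'   (`"pointing"`/`"parallel"`), and the distal endpoint `distal_x`,
#'   `distal_y` (see [classify_fas()]).
#' @return The relative position in \[0, 1\], or `NA` (with a warning) when
#'   there are no stable areas.
#' @export
weighted_centre <- function(areas, fa) {
  fa <- as.list(fa)
  if (nrow(areas) == 0) {
    rlang::warn("no stable areas: weighted centre undefined, FA excluded")
    return(NA_real_)
  }
  cx <- sum(areas$centroid_x * areas$area_um2) / sum(areas$area_um2)
  cy <- sum(areas$centroid_y * areas$area_um2) / sum(areas$area_um2)
  orient <- fa$orientation %||% "pointing"
  axis_len <- if (identical(orient, "parallel")) fa$minor_um else fa$major_um
  d <- c(fa$distal_x, fa$distal_y)
  ctr <- c(fa$centroid_x, fa$centroid_y)
  u <- (ctr - d) / sqrt(sum((ctr - d)^2))  # distal -> proximal direction
  sum((c(cx, cy) - d) * u) / axis_len
}

#' Stable-area coverage statistics of one FA
#'
#' @param areas A [detect_stable_areas()] tibble.
#' @param fa_mask Optional logical FA mask; defaults to the mask stored in
#'   `areas`.
#' @return A tibble: `n_areas`, `summed_area_um2`, `fa_area_um2`,
#'   `coverage_ratio` (summed stable area over FA area, in \[0, 1\]), and
#'   the individual sizes in the list-column `area_sizes_um2`.
#' @export
coverage_stats <- function(areas, fa_mask = NULL) {
  fa_mask <- fa_mask %||% attr(areas, "fa_mask")
  px2 <- attr(areas, "pixel_size")^2
  fa_area <- sum(fa_mask) * px2
  if (fa_area <= 0) rlang::abort("FA mask area must be positive")
  summed <- sum(areas$area_um2)
  tibble::tibble(
    n_areas = nrow(areas),
    summed_area_um2 = summed,
    fa_area_um2 = fa_area,
    coverage_ratio = summed / fa_area,
    area_sizes_um2 = list(areas$area_um2)
  )
}
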