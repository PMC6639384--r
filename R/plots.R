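#' Plot a simulated or measured FRAP curve
#'
#' @param object A `frap_curve` tibble from [simulate_frap()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot frap_curve
#' @export
autoplot.frap_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$normalized)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(object, "bleach_times"),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (s)", y = "normalized FA intensity") +
    ggplot2::theme_classic()
}

#' Plot a ratio-view image
#'
#' Displays the per-pixel retained-signal ratio on the FA mask with a
#' fire-like palette: dark = low ratio (dynamically bound), bright = high
#' ratio (stably bound).
#'
#' @param object A [ratio_view()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_view
#' @export
autoplot.ratio_view <- function(object, ...) {
  idx <- which(!is.na(object$ratio), arr.ind = TRUE)
  df <- tibble::tibble(
    x = idx[, 2] * object$pixel_size,
    y = idx[, 1] * object$pixel_size,
    ratio = object$ratio[idx]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$ratio)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("black", "purple4", "red3", "orange", "yellow", "white")
    ) +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "RV") +
    ggplot2::theme_classic()
}

#' Rotated stable-area plot of one FA
#'
#' Draws the FA with its stably bound areas in red and the rest in green,
#' rotated to the common comparison frame: the distal side (nearest the
#' ventral membrane edge) on the left, pointing FAs with their long axis
#' horizontal, parallel FAs with their long axis vertical.  Unclassified
#' FAs are plotted unrotated with a warning.
#'
#' @param fa FA record (see [weighted_centre()]).
#' @param areas A [detect_stable_areas()] tibble.
#' @param rv The [ratio_view()] the areas were detected in.
#' @return A ggplot.
#' @export
rotated_plot <- function(fa, areas, rv) {
  fa <- as.list(fa)
  labels <- attr(areas, "labels")
  mask <- attr(areas, "fa_mask")
  idx <- which(mask, arr.ind = TRUE)
  px <- rv$pixel_size
  pts <- cbind(idx[, 2] * px, idx[, 1] * px)
  stable <- labels[mask] > 0

  orient <- fa$orientation %||% "other"
  if (!orient %in% c("pointing", "parallel")) {
    rlang::warn("FA not classified as pointing/parallel: plotted unrotated")
    rot <- pts
  } else {
    ctr <- c(fa$centroid_x, fa$centroid_y)
    # angle of the distal->proximal axis in the image frame
    d <- c(fa$distal_x, fa$distal_y)
    u <- ctr - d
    ang <- atan2(u[2], u[1])
    # rotate so that distal->proximal becomes +x (distal on the left)
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    rot <- sweep(pts, 2, ctr) %*% t(R)
    if (identical(orient, "parallel")) {
      # long axis should be vertical: it already is, since the rotation
      # put the (minor) distal->proximal axis on x
    }
  }
  df <- tibble::tibble(x = rot[, 1], y = rot[, 2],
                       fraction = ifelse(stable, "stable", "dynamic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile(width = px, height = px) +
    ggplot2::scale_fill_manual(values = c(stable = "red3",
                                          dynamic = "green4")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "distal → proximal (um)", y = "(um)") +
    ggplot2::theme_classic()
}

#' Cohort bar chart of fitted fraction sizes
#'
#' Mean stably bound, dynamically bound and mobile fractions per group
#' with 2 x SEM error bars.
#'
#' @param summary_tbl Output of [aggregate_fits()].
#' @param group Optional name of the grouping column.
#' @return A ggplot.
#' @export
plot_fraction_summary <- function(summary_tbl, group = NULL) {
  df <- dplyr::filter(summary_tbl,
                      .data$parameter %in% c("f_stable", "f_dynamic",
                                             "f_mobile"))
  aes <- if (is.null(group)) {
    ggplot2::aes(x = .data$parameter, y = .data$mean)
  } else {
    ggplot2::aes(x = .data$parameter, y = .data$mean,
                 fill = .data[[group]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem2,
                   ymax = .data$mean + .data$sem2),
      width = 0.2, position = ggplot2::position_dodge(0.9)
    ) +
    ggplot2::labs(x = NULL, y = "fraction of pool (mean ± 2 SEM)") +
    ggplot2::theme_classic()
}
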