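#' Acquisition noise model for synthetic FRAP traces
#'
#' Synthetic traces convert simulated molecule counts to camera-like
#' intensities: `intensity = count * photon_scale + background(t) + noise`,
#' with Poisson photon noise on the scaled signal and Gaussian read noise.
#' Defaults give a normalized noise level of about 2% on a typical bleached
#' FA trace, well below the 5% ceiling a usable experiment should show.
#'
#' @param photon_scale Camera counts per simulated molecule.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param background Background level (counts).
#' @param drift_per_s Linear background/illumination drift per second
#'   applied multiplicatively to all ROI signals (0 = stable microscope;
#'   negative values emulate monitor bleaching).
#' @return An object of class `trace_noise`.
#' @export
trace_noise <- function(photon_scale = 10, read_noise_sd = 5,
                        background = 100, drift_per_s = 0) {
  stopifnot(photon_scale >= 0, read_noise_sd >= 0, background >= 0)
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 background = background, drift_per_s = drift_per_s),
            class = "trace_noise")
}

#' Generate a synthetic FRAP experiment with known ground truth
#'
#' Wraps [simulate_frap()] in a realistic acquisition: 30 s prebleach and
#' 6 min postbleach at 500 ms sampling, `n_fas` bleached FA traces,
#' unbleached control FAs and background ROIs, all on one shared time
#' grid.  The generating kinetic parameters are attached as the `truth`
#' attribute (and written as a JSON sidecar by [write_frap_experiment()]),
#' so recovery of the parameters by the fitting pipeline can be scored
#' without re-deriving anything.
#'
#' @param params One-row [kinetic_params()] tibble: the ground truth.
#' @param n_fas Number of bleached FA traces.
#' @param n_controls,n_backgrounds Numbers of control / background ROIs.
#' @param noise A [trace_noise()].
#' @param geometry,d,pulse,t_pre,t_post,n_molecules Passed to
#'   [simulate_frap()].
#' @param seed Integer seed; the experiment is bit-reproducible.
#' @return An experiment tibble (`roi_id`, `role`, `time_s`, `intensity`)
#'   of class `frap_experiment` with attributes `truth` (params, seed,
#'   per-trace seeds) and `noise`.
#' @export
gen_frap_experiment <- function(params, n_fas = 5, n_controls = 3,
                                n_backgrounds = 2, noise = trace_noise(),
                                geometry = cell_geometry(),
                                d = diffusion_params(),
                                pulse = bleach_pulse(), t_pre = 30,
                                t_post = 360, n_molecules = 1e4, seed = 1) {
  validate_kinetic_params(params)
  set.seed(seed)
  n_samples <- as.integer(round((t_pre + t_post) / d$sample_interval))
  time_s <- seq_len(n_samples) * d$sample_interval
  gain <- 1 + noise$drift_per_s * pmax(time_s - t_pre, 0)
  trace_seeds <- seed * 1000003 + seq_len(n_fas)

  noisy <- function(signal) {
    lambda <- pmax(signal * gain, 0)
    photons <- if (noise$photon_scale > 0) rpois(length(lambda), lambda) else
      lambda
    photons + noise$background * gain +
      rnorm(length(lambda), 0, noise$read_noise_sd)
  }

  rois <- list()
  for (i in seq_len(n_fas)) {
    cv <- simulate_frap(params, geometry = geometry, d = d, pulse = pulse,
                        t_pre = t_pre, t_post = t_post,
                        n_molecules = n_molecules, seed = trace_seeds[i])
    rois[[length(rois) + 1]] <- tibble::tibble(
      roi_id = sprintf("fa%02d", i), role = "bleached", time_s = time_s,
      intensity = noisy(cv$count * noise$photon_scale)
    )
  }
  # unbleached controls: steady FA-level signal, drift and noise only
  pre_level <- mean(rois[[1]]$intensity[time_s <= t_pre]) - noise$background
  for (i in seq_len(n_controls)) {
    rois[[length(rois) + 1]] <- tibble::tibble(
      roi_id = sprintf("ctrl%02d", i), role = "control", time_s = time_s,
      intensity = noisy(rep(max(pre_level, 50), n_samples))
    )
  }
  for (i in seq_len(n_backgrounds)) {
    rois[[length(rois) + 1]] <- tibble::tibble(
      roi_id = sprintf("bg%02d", i), role = "background", time_s = time_s,
      intensity = noise$background * gain +
        rnorm(n_samples, 0, noise$read_noise_sd)
    )
  }
  out <- dplyr::bind_rows(rois)
  attr(out, "truth") <- list(params = tibble::as_tibble(params), seed = seed,
                             trace_seeds = trace_seeds,
                             n_molecules = n_molecules)
  attr(out, "noise") <- noise
  class(out) <- c("frap_experiment", class(out))
  out
}

#' Write / read a synthetic FRAP experiment (CSV + truth JSON sidecar)
#'
#' @param experiment A [gen_frap_experiment()] tibble.
#' @param path Output CSV path; the ground truth goes to the same path
#'   with extension `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_frap_experiment <- function(experiment, path) {
  write.csv(as.data.frame(experiment), path, row.names = FALSE)
  truth <- attr(experiment, "truth")
  if (!is.null(truth)) {
    truth$params <- as.list(truth$params)
    jsonlite::write_json(truth, sub("\\.csv$", ".truth.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_frap_experiment
#' @export
read_frap_experiment <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  sidecar <- sub("\\.csv$", ".truth.json", path)
  if (file.exists(sidecar)) {
    attr(out, "truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  class(out) <- c("frap_experiment", class(out))
  out
}

#' Specification of a synthetic photoconversion stack
#'
#' Describes the scene the image generator draws: one elliptical FA on a
#' cytoplasmic background, a conversion ROI around the FA, implanted
#' stable clusters (full retention of converted protein), and an exchange
#' fraction for the rest of the FA.  Conversion efficiency models the fact
#' that only part of the green pool is converted; it scales the red signal
#' without changing any ratio.
#'
#' @param shape Image shape (rows, cols) in pixels.
#' @param pixel_size Pixel size, um.
#' @param fa_centre,fa_half_axes FA ellipse centre and half-axes, um.
#' @param fa_theta_deg FA long-axis angle, degrees.
#' @param clusters A data frame with columns `x`, `y`, `r` (um): centres
#'   and radii of the implanted stable clusters (must lie inside the FA).
#' @param exchange_fraction Fraction of converted protein replaced by
#'   unconverted protein outside the clusters by `t_post` (0 = fixed
#'   control, 1 = full exchange).
#' @param conversion_efficiency Fraction of the green pool converted to
#'   red at `t_0`, in (0, 1\].
#' @param fa_intensity,cytoplasm_intensity,red_floor Mean signal levels
#'   (arbitrary camera units).
#' @param photon_scale,read_noise_sd Noise model (Poisson at
#'   `photon_scale` counts/unit plus Gaussian read noise).
#' @return An object of class `stack_spec`.
#' @export
stack_spec <- function(shape = c(60, 80), pixel_size = 0.1,
                       fa_centre = c(4, 3), fa_half_axes = c(1.0, 0.5),
                       fa_theta_deg = 0,
                       clusters = data.frame(x = numeric(0), y = numeric(0),
                                             r = numeric(0)),
                       exchange_fraction = 1, conversion_efficiency = 0.7,
                       fa_intensity = 600, cytoplasm_intensity = 60,
                       red_floor = 8, photon_scale = 1, read_noise_sd = 3) {
  stopifnot(length(shape) == 2, pixel_size > 0,
            exchange_fraction >= 0, exchange_fraction <= 1,
            conversion_efficiency > 0, conversion_efficiency <= 1)
  spec <- structure(
    list(shape = as.integer(shape), pixel_size = pixel_size,
         fa_centre = fa_centre, fa_half_axes = fa_half_axes,
         fa_theta_deg = fa_theta_deg, clusters = clusters,
         exchange_fraction = exchange_fraction,
         conversion_efficiency = conversion_efficiency,
         fa_intensity = fa_intensity,
         cytoplasm_intensity = cytoplasm_intensity, red_floor = red_floor,
         photon_scale = photon_scale, read_noise_sd = read_noise_sd),
    class = "stack_spec"
  )
  masks <- spec_masks(spec)
  if (nrow(clusters) > 0 && any(masks$cluster & !masks$fa)) {
    rlang::abort("implanted clusters must lie inside the FA ellipse")
  }
  spec
}

# pixel-centre masks of the FA ellipse and the implanted clusters
spec_masks <- function(spec) {
  nr <- spec$shape[1]
  nc <- spec$shape[2]
  x <- outer(rep(1, nr), seq_len(nc)) * spec$pixel_size
  y <- outer(seq_len(nr), rep(1, nc)) * spec$pixel_size
  th <- spec$fa_theta_deg * pi / 180
  dx <- x - spec$fa_centre[1]
  dy <- y - spec$fa_centre[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  fa <- (u / spec$fa_half_axes[1])^2 + (v / spec$fa_half_axes[2])^2 <= 1
  cl <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(spec$clusters))) {
    cl <- cl | ((x - spec$clusters$x[i])^2 + (y - spec$clusters$y[i])^2 <=
                  spec$clusters$r[i]^2)
  }
  list(fa = fa, cluster = cl, x = x, y = y)
}

#' Generate a synthetic photoconversion stack with known ground truth
#'
#' Emulates the pulse-chase physics: at `t_pre` all signal is green; the
#' conversion pulse turns a fraction (`conversion_efficiency`) of the
#' green signal inside the conversion ROI red at `t_0`; by `t_post`, red
#' signal outside the implanted stable clusters has decayed by the
#' exchange fraction (replaced by unconverted green protein), while the
#' clusters retain their converted protein completely.  Two independently
#' noisy frames are produced per channel and time point.
#'
#' @param spec A [stack_spec()].
#' @param seed Integer seed.
#' @return A [photoconv_stack()] with attribute `truth`: the generating
#'   `stack_spec` plus
#'   logical ground-truth masks (`fa_mask`, `cluster_mask`) and the
#'   exchange map.
#' @export
gen_photoconv_stack <- function(spec = stack_spec(), seed = 1) {
  set.seed(seed)
  m <- spec_masks(spec)
  nr <- spec$shape[1]
  nc <- spec$shape[2]
  base_green <- matrix(spec$cytoplasm_intensity, nr, nc) +
    spec$fa_intensity * m$fa
  # conversion ROI: rectangle tightly around the FA (plus margin)
  margin <- 0.3
  roi <- abs(m$x - spec$fa_centre[1]) <=
    (max(spec$fa_half_axes) + margin) &
    abs(m$y - spec$fa_centre[2]) <= (max(spec$fa_half_axes) + margin)
  eff <- spec$conversion_efficiency
  red_t0_mean <- spec$red_floor + eff * base_green * roi
  green_t0_mean <- base_green - eff * base_green * roi
  retention <- matrix(1 - spec$exchange_fraction, nr, nc)
  retention[m$cluster] <- 1
  red_post_mean <- spec$red_floor + eff * base_green * roi * retention
  green_post_mean <- base_green - eff * base_green * roi * retention

  two_frames <- function(mean_img) {
    f <- function() {
      lam <- pmax(mean_img * spec$photon_scale, 0)
      img <- if (spec$photon_scale > 0) {
        matrix(rpois(length(lam), lam), nr, nc) / spec$photon_scale
      } else {
        mean_img
      }
      img + matrix(rnorm(length(lam), 0, spec$read_noise_sd), nr, nc)
    }
    array(c(f(), f()), dim = c(nr, nc, 2))
  }

  stack <- photoconv_stack(
    green_pre = two_frames(base_green),
    red_pre = two_frames(matrix(spec$red_floor, nr, nc)),
    green_t0 = two_frames(green_t0_mean),
    red_t0 = two_frames(red_t0_mean),
    green_post = two_frames(green_post_mean),
    red_post = two_frames(red_post_mean),
    pixel_size = spec$pixel_size
  )
  attr(stack, "truth") <- list(spec = spec, fa_mask = m$fa,
                               cluster_mask = m$cluster,
                               retention = retention, conversion_roi = roi)
  stack
}

#' Generate a synthetic cell: membrane edge, FA outlines, truth labels
#'
#' Places elliptical FAs relative to a straight ventral membrane edge
#' (the y axis at x = 0, cell interior at x > 0) with known orientation
#' and location labels: orientations are drawn from `orientation_mix` (or
#' uniformly when `NULL`); a subset of FAs is placed as inner members of
#' two-FA chains, with an outer FA sitting between them and the edge along
#' the same edge normal.
#'
#' @param n_fas Number of FAs.
#' @param orientation_mix Optional named numeric vector of sampling
#'   weights for `c(pointing = , parallel = , other = )`; `NULL` draws
#'   long-axis angles uniformly on \[0, 180).
#' @param frac_inner Fraction of FAs placed as inner chain members.
#' @param fa_half_axes FA ellipse half-axes, um.
#' @param seed Integer seed.
#' @return A list of class `synthetic_cell`: `fas` (tibble `fa_id`,
#'   `polygon`, truth columns `true_orientation`, `true_location`,
#'   `true_theta_deg`, `true_distal_x`, `true_distal_y`), and `edge`
#'   (a [membrane_edge()]).
#' @export
gen_cell_geometry <- function(n_fas = 10, orientation_mix = NULL,
                              frac_inner = 0.3, fa_half_axes = c(1.0, 0.4),
                              seed = 1) {
  stopifnot(n_fas >= 1)
  set.seed(seed)
  edge <- membrane_edge(cbind(0, seq(-5, 5 + 6 * n_fas, length.out = 50)))
  # The edge is vertical, so its tangent angle is 90 deg: a pointing FA
  # has its long axis near 0/180 deg (horizontal, perpendicular to the
  # edge), a parallel FA near 90 deg, "other" FAs near 45/135 deg.
  theta <- if (is.null(orientation_mix)) {
    runif(n_fas, 0, 180)
  } else {
    cls <- sample(names(orientation_mix), n_fas, replace = TRUE,
                  prob = orientation_mix)
    vapply(cls, function(cl) {
      switch(cl,
        pointing = runif(1, -25, 25) %% 180,
        parallel = 90 + runif(1, -25, 25),
        other = sample(c(45, 135), 1) + runif(1, -8, 8)
      )
    }, numeric(1))
  }
  inner <- rep(FALSE, n_fas)
  if (n_fas >= 2 && frac_inner > 0) {
    inner[sample.int(n_fas, max(0, round(frac_inner * n_fas)))] <- TRUE
  }
  rows <- list()
  y_slots <- seq(0, by = 6, length.out = n_fas)
  helper_id <- 0
  for (i in seq_len(n_fas)) {
    y0 <- y_slots[i]
    if (inner[i]) {
      cx <- 12
      # blocking outer FA on the segment from (cx, y0) to the edge (0, y0)
      helper_id <- helper_id + 1
      blocker <- ellipse_polygon(c(5, y0), c(1.0, 0.6), 90)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fa_id = sprintf("blk%02d", helper_id), polygon = list(blocker),
        true_orientation = "parallel", true_location = "outer",
        true_theta_deg = 90, true_inner_chain = FALSE
      )
    } else {
      cx <- 4
    }
    poly <- ellipse_polygon(c(cx, y0), fa_half_axes, theta[i])
    rows[[length(rows) + 1]] <- tibble::tibble(
      fa_id = sprintf("fa%02d", i), polygon = list(poly),
      true_orientation = orientation_class(theta[i], 90),
      true_location = ifelse(inner[i], "inner", "outer"),
      true_theta_deg = theta[i], true_inner_chain = inner[i]
    )
  }
  fas <- dplyr::bind_rows(rows)
  # truth distal endpoint: the relevant-axis endpoint nearer the edge
  fas$true_distal_x <- NA_real_
  fas$true_distal_y <- NA_real_
  for (i in seq_len(nrow(fas))) {
    ctr <- polygon_centroid(fas$polygon[[i]])
    th <- fas$true_theta_deg[i]
    orient <- fas$true_orientation[i]
    axis_theta <- if (identical(orient, "parallel")) (th + 90) %% 180 else th
    len <- if (identical(orient, "parallel")) 2 * min(fa_half_axes) else
      2 * max(fa_half_axes)
    if (grepl("^blk", fas$fa_id[i])) len <- 2 * 0.6  # blocker minor axis
    u <- c(cos(axis_theta * pi / 180), sin(axis_theta * pi / 180))
    e1 <- ctr + u * len / 2
    e2 <- ctr - u * len / 2
    d <- if (abs(e1[1]) < abs(e2[1])) e1 else e2  # edge is x = 0
    fas$true_distal_x[i] <- d[1]
    fas$true_distal_y[i] <- d[2]
  }
  structure(list(fas = fas, edge = edge), class = "synthetic_cell")
}

#' Polygon approximation of an ellipse outline
#'
#' @param centre Ellipse centre (x, y), um.
#' @param half_axes Semi-axes (a, b), um.
#' @param theta_deg Rotation of the first axis, degrees.
#' @param n Number of vertices.
#' @return An n x 2 matrix of outline points.
#' @export
ellipse_polygon <- function(centre, half_axes, theta_deg, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-1]
  th <- theta_deg * pi / 180
  x <- half_axes[1] * cos(t)
  y <- half_axes[2] * sin(t)
  cbind(centre[1] + x * cos(th) - y * sin(th),
        centre[2] + x * sin(th) + y * cos(th))
}
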