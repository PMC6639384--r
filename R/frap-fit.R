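#' Experiment-level FRAP trace utilities
#'
#' An experiment is a long-format tibble with columns `roi_id`, `role`
#' (`"bleached"`, `"control"` for unbleached control FAs, `"background"`),
#' `time_s` (0.5 s grid) and `intensity` (raw counts).  All FAs of one
#' experiment share one background series: the mean over the background
#' ROIs at each time point.
#'
#' @param experiment Experiment tibble as above.
#' @return A tibble `time_s`, `background` with the averaged background
#'   series.
#' @export
background_series <- function(experiment) {
  bg <- dplyr::filter(experiment, .data$role == "background")
  if (nrow(bg) == 0) {
    rlang::abort("experiment needs at least one background ROI")
  }
  dplyr::summarise(dplyr::group_by(bg, .data$time_s),
                   background = mean(.data$intensity), .groups = "drop")
}

#' Normalize FRAP traces to prebleach levels
#'
#' Background-corrects each FA trace and scales it so that the prebleach
#' mean is 1:
#' \deqn{I_{norm} = \frac{I_t - I_{BG,t}}{I_{pre} - I_{BG,pre}}}
#' where `I_pre` and `I_BG,pre` are averages over the entire prebleach
#' period.
#'
#' @param experiment Experiment tibble (see [background_series()]).
#' @param bleach_time Time of the bleach pulse in seconds; samples with
#'   `time_s <= bleach_time` form the prebleach window.
#' @return A tibble `roi_id`, `role`, `time_s`, `i_norm` for every
#'   non-background ROI.
#' @examples
#' exp <- tibble::tibble(
#'   roi_id = "fa1", role = "bleached", time_s = c(29.5, 30, 30.5),
#'   intensity = c(900, 900, 500)
#' )
#' bg <- tibble::tibble(
#'   roi_id = "bg", role = "background", time_s = c(29.5, 30, 30.5),
#'   intensity = 100
#' )
#' normalize_prebleach(rbind(exp, bg))
#' @export
normalize_prebleach <- function(experiment, bleach_time = 30) {
  bg <- background_series(experiment)
  tr <- dplyr::filter(experiment, .data$role != "background")
  tr <- dplyr::left_join(tr, bg, by = "time_s")
  pre_bg <- mean(bg$background[bg$time_s <= bleach_time])
  out <- tr |>
    dplyr::group_by(.data$roi_id, .data$role) |>
    dplyr::group_modify(function(d, key) {
      pre <- mean(d$intensity[d$time_s <= bleach_time])
      denom <- pre - pre_bg
      if (!is.finite(denom) || denom <= 0) {
        rlang::abort(paste0(
          "degenerate trace: prebleach signal does not exceed background"
        ))
      }
      tibble::tibble(time_s = d$time_s,
                     i_norm = (d$intensity - d$background) / denom)
    }) |>
    dplyr::ungroup()
  out[, c("roi_id", "role", "time_s", "i_norm")]
}

#' Normalize FRAP traces to the zero-one recovery scale
#'
#' Rescales each bleached trace so the first postbleach value is 0 and the
#' final recovery level is 1:
#' \deqn{I_{norm} = \frac{(I_t - I_{BG,t}) - (I_0 - I_{BG,0})}
#'   {(I_{post} - I_{BG,post}) - (I_0 - I_{BG,0})}}
#' with `I_0` the first postbleach sample and `I_post` the mean over the
#' last `final_window` samples.  Traces with a nonpositive denominator (no
#' measurable recovery, e.g. an FA not in a stable state) are excluded and
#' reported in the `excluded` attribute.
#'
#' @inheritParams normalize_prebleach
#' @param final_window Number of final samples averaged for the recovery
#'   level (default 25).
#' @return A tibble `roi_id`, `time_s`, `i_norm` for bleached ROIs;
#'   attribute `excluded` lists ROIs dropped for nonpositive denominators.
#' @export
normalize_zero_one <- function(experiment, bleach_time = 30,
                               final_window = 25) {
  bg <- background_series(experiment)
  tr <- dplyr::filter(experiment, .data$role == "bleached")
  tr <- dplyr::left_join(tr, bg, by = "time_s")
  excluded <- character(0)
  out <- tr |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time_s)
      post <- d$time_s > bleach_time
      i0 <- d$intensity[post][1] - d$background[post][1]
      last <- seq.int(max(1L, nrow(d) - final_window + 1L), nrow(d))
      ipost <- mean(d$intensity[last]) - mean(d$background[last])
      denom <- ipost - i0
      if (!is.finite(denom) || denom <= 0) {
        excluded <<- c(excluded, key$roi_id)
        return(tibble::tibble(time_s = numeric(0), i_norm = numeric(0)))
      }
      tibble::tibble(time_s = d$time_s,
                     i_norm = ((d$intensity - d$background) - i0) / denom)
    }) |>
    dplyr::ungroup()
  attr(out, "excluded") <- excluded
  out
}

#' Quality control of a FRAP experiment
#'
#' Applies the two acquisition QC rules: (1) the whole experiment is
#' discarded when the mean prebleach-normalized intensity of the unbleached
#' control FAs falls below `control_floor` (default 90% of original
#' levels) at any postbleach time point (monitor bleaching / bleaching of
#' too large a share of the pool); (2) an individual bleached FA is
#' excluded when its first postbleach normalized value is not below
#' `bleach_ceiling` (default 20% of prebleach; insufficient bleach).
#'
#' @inheritParams normalize_prebleach
#' @param control_floor Minimum admissible control level (fraction of
#'   prebleach).
#' @param bleach_ceiling Maximum admissible first-postbleach level of a
#'   bleached FA (fraction of prebleach).
#' @return A list of class `frap_qc`: `experiment_pass` (logical), `log`
#'   (tibble `roi_id`, `role`, `kept`, `reason`), and `traces` (the
#'   surviving bleached rows of `experiment`; empty when the experiment is
#'   discarded).
#' @export
qc_experiment <- function(experiment, bleach_time = 30, control_floor = 0.9,
                          bleach_ceiling = 0.2) {
  roles <- unique(experiment$role)
  if (!"control" %in% roles) {
    rlang::abort("experiment needs at least one unbleached control ROI")
  }
  if (!"background" %in% roles) {
    rlang::abort("experiment needs at least one background ROI")
  }
  norm <- normalize_prebleach(experiment, bleach_time = bleach_time)
  ctrl <- norm |>
    dplyr::filter(.data$role == "control", .data$time_s > bleach_time) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(level = mean(.data$i_norm), .groups = "drop")
  experiment_pass <- all(ctrl$level >= control_floor)

  bleached <- dplyr::filter(norm, .data$role == "bleached")
  ids <- unique(bleached$roi_id)
  first_post <- vapply(ids, function(id) {
    d <- bleached[bleached$roi_id == id, ]
    d$i_norm[d$time_s > bleach_time][1]
  }, numeric(1))
  log <- tibble::tibble(
    roi_id = ids, role = "bleached",
    kept = experiment_pass & first_post < bleach_ceiling,
    reason = dplyr::case_when(
      !experiment_pass ~ "monitor bleaching",
      first_post >= bleach_ceiling ~ "insufficient bleach",
      TRUE ~ ""
    )
  )
  ctrl_ids <- unique(norm$roi_id[norm$role == "control"])
  log <- dplyr::bind_rows(log, tibble::tibble(
    roi_id = ctrl_ids, role = "control", kept = experiment_pass,
    reason = ifelse(experiment_pass, "", "monitor bleaching")
  ))
  kept_ids <- log$roi_id[log$kept & log$role == "bleached"]
  traces <- dplyr::filter(experiment, .data$roi_id %in% kept_ids)
  structure(list(experiment_pass = experiment_pass, log = log,
                 traces = traces),
            class = "frap_qc")
}

#' @export
print.frap_qc <- function(x, ...) {
  cat("<frap_qc> experiment", if (x$experiment_pass) "PASS" else
    "DISCARDED (monitor bleaching)", "\n")
  dropped <- x$log[!x$log$kept & x$log$role == "bleached", ]
  cat("  bleached FAs kept:", sum(x$log$kept & x$log$role == "bleached"),
      "dropped:", nrow(dropped), "\n")
  invisible(x)
}

#' Parameter ranges for the simulated-curve database
#'
#' The database draws both immobile fractions uniformly between 0 and 70%,
#' medium residence times uniformly between 20 and 100 s and long residence
#' times uniformly between 600 and 3200 s.  Draws whose fractions sum to
#' `f_sum_max` or more are rejected (the mobile pool must not vanish).
#' Each range may be collapsed to a point.
#'
#' @param f_medium,f_long Sampling ranges `c(lo, hi)` of the two immobile
#'   fractions.
#' @param t_r_medium,t_r_long Residence-time ranges in seconds; the two
#'   ranges must stay disjoint (medium below long).
#' @param f_sum_max Rejection bound on `f_medium + f_long`.
#' @return A list of ranges used by [build_database()].
#' @export
db_ranges <- function(f_medium = c(0, 0.7), f_long = c(0, 0.7),
                      t_r_medium = c(20, 100), t_r_long = c(600, 3200),
                      f_sum_max = 0.95) {
  if (length(f_medium) == 1) f_medium <- rep(f_medium, 2)
  if (length(f_long) == 1) f_long <- rep(f_long, 2)
  stopifnot(f_medium[1] >= 0, f_medium[2] < 1, diff(f_medium) >= 0,
            f_long[1] >= 0, f_long[2] < 1, diff(f_long) >= 0,
            f_sum_max <= 1, f_medium[1] + f_long[1] < f_sum_max,
            t_r_medium[1] > 0, diff(t_r_medium) >= 0,
            t_r_long[1] > 0, diff(t_r_long) >= 0,
            t_r_medium[2] <= t_r_long[1])
  if (f_long[2] > 0 && f_medium[2] == 0) {
    rlang::abort("f_long > 0 requires a nonzero f_medium range")
  }
  list(f_medium = f_medium, f_long = f_long, t_r_medium = t_r_medium,
       t_r_long = t_r_long, f_sum_max = f_sum_max)
}

#' Draw random kinetic parameter sets from the database ranges
#'
#' @param n Number of parameter sets.
#' @param ranges A [db_ranges()] list.
#' @param seed Integer seed.
#' @return A `kinetic_params` tibble with `n` rows.
#' @export
sample_kinetic_params <- function(n, ranges = db_ranges(), seed = 1) {
  set.seed(seed)
  f_m <- f_l <- numeric(0)
  while (length(f_m) < n) {
    m <- runif(n, ranges$f_medium[1], ranges$f_medium[2])
    l <- runif(n, ranges$f_long[1], ranges$f_long[2])
    ok <- (m + l) < ranges$f_sum_max & !(l > 0 & m == 0)
    f_m <- c(f_m, m[ok])
    f_l <- c(f_l, l[ok])
  }
  kinetic_params(
    f_medium = f_m[seq_len(n)], f_long = f_l[seq_len(n)],
    t_r_medium_s = runif(n, ranges$t_r_medium[1], ranges$t_r_medium[2]),
    t_r_long_s = runif(n, ranges$t_r_long[1], ranges$t_r_long[2])
  )
}

#' Build a database of simulated FRAP curves
#'
#' Draws `n` kinetic parameter sets uniformly from the stated ranges,
#' simulates each one with [simulate_frap()] on the experimental sampling
#' grid and stores the prebleach-normalized curves.  Full-scale
#' analyses use databases of 5122 (U2OS) or 2027 (MDCK) entries; `n` and the molecule
#' count are configurable so that reduced-scale databases can be built for
#' testing.
#'
#' @param n Number of database entries.
#' @param ranges A [db_ranges()] list.
#' @param geometry,d,pulse Simulator configuration (see [simulate_frap()]).
#' @param t_pre,t_post Simulated pre/postbleach durations (seconds).
#' @param n_molecules Molecules per simulated curve.
#' @param seed Integer seed; entry seeds are derived deterministically.
#' @param transport Mobile-transport scheme passed to [simulate_frap()];
#'   the default `"well_mixed"` makes database-scale generation feasible
#'   without changing the curves' distribution.
#' @return An object of class `frap_db`: `params` (tibble with fractions,
#'   residence times, derived rates, per-entry seed and a `low_signal`
#'   flag), `curves` (n x n_samples matrix of normalized intensities),
#'   `time_s`, `n_prebleach`, and the configuration.
#' @export
build_database <- function(n, ranges = db_ranges(),
                           geometry = cell_geometry(),
                           d = diffusion_params(), pulse = bleach_pulse(),
                           t_pre = 30, t_post = 360, n_molecules = 1e4,
                           seed = 1, transport = "well_mixed") {
  stopifnot(n >= 1)
  params <- sample_kinetic_params(n, ranges, seed = seed)
  entry_seeds <- as.numeric(seed) * 1000003 + seq_len(n)
  n_samples <- as.integer(round((t_pre + t_post) / d$sample_interval))
  curves <- matrix(NA_real_, n, n_samples)
  pre_means <- numeric(n)
  for (i in seq_len(n)) {
    cv <- simulate_frap(params[i, ], geometry = geometry, d = d,
                        pulse = pulse, t_pre = t_pre, t_post = t_post,
                        n_molecules = n_molecules, seed = entry_seeds[i],
                        transport = transport)
    curves[i, ] <- cv$normalized
    pre_means[i] <- attr(cv, "prebleach_mean")
  }
  rates <- derive_rates(params)
  ptab <- dplyr::mutate(rates, entry = dplyr::row_number(),
                        seed = entry_seeds, prebleach_mean = pre_means,
                        low_signal = pre_means < 20)
  structure(
    list(params = ptab, curves = curves,
         time_s = seq_len(n_samples) * d$sample_interval,
         n_prebleach = as.integer(round(t_pre / d$sample_interval)),
         ranges = ranges, geometry = geometry, d = d, pulse = pulse,
         n_molecules = n_molecules, seed = seed),
    class = "frap_db"
  )
}

#' @export
print.frap_db <- function(x, ...) {
  cat("<frap_db>", nrow(x$curves), "simulated FRAP curves,",
      ncol(x$curves), "samples each (", x$n_prebleach, "prebleach ),",
      x$n_molecules, "molecules/curve\n")
  invisible(x)
}

#' @method tidy frap_db
#' @export
tidy.frap_db <- function(x, ...) {
  tibble::as_tibble(x$params)
}

#' Fit one normalized FRAP trace against the curve database
#'
#' Ranks every database entry by the sum of squared residuals between the
#' trace and the simulated curve over the postbleach samples (prebleach
#' samples carry no information once both are normalized to 1) and returns
#' the ranked table; the rank-1 row is the least-squares best fit.
#'
#' @param trace Numeric vector of prebleach-normalized intensities on the
#'   database time grid, or a tibble with columns `time_s` and a
#'   normalized-intensity column (`i_norm` or `normalized`).
#' @param db A [build_database()] object.
#' @param top Number of ranked rows to return (default all).
#' @return A tibble with columns `rank`, `entry`, `ssr` and the entry's
#'   kinetic parameters, sorted by ascending `ssr`.
#' @export
fit_curve <- function(trace, db, top = Inf) {
  y <- trace_to_vector(trace, db)
  post <- (db$n_prebleach + 1):ncol(db$curves)
  resid <- sweep(db$curves[, post, drop = FALSE], 2, y[post], "-")
  ssr <- rowSums(resid^2)
  ord <- order(ssr)
  k <- min(length(ord), top)
  out <- db$params[ord[seq_len(k)], ]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(k), ssr = ssr[ord[seq_len(k)]]),
                   out)
}

trace_to_vector <- function(trace, db) {
  if (is.data.frame(trace)) {
    col <- intersect(c("i_norm", "normalized"), names(trace))[1]
    if (is.na(col)) {
      rlang::abort("trace tibble needs an 'i_norm' or 'normalized' column")
    }
    if (!isTRUE(all.equal(trace$time_s, db$time_s))) {
      rlang::abort("trace time grid does not match the database grid")
    }
    trace <- trace[[col]]
  }
  if (length(trace) != ncol(db$curves)) {
    rlang::abort("trace length does not match the database grid")
  }
  as.numeric(trace)
}

#' Fit a cohort of FRAP traces against the database
#'
#' Fits every trace with [fit_curve()] and keeps the full ranking so that
#' [iqr_refit()] can reassign outlying FAs to their next-best entries.
#'
#' @param traces A matrix (one row per trace, columns on the database
#'   grid), a list of vectors/tibbles, or a long tibble with columns
#'   `roi_id`, `time_s`, `i_norm`.
#' @param db A [build_database()] object.
#' @return An object of class `frap_fit`; [tidy()] gives the per-FA table
#'   of fitted parameters and derived fraction sizes (`f_stable` is the
#'   long/stable fraction, `f_dynamic` the medium fraction, `f_mobile` the
#'   remainder).
#' @export
fit_cohort <- function(traces, db) {
  m <- traces_to_matrix(traces, db)
  post <- (db$n_prebleach + 1):ncol(db$curves)
  X <- db$curves[, post, drop = FALSE]
  Y <- m$mat[, post, drop = FALSE]
  # SSR_ij = |y_i|^2 + |x_j|^2 - 2 y_i . x_j
  cross <- Y %*% t(X)
  ssr <- outer(rowSums(Y^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(Y)), rowSums(X^2)) - 2 * cross
  ssr[ssr < 0] <- 0
  ord <- t(apply(ssr, 1, order))
  fit <- new_frap_fit(ids = m$ids, rank = rep(1L, nrow(Y)), ord = ord,
                      ssr = ssr, db = db)
  fit
}

traces_to_matrix <- function(traces, db) {
  if (is.matrix(traces)) {
    ids <- rownames(traces) %||% as.character(seq_len(nrow(traces)))
    return(list(mat = traces, ids = ids))
  }
  if (is.data.frame(traces)) {
    wide <- tidyr::pivot_wider(traces, id_cols = "roi_id",
                               names_from = "time_s",
                               values_from = "i_norm")
    ids <- wide$roi_id
    mat <- as.matrix(wide[, -1])
    if (ncol(mat) != ncol(db$curves)) {
      rlang::abort("trace grid does not match the database grid")
    }
    return(list(mat = mat, ids = as.character(ids)))
  }
  if (is.list(traces)) {
    mat <- do.call(rbind, lapply(traces, trace_to_vector, db = db))
    ids <- names(traces) %||% as.character(seq_along(traces))
    return(list(mat = mat, ids = ids))
  }
  rlang::abort("unsupported trace container")
}

new_frap_fit <- function(ids, rank, ord, ssr, db, flagged = NULL) {
  structure(
    list(ids = ids, rank = rank, ord = ord, ssr = ssr, db = db,
         flagged = flagged %||% rep(FALSE, length(ids))),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>", length(x$ids), "FA trace(s) fitted against",
      nrow(x$db$curves), "database curves\n")
  if (any(x$rank > 1)) {
    cat("  ", sum(x$rank > 1), "FA(s) reassigned by IQR refit\n")
  }
  invisible(x)
}

#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  entry <- x$ord[cbind(seq_along(x$ids), x$rank)]
  p <- x$db$params[entry, ]
  tibble::tibble(
    roi_id = x$ids,
    rank = x$rank,
    entry = entry,
    ssr = x$ssr[cbind(seq_along(x$ids), entry)],
    f_stable = p$f_long,
    f_dynamic = p$f_medium,
    f_mobile = 1 - p$f_long - p$f_medium,
    t_r_medium_s = p$t_r_medium_s,
    t_r_long_s = p$t_r_long_s,
    k_on_medium = p$k_on_medium,
    k_off_medium = p$k_off_medium,
    k_on_long = p$k_on_long,
    k_off_long = p$k_off_long,
    flagged = x$flagged
  )
}

#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n = nrow(td),
    mean_f_stable = mean(td$f_stable),
    mean_f_dynamic = mean(td$f_dynamic),
    mean_f_mobile = mean(td$f_mobile),
    mean_ssr = mean(td$ssr),
    n_reassigned = sum(td$rank > 1),
    n_flagged = sum(td$flagged)
  )
}

#' Iterative 1.5 x IQR refit of outlying best fits
#'
#' Computes the interquartile range of `k_on_medium` and `k_off_medium`
#' over the initial rank-1 fits (once; bounds are not recomputed during
#' reassignment).  Every FA whose best-fit parameters fall outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` is moved to its next-best database entry
#' iteratively until both parameters fall within bounds; if the ranking is
#' exhausted the original best fit is kept and the FA flagged.  The
#' operation is idempotent.
#'
#' @param fit A [fit_cohort()] object with at least 4 traces.
#' @param k Multiplier on the IQR (default 1.5).
#' @return The updated `frap_fit`.
#' @export
iqr_refit <- function(fit, k = 1.5) {
  n <- length(fit$ids)
  if (n < 4) {
    rlang::warn("fewer than 4 fits: IQR refit skipped")
    return(fit)
  }
  first <- fit$ord[, 1]
  kon <- fit$db$params$k_on_medium[first]
  koff <- fit$db$params$k_off_medium[first]
  bounds <- function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    c(q[1] - k * diff(q), q[2] + k * diff(q))
  }
  b_on <- bounds(kon)
  b_off <- bounds(koff)
  inside <- function(entry) {
    p <- fit$db$params[entry, ]
    p$k_on_medium >= b_on[1] & p$k_on_medium <= b_on[2] &
      p$k_off_medium >= b_off[1] & p$k_off_medium <= b_off[2]
  }
  rank <- integer(n)
  flagged <- logical(n)
  n_db <- ncol(fit$ord)
  for (i in seq_len(n)) {
    r <- 1L
    while (r <= n_db && !inside(fit$ord[i, r])) r <- r + 1L
    if (r > n_db) {
      rank[i] <- 1L
      flagged[i] <- TRUE
    } else {
      rank[i] <- r
    }
  }
  fit$rank <- rank
  fit$flagged <- flagged
  fit
}

#' Cohort summary: mean and 2 x SEM per group
#'
#' Averages the fitted mobility parameters over the FAs of each group and
#' reports twice the standard error of the mean (the error-bar convention
#' used throughout).
#'
#' @param fits A `frap_fit` or its [tidy()] tibble, optionally with extra
#'   grouping columns joined on.
#' @param ... Grouping columns (tidy-select style); omit for one global
#'   group.
#' @param values Columns to summarise.
#' @return A tibble with one row per group x parameter: `n`, `mean`,
#'   `sem2` (2 x SEM).  Groups with fewer than 2 FAs are omitted with a
#'   warning.
#' @export
aggregate_fits <- function(fits, ...,
                           values = c("f_stable", "f_dynamic", "f_mobile",
                                      "k_on_medium", "k_off_medium")) {
  td <- if (inherits(fits, "frap_fit")) tidy(fits) else tibble::as_tibble(fits)
  group_cols <- vapply(rlang::enquos(...), rlang::as_name, character(1))
  values <- intersect(values, names(td))
  long <- tidyr::pivot_longer(td[, c(group_cols, values), drop = FALSE],
                              dplyr::all_of(values),
                              names_to = "parameter", values_to = "value")
  grouped <- dplyr::group_by(
    long, dplyr::across(dplyr::all_of(c(group_cols, "parameter")))
  )
  out <- dplyr::summarise(
    grouped, n = dplyr::n(), mean = mean(.data$value),
    sem2 = 2 * sd(.data$value) / sqrt(dplyr::n()), .groups = "drop"
  )
  small <- out$n < 2
  if (any(small)) {
    rlang::warn("groups with fewer than 2 FAs omitted")
    out <- out[!small, ]
  }
  out
}

#' Rank-based group comparisons with a capped contrast set
#'
#' Two groups are compared with a two-sided Mann-Whitney U test.  Four
#' location x orientation groups are first tested with a Kruskal-Wallis
#' omnibus test; if its p-value is below `omnibus_alpha`, only the four
#' meaningful pairwise contrasts are run (outer-pointing vs inner-pointing,
#' outer-parallel vs inner-parallel, outer-pointing vs outer-parallel,
#' inner-pointing vs inner-parallel), capping the number of tests per
#' parameter at 4.  Significance is declared at `p < alpha` (default 0.01).
#'
#' @param data A tibble with one value column and one group column.
#' @param value,group Column names (unquoted) of the measured parameter
#'   and the group label.  With four groups the labels must be
#'   `"outer-pointing"`, `"outer-parallel"`, `"inner-pointing"`,
#'   `"inner-parallel"`.
#' @param alpha Significance threshold for the pairwise tests.
#' @param omnibus_alpha Threshold of the omnibus test that gates the
#'   pairwise contrasts.
#' @return A tibble `comparison`, `test`, `p_value`, `significant`,
#'   `degenerate` (ties-only data: p set to 1 by convention).
#' @export
compare_groups <- function(data, value, group, alpha = 0.01,
                           omnibus_alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- g[keep]
  lev <- unique(g)
  pair_test <- function(a, b) {
    x <- v[g == a]
    y <- v[g == b]
    if (length(unique(c(x, y))) == 1) {
      return(tibble::tibble(comparison = paste(a, "vs", b),
                            test = "mann-whitney", p_value = 1,
                            significant = FALSE, degenerate = TRUE))
    }
    p <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    tibble::tibble(comparison = paste(a, "vs", b), test = "mann-whitney",
                   p_value = p, significant = p < alpha, degenerate = FALSE)
  }
  if (length(lev) == 2) {
    return(pair_test(lev[1], lev[2]))
  }
  canonical <- c("outer-pointing", "outer-parallel", "inner-pointing",
                 "inner-parallel")
  if (length(lev) == 4 && all(sort(lev) == sort(canonical))) {
    if (length(unique(v)) == 1) {
      return(tibble::tibble(comparison = "omnibus", test = "kruskal-wallis",
                            p_value = 1, significant = FALSE,
                            degenerate = TRUE))
    }
    omni <- kruskal.test(v, factor(g))$p.value
    out <- tibble::tibble(comparison = "omnibus", test = "kruskal-wallis",
                          p_value = omni, significant = omni < alpha,
                          degenerate = FALSE)
    if (omni < omnibus_alpha) {
      contrasts <- list(
        c("outer-pointing", "inner-pointing"),
        c("outer-parallel", "inner-parallel"),
        c("outer-pointing", "outer-parallel"),
        c("inner-pointing", "inner-parallel")
      )
      out <- dplyr::bind_rows(out, purrr::map_dfr(contrasts,
                                                  ~ pair_test(.x[1], .x[2])))
    }
    return(out)
  }
  rlang::abort(paste0(
    "compare_groups expects 2 groups, or the 4 canonical location x ",
    "orientation groups"
  ))
}
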