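make_toy_experiment <- function(fa = c(900, 900, 500, 600, 700),
                                bg = 100, ctrl_level = NULL,
                                times = c(29.5, 30, 30.5, 31, 31.5)) {
  n <- length(times)
  rows <- list(
    tibble::tibble(roi_id = "fa1", role = "bleached", time_s = times,
                   intensity = fa),
    tibble::tibble(roi_id = "bg1", role = "background", time_s = times,
                   intensity = rep(bg, n))
  )
  if (!is.null(ctrl_level)) {
    rows[[3]] <- tibble::tibble(roi_id = "c1", role = "control",
                                time_s = times, intensity = ctrl_level)
  }
  dplyr::bind_rows(rows)
}

test_that("prebleach normalization matches the hand-computed values", {
  exp <- make_toy_experiment()
  norm <- normalize_prebleach(exp)
  # I_pre = 900 over the two prebleach samples, I_BG = 100
  expect_equal(norm$i_norm[norm$time_s == 30.5], (500 - 100) / 800)
  expect_equal(norm$i_norm[norm$time_s == 30], 1)
  # pure background pixel normalizes to zero
  exp2 <- make_toy_experiment(fa = c(900, 900, 100, 100, 100))
  norm2 <- normalize_prebleach(exp2)
  expect_equal(norm2$i_norm[norm2$time_s > 30], rep(0, 3))
  # worked example: I_t 500, bg 100, I_pre 900 -> 0.5
  exp3 <- make_toy_experiment(fa = c(900, 900, 500, 500, 500))
  expect_equal(normalize_prebleach(exp3)$i_norm[3], 0.5)
})

test_that("normalization is invariant to adding a constant everywhere", {
  exp <- make_toy_experiment()
  shifted <- dplyr::mutate(exp, intensity = intensity + 250)
  expect_equal(normalize_prebleach(shifted)$i_norm,
               normalize_prebleach(exp)$i_norm)
  expect_equal(normalize_zero_one(shifted)$i_norm,
               normalize_zero_one(exp)$i_norm)
})

test_that("zero-one normalization anchors at 0 and 1 and is linear", {
  times <- seq(29.5, 33, by = 0.5)
  fa <- c(900, 900, 300, 400, 500, 500, 500, 500)
  exp <- make_toy_experiment(fa = fa, times = times)
  nz <- normalize_zero_one(exp, final_window = 3)
  expect_equal(nz$i_norm[nz$time_s == 30.5], 0)        # first postbleach
  expect_equal(mean(utils::tail(nz$i_norm, 3)), 1)     # final window
  # midway intensity maps to 0.5 under constant background
  expect_equal(nz$i_norm[nz$time_s == 31], 0.5)
  # non-recovering trace is excluded and reported
  flat <- make_toy_experiment(fa = c(900, 900, 400, 350, 300, 250, 200, 150),
                              times = times)
  nz2 <- normalize_zero_one(flat, final_window = 3)
  expect_equal(attr(nz2, "excluded"), "fa1")
  expect_equal(nrow(nz2), 0)
})

test_that("QC keeps good experiments and applies both exclusion rules", {
  times <- seq(29.5, 31.5, by = 0.5)
  # deeply bleached FA (first postbleach at 12.5% of prebleach), steady
  # controls at 95%
  good <- make_toy_experiment(fa = c(900, 900, 200, 230, 260),
                              ctrl_level = rep(860, 5), times = times)
  qc <- qc_experiment(good)
  expect_true(qc$experiment_pass)
  expect_true(all(qc$log$kept[qc$log$role == "bleached"]))

  # controls drifting below 90% of prebleach: whole experiment discarded
  drifting <- make_toy_experiment(
    ctrl_level = c(860, 860, 700, 700, 700), times = times
  )
  qc2 <- qc_experiment(drifting)
  expect_false(qc2$experiment_pass)
  expect_true(all(qc2$log$reason[qc2$log$role == "bleached"] ==
                    "monitor bleaching"))
  expect_equal(nrow(qc2$traces), 0)

  # insufficiently bleached FA (>= 20% of prebleach) excluded individually
  shallow <- make_toy_experiment(fa = c(900, 900, 500, 500, 500),
                                 ctrl_level = rep(860, 5), times = times)
  qc3 <- qc_experiment(shallow)
  expect_true(qc3$experiment_pass)
  expect_equal(qc3$log$reason[qc3$log$roi_id == "fa1"],
               "insufficient bleach")
  # missing controls are a configuration error
  expect_error(qc_experiment(make_toy_experiment()), "control")
})

test_that("database generation respects ranges and is reproducible", {
  db <- build_database(10, n_molecules = 200, seed = 31)
  p <- db$params
  expect_equal(nrow(p), 10)
  expect_true(all(p$f_medium >= 0 & p$f_medium <= 0.7))
  expect_true(all(p$f_long >= 0 & p$f_long <= 0.7))
  expect_true(all(p$f_medium + p$f_long < 1))
  expect_true(all(p$t_r_medium_s >= 20 & p$t_r_medium_s <= 100))
  expect_true(all(p$t_r_long_s >= 600 & p$t_r_long_s <= 3200))
  db2 <- build_database(10, n_molecules = 200, seed = 31)
  expect_identical(db$curves, db2$curves)
  # degenerate point ranges: all parameters equal, curves differ by noise
  pt <- db_ranges(f_medium = 0.2, f_long = 0.3, t_r_medium = c(50, 50),
                  t_r_long = c(1800, 1800))
  db3 <- build_database(3, ranges = pt, n_molecules = 200, seed = 32)
  expect_equal(length(unique(db3$params$f_medium)), 1)
  expect_equal(length(unique(db3$params$t_r_long_s)), 1)
  expect_false(identical(db3$curves[1, ], db3$curves[2, ]))
})

test_that("self-fit is exact and a singleton database always wins", {
  db <- small_db()
  self <- fit_curve(db$curves[7, ], db, top = 2)
  expect_equal(self$entry[1], 7)
  expect_equal(self$ssr[1], 0)
  # singleton database: that entry is returned whatever the residual
  db1 <- db
  db1$curves <- db$curves[3, , drop = FALSE]
  db1$params <- db$params[3, ]
  far <- rep(5, ncol(db$curves))
  expect_equal(fit_curve(far, db1)$entry, 3)
  # grid mismatch is an error
  expect_error(fit_curve(far[-1], db), "grid")
})

test_that("fit_cohort agrees with per-trace fit_curve", {
  db <- small_db()
  traces <- db$curves[c(5, 9), ] +
    matrix(rnorm(2 * ncol(db$curves), 0, 0.01), 2)
  fit <- fit_cohort(traces, db)
  td <- tidy(fit)
  for (i in 1:2) {
    expect_equal(td$entry[i], fit_curve(traces[i, ], db, top = 1)$entry)
  }
  expect_equal(td$f_stable + td$f_dynamic + td$f_mobile, rep(1, 2))
})

test_that("IQR refit moves only constructed outliers and is idempotent", {
  # constructed fit with fully controlled rankings: 10 database entries,
  # nine with tightly clustered rates and one extreme in k_on_medium
  params <- tibble::tibble(
    entry = 1:10,
    k_on_medium = c(seq(0.020, 0.028, length.out = 9), 0.5),
    k_off_medium = c(seq(0.018, 0.022, length.out = 9), 0.02),
    k_on_long = 0, k_off_long = 1 / 1800,
    f_medium = 0.3, f_long = 0.3, t_r_medium_s = 50, t_r_long_s = 1800
  )
  db <- structure(list(params = params, curves = matrix(0, 10, 4),
                       n_prebleach = 1L), class = "frap_db")
  # nine traces best-fit by the clustered entries, one by the extreme
  # entry with an inlier as its next-best
  ord <- rbind(
    t(sapply(1:9, function(i) c(i, setdiff(1:10, i)))),
    c(10, 5, setdiff(1:9, 5))
  )
  ssr <- matrix(rep(seq(0.1, 1, length.out = 10), each = 10), 10)
  fit <- fadyn:::new_frap_fit(ids = as.character(1:10),
                              rank = rep(1L, 10), ord = ord, ssr = ssr,
                              db = db)
  refit <- iqr_refit(fit)
  td1 <- tidy(refit)
  expect_equal(td1$rank[1:9], rep(1L, 9))          # inliers untouched
  expect_equal(td1$rank[10], 2L)                   # outlier -> next best
  expect_equal(td1$entry[10], 5)
  expect_false(any(td1$flagged))
  # idempotent
  expect_identical(tidy(iqr_refit(refit)), td1)
  # degenerate cohort of identical fits: IQR 0, bounds collapse, all pass
  same <- fadyn:::new_frap_fit(ids = as.character(1:5),
                               rank = rep(1L, 5),
                               ord = matrix(rep(c(4L, 1:3, 5:10), 5), 5,
                                            byrow = TRUE),
                               ssr = matrix(1, 5, 10), db = db)
  expect_identical(tidy(iqr_refit(same))$rank, rep(1L, 5))
  # too few fits: warning, unchanged
  few <- fadyn:::new_frap_fit(ids = as.character(1:2), rank = rep(1L, 2),
                              ord = matrix(rep(1:10, 2), 2, byrow = TRUE),
                              ssr = matrix(1, 2, 10), db = db)
  expect_warning(iqr_refit(few), "fewer than 4")
})
test_that("cohort aggregation reports means and 2 x SEM per group", {
  td <- tibble::tibble(
    f_stable = c(0.5, 0.3), f_dynamic = c(0.3, 0.3), f_mobile = c(0.2, 0.4)
  )
  agg <- aggregate_fits(td)
  expect_equal(agg$mean[agg$parameter == "f_stable"], 0.4)
  expect_equal(agg$mean[agg$parameter == "f_dynamic"], 0.3)
  expect_equal(agg$sem2[agg$parameter == "f_dynamic"], 0)
  expect_equal(agg$sem2[agg$parameter == "f_stable"],
               2 * sd(c(0.5, 0.3)) / sqrt(2))
  # identical fits: SEM exactly 0
  same <- tibble::tibble(f_stable = c(0.4, 0.4))
  expect_equal(aggregate_fits(same, values = "f_stable")$sem2, 0)
  # grouped, with a singleton group dropped
  td$group <- c("a", "a")
  td2 <- dplyr::bind_rows(td, tibble::tibble(f_stable = 0.9, f_dynamic = 0.05,
                                             f_mobile = 0.05, group = "b"))
  expect_warning(agg2 <- aggregate_fits(td2, group), "fewer than 2")
  expect_true(all(agg2$group == "a"))
})

test_that("group means cover the truth at the advertised 2 x SEM rate", {
  set.seed(77)
  truth <- 0.4
  hits <- replicate(100, {
    x <- truth + rnorm(40, 0, 0.08)
    m <- mean(x)
    abs(m - truth) <= 2 * sd(x) / sqrt(40)
  })
  expect_gte(mean(hits), 0.90)  # nominal ~95%
})

test_that("rank tests: two-group, power, and the capped four-group path", {
  # identical samples: p ~ 1, not significant
  d0 <- tibble::tibble(v = rep(c(1, 2, 3), 4), g = rep(c("a", "b"), 6))
  r0 <- compare_groups(d0, v, g)
  expect_false(r0$significant)
  # ties-only degenerate data flagged with p = 1
  dt <- tibble::tibble(v = rep(1, 10), g = rep(c("a", "b"), 5))
  rt <- compare_groups(dt, v, g)
  expect_true(rt$degenerate)
  expect_equal(rt$p_value, 1)
  # power: shift of 2 pooled SD at n = 50 detected at p < 0.01
  set.seed(5)
  power <- mean(replicate(60, {
    d <- tibble::tibble(v = c(rnorm(50), rnorm(50, 2)),
                        g = rep(c("a", "b"), each = 50))
    compare_groups(d, v, g)$p_value < 0.01
  }))
  expect_gte(power, 0.95)
  # four groups: omnibus plus exactly the four stated contrasts
  set.seed(8)
  d4 <- tibble::tibble(
    v = c(rnorm(30, 2), rnorm(30), rnorm(30), rnorm(30)),
    g = rep(c("outer-pointing", "outer-parallel", "inner-pointing",
              "inner-parallel"), each = 30)
  )
  r4 <- compare_groups(d4, v, g)
  expect_equal(r4$test[1], "kruskal-wallis")
  expect_equal(sum(r4$test == "mann-whitney"), 4)
  expect_setequal(
    r4$comparison[-1],
    c("outer-pointing vs inner-pointing", "outer-parallel vs inner-parallel",
      "outer-pointing vs outer-parallel", "inner-pointing vs inner-parallel")
  )
})
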