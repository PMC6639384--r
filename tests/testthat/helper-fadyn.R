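# Shared fixtures and independent oracles for the test suite.

# ---- continuous-time Markov chain (Gillespie) oracle -----------------------
# Simulates one molecule through the three-state scheme with exponential
# waiting times and returns the fraction of time spent in each state.
# Independent of the package's discrete-time simulator.
gillespie_occupancy <- function(rates, t_total = 1e6, seed = 1) {
  set.seed(seed)
  kon_m <- rates$k_on_medium
  koff_m <- rates$k_off_medium
  kon_l <- rates$k_on_long
  koff_l <- rates$k_off_long
  t_in <- c(mobile = 0, medium = 0, long = 0)
  state <- 1L  # 1 mobile, 2 medium, 3 long
  t <- 0
  while (t < t_total) {
    rate <- switch(state, kon_m, koff_m + kon_l, koff_l)
    if (rate <= 0) {          # absorbing: all remaining time in this state
      t_in[state] <- t_in[state] + (t_total - t)
      break
    }
    dwell <- min(rexp(1, rate), t_total - t)
    t_in[state] <- t_in[state] + dwell
    t <- t + dwell
    if (t >= t_total) break
    state <- switch(state,
      2L,
      if (runif(1) < kon_l / (koff_m + kon_l)) 3L else 1L,
      1L
    )
  }
  t_in / sum(t_in)
}

# ---- closed-form plateau accounting ---------------------------------------
# Expected late-plateau level of a simulated FRAP curve from the pulse
# bookkeeping: medium/mobile pools recover to the fluorescent fraction of
# the exchanging pool, the long pool relaxes with rate k_off_long.
expected_plateau <- function(cv, window = c(300, 360)) {
  r <- attr(cv, "rates")
  n <- attr(cv, "n_molecules")
  book <- attr(cv, "bleach_book")
  pre <- attr(cv, "prebleach_mean")
  fr <- steady_state_fractions(r)
  tmid <- mean(window) - attr(cv, "bleach_times")[1]
  b_med <- book[1, "medium_in_fa"]
  b_long <- book[1, "long_in_fa"]
  b_mob <- book[1, "total"] - b_med - b_long
  exch <- n * (fr$f_mobile + fr$f_medium)
  rel <- exp(-r$k_off_long * tmid)
  f <- 1 - (b_mob + b_med + b_long * (1 - rel)) / exch
  m_cap <- n * fr$f_medium / 2
  l_cap <- n * fr$f_long / 2
  fl_long <- l_cap * f * (1 - rel) + (l_cap - b_long) * rel
  fl_med <- m_cap * f
  mob <- max(pre - m_cap - l_cap, 0) * f
  (fl_med + fl_long + mob) / pre
}

# ---- brute-force moment-preserving threshold oracle ------------------------
# Enumerates all 255 inter-bin cuts of a 256-bin histogram and returns the
# candidate cut(s) whose below-threshold pixel fraction is closest to the
# p0-tile of the moment-preserving bilevel fit (computed directly from the
# first three moments).
moments_threshold_oracle <- function(v, n_bins = 256) {
  lo <- min(v)
  hi <- max(v)
  idx <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1)
  p <- tabulate(idx + 1L, nbins = n_bins) / length(v)
  mids <- seq_len(n_bins) - 1
  m1 <- sum(mids * p); m2 <- sum(mids^2 * p); m3 <- sum(mids^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  z0 <- 0.5 * (-c1 - sqrt(c1^2 - 4 * c0))
  z1 <- 0.5 * (-c1 + sqrt(c1^2 - 4 * c0))
  p0 <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  best <- which(abs(cum - p0) == min(abs(cum - p0)))
  # candidate thresholds on the data scale (upper bin edges)
  lo + best / n_bins * (hi - lo)
}

# ---- cached fixtures --------------------------------------------------------
.fadyn_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fadyn_cache[[key]])) .fadyn_cache[[key]] <- force(expr)
  .fadyn_cache[[key]]
}

# small database for unit tests of the fitting machinery
small_db <- function() {
  cached("small_db", build_database(40, n_molecules = 1000, seed = 101))
}

# reduced-scale recovery database: 2000 curves (full-scale analyses use
# 5122) at the model's default 1e4 molecules per curve
recovery_db <- function() {
  cached("recovery_db", build_database(2000, n_molecules = 1e4, seed = 202))
}

# noisy synthetic traces at a known truth: normalized curves + i.i.d.
# Gaussian noise, as a matrix on the database grid
truth_traces <- function(f_medium, f_long, n = 50, noise_sd = 0.02,
                         n_molecules = 1e4, seed = 1,
                         t_r_medium = 60, t_r_long = 1800) {
  p <- kinetic_params(f_medium, f_long, t_r_medium, t_r_long)
  sapply(seq_len(n), function(i) {
    cv <- simulate_frap(p, n_molecules = n_molecules, seed = seed * 7919 + i,
                        transport = "well_mixed")
    cv$normalized + rnorm(length(cv$normalized), 0, noise_sd)
  }) |> t()
}

# two-cluster photoconversion spec shared by several tests
two_cluster_spec <- function(exchange = 1) {
  stack_spec(
    clusters = data.frame(x = c(3.35, 4.65), y = c(3, 3), r = 0.25),
    exchange_fraction = exchange
  )
}
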