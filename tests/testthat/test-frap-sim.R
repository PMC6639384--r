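test_that("diffusion steps have the prescribed Gaussian statistics", {
  d <- diffusion_params(D = 1, dt = 0.1)
  expect_equal(sqrt(2 * d$D * d$dt), 0.4472, tolerance = 1e-4)
  # free-space MSD: one step, many molecules
  st <- sim_state(2e4, derive_rates(kinetic_params(0, 0, 50, 1800)),
                  cell_geometry("u2os"), seed = 3)
  pos0 <- st$pos
  st1 <- diffusion_step(st, d, n_steps = 1, seed = 9, bounded = FALSE)
  disp2 <- rowSums((st1$pos - pos0)^2)
  expect_equal(mean(disp2), 6 * d$D * d$dt, tolerance = 0.02)
  expect_equal(sd(st1$pos[, 1] - pos0[, 1]), sqrt(2 * d$D * d$dt),
               tolerance = 0.02)
})

test_that("D = 0 leaves positions unchanged and bound molecules never move", {
  r <- derive_rates(kinetic_params(0.3, 0.45, 50, 1800))
  st <- sim_state(500, r, cell_geometry("u2os"), seed = 4)
  st0 <- diffusion_step(st, diffusion_params(D = 0), n_steps = 5, seed = 1)
  expect_identical(st0$pos, st$pos)
  stm <- diffusion_step(st, diffusion_params(), n_steps = 3, seed = 1)
  bound <- st$state != "mobile"
  expect_identical(stm$pos[bound, ], st$pos[bound, ])
  expect_false(isTRUE(all.equal(stm$pos[!bound, ], st$pos[!bound, ])))
})

test_that("binding_step leaves a rate-free state untouched", {
  r <- tibble::tibble(k_on_medium = 0, k_off_medium = 0, k_on_long = 0,
                      k_off_long = 0)
  st <- sim_state(200, r, cell_geometry("u2os"), seed = 5)
  st1 <- binding_step(st, dt = 0.1, seed = 1)
  expect_identical(st1$state, st$state)
  expect_identical(st1$pos, st$pos)
})

test_that("medium-state dwell times are exponential with the right mean", {
  # k_off_medium = 0.02, no promotion: mean dwell 50 s
  r <- tibble::tibble(k_on_medium = 0, k_off_medium = 0.02, k_on_long = 0,
                      k_off_long = 1 / 1800)
  n <- 4000
  st <- sim_state(n, tibble::tibble(k_on_medium = 1, k_off_medium = 1e-12,
                                    k_on_long = 1e-12, k_off_long = 1e-12),
                  cell_geometry("u2os"), seed = 6)
  st$state <- rep("medium", n)  # cohort all starts medium-bound
  st$rates <- r
  dwell <- rep(NA_real_, n)
  set.seed(42)
  for (k in seq_len(12000)) {
    st <- binding_step(st, dt = 0.1)
    newly <- is.na(dwell) & st$state == "mobile"
    dwell[newly] <- k * 0.1
    if (!anyNA(dwell)) break
  }
  expect_lt(mean(is.na(dwell)), 0.001)
  expect_equal(mean(dwell, na.rm = TRUE), 50, tolerance = 0.05)
})

test_that("bleach probabilities behave at the limits", {
  st <- sim_state(300, derive_rates(kinetic_params(0.3, 0.45, 50, 1800)),
                  cell_geometry("u2os"), seed = 7)
  none <- bleach(st, bleach_pulse(alpha = 0), seed = 1)
  expect_true(all(none$fluorescent))
  hot <- bleach_pulse(centre = c(0, 0, 0), alpha = 1e9)
  st$pos[1, ] <- c(0, 0, 0)
  expect_equal(bleach_probability(hot, st$pos[1, , drop = FALSE]), 1)
  expect_lt(bleach_probability(bleach_pulse(centre = c(0, 0, 0)),
                               matrix(c(8, 0, 0), 1)), 1e-6)
  # default efficiency: centre bleach probability ~0.98
  expect_equal(bleach_probability(bleach_pulse(centre = c(0, 0, 0)),
                                  matrix(0, 1, 3)), 0.98)
})

test_that("the simulated pulse satisfies the bleach-depth inclusion rule", {
  p <- kinetic_params(0.30, 0.45, 50, 1800)
  cv <- simulate_frap(p, n_molecules = 5000, seed = 8)
  first_post <- cv$normalized[cv$phase == "postbleach"][1]
  expect_lt(first_post, 0.20)
})

test_that("identical seeds give bit-identical curves, different seeds differ", {
  p <- kinetic_params(0.2, 0.3, 40, 900)
  a <- simulate_frap(p, n_molecules = 800, seed = 12)
  b <- simulate_frap(p, n_molecules = 800, seed = 12)
  c <- simulate_frap(p, n_molecules = 800, seed = 13)
  expect_identical(a$count, b$count)
  expect_false(identical(a$count, c$count))
})

test_that("molecule count is conserved in the state bookkeeping", {
  p <- kinetic_params(0.25, 0.40, 50, 1200)
  cv <- simulate_frap(p, n_molecules = 3000, seed = 9, record_states = TRUE,
                      t_post = 60)
  sc <- attr(cv, "state_counts")
  expect_true(all(rowSums(sc) == 3000))
})

test_that("plateaus decrease as the stable fraction grows", {
  plateaus <- sapply(c(0.1, 0.3, 0.5), function(fl) {
    mean(sapply(1:10, function(s) {
      cv <- simulate_frap(kinetic_params(0.2, fl, 50, 1800),
                          n_molecules = 1500, seed = 300 + s)
      mean(cv$normalized[cv$time_s >= 300])
    }))
  })
  expect_true(all(diff(plateaus) < 0))
})

test_that("curves round-trip through CSV with their JSON sidecar", {
  p <- kinetic_params(0.2, 0.3, 40, 900)
  cv <- simulate_frap(p, n_molecules = 500, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frap_curve(cv, path)
  back <- read.csv(path)
  expect_equal(back$count, cv$count)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 21)
  expect_equal(meta$params$f_long, 0.3)
})
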