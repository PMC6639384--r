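test_that("moments threshold separates a two-delta histogram", {
  v <- c(rep(10, 50), rep(200, 50))
  thr <- moments_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # agrees with the brute-force moment-preservation oracle
  oracle <- moments_threshold_oracle(v)
  expect_true(any(abs(thr - oracle) < (200 - 10) / 256 + 1e-9))
  # deterministic
  expect_identical(thr, moments_threshold(v))
})

test_that("moments threshold matches the oracle on assorted histograms", {
  set.seed(12)
  for (k in 1:5) {
    v <- c(rnorm(400, 30, 5), rnorm(100 + 40 * k, 120, 15))
    thr <- moments_threshold(v)
    oracle <- moments_threshold_oracle(v)
    binw <- (max(v) - min(v)) / 256
    expect_true(min(abs(thr - oracle)) <= binw + 1e-9)
    expect_gt(thr, 40)
    expect_lt(thr, 120)
  }
})

test_that("a constant region has no foreground", {
  expect_true(is.na(moments_threshold(rep(7, 100))))
})

test_that("the green-channel mask recovers a synthetic FA (Jaccard >= 0.8)", {
  spec <- stack_spec()
  stack <- gen_photoconv_stack(spec, seed = 3)
  truth <- attr(stack, "truth")
  g <- apply(stack$green_pre, c(1, 2), mean)
  thr <- moments_threshold(g)
  mask <- g > thr
  jac <- sum(mask & truth$fa_mask) / sum(mask | truth$fa_mask)
  expect_gte(jac, 0.8)
})

test_that("8-connected labelling joins diagonals and separates islands", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE          # diagonal pair: one component
  m[5, 5] <- TRUE                            # far island
  lab <- label_components(m)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(max(lab), 2)
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("ratio view is the identity when nothing exchanges", {
  spec <- stack_spec(exchange_fraction = 0, read_noise_sd = 0,
                     photon_scale = 0)
  stack <- gen_photoconv_stack(spec, seed = 1)
  rv <- ratio_view(stack)
  expect_true(all(abs(rv$ratio[rv$fa_mask] - 1) < 1e-9))
})

test_that("ratio view is invariant to a common red-channel gain", {
  stack <- gen_photoconv_stack(two_cluster_spec(), seed = 5)
  gained <- stack
  gained$red_t0 <- stack$red_t0 * 3.7
  gained$red_post <- stack$red_post * 3.7
  rv1 <- ratio_view(stack)
  rv2 <- ratio_view(gained)
  expect_equal(rv2$ratio, rv1$ratio, tolerance = 1e-12)
})

test_that("median mask ratio falls monotonically with the exchange fraction", {
  med <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(ex) {
    spec <- stack_spec(exchange_fraction = ex)
    rv <- ratio_view(gen_photoconv_stack(spec, seed = 9))
    median(rv$ratio[rv$fa_mask])
  })
  expect_true(all(diff(med) < 0))
  expect_gt(med[1], 0.9)   # fixed control: ratios high throughout the FA
  expect_lt(med[5], 0.3)   # full exchange: ratio collapses to the red floor
})

test_that("fixed control yields one stable area covering nearly the whole FA", {
  stack <- gen_photoconv_stack(stack_spec(exchange_fraction = 0), seed = 2)
  rv <- ratio_view(stack)
  areas <- detect_stable_areas(rv)
  expect_equal(nrow(areas), 1)
  cov <- coverage_stats(areas)
  expect_gte(cov$coverage_ratio, 0.9)
  expect_false(attr(areas, "split_accepted"))
})

test_that("two implanted clusters are recovered at their true positions", {
  stack <- gen_photoconv_stack(two_cluster_spec(), seed = 4)
  truth <- attr(stack, "truth")
  rv <- ratio_view(stack)
  areas <- detect_stable_areas(rv)
  expect_equal(nrow(areas), 2)
  got <- areas[order(areas$centroid_x), ]
  for (i in 1:2) {
    expect_lt(abs(got$centroid_x[i] - truth$spec$clusters$x[i]),
              rv$pixel_size + 1e-9)
    expect_lt(abs(got$centroid_y[i] - truth$spec$clusters$y[i]),
              rv$pixel_size + 1e-9)
  }
  # deterministic labelling
  areas2 <- detect_stable_areas(ratio_view(stack))
  expect_identical(attr(areas, "labels"), attr(areas2, "labels"))
})

test_that("the 0.05 um^2 area rule is inclusive at the boundary", {
  # hand-built ratio view: 0.1 um pixels, so 5 px = 0.05 um^2 (kept) and
  # 4 px = 0.04 um^2 (rejected)
  ratio <- matrix(0.1, 20, 20)
  mask <- matrix(TRUE, 20, 20)
  ratio[3, 3:7] <- 1          # 5-px line
  ratio[10, 3:6] <- 1         # 4-px line
  rv <- structure(list(ratio = ratio, fa_mask = mask, pixel_size = 0.1),
                  class = "ratio_view")
  areas <- detect_stable_areas(rv, min_separation = 0.5)
  expect_equal(nrow(areas), 1)
  expect_equal(areas$area_um2, 0.05)
})

test_that("stable areas stay inside the FA mask and bound the coverage", {
  stack <- gen_photoconv_stack(two_cluster_spec(), seed = 6)
  rv <- ratio_view(stack)
  areas <- detect_stable_areas(rv)
  lab <- attr(areas, "labels")
  expect_true(all(rv$fa_mask[lab > 0]))
  cov <- coverage_stats(areas)
  expect_gte(cov$coverage_ratio, 0)
  expect_lte(cov$coverage_ratio, 1)
  expect_equal(cov$summed_area_um2, sum(areas$area_um2))
})

test_that("weighted centre reduces to the area-weighted projection", {
  fa <- list(centroid_x = 5, centroid_y = 3, theta_deg = 0, major_um = 4,
             minor_um = 1, orientation = "pointing", distal_x = 3,
             distal_y = 3)
  one <- tibble::tibble(area_um2 = 0.2, centroid_x = 5, centroid_y = 3)
  expect_equal(weighted_centre(one, fa), 0.5)
  two <- tibble::tibble(area_um2 = c(0.2, 0.2),
                        centroid_x = c(4, 6), centroid_y = c(3, 3))
  expect_equal(weighted_centre(two, fa), 0.5)
  asym <- tibble::tibble(area_um2 = c(0.1, 0.3),
                         centroid_x = 3 + c(0.2, 0.8) * 4,
                         centroid_y = c(3, 3))
  expect_equal(weighted_centre(asym, fa), 0.65)
  none <- tibble::tibble(area_um2 = numeric(0), centroid_x = numeric(0),
                         centroid_y = numeric(0))
  expect_warning(out <- weighted_centre(none, fa), "no stable areas")
  expect_true(is.na(out))
})

test_that("conversion efficiency scales red signal but not the pipeline output", {
  lo <- gen_photoconv_stack(stack_spec(exchange_fraction = 0,
                                       conversion_efficiency = 0.5,
                                       read_noise_sd = 0, photon_scale = 0),
                            seed = 7)
  hi <- gen_photoconv_stack(stack_spec(exchange_fraction = 0,
                                       conversion_efficiency = 1,
                                       read_noise_sd = 0, photon_scale = 0),
                            seed = 7)
  fa <- attr(lo, "truth")$fa_mask
  r_lo <- apply(lo$red_t0, c(1, 2), mean)[fa]
  r_hi <- apply(hi$red_t0, c(1, 2), mean)[fa]
  expect_equal(mean(r_lo / r_hi), 0.5, tolerance = 0.05)
  expect_equal(ratio_view(lo)$ratio, ratio_view(hi)$ratio, tolerance = 1e-9)
})

test_that("rotated plots follow the distal-left convention", {
  stack <- gen_photoconv_stack(two_cluster_spec(), seed = 8)
  rv <- ratio_view(stack)
  areas <- detect_stable_areas(rv)
  fa <- list(centroid_x = 4, centroid_y = 3, theta_deg = 0, major_um = 2,
             minor_um = 1, orientation = "pointing", distal_x = 3,
             distal_y = 3)
  p <- rotated_plot(fa, areas, rv)
  expect_s3_class(p, "ggplot")
  # pointing: long axis horizontal in the rotated frame
  expect_gt(diff(range(p$data$x)), diff(range(p$data$y)))
  fa$orientation <- "other"
  expect_warning(rotated_plot(fa, areas, rv), "unrotated")
})

test_that("stacks round-trip through TIFF with their sidecar", {
  stack <- gen_photoconv_stack(stack_spec(shape = c(30, 40)), seed = 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_photoconv_stack(stack, path)
  back <- read_photoconv_stack(path)
  expect_equal(back$pixel_size, stack$pixel_size)
  expect_equal(back$green_pre, stack$green_pre, tolerance = 1e-5)
  expect_equal(back$red_post, stack$red_post, tolerance = 1e-5)
})
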