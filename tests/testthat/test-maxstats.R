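test_that("degenerate and separable inputs behave as designed", {
  set.seed(50)
  # all-unit topographies: observed max equals the null value, nothing significant
  ones <- matrix(1, 8, 16)
  r <- max_stat_test(ones, n_perm = 500)
  expect_length(r$significant, 0)
  expect_equal(unname(r$observed), rep(1, 16))
  # one clearly separated channel is detected
  topos <- matrix(rnorm(8 * 16, mean = 1, sd = 0.3), 8, 16)
  topos[, 5] <- 50
  r2 <- max_stat_test(topos, n_perm = 500)
  expect_true("5" %in% r2$significant)
  expect_error(max_stat_test(topos[1, , drop = FALSE]), "at least 2")
})

test_that("threshold is the empirical null quantile, monotone in alpha, seed-stable", {
  set.seed(51)
  topos <- matrix(rnorm(10 * 32, 1, 0.5), 10, 32)
  set.seed(52); a <- max_stat_test(topos, n_perm = 1000, alpha = 0.05)
  set.seed(52); b <- max_stat_test(topos, n_perm = 1000, alpha = 0.05)
  expect_identical(a$threshold, b$threshold)
  expect_identical(a$significant, b$significant)
  expect_equal(a$threshold,
               unname(quantile(a$null_max, 0.95, type = 1)))
  set.seed(52); strict <- max_stat_test(topos, n_perm = 1000, alpha = 0.01)
  expect_gte(strict$threshold, a$threshold)
  # doubling n_perm moves the threshold by < 2%
  set.seed(53); t1 <- max_stat_test(topos, n_perm = 4000)$threshold
  set.seed(53); t2 <- max_stat_test(topos, n_perm = 8000)$threshold
  expect_lt(abs(t2 - t1) / t1, 0.02)
})

test_that("tibble and matrix inputs agree", {
  set.seed(54)
  topos <- matrix(rnorm(6 * 8, 1, 0.4), 6, 8,
                  dimnames = list(NULL, as.character(1:8)))
  long <- tibble::tibble(
    unit = rep(1:6, times = 8),
    channel = rep(1:8, each = 6),
    snr = as.vector(topos)
  )
  set.seed(99); a <- max_stat_test(topos, n_perm = 200)
  set.seed(99); b <- max_stat_test(long, n_perm = 200)
  expect_equal(a$observed, b$observed)
  expect_identical(a$threshold, b$threshold)
})

test_that("null error rates of the two surrogate schemes match their measured behaviour", {
  # On white-noise SNR topographies the unit-topography masking scheme is
  # anticonservative by construction (the replacement value carries no
  # variance); the sign-flip scheme is near-nominal, inflated only by the
  # skew of the null SNR distribution. These bands pin that behaviour.
  set.seed(55)
  run <- function(method, nrep) {
    mean(replicate(nrep, {
      topos <- t(sapply(1:8, function(i) null_topography(n_ch = 24, fs = 100)))
      length(max_stat_test(topos, n_perm = 500, method = method)$significant) > 0
    }))
  }
  fwe_mask <- run("mask", 120)
  fwe_flip <- run("signflip", 120)
  expect_gt(fwe_mask, 0.15)
  expect_lt(fwe_flip, 0.20)
  expect_lt(fwe_flip, fwe_mask)
})

test_that("individual and group ROI localize a strong occipital responder", {
  set.seed(56)
  # 8 valid trials: with the masking surrogate, significance needs enough
  # units that near-complete masks are rare in the null distribution
  rec <- quick_subject("doublet", n_trials = 8, fs = 100,
                       looking = rep(20, 8))
  st <- snr_table(segment_trials(rereference_average(rec)), c(6, 9))
  rois <- individual_roi(st, c(6, 9), n_perm = 1000)
  expect_named(rois, c("6", "9"))
  expect_true(any(c("74", "75", "82") %in% rois[["6"]]$significant))
  # significant channels cluster occipitally (high spatial gain region)
  gain <- setNames(freqtagsl:::occipital_gain(the_montage),
                   the_montage$positions$channel)
  expect_true(all(gain[rois[["6"]]$significant] > 0.1))

  # null subject: no significant channels expected
  set.seed(57)
  rec0 <- quick_subject("random", n_trials = 4, fs = 100, looking = rep(0, 4))
  st0 <- snr_table(segment_trials(rereference_average(rec0)), 9)
  r0 <- individual_roi(st0, 9, n_perm = 1000)
  expect_lte(length(r0[["9"]]$significant), 2)
})
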