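test_that("build_table restricts orders and transforms outcomes", {
  set.seed(60)
  tbl <- simulate_snr_table(n_per_condition = 2, n_trials = 12)
  built <- build_table(tbl, max_order = 9)
  expect_lte(max(built$order), 9)
  expect_equal(built$log_snr_base, log10(built$snr_base))
  one <- built[1, ]
  expect_equal(one$learning_index, one$snr_doublet / one$snr_base)
  # snr of 10 maps to log DV 1
  fake <- tbl[1, ]
  fake$snr_base <- 10
  expect_equal(build_table(fake, max_order = 99)$log_snr_base, 1)
})

test_that("simple coding makes the intercept the unweighted grand mean", {
  set.seed(61)
  tbl <- build_table(simulate_snr_table(n_per_condition = 6, n_trials = 6))
  fit <- lme4::lmer(log_snr_doublet ~ condition + (1 | subject_id),
                    data = tbl, REML = FALSE)
  cond_means <- tapply(predict(fit, re.form = NA), tbl$condition, mean)
  expect_equal(unname(lme4::fixef(fit)[1]), mean(cond_means), tolerance = 1e-6)
  # coding matrix columns sum to zero
  expect_equal(colSums(stats::contrasts(tbl$condition)), c(`2` = 0, `3` = 0))
})

test_that("the ladder recovers a pure condition effect on doublet-level SNR", {
  set.seed(62)
  tbl <- build_table(simulate_snr_table(n_per_condition = 8, n_trials = 9))
  lad <- fit_ladder(tbl, "snr_doublet")
  expect_true("condition" %in% lad$selected)
  expect_true(all(lad$steps$chisq[-1] >= 0, na.rm = TRUE))
  ph <- post_hoc(lad)
  m <- setNames(ph$means$mean, as.character(ph$means$condition))
  expect_gt(m[["doublet"]], m[["control"]])
  expect_gt(m[["control"]], m[["random"]])
  # Tukey adjustment never decreases a p value below its unadjusted value
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(lad$fit, "condition", lmer.df = "satterthwaite"),
    method = "pairwise", adjust = "none"
  ))
  expect_true(all(ph$contrasts$p.value >= raw$p.value - 1e-12))
  # back-transformed means are 10^mean
  expect_equal(ph$means$back_mean, 10^ph$means$mean)
})

test_that("the ladder recovers a negative order slope on base-level SNR", {
  set.seed(63)
  tbl <- build_table(simulate_snr_table(n_per_condition = 8, n_trials = 9))
  lad <- fit_ladder(tbl, "snr_base")
  expect_true("order" %in% lad$selected)
  est <- tidy(lad)
  expect_lt(est$estimate[est$term == "order"], 0)
  expect_true(all(c("aic_ml", "icc") %in% names(glance(lad))))
})

test_that("the null ladder keeps the random-intercept model at roughly (1-alpha)^4", {
  set.seed(64)
  keeps <- replicate(100, {
    tbl <- build_table(simulate_snr_table(
      n_per_condition = 5, n_trials = 6,
      base_slope = 0,
      doublet_means = c(doublet = 0.1, control = 0.1, random = 0.1)
    ))
    lad <- fit_ladder(tbl, "snr_doublet")
    identical(lad$selected, "intercept-only")
  })
  # four independent-ish LRTs at alpha = .05: expect about 0.95^4 = 0.81
  expect_gt(mean(keeps), 0.70)
  expect_lt(mean(keeps), 0.93)
})

test_that("ICC reflects the generating variance ratio and its limits", {
  set.seed(65)
  # between:residual = 1:3 -> ICC 0.25 (condition means equal, so no
  # condition variance loads into the subject intercepts)
  iccs <- replicate(12, {
    tbl <- build_table(simulate_snr_table(
      n_per_condition = 14, n_trials = 10,
      doublet_means = c(doublet = 0.1, control = 0.1, random = 0.1),
      doublet_sd_subject = 0.2, doublet_sd_resid = 0.2 * sqrt(3)
    ))
    icc(lme4::lmer(log_snr_doublet ~ (1 | subject_id), data = tbl, REML = TRUE))
  })
  expect_lt(abs(mean(iccs) - 0.25), 0.05)
  # near-zero between-subject variance
  set.seed(66)
  eq <- c(doublet = 0.1, control = 0.1, random = 0.1)
  tbl0 <- build_table(simulate_snr_table(n_per_condition = 10, n_trials = 8,
                                         doublet_means = eq,
                                         doublet_sd_subject = 1e-4))
  expect_lt(icc(lme4::lmer(log_snr_doublet ~ (1 | subject_id), data = tbl0)), 0.1)
  # near-zero residual variance
  set.seed(67)
  tbl1 <- build_table(simulate_snr_table(n_per_condition = 10, n_trials = 8,
                                         doublet_means = eq,
                                         doublet_sd_subject = 0.3,
                                         doublet_sd_resid = 0.02))
  expect_gt(icc(lme4::lmer(log_snr_doublet ~ (1 | subject_id), data = tbl1)), 0.9)
})

test_that("post_hoc reports slope contrasts and per-order comparisons when the interaction is retained", {
  set.seed(68)
  tbl <- build_table(simulate_snr_table(
    n_per_condition = 10, n_trials = 9,
    doublet_slopes = c(doublet = -0.05, control = 0, random = 0.03)
  ))
  lad <- fit_ladder(tbl, "snr_doublet")
  expect_true("condition:order" %in% lad$selected)
  ph <- post_hoc(lad, at_orders = c(1, 5, 9))
  expect_equal(nrow(ph$slopes), 3)
  expect_equal(nrow(ph$slope_contrasts), 3)
  expect_setequal(unique(ph$by_order$order), c(1, 5, 9))
  sl <- setNames(ph$slopes$order.trend, as.character(ph$slopes$condition))
  expect_lt(sl[["doublet"]], sl[["random"]])
})

test_that("post_hoc refuses models without a condition term", {
  set.seed(69)
  tbl <- build_table(simulate_snr_table(
    n_per_condition = 4, n_trials = 5,
    doublet_means = c(doublet = 0.1, control = 0.1, random = 0.1)
  ))
  lad <- fit_ladder(tbl, "snr_doublet")
  if (!"condition" %in% lad$selected) {
    expect_error(post_hoc(lad), "condition")
  } else {
    succeed() # rare under the null, but then post_hoc is legitimately callable
  }
})
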