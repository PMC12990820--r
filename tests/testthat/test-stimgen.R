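test_that("pairing schemes partition the eight shapes and are seed-reproducible", {
  set.seed(1)
  for (cond in c("doublet", "control")) {
    p <- make_pairing(cond)
    expect_setequal(c(p$first, p$second), 1:8)
    expect_length(p$first, 4)
  }
  expect_length(make_pairing("random")$first, 0)
  set.seed(99); a <- make_pairing("doublet")
  set.seed(99); b <- make_pairing("doublet")
  expect_identical(a, b)
})

test_that("pairings are uniform over admissible partitions", {
  set.seed(2)
  # shape 1's partner in the doublet condition should be uniform over 2..8
  partners <- replicate(3500, {
    p <- make_pairing("doublet")
    i <- which(p$first == 1)
    if (length(i)) p$second[i] else p$first[which(p$second == 1)]
  })
  tab <- table(factor(partners, levels = 2:8))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("trial sequences satisfy their condition's structural invariants", {
  set.seed(3)
  # doublet: partner always follows, no immediate doublet repetition
  p <- make_pairing("doublet")
  s <- generate_trial_sequence(p, n_core = 120, n_fade = 12)
  expect_equal(nrow(s), 144)
  expect_equal(sum(s$triggered), 120)
  expect_false(any(s$triggered[1:12]) || any(s$triggered[133:144]))
  partner <- setNames(p$second, p$first)
  odd <- seq(1, 143, by = 2)
  expect_true(all(s$shape_id[odd + 1] == partner[as.character(s$shape_id[odd])]))
  dbl <- s$shape_id[odd]
  expect_false(any(dbl[-1] == dbl[-length(dbl)]))

  # control: positions alternate between the two sets; no identical doublet twice
  pc <- make_pairing("control")
  sc <- generate_trial_sequence(pc, n_core = 400, n_fade = 0)
  oddc <- seq(1, 399, by = 2)
  expect_true(all(sc$shape_id[oddc] %in% pc$first))
  expect_true(all(sc$shape_id[oddc + 1] %in% pc$second))
  key <- paste(sc$shape_id[oddc], sc$shape_id[oddc + 1])
  expect_false(any(key[-1] == key[-length(key)]))

  # random: no immediate shape repetition
  sr <- generate_trial_sequence(make_pairing("random"), n_core = 1000, n_fade = 0)
  expect_false(any(sr$shape_id[-1] == sr$shape_id[-1000]))

  # odd core counts are rejected for paired conditions
  expect_error(generate_trial_sequence(p, n_core = 121), "even")
})

test_that("empirical transitional probabilities match the analytic design values", {
  set.seed(4)
  # doublet: within-TP exactly 1, between-TP exactly 1/3 over observed successors
  p <- make_pairing("doublet")
  s <- generate_trial_sequence(p, n_core = 20000, n_fade = 0)
  tp <- empirical_tp(s)
  expect_identical(tp$tp_within, 1)
  expect_equal(tp$tp_between, 1 / 3, tolerance = 1e-12)
  # every admissible successor close to 1/3 individually
  b <- tp$between[rowSums(tp$between) > 0, ]
  expect_lt(max(abs(b[b > 0] - 1 / 3)), 0.05)

  # random: off-diagonal entries converge to 1/7. The mean over observed
  # successors is exactly 1/7 at any length; the worst cell among all 56
  # has a binomial SD of ~0.010 at 10,000 transitions, so the worst-cell
  # bound of 0.02 is checked at 50,000 transitions where it holds with
  # wide margin.
  sr <- generate_trial_sequence(make_pairing("random"), n_core = 10000, n_fade = 0)
  tpr <- empirical_tp(sr)
  expect_true(is.na(tpr$tp_within))
  expect_equal(tpr$tp_between, 1 / 7, tolerance = 1e-12)
  sr2 <- generate_trial_sequence(make_pairing("random"), n_core = 50000, n_fade = 0)
  off <- empirical_tp(sr2)$matrix
  off <- off[row(off) != col(off)]
  expect_lt(max(abs(off - 1 / 7)), 0.02)

  # control: P(specific second | first) converges to 1/4
  sc <- generate_trial_sequence(make_pairing("control"), n_core = 20000, n_fade = 0)
  tpc <- empirical_tp(sc)
  expect_equal(tpc$tp_within, 1 / 4, tolerance = 1e-12)
  w <- tpc$within[rowSums(tpc$within) > 0, ]
  expect_lt(max(abs(w[w > 0] - 1 / 4)), 0.05)
})

test_that("transition counting respects trial boundaries and exports tidy tables", {
  set.seed(5)
  p <- make_pairing("doublet")
  seqs <- lapply(1:3, function(i) generate_trial_sequence(p))
  tp <- empirical_tp(seqs)
  expect_identical(tp$tp_within, 1)
  tab <- sequence_table(seqs)
  expect_equal(nrow(tab), 3 * 144)
  expect_setequal(names(tab), c("trial", "position", "shape_id", "triggered"))
  td <- tidy(tp)
  expect_equal(nrow(td), 64)
  # rows of the full matrix are probability distributions
  expect_true(all(abs(rowSums(tp$matrix) - 1) < 1e-12))
})
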