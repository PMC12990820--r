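test_that("validity combines the occipital SNR and looking criteria with strict bounds", {
  occ10 <- the_montage$occ10
  topo <- setNames(rep(1, 128), 1:128)
  topo["75"] <- 3.1
  expect_true(trial_is_valid(topo, looking_s = 12, occ10 = occ10))
  topo["75"] <- 5
  expect_false(trial_is_valid(topo, looking_s = 6, occ10 = occ10))
  # boundary: SNR exactly 2 and looking exactly 7 both fail
  topo[as.character(occ10)] <- 2
  expect_false(trial_is_valid(topo, looking_s = 20, occ10 = occ10))
  topo["75"] <- 2.5
  expect_false(trial_is_valid(topo, looking_s = 7, occ10 = occ10))
  # SNR high outside occ10 does not rescue a trial
  topo[as.character(occ10)] <- 1
  topo["1"] <- 50
  expect_false(trial_is_valid(topo, looking_s = 20, occ10 = occ10))
})

test_that("renumbering drops invalid trials and sparse subjects", {
  rec <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), times = c(4, 2, 1)),
    trial = c(1:4, 1:2, 1),
    valid = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  out <- renumber_and_filter(rec)
  expect_equal(out$subject_id, rep("a", 3)) # b: 1 valid, c: 1 valid -> dropped
  expect_equal(out$order, 1:3)
  expect_equal(out$trial, c(1, 3, 4))
  # idempotent on its own output
  again <- renumber_and_filter(out)
  expect_equal(again$order, out$order)
  expect_equal(nrow(renumber_and_filter(rec[0, ])), 0)
})

test_that("order restriction keeps the longest prefix with balanced contributions", {
  base <- tidyr::crossing(
    condition = c("doublet", "control", "random"),
    subject = 1:10, order = 1:12
  ) |>
    dplyr::mutate(subject_id = paste0(condition, subject))
  # in one condition only 3/10 subjects reach order 10
  thinned <- base |>
    dplyr::filter(!(condition == "random" & subject > 3 & order >= 10))
  out <- restrict_orders(thinned)
  expect_equal(attr(out, "max_order"), 9)
  expect_lte(max(out$order), 9)
  # full contribution: no restriction
  full <- restrict_orders(base)
  expect_equal(attr(full, "max_order"), 12)
  # min_fraction 0 disables the restriction
  none <- restrict_orders(thinned, min_fraction = 0)
  expect_equal(attr(none, "max_order"), 12)
})

test_that("harmonic selection finds exactly the stimulated frequencies", {
  set.seed(40)
  fs <- 100
  n <- 20 * fs
  t <- 0:(n - 1)
  base_freqs <- c(6, 12, 18, 24)
  amps <- c(0.15, 0.12, 0.09, 0.07)
  make_trial <- function(i) {
    x <- rnorm(n)
    for (j in seq_along(base_freqs)) {
      x <- x + amps[j] * n_signal(base_freqs[j], t, fs)
    }
    sp <- amplitude_spectrum(matrix(x, 1), fs)
    freqs <- c(harmonic_candidates("base"), harmonic_candidates("doublet"))
    tibble::tibble(trial = i, frequency = freqs,
                   snr = vapply(freqs, function(f) snr_at(sp, f)[[1]], 0))
  }
  n_signal <- function(f, t, fs) sin(2 * pi * f * t / fs)
  trials <- dplyr::bind_rows(lapply(1:40, make_trial))
  base_sel <- select_harmonics(trials, "base")
  expect_true(all(c(6, 12, 18, 24) %in% base_sel$harmonics))
  expect_false(any(c(30, 36) %in% base_sel$harmonics))
  # doublet family sees only noise here
  dbl_sel <- select_harmonics(trials, "doublet")
  expect_lte(length(dbl_sel$harmonics), 1) # at most a rare false positive
  expect_true(all(tidy(base_sel)$W >= 0))
  expect_error(select_harmonics(trials[trials$trial == 1, ], "base"), "fewer than 2")
})

test_that("valid_trial_records assembles the analysis table end to end", {
  set.seed(41)
  recs <- lapply(1:2, function(i) {
    r <- quick_subject("doublet", n_trials = 4, fs = 100,
                       subject_id = sprintf("s%02d", i),
                       looking = c(20, 18, 3, 16))
    snr_table(segment_trials(rereference_average(r)), c(3, 6, 9, 12, 18, 24))
  })
  tbl <- valid_trial_records(dplyr::bind_rows(recs),
                             roi = the_montage$occ3, occ10 = the_montage$occ10)
  # the 3-s looking trial can never be valid
  expect_false(any(tbl$trial == 3))
  expect_true(all(tbl$order == ave(tbl$order, tbl$subject_id, FUN = seq_along)))
  expect_true(all(tbl$learning_index > 0))
  expect_equal(tbl$learning_index, tbl$snr_doublet / tbl$snr_base)
})
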