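# Valid-trial selection, trial-order renumbering, analyzable-order
# restriction, and Wilcoxon harmonic selection.

#' Valid-trial criterion
#'
#' A trial is valid when the 6-Hz SNR exceeds 2 in at least one of the 10
#' pre-defined medial occipital channels AND the infant looked at the
#' screen for more than 7 s. Both bounds are strict.
#'
#' @param snr_topo_6hz Named numeric: per-channel SNR at 6 Hz (names =
#'   channel numbers).
#' @param looking_s Looking duration in seconds.
#' @param occ10 Channel numbers of the occipital selection set.
#' @param snr_threshold SNR cut-off (default 2).
#' @param min_look_s Looking cut-off in seconds (default 7).
#' @return Logical flag.
#' @export
trial_is_valid <- function(snr_topo_6hz, looking_s,
                           occ10 = load_montage()$occ10,
                           snr_threshold = 2, min_look_s = 7) {
  topo <- snr_topo_6hz[as.character(occ10)]
  stopifnot(!any(is.na(topo)))
  max(topo) > snr_threshold && looking_s > min_look_s
}

#' Drop invalid trials, renumber orders, drop sparse subjects
#'
#' Removes invalid trials, renumbers each subject's remaining trials
#' consecutively from 1 in acquisition order (`order` = the relative
#' position of each valid trial), and removes subjects contributing fewer
#' than `min_valid` valid trials.
#'
#' @param records Tibble with columns `subject_id`, `trial` (acquisition
#'   index), `valid` (logical), and any others.
#' @param min_valid Minimum valid trials per retained subject (default 2).
#' @return The filtered tibble with an `order` column.
#' @export
renumber_and_filter <- function(records, min_valid = 2L) {
  stopifnot(all(c("subject_id", "trial", "valid") %in% names(records)))
  records |>
    dplyr::filter(.data$valid) |>
    dplyr::arrange(.data$subject_id, .data$trial) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::filter(dplyr::n() >= min_valid) |>
    dplyr::ungroup()
}

#' Restrict analysis to well-populated trial orders
#'
#' Keeps the longest prefix of orders 1..K such that, at every retained
#' order, every condition still has at least `min_fraction` of its subjects
#' contributing a trial.
#'
#' @param records Output of [renumber_and_filter()] with columns
#'   `subject_id`, `condition`, `order`.
#' @param min_fraction Minimum fraction of a condition's subjects per
#'   retained order (default 0.40).
#' @return The records restricted to orders 1..K, with attribute
#'   `max_order` = K.
#' @export
restrict_orders <- function(records, min_fraction = 0.40) {
  stopifnot(all(c("subject_id", "condition", "order") %in% names(records)))
  n_subj <- records |>
    dplyr::distinct(.data$condition, .data$subject_id) |>
    dplyr::count(.data$condition, name = "n_subjects")
  frac <- records |>
    dplyr::count(.data$condition, .data$order) |>
    dplyr::left_join(n_subj, by = "condition") |>
    dplyr::mutate(fraction = .data$n / .data$n_subjects)
  # an order qualifies when every condition reaches the threshold there
  ok_by_order <- frac |>
    tidyr::complete(.data$order, .data$condition, fill = list(fraction = 0)) |>
    dplyr::group_by(.data$order) |>
    dplyr::summarise(ok = all(.data$fraction >= min_fraction) &&
                       dplyr::n() == nrow(n_subj), .groups = "drop") |>
    dplyr::arrange(.data$order)
  k <- 0L
  for (i in seq_len(nrow(ok_by_order))) { # retained orders must be a prefix
    if (ok_by_order$order[i] == i && ok_by_order$ok[i]) k <- i else break
  }
  out <- dplyr::filter(records, .data$order <= k)
  attr(out, "max_order") <- k
  out
}

#' Select significant harmonics with one-sample Wilcoxon tests
#'
#' For each candidate frequency of the family, tests whether the per-trial
#' SNR differs from 1 (two-sided Wilcoxon signed rank, zeros dropped). Base
#' candidates use trials from all conditions; doublet candidates should be
#' given doublet- and control-condition trials only (no doublet-rate
#' response exists under the random condition).
#'
#' @param trial_snr Tibble with columns `frequency` and `snr`, one row per
#'   trial x frequency (pre-filtered to the appropriate conditions).
#' @param family `"base"` or `"doublet"`.
#' @param range Candidate frequency range in Hz (default 2-36).
#' @param alpha Selection level (default 0.05).
#' @return List of class `harmonic_selection`: `family`, `harmonics`
#'   (selected frequencies), `tests` (tibble: frequency, W, p_value,
#'   selected).
#' @export
select_harmonics <- function(trial_snr, family = c("base", "doublet"),
                             range = c(2, 36), alpha = 0.05) {
  family <- match.arg(family)
  candidates <- harmonic_candidates(family, range)
  tests <- purrr::map_dfr(candidates, function(f) {
    x <- trial_snr$snr[trial_snr$frequency == f]
    if (length(x) < 2L) stop(sprintf("fewer than 2 trials at %g Hz", f))
    w <- stats::wilcox.test(x, mu = 1, alternative = "two.sided", exact = FALSE)
    tibble::tibble(frequency = f, W = unname(w$statistic), p_value = w$p.value)
  })
  tests$selected <- tests$p_value < alpha
  structure(
    list(family = family, harmonics = tests$frequency[tests$selected], tests = tests),
    class = "harmonic_selection"
  )
}

#' @export
print.harmonic_selection <- function(x, ...) {
  cat("<harmonic_selection>", x$family, "family; selected:",
      if (length(x$harmonics)) paste(x$harmonics, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @describeIn select_harmonics Tidy table of the per-frequency tests.
#' @param x A `harmonic_selection`.
#' @param ... Unused.
#' @export
tidy.harmonic_selection <- function(x, ...) x$tests

#' Build per-trial valid-trial records from SNR tables
#'
#' Combines a long SNR table (one row per trial x channel x frequency) into
#' the analysis table: per-trial validity (6-Hz criterion + looking),
#' renumbered orders, and ROI-mean SNR summaries at the base and doublet
#' harmonic sets plus their ratio (the doublet learning index).
#'
#' @param snr_tbl Output of [snr_table()] covering 6 Hz, the base set and
#'   the doublet set.
#' @param base_set,doublet_set Harmonic sets to average.
#' @param roi Channels over which SNR is averaged for the summaries
#'   (default the 3-channel medial occipital ROI).
#' @param occ10 Channel set for the validity criterion.
#' @param snr_threshold,min_look_s,min_valid See [trial_is_valid()] and
#'   [renumber_and_filter()].
#' @return Tibble: subject_id, condition, age_days, trial, looking_s,
#'   valid, order, snr_base, snr_doublet, learning_index.
#' @export
valid_trial_records <- function(snr_tbl,
                                base_set = c(6, 12, 18, 24),
                                doublet_set = c(3, 9),
                                roi = load_montage()$occ3,
                                occ10 = load_montage()$occ10,
                                snr_threshold = 2, min_look_s = 7,
                                min_valid = 2L) {
  validity <- snr_tbl |>
    dplyr::filter(.data$frequency == 6, .data$channel %in% occ10) |>
    dplyr::group_by(.data$subject_id, .data$trial) |>
    dplyr::summarise(
      max_occ_snr = max(.data$snr),
      looking_s = .data$looking_s[1L], .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$max_occ_snr > snr_threshold &
                    .data$looking_s > min_look_s)
  summaries <- snr_tbl |>
    dplyr::filter(.data$channel %in% roi) |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$age_days, .data$trial) |>
    dplyr::summarise(
      snr_base = mean(.data$snr[.data$frequency %in% base_set]),
      snr_doublet = mean(.data$snr[.data$frequency %in% doublet_set]),
      .groups = "drop"
    ) |>
    dplyr::mutate(learning_index = .data$snr_doublet / .data$snr_base)
  out <- summaries |>
    dplyr::left_join(validity[c("subject_id", "trial", "looking_s", "valid")],
                     by = c("subject_id", "trial")) |>
    renumber_and_filter(min_valid = min_valid)
  out
}
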