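# Permutation maximum statistics over whole-scalp SNR topographies.
#
# The null hypothesis is SNR = 1 everywhere. Surrogates replace each unit's
# topography, independently with probability 1/2, by the all-ones "unit
# topography"; the maximum over channels of the surrogate mean forms the
# null distribution, whose (1 - alpha) quantile is the family-wise
# significance threshold.

#' Permutation maximum-statistics test
#'
#' @param topos Units x channels matrix of SNR topographies (one row per
#'   unit: trials for individual-level analysis, subjects for group-level),
#'   or a long tibble with columns `unit`, `channel`, `snr`.
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Family-wise level (default 0.05).
#' @param method Surrogate scheme. `"mask"` (default) replaces each unit's
#'   topography, independently with probability 1/2, by the all-ones unit
#'   topography before averaging — the masking scheme of the
#'   frequency-tagging literature. Because the replacement value carries no
#'   variance, this null distribution is narrower than the observed mean
#'   and the scheme is anticonservative on null data; it behaves as a
#'   detection heuristic rather than an exact test. `"signflip"` reflects
#'   each unit's topography about the unit topography (SNR -> 2 - SNR)
#'   instead, the standard one-sample permutation scheme, exact when the
#'   null SNR distribution is symmetric about 1.
#' @return Object of class `max_stat_result`: `observed` (named per-channel
#'   mean), `null_max` (length `n_perm`), `threshold` (empirical
#'   (1-alpha) quantile, higher-order statistic), `significant` (channel
#'   names with observed mean strictly above threshold), `alpha`, `n_unit`.
#' @export
max_stat_test <- function(topos, n_perm = 10000L, alpha = 0.05,
                          method = c("mask", "signflip")) {
  method <- match.arg(method)
  if (is.data.frame(topos)) {
    stopifnot(all(c("unit", "channel", "snr") %in% names(topos)))
    topos <- tidyr::pivot_wider(
      topos[c("unit", "channel", "snr")],
      names_from = "channel", values_from = "snr"
    )
    topos <- as.matrix(topos[, -1L, drop = FALSE])
  }
  stopifnot(is.matrix(topos), n_perm >= 1L)
  n_unit <- nrow(topos)
  if (n_unit < 2L) stop("at least 2 units (trials or subjects) are required")
  if (is.null(colnames(topos))) colnames(topos) <- seq_len(ncol(topos))

  observed <- colMeans(topos)
  # Centering at 1 turns "replace by the unit topography" into zeroing a
  # row (mask) and "reflect about the unit topography" into negating it
  # (signflip).
  centered <- topos - 1
  masks <- matrix(stats::rbinom(n_perm * n_unit, 1L, 0.5), n_perm, n_unit)
  if (method == "signflip") masks <- 2 * masks - 1
  null_max <- apply((masks %*% centered) / n_unit + 1, 1, max)
  threshold <- unname(stats::quantile(null_max, 1 - alpha, type = 1))
  structure(
    list(
      observed = observed, null_max = null_max, threshold = threshold,
      significant = names(observed)[observed > threshold],
      alpha = alpha, n_unit = n_unit, n_perm = n_perm
    ),
    class = "max_stat_result"
  )
}

#' @export
print.max_stat_result <- function(x, ...) {
  cat(sprintf(
    "<max_stat_result> %d units | threshold (alpha = %g) = %.3f | %d significant channel(s)\n",
    x$n_unit, x$alpha, x$threshold, length(x$significant)
  ))
  if (length(x$significant)) cat("  channels:", paste(x$significant, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn max_stat_test Tidy per-channel table.
#' @param x A `max_stat_result`.
#' @param ... Unused.
#' @export
tidy.max_stat_result <- function(x, ...) {
  tibble::tibble(
    channel = names(x$observed),
    mean_snr = unname(x$observed),
    threshold = x$threshold,
    significant = names(x$observed) %in% x$significant
  )
}

#' Per-subject maximum-statistics ROI
#'
#' Runs the maximum-statistics test per frequency with the subject's valid
#' trials as units.
#'
#' @param snr_tbl Long SNR table for one subject (columns `trial`,
#'   `channel`, `frequency`, `snr`), valid trials only.
#' @param freqs Frequencies to test.
#' @param n_perm,alpha See [max_stat_test()].
#' @return Named list of `max_stat_result`, one per frequency.
#' @export
individual_roi <- function(snr_tbl, freqs, n_perm = 10000L, alpha = 0.05) {
  purrr::map(setNames(freqs, freqs), function(f) {
    d <- snr_tbl[snr_tbl$frequency == f, ]
    max_stat_test(
      tibble::tibble(unit = d$trial, channel = d$channel, snr = d$snr),
      n_perm = n_perm, alpha = alpha
    )
  })
}

#' Group-level maximum-statistics ROI
#'
#' Averages each subject's valid-trial topographies per frequency, then runs
#' the maximum-statistics test with subjects as units. The significant
#' channel sets are the group ROIs.
#'
#' @param snr_tbl Long SNR table (columns `subject_id`, `trial`, `channel`,
#'   `frequency`, `snr`), valid trials only.
#' @param freqs Frequencies to test.
#' @param n_perm,alpha See [max_stat_test()].
#' @return Named list of `max_stat_result`, one per frequency.
#' @export
group_roi <- function(snr_tbl, freqs, n_perm = 10000L, alpha = 0.05) {
  subj_mean <- snr_tbl |>
    dplyr::filter(.data$frequency %in% freqs) |>
    dplyr::group_by(.data$subject_id, .data$frequency, .data$channel) |>
    dplyr::summarise(snr = mean(.data$snr), .groups = "drop")
  purrr::map(setNames(freqs, freqs), function(f) {
    d <- subj_mean[subj_mean$frequency == f, ]
    max_stat_test(
      tibble::tibble(unit = d$subject_id, channel = d$channel, snr = d$snr),
      n_perm = n_perm, alpha = alpha
    )
  })
}

#' Plot a maximum-statistics topography
#'
#' Projects the per-channel mean SNR on the flattened sensor layout,
#' highlighting channels above the permutation threshold.
#'
#' @param object A `max_stat_result`.
#' @param montage A [load_montage()] result.
#' @param ... Unused.
#' @export
autoplot.max_stat_result <- function(object, montage = load_montage(), ...) {
  d <- tidy(object)
  d$channel <- as.integer(d$channel)
  d <- dplyr::left_join(d, montage$positions, by = "channel")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mean_snr,
                                     shape = .data$significant), size = 3) +
    ggplot2::scale_colour_viridis_c(name = "mean SNR") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
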