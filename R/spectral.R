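# Amplitude spectra and the SNR statistic.
#
# Trials are 20 s, so the FFT bin spacing is 1/20 = 0.05 Hz and every
# stimulation frequency (multiples of 3 Hz) falls exactly on a bin. SNR at
# a tagged frequency is the amplitude at its bin divided by the mean
# amplitude of the 10 surrounding bins (5 per side, skipping the bin
# immediately adjacent on each side, i.e. offsets +/-2..6).

SNR_OFFSETS <- c(-(6:2), 2:6)

#' Amplitude spectrum of one trial segment
#'
#' Magnitude of the discrete Fourier transform, per channel, with no taper,
#' detrending or zero padding (tagged frequencies are bin-exact, so leakage
#' is structural rather than window-dependent).
#'
#' @param seg A channels x samples matrix, or one element of
#'   [segment_trials()] output.
#' @param fs Sampling rate in Hz.
#' @return Object of class `amplitude_spectrum`: list with `amplitude`
#'   (channels x bins matrix, bins up to Nyquist), `freq` (bin centre
#'   frequencies), `df` (bin spacing), `fs`.
#' @export
amplitude_spectrum <- function(seg, fs = 1000) {
  if (is.numeric(seg) && is.null(dim(seg))) seg <- matrix(seg, nrow = 1L)
  stopifnot(is.matrix(seg), ncol(seg) >= 2L)
  n <- ncol(seg)
  amp <- abs(stats::mvfft(t(seg))) # bins x channels
  n_keep <- floor(n / 2) + 1L
  amp <- t(amp[seq_len(n_keep), , drop = FALSE])
  df <- fs / n
  structure(
    list(
      amplitude = amp,
      freq = (seq_len(n_keep) - 1L) * df,
      df = df, fs = fs
    ),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spectrum> %d ch x %d bins | df = %g Hz\n",
    nrow(x$amplitude), ncol(x$amplitude), x$df
  ))
  invisible(x)
}

bin_index <- function(spec, f) {
  i <- f / spec$df
  if (abs(i - round(i)) > 1e-9) {
    stop(sprintf("frequency %g Hz is not on a bin (spacing %g Hz)", f, spec$df))
  }
  as.integer(round(i)) + 1L
}

#' SNR at one tagged frequency
#'
#' Ratio of the amplitude at the tagged bin to the mean amplitude of the 10
#' surrounding bins (offsets +/-2..6). The neighbour mean is floored at
#' machine epsilon times the spectrum's norm so that noiseless synthetic
#' input yields a large finite SNR instead of infinity.
#'
#' @param spec An [amplitude_spectrum()].
#' @param f Tagged frequency in Hz; must fall exactly on a bin and have at
#'   least 6 bins of margin on each side.
#' @return Named numeric vector: one SNR per channel.
#' @export
snr_at <- function(spec, f) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  i <- bin_index(spec, f)
  nb <- i + SNR_OFFSETS
  if (min(nb) < 1L || max(nb) > ncol(spec$amplitude)) {
    stop("not enough margin around the tagged frequency")
  }
  target <- spec$amplitude[, i]
  noise <- rowMeans(spec$amplitude[, nb, drop = FALSE])
  eps <- .Machine$double.eps * sqrt(rowSums(spec$amplitude^2))
  out <- target / pmax(noise, eps)
  names(out) <- rownames(spec$amplitude) %||% as.character(seq_along(out))
  out
}

#' Per-trial SNR table across frequencies
#'
#' Convenience wrapper applying [snr_at()] over a set of frequencies for
#' every segment, returning a tidy long table.
#'
#' @param segments A `trial_segments` object.
#' @param freqs Frequencies in Hz.
#' @return Tibble: `subject_id`, `trial`, `condition`, `looking_s`,
#'   `age_days`, `channel`, `frequency`, `snr`.
#' @export
snr_table <- function(segments, freqs) {
  stopifnot(inherits(segments, "trial_segments"))
  purrr::map2_dfr(segments$signal, seq_along(segments$signal), function(sig, k) {
    spec <- amplitude_spectrum(sig, fs = segments$fs)
    meta <- segments$meta[k, ]
    purrr::map_dfr(freqs, function(f) {
      s <- snr_at(spec, f)
      tibble::tibble(
        subject_id = meta$subject_id, trial = meta$trial,
        condition = meta$condition, looking_s = meta$looking_s,
        age_days = meta$age_days,
        channel = as.integer(names(s)), frequency = f, snr = unname(s)
      )
    })
  })
}

#' Average SNR across a harmonic set
#'
#' @param snr_values Named numeric (names = frequencies in Hz) or a tibble
#'   with columns `frequency` and `snr`.
#' @param harmonics Frequencies to average (all must be present).
#' @return Arithmetic mean of the SNR across the harmonic set (per group if
#'   a grouped tibble is supplied).
#' @export
aggregate_harmonics <- function(snr_values, harmonics) {
  stopifnot(length(harmonics) >= 1L)
  if (is.data.frame(snr_values)) {
    missing <- setdiff(harmonics, unique(snr_values$frequency))
    if (length(missing)) {
      stop("missing frequencies: ", paste(missing, collapse = ", "))
    }
    out <- dplyr::summarise(
      dplyr::filter(snr_values, .data$frequency %in% harmonics),
      snr = mean(.data$snr), .groups = "drop"
    )
    return(out)
  }
  key <- as.character(harmonics)
  if (!all(key %in% names(snr_values))) {
    stop("missing frequencies: ",
         paste(setdiff(key, names(snr_values)), collapse = ", "))
  }
  mean(snr_values[key])
}

#' Dominant frequency of a harmonic family
#'
#' @param group_mean_snr Named numeric: group-mean SNR per frequency (names
#'   = frequencies in Hz).
#' @param harmonics Frequencies of the family to search.
#' @return The frequency with the highest mean SNR; ties go to the lower
#'   frequency.
#' @export
dominant_frequency <- function(group_mean_snr, harmonics) {
  stopifnot(length(harmonics) >= 1L)
  harmonics <- sort(harmonics)
  vals <- group_mean_snr[as.character(harmonics)]
  stopifnot(!any(is.na(vals)))
  harmonics[which.max(vals)] # which.max takes the first (lowest) on ties
}

#' Candidate harmonics of the base and doublet families
#'
#' Base candidates are multiples of the 6-Hz stimulation rate; doublet
#' candidates are odd multiples of 3 Hz (3, 9, 15, ...), i.e. the doublet
#' harmonics that do not overlap base harmonics.
#'
#' @param family `"base"` or `"doublet"`.
#' @param range Frequency range in Hz (default 2-36).
#' @return Numeric vector of candidate frequencies.
#' @export
harmonic_candidates <- function(family = c("base", "doublet"), range = c(2, 36)) {
  family <- match.arg(family)
  f <- if (family == "base") seq(6, range[2], by = 6) else seq(3, range[2], by = 6)
  f[f >= range[1] & f <= range[2]]
}

#' SNR spectrum over all bins with enough margin
#'
#' @param spec An [amplitude_spectrum()].
#' @param range Frequency range in Hz to evaluate.
#' @return Tibble: `channel`, `frequency`, `snr`.
#' @export
snr_spectrum <- function(spec, range = c(2, 36)) {
  stopifnot(inherits(spec, "amplitude_spectrum"))
  lo <- max(range[1], 6L * spec$df)
  hi <- min(range[2], (ncol(spec$amplitude) - 7L) * spec$df)
  freqs <- spec$freq[spec$freq >= lo & spec$freq <= hi]
  purrr::map_dfr(freqs, function(f) {
    s <- snr_at(spec, f)
    tibble::tibble(channel = as.integer(names(s)), frequency = f, snr = unname(s))
  })
}

#' @describeIn snr_spectrum Plot the channel-averaged SNR spectrum.
#' @param object An `amplitude_spectrum`.
#' @param ... Passed to [snr_spectrum()].
#' @export
autoplot.amplitude_spectrum <- function(object, ...) {
  d <- snr_spectrum(object, ...)
  d <- dplyr::summarise(dplyr::group_by(d, .data$frequency),
                        snr = mean(.data$snr), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$snr)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Frequency (Hz)", y = "SNR")
}
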