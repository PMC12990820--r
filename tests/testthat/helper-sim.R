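# Shared fixtures, built in code. Tests run at reduced sampling rates
# (100 or 250 Hz); the noise model is PSD-referenced so SNR structure is
# identical to the 1000 Hz default.

the_montage <- load_montage()

# Small clean subject for chain tests
quick_subject <- function(condition, n_trials = 3L, fs = 250, ...) {
  simulate_subject(condition, n_trials = n_trials, fs = fs,
                   montage = the_montage, noise = noise_spec(n_bad = 0L), ...)
}

# One white-noise SNR topography: n_ch channels of 20-s white noise at fs,
# SNR evaluated at `f` through the package's spectral path.
null_topography <- function(n_ch = 32L, fs = 100, f = 6) {
  snr_at(amplitude_spectrum(matrix(stats::rnorm(n_ch * 20 * fs), n_ch), fs), f)
}

# Long SNR tibble of white-noise trials at the given frequencies (single
# channel), as consumed by select_harmonics().
null_snr_trials <- function(n_trials, freqs, fs = 100) {
  rows <- lapply(seq_len(n_trials), function(i) {
    sp <- amplitude_spectrum(matrix(stats::rnorm(20 * fs), 1), fs)
    tibble::tibble(trial = i, frequency = freqs,
                   snr = vapply(freqs, function(f) snr_at(sp, f)[[1]], 0))
  })
  dplyr::bind_rows(rows)
}
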