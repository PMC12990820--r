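# Synthetic steady-state EEG: occipitally weighted sinusoidal responses at
# the tagged frequencies on top of 1/f background noise, with triggers,
# fade periods, per-trial looking behaviour and optional bad channels.

#' Steady-state response profile
#'
#' Describes the evoked-response content of a simulated subject: amplitudes
#' (arbitrary signal units) of the sinusoids at the base stimulation
#' frequency and harmonics (6, 12, 18, 24 Hz) and at the doublet frequency
#' and its non-overlapping harmonic (3, 9 Hz), an occipitally peaked spatial
#' gain, and an optional per-trial drift of log-amplitude. Default doublet
#' amplitudes depend on condition: present and strongest under the doublet
#' condition, weaker under control, absent under random — the structure the
#' analysis pipeline is meant to recover. Amplitude defaults are calibration
#' constants chosen so that group-mean SNRs on default noise approximate the
#' magnitudes reported in infant frequency-tagging work (combined doublet
#' SNR near 1.9 / 1.4 / 1.0 for doublet / control / random).
#'
#' @param condition Condition label; fixes the default `doublet_amps`.
#' @param base_amps Named numeric: amplitude per base harmonic in Hz.
#' @param doublet_amps Named numeric: amplitude per doublet harmonic in Hz.
#'   Must be all zero for the random condition.
#' @param drift Per-trial drift of log10 amplitude (0 = stationary).
#' @param subject_sd SD of the per-subject log10 responsiveness gain (one
#'   multiplier per subject applied to all amplitudes), generating
#'   between-subject variance in SNR.
#' @param gain_width Width (m) of the Gaussian spatial gain around the
#'   medial occipital ROI centroid.
#' @return Object of class `response_profile`.
#' @export
response_profile <- function(condition,
                             base_amps = c("6" = 0.045, "12" = 0.015,
                                           "18" = 0.008, "24" = 0.0046),
                             doublet_amps = NULL,
                             drift = 0,
                             subject_sd = 0.15,
                             gain_width = 0.045) {
  condition <- match_condition(condition)
  if (is.null(doublet_amps)) {
    doublet_amps <- switch(condition,
      doublet = c("3" = 0.014, "9" = 0.017),
      control = c("3" = 0.009, "9" = 0.010),
      random = c("3" = 0, "9" = 0)
    )
  }
  stopifnot(all(base_amps >= 0), all(doublet_amps >= 0), subject_sd >= 0)
  if (condition == "random" && any(doublet_amps > 0)) {
    stop("random condition carries no doublet-rate response: doublet_amps must be 0")
  }
  structure(
    list(
      condition = condition,
      base_amps = base_amps,
      doublet_amps = doublet_amps,
      drift = drift,
      subject_sd = subject_sd,
      gain_width = gain_width
    ),
    class = "response_profile"
  )
}

#' Background-noise specification
#'
#' @param exponent Power-spectrum exponent of the 1/f background (power
#'   proportional to f^-exponent); default 1.
#' @param scale Noise amplitude multiplier (0 gives a noiseless recording).
#' @param channel_jitter SD of per-channel log-normal variance jitter.
#' @param n_bad Number of channels corrupted by [corrupt_channels()];
#'   default 18, matching the typical per-infant interpolated-channel count
#'   in high-density infant recordings.
#' @param bad_gain Amplitude multiplier of the white noise that replaces a
#'   corrupted channel (> 1).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(exponent = 1, scale = 1, channel_jitter = 0.1,
                       n_bad = 18L, bad_gain = 20) {
  stopifnot(exponent >= 0, scale >= 0, channel_jitter >= 0, n_bad >= 0, bad_gain > 1)
  structure(
    list(
      exponent = exponent, scale = scale, channel_jitter = channel_jitter,
      n_bad = as.integer(n_bad), bad_gain = bad_gain
    ),
    class = "noise_spec"
  )
}

# One channel of 1/f noise by spectral shaping of white noise.
# Amplitude spectrum scaled by f^(-exponent/2) below a 0.5 Hz floor knee.
# `scale` is referenced to a 1000 Hz sampling rate: the per-sample SD grows
# with sqrt(fs) so the noise power spectral density — and therefore the SNR
# of a fixed-amplitude evoked response — is independent of sampling rate.
pink_noise <- function(n, fs, exponent, scale) {
  scale <- scale * sqrt(fs / 1000)
  if (scale <= 0 || n < 2L) return(numeric(n))
  x <- stats::rnorm(n)
  if (exponent == 0) return(scale * x)
  f <- c(0, seq_len(n - 1L)) * fs / n
  f <- pmin(f, fs - f) # fold to two-sided frequencies
  shape <- pmax(f, 0.5)^(-exponent / 2)
  shape[1L] <- 0
  xf <- stats::fft(x) * shape
  scale * Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Simulate one subject's recording
#'
#' Builds a continuous multichannel recording: per trial, a fade-in, a
#' triggered 20-s core and a fade-out, separated by noise-only gaps. The
#' evoked signal is a fixed-phase sum of sinusoids at the profile's
#' frequencies, weighted per channel by the occipital spatial gain, present
#' only while the simulated infant is looking (fade-in plus the first
#' `looking` seconds of the core), and superimposed on 1/f noise.
#'
#' @param condition Condition label.
#' @param n_trials Number of trials.
#' @param profile A [response_profile()]; defaults to the condition's default.
#' @param noise A [noise_spec()].
#' @param montage A [load_montage()] result.
#' @param fs Sampling rate in Hz (default 1000).
#' @param subject_id Subject identifier string.
#' @param age_days Age in days (default drawn uniformly in 120..195,
#'   i.e. 4-6 months).
#' @param looking Per-trial looking durations in seconds (0..20); default
#'   drawn from 20 * Beta(1.6, 1), under which roughly 80% of trials exceed
#'   the 7-s attention criterion and, combined with the SNR criterion,
#'   about three quarters of trials end up valid.
#' @param n_core,n_fade Triggered shapes per trial and fade shapes per side.
#' @param gap_s Inter-trial gap in seconds.
#' @return Object of class `eeg_recording`: list with `signal` (channels x
#'   samples matrix), `fs`, `events` (tibble: sample, trial, position,
#'   shape_id), `trials` (tibble: trial, condition, looking_s,
#'   core_start_sample), `subject_id`, `age_days`, `condition`,
#'   `bad_channels`, and the generating `scheme`.
#' @export
simulate_subject <- function(condition, n_trials = 10L,
                             profile = response_profile(condition),
                             noise = noise_spec(),
                             montage = load_montage(),
                             fs = 1000, subject_id = "s01", age_days = NULL,
                             looking = NULL,
                             n_core = 120L, n_fade = 12L, gap_s = 1) {
  condition <- match_condition(condition)
  stopifnot(n_trials >= 1L, inherits(profile, "response_profile"),
            profile$condition == condition)
  rate <- 6 # shapes per second
  core_len <- as.integer(round(n_core / rate * fs))
  fade_len <- as.integer(round(n_fade / rate * fs))
  gap_len <- as.integer(round(gap_s * fs))
  trial_len <- fade_len + core_len + fade_len
  n_samp <- gap_len + n_trials * (trial_len + gap_len)
  n_ch <- montage$n_channels

  age_days <- age_days %||% round(stats::runif(1, 120, 195))
  if (is.null(looking)) looking <- 20 * stats::rbeta(n_trials, 1.6, 1)
  stopifnot(length(looking) == n_trials, all(looking >= 0), all(looking <= 20))

  scheme <- make_pairing(condition)
  freqs <- c(as.numeric(names(profile$base_amps)),
             as.numeric(names(profile$doublet_amps)))
  amps0 <- c(profile$base_amps, profile$doublet_amps) *
    10^stats::rnorm(1, 0, profile$subject_sd)
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  gain <- occipital_gain(montage, width = profile$gain_width)

  events <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  evoked <- numeric(n_samp) # single source waveform, scaled per channel

  for (i in seq_len(n_trials)) {
    trial_start <- gap_len + (i - 1L) * (trial_len + gap_len) + 1L
    core_start <- trial_start + fade_len
    seqs <- generate_trial_sequence(scheme, n_core = n_core, n_fade = n_fade)
    core_pos <- which(seqs$triggered)
    trig <- core_start + as.integer(round((seq_along(core_pos) - 1L) * fs / rate))
    events[[i]] <- tibble::tibble(
      sample = trig, trial = i, position = core_pos,
      shape_id = seqs$shape_id[core_pos]
    )
    trials[[i]] <- tibble::tibble(
      trial = i, condition = condition, looking_s = looking[i],
      core_start_sample = core_start
    )
    # evoked waveform while looking: fade-in + first looking_s seconds of core
    on_start <- trial_start
    on_end <- min(core_start + as.integer(round(looking[i] * fs)) - 1L,
                  trial_start + trial_len - 1L)
    if (on_end >= on_start) {
      idx <- on_start:on_end
      tt <- (idx - core_start) / fs # time origin at core start
      amps <- amps0 * 10^(profile$drift * (i - 1L))
      w <- numeric(length(idx))
      for (j in seq_along(freqs)) {
        if (amps[j] > 0) w <- w + amps[j] * sin(2 * pi * freqs[j] * tt + phases[j])
      }
      evoked[idx] <- w
    }
  }

  signal <- matrix(0, n_ch, n_samp)
  for (c in seq_len(n_ch)) {
    jit <- exp(stats::rnorm(1, 0, noise$channel_jitter))
    signal[c, ] <- gain[c] * evoked +
      jit * pink_noise(n_samp, fs, noise$exponent, noise$scale)
  }
  rownames(signal) <- montage$positions$channel

  structure(
    list(
      signal = signal, fs = fs,
      events = dplyr::bind_rows(events),
      trials = dplyr::bind_rows(trials),
      subject_id = subject_id, age_days = age_days, condition = condition,
      bad_channels = integer(0), scheme = scheme,
      n_core = as.integer(n_core), n_fade = as.integer(n_fade)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s | %s | %d ch x %d samples @ %g Hz | %d trials | age %d d\n",
    x$subject_id, x$condition, nrow(x$signal), ncol(x$signal), x$fs,
    nrow(x$trials), x$age_days
  ))
  invisible(x)
}

#' Corrupt channels with high-variance noise
#'
#' Replaces randomly chosen channels with white noise amplified by
#' `noise$bad_gain`, recording their identities as ground truth for
#' channel-repair testing.
#'
#' @param rec An `eeg_recording`.
#' @param noise A [noise_spec()]; `n_bad` channels are corrupted.
#' @return The recording with `bad_channels` set.
#' @export
corrupt_channels <- function(rec, noise = noise_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (noise$n_bad == 0L) return(rec)
  bad <- sort(sample.int(nrow(rec$signal), noise$n_bad))
  for (c in bad) {
    rec$signal[c, ] <- noise$bad_gain * noise$scale * sqrt(rec$fs / 1000) *
      stats::rnorm(ncol(rec$signal))
  }
  rec$bad_channels <- bad
  rec
}

#' Simulate a cohort of subjects
#'
#' Generates one recording per subject under a between-subject design with
#' the given per-condition counts. Trial counts are drawn per subject from a
#' discretized normal (mean 10.8, SD 3.4, clipped to 4..18) and ages
#' uniformly from the configured range. When `noise$n_bad > 0` each
#' recording is passed through [corrupt_channels()].
#'
#' @param n_per_condition Named integer vector of subjects per condition.
#' @param profiles Named list of [response_profile()]s per condition.
#' @param noise A [noise_spec()].
#' @param montage A [load_montage()] result.
#' @param age_range Age range in days.
#' @param n_trials Fixed trial count, or NULL to draw per subject.
#' @param process Optional function applied to each recording as soon as it
#'   is generated; its value is kept instead of the raw recording (keeps a
#'   full-scale cohort within memory).
#' @param ... Passed on to [simulate_subject()].
#' @return List with one element per subject (recordings, or `process`
#'   results).
#' @export
simulate_cohort <- function(n_per_condition = c(doublet = 10L, control = 10L, random = 10L),
                            profiles = NULL, noise = noise_spec(),
                            montage = load_montage(),
                            age_range = c(120, 195), n_trials = NULL,
                            process = NULL, ...) {
  stopifnot(all(names(n_per_condition) %in% CONDITIONS), all(n_per_condition >= 1L))
  conditions <- rep(names(n_per_condition), times = n_per_condition)
  out <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    prof <- if (!is.null(profiles)) profiles[[cond]] else response_profile(cond)
    nt <- n_trials %||% max(4L, min(18L, as.integer(round(stats::rnorm(1, 10.83, 3.36)))))
    rec <- simulate_subject(
      condition = cond, n_trials = nt, profile = prof, noise = noise,
      montage = montage,
      age_days = round(stats::runif(1, age_range[1], age_range[2])),
      subject_id = sprintf("s%02d", i), ...
    )
    if (noise$n_bad > 0L) rec <- corrupt_channels(rec, noise)
    out[[i]] <- if (is.null(process)) rec else process(rec)
  }
  names(out) <- sprintf("s%02d", seq_along(conditions))
  out
}
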