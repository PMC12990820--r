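# Simplified preprocessing: average reference, robust-z bad-channel repair,
# trigger-based segmentation into 20-s trial cores.

#' Re-reference to the average reference
#'
#' Subtracts, at every sample, the mean across channels, so that the
#' channel mean is zero everywhere.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$signal) >= 2L)
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

#' Detect and repair noisy channels
#'
#' Flags channels whose variance is an outlier on a robust z score
#' (`(var - median(var)) / (1.4826 * MAD(var))`, one-sided: high variance
#' only) and replaces each by the mean of its non-flagged montage
#' neighbours. Detection and repair are reiterated until no channel exceeds
#' the threshold, up to 3 times.
#'
#' @param rec An `eeg_recording`.
#' @param montage A [load_montage()] result supplying the adjacency.
#' @param z_threshold Robust z cut-off (default 4).
#' @param max_iter Maximum detect/repair iterations (default 3).
#' @return The recording, with attribute-free field `repaired` listing
#'   repaired channel indices and `repair_iterations` the iterations used.
#' @export
detect_and_interpolate <- function(rec, montage = load_montage(),
                                   z_threshold = 4, max_iter = 3L) {
  stopifnot(inherits(rec, "eeg_recording"))
  adj <- montage$adjacency
  stopifnot(nrow(adj) == nrow(rec$signal))
  repaired <- integer(0)
  iter <- 0L
  repeat {
    v <- apply(rec$signal, 1, stats::var)
    z <- (v - stats::median(v)) / (1.4826 * stats::mad(v, constant = 1))
    bad <- which(z > z_threshold)
    if (length(bad) == 0L || iter >= max_iter) break
    if (length(bad) == nrow(rec$signal)) {
      stop("all channels flagged as noisy; recording unusable")
    }
    iter <- iter + 1L
    good <- setdiff(seq_len(nrow(rec$signal)), bad)
    for (c in bad) {
      nb <- intersect(which(adj[c, ]), good)
      if (length(nb) == 0L) next # all neighbours bad: retry next iteration
      rec$signal[c, ] <- colMeans(rec$signal[nb, , drop = FALSE])
      repaired <- union(repaired, c)
    }
  }
  rec$repaired <- sort(repaired)
  rec$repair_iterations <- iter
  rec
}

#' Segment a recording into 20-s trial cores
#'
#' Cuts one segment per trial, starting at the trial's first non-fade
#' trigger and spanning exactly 20 s (the fade periods are excluded).
#' Trials whose triggers are missing are dropped with a warning.
#'
#' @param rec An `eeg_recording`.
#' @return Object of class `trial_segments`: list with `signal` (list of
#'   channels x samples matrices), `meta` (tibble: trial, condition,
#'   subject_id, age_days, looking_s), and `fs`.
#' @export
segment_trials <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$events) == 0L) stop("no triggers present")
  seg_len <- as.integer(round(20 * rec$fs))
  trials <- sort(unique(rec$trials$trial))
  sigs <- list()
  keep <- logical(length(trials))
  for (k in seq_along(trials)) {
    ev <- rec$events[rec$events$trial == trials[k], ]
    if (nrow(ev) == 0L) {
      warning(sprintf("trial %d has no triggers; dropped", trials[k]))
      next
    }
    start <- min(ev$sample)
    if (start + seg_len - 1L > ncol(rec$signal)) {
      warning(sprintf("trial %d extends past the recording; dropped", trials[k]))
      next
    }
    keep[k] <- TRUE
    sigs[[length(sigs) + 1L]] <- rec$signal[, start:(start + seg_len - 1L), drop = FALSE]
  }
  meta <- rec$trials[keep, c("trial", "condition", "looking_s")]
  meta$subject_id <- rec$subject_id
  meta$age_days <- rec$age_days
  structure(
    list(signal = sigs, meta = tibble::as_tibble(meta), fs = rec$fs),
    class = "trial_segments"
  )
}

#' @export
print.trial_segments <- function(x, ...) {
  cat(sprintf(
    "<trial_segments> %d trials | %d ch x %d samples @ %g Hz\n",
    length(x$signal),
    if (length(x$signal)) nrow(x$signal[[1]]) else 0L,
    if (length(x$signal)) ncol(x$signal[[1]]) else 0L, x$fs
  ))
  invisible(x)
}
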