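# Minimal EDF (European Data Format) writer/reader for continuous
# recordings, plus CSV/JSON sidecars carrying triggers, trial metadata and
# looking durations. One data record per second; samples are 16-bit
# integers scaled per channel to a symmetric physical range.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = width - 2, width = 1)
  pad_field(s, width)
}

#' Write a recording to an EDF file
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path (`.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  sig <- rec$signal
  fs <- as.integer(round(rec$fs))
  n_ch <- nrow(sig)
  n_rec <- as.integer(ceiling(ncol(sig) / fs))
  if (ncol(sig) < n_rec * fs) { # zero-pad the final partial record
    sig <- cbind(sig, matrix(0, n_ch, n_rec * fs - ncol(sig)))
  }
  pmax_ch <- pmax(apply(abs(sig), 1, max), .Machine$double.eps)
  dig <- round(sweep(sig, 1, pmax_ch, "/") * 32767)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field(paste("condition", rec$condition), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L + 256L * n_ch, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(n_ch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  labels <- paste0("E", rownames(sig) %||% seq_len(n_ch))
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(vapply(-pmax_ch, num_field, "", width = 8), 8)
  field(vapply(pmax_ch, num_field, "", width = 8), 8)
  field(rep("-32767", n_ch), 8)
  field(rep("32767", n_ch), 8)
  field(rep("", n_ch), 80)
  field(rep(fs, n_ch), 8)
  field(rep("", n_ch), 32)
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List: `signal` (channels x samples), `fs`, `labels`,
#'   `subject_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8))
  phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8))
  dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  stopifnot(length(unique(spr)) == 1L)
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  sig <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1L) * sum(spr) + 1L):(r * sum(spr))],
                    nrow = spr[1], ncol = n_ch)
    sig[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- sweep(sweep(sig, 1, dig_min), 1, scale, "*") + phys_min
  rownames(sig) <- sub("^E", "", labels)
  list(signal = sig, fs = fs, labels = labels, subject_id = subject_id)
}

#' Write a recording with its sidecar metadata
#'
#' Writes `<base>.edf` plus `<base>_events.csv` (trigger samples),
#' `<base>_trials.csv` (per-trial condition and looking durations) and
#' `<base>_meta.json` (subject, age, condition, rates, pairing scheme).
#'
#' @param rec An `eeg_recording`.
#' @param dir Output directory (created if missing).
#' @param base File base name; defaults to the subject id.
#' @return Base path, invisibly.
#' @export
write_recording <- function(rec, dir, base = rec$subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  root <- file.path(dir, base)
  write_edf(rec, paste0(root, ".edf"))
  readr::write_csv(rec$events, paste0(root, "_events.csv"))
  readr::write_csv(rec$trials, paste0(root, "_trials.csv"))
  meta <- list(
    subject_id = rec$subject_id, condition = rec$condition,
    age_days = rec$age_days, fs = rec$fs,
    n_core = rec$n_core, n_fade = rec$n_fade,
    n_samples = ncol(rec$signal),
    bad_channels = rec$bad_channels,
    scheme = list(first = rec$scheme$first, second = rec$scheme$second)
  )
  jsonlite::write_json(meta, paste0(root, "_meta.json"), auto_unbox = TRUE)
  invisible(root)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory holding the files.
#' @param base File base name.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(dir, base) {
  root <- file.path(dir, base)
  meta <- jsonlite::read_json(paste0(root, "_meta.json"), simplifyVector = TRUE)
  edf <- read_edf(paste0(root, ".edf"))
  sig <- edf$signal[, seq_len(meta$n_samples), drop = FALSE]
  scheme <- structure(
    list(condition = meta$condition,
         first = as.integer(meta$scheme$first),
         second = as.integer(meta$scheme$second)),
    class = "pairing_scheme"
  )
  structure(
    list(
      signal = sig, fs = meta$fs,
      events = readr::read_csv(paste0(root, "_events.csv"), show_col_types = FALSE),
      trials = readr::read_csv(paste0(root, "_trials.csv"), show_col_types = FALSE),
      subject_id = meta$subject_id, age_days = meta$age_days,
      condition = meta$condition,
      bad_channels = as.integer(meta$bad_channels %||% integer(0)),
      scheme = scheme,
      n_core = as.integer(meta$n_core), n_fade = as.integer(meta$n_fade)
    ),
    class = "eeg_recording"
  )
}
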