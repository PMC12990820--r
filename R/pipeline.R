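# End-to-end orchestration: simulate -> preprocess -> spectra/SNR ->
# selection -> maximum statistics -> mixed-model ladder, with a manifest
# recording configuration and seed for exact reproduction.

#' Pipeline configuration
#'
#' Bundles the experimental design, timing, response/noise calibration,
#' analysis thresholds and seed. Any element can be overridden; defaults
#' are the study conditions the synthetic cohort emulates (10 subjects per
#' condition, 1000 Hz, 120 triggered shapes per trial, SNR validity
#' threshold 2, 7-s looking criterion, alpha 0.05, 10,000 permutations,
#' 40% order-restriction threshold, 2-36 Hz harmonic range).
#'
#' @param ... Named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @param yaml Optional path to a YAML file of overrides (requires the
#'   `yaml` package).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  config <- list(
    seed = 1L,
    design = list(
      n_per_condition = c(doublet = 10L, control = 10L, random = 10L),
      n_trials = NULL, # NULL: drawn per subject (mean 10.83, SD 3.36)
      age_range = c(120, 195)
    ),
    timing = list(fs = 1000, n_core = 120L, n_fade = 12L, gap_s = 1),
    noise = list(exponent = 1, scale = 1, channel_jitter = 0.1,
                 n_bad = 18L, bad_gain = 20),
    thresholds = list(
      snr_valid = 2, min_look_s = 7, min_valid = 2L, alpha = 0.05,
      n_perm = 10000L, min_fraction = 0.40, harmonic_range = c(2, 36),
      z_threshold = 4
    ),
    write_raw = FALSE
  )
  if (!is.null(yaml)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    config <- utils::modifyList(config, yaml::read_yaml(yaml))
  }
  overrides <- list(...)
  if (length(overrides)) config <- utils::modifyList(config, overrides)
  stopifnot(
    config$thresholds$snr_valid > 0, config$thresholds$min_look_s > 0,
    config$thresholds$alpha > 0, config$thresholds$n_perm >= 1,
    config$thresholds$min_fraction >= 0
  )
  structure(config, class = "pipeline_config")
}

subject_snr_stage <- function(config, montage, freqs) {
  force(freqs)
  function(rec) {
    # repair corrupted channels before averaging so they cannot leak
    # broadband noise into the common reference
    rec <- detect_and_interpolate(rec, montage,
                                  z_threshold = config$thresholds$z_threshold)
    rec <- rereference_average(rec)
    segs <- segment_trials(rec)
    snr_table(segs, freqs)
  }
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a cohort under the configured design, preprocesses each
#' recording (average reference, noisy-channel repair, segmentation),
#' computes per-trial SNR at all candidate frequencies, applies the
#' valid-trial criteria, selects significant harmonics (base family on all
#' conditions, doublet family on doublet + control), localizes group-level
#' ROIs by permutation maximum statistics, restricts trial orders, and fits
#' the mixed-model ladder for the three outcomes with post hocs where
#' condition is retained. Artifacts (CSV tables, JSON summaries, manifest)
#' are written under `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or NULL for no files.
#' @return List: `records` (analysis table), `harmonics` (base/doublet
#'   selections), `rois` (per-frequency `max_stat_result`s), `ladders`,
#'   `post_hocs`, `max_order`, `valid_rate`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  t0 <- Sys.time()
  montage <- load_montage()
  th <- config$thresholds
  freqs <- sort(unique(c(
    harmonic_candidates("base", th$harmonic_range),
    harmonic_candidates("doublet", th$harmonic_range)
  )))
  noise <- noise_spec(
    exponent = config$noise$exponent, scale = config$noise$scale,
    channel_jitter = config$noise$channel_jitter,
    n_bad = config$noise$n_bad, bad_gain = config$noise$bad_gain
  )
  message("stage simulate+snr: ", sum(config$design$n_per_condition), " subjects")
  if (isTRUE(config$write_raw) && !is.null(out_dir)) {
    raw_dir <- file.path(out_dir, "raw")
    stage <- subject_snr_stage(config, montage, freqs)
    process <- function(rec) {
      write_recording(rec, raw_dir)
      stage(rec)
    }
  } else {
    process <- subject_snr_stage(config, montage, freqs)
  }
  snr_all <- dplyr::bind_rows(simulate_cohort(
    n_per_condition = config$design$n_per_condition,
    noise = noise, montage = montage,
    age_range = config$design$age_range,
    n_trials = config$design$n_trials,
    process = process,
    fs = config$timing$fs, n_core = config$timing$n_core,
    n_fade = config$timing$n_fade, gap_s = config$timing$gap_s
  ))

  message("stage selection")
  records <- valid_trial_records(
    snr_all, roi = montage$occ3, occ10 = montage$occ10,
    snr_threshold = th$snr_valid, min_look_s = th$min_look_s,
    min_valid = th$min_valid
  )
  n_trials_total <- dplyr::n_distinct(snr_all[c("subject_id", "trial")])
  valid_rate <- nrow(records) / n_trials_total
  message(sprintf("  valid trials: %d / %d (%.2f%%)",
                  nrow(records), n_trials_total, 100 * valid_rate))

  valid_keys <- records[c("subject_id", "trial")]
  snr_valid <- dplyr::semi_join(snr_all, valid_keys,
                                by = c("subject_id", "trial"))
  roi_snr <- dplyr::filter(snr_valid, .data$channel %in% montage$occ3) |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$trial, .data$frequency) |>
    dplyr::summarise(snr = mean(.data$snr), .groups = "drop")
  base_sel <- select_harmonics(roi_snr, "base",
                               range = th$harmonic_range, alpha = th$alpha)
  doublet_sel <- select_harmonics(
    dplyr::filter(roi_snr, .data$condition %in% c("doublet", "control")),
    "doublet", range = th$harmonic_range, alpha = th$alpha
  )
  message("  base harmonics: ", paste(base_sel$harmonics, collapse = ", "))
  message("  doublet harmonics: ", paste(doublet_sel$harmonics, collapse = ", "))

  message("stage maximum statistics")
  # base-family ROIs over all subjects; doublet-family ROIs over the
  # doublet + control subjects (no doublet-rate response exists under random)
  rois <- c(
    if (length(base_sel$harmonics)) {
      group_roi(snr_valid, base_sel$harmonics,
                n_perm = th$n_perm, alpha = th$alpha)
    },
    if (length(doublet_sel$harmonics)) {
      group_roi(
        dplyr::filter(snr_valid, .data$condition %in% c("doublet", "control")),
        doublet_sel$harmonics, n_perm = th$n_perm, alpha = th$alpha
      )
    }
  )

  message("stage models")
  restricted <- restrict_orders(records, min_fraction = th$min_fraction)
  max_order <- attr(restricted, "max_order")
  message("  analyzable orders: 1..", max_order)
  table <- build_table(restricted, max_order = max_order)
  ladders <- purrr::map(
    setNames(c("snr_base", "snr_doublet", "learning_index"),
             c("snr_base", "snr_doublet", "learning_index")),
    function(dv) fit_ladder(table, dv, alpha = th$alpha)
  )
  post_hocs <- purrr::map(ladders, function(l) {
    if ("condition" %in% l$selected) post_hoc(l, at_orders = c(1, 5, max_order))
  })

  manifest <- list(
    package = "freqtagsl",
    version = as.character(utils::packageVersion("freqtagsl")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_subjects = sum(config$design$n_per_condition),
    n_trials_total = n_trials_total,
    valid_rate = valid_rate,
    max_order = max_order,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(
    records = records, harmonics = list(base = base_sel, doublet = doublet_sel),
    rois = rois, ladders = ladders, post_hocs = post_hocs,
    max_order = max_order, valid_rate = valid_rate, manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  result
}

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$records, file.path(out_dir, "trial_records.csv"))
  readr::write_csv(
    dplyr::bind_rows(
      dplyr::mutate(tidy(result$harmonics$base), family = "base"),
      dplyr::mutate(tidy(result$harmonics$doublet), family = "doublet")
    ),
    file.path(out_dir, "harmonic_selection.csv")
  )
  rois <- purrr::imap(result$rois, function(r, f) {
    list(frequency = as.numeric(f), threshold = r$threshold,
         channels = as.integer(r$significant))
  })
  jsonlite::write_json(unname(rois), file.path(out_dir, "rois.json"),
                       auto_unbox = TRUE, digits = NA)
  models <- purrr::map(result$ladders, function(l) {
    list(steps = l$steps, selected = l$selected, icc = icc(l),
         coefficients = tidy(l))
  })
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(
    jsonlite::toJSON(result$manifest, auto_unbox = TRUE, digits = NA,
                     pretty = TRUE),
    file.path(out_dir, "manifest.json")
  )
  invisible(out_dir)
}

#' Plot outcome trajectories over trial order by condition
#'
#' Condition-mean trajectories with subject-level traces, mirroring the
#' exposure-course figures of frequency-tagging learning studies.
#'
#' @param table A [build_table()] result.
#' @param dv Outcome to plot.
#' @return A ggplot.
#' @export
plot_learning_curves <- function(table, dv = c("snr_doublet", "snr_base", "learning_index")) {
  dv <- match.arg(dv)
  col <- dv_column(dv)
  means <- table |>
    dplyr::group_by(.data$condition, .data$order) |>
    dplyr::summarise(value = mean(.data[[col]]), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$order, y = .data$value,
                                      colour = .data$condition)) +
    ggplot2::geom_line(
      data = table |>
        dplyr::mutate(value = .data[[col]]),
      ggplot2::aes(group = .data$subject_id), alpha = 0.25, linewidth = 0.3
    ) +
    ggplot2::geom_line(linewidth = 1.2) +
    ggplot2::labs(x = "Trial order", y = col, colour = "Condition")
}
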