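# Stimulus-sequence generation for the three exposure conditions.
#
# Eight abstract shapes are streamed at 6 Hz. Depending on the condition the
# stream carries different transitional-probability (TP) structure:
#   doublet — shapes are organized in 4 fixed ordered pairs; within-pair TP
#             is 1, pair-to-pair TP is 1/3 (no immediate pair repetition).
#   control — 4 shapes can occupy the first position of a pair and the other
#             4 the second, giving 16 possible pairs; only the identical
#             previous pair is excluded from the next draw.
#   random  — shapes follow each other with no structure beyond "no
#             immediate repetition", giving shape-to-shape TP of 1/7.

N_SHAPES <- 8L

#' Create a per-subject shape pairing scheme
#'
#' Randomizes how the eight shapes are organized for one subject. In the
#' doublet condition the shapes are partitioned into four ordered pairs; in
#' the control condition into a first-position set and a second-position set
#' of four shapes each; the random condition carries no pairing. The scheme
#' is drawn uniformly among admissible partitions and is meant to be fixed
#' across all trials of a subject.
#'
#' @param condition One of `"doublet"`, `"control"`, `"random"`.
#' @return An object of class `pairing_scheme`: a list with elements
#'   `condition`, `first` and `second` (integer vectors of length 4 for the
#'   paired conditions, length 0 for random). In the doublet condition
#'   `first[i]` is always followed by `second[i]`.
#' @examples
#' set.seed(1)
#' make_pairing("doublet")
#' @export
make_pairing <- function(condition) {
  condition <- match_condition(condition)
  if (condition == "random") {
    first <- integer(0)
    second <- integer(0)
  } else {
    perm <- sample.int(N_SHAPES)
    if (condition == "doublet") {
      # consecutive elements of a uniform permutation give uniform ordered pairs
      first <- perm[c(1L, 3L, 5L, 7L)]
      second <- perm[c(2L, 4L, 6L, 8L)]
    } else {
      first <- perm[1:4]
      second <- perm[5:8]
    }
  }
  structure(
    list(condition = condition, first = first, second = second),
    class = "pairing_scheme"
  )
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat("<pairing_scheme> condition:", x$condition, "\n")
  if (x$condition == "doublet") {
    cat("  pairs:", paste(sprintf("%d-%d", x$first, x$second), collapse = " "), "\n")
  } else if (x$condition == "control") {
    cat("  first-position set: ", paste(x$first, collapse = " "), "\n")
    cat("  second-position set:", paste(x$second, collapse = " "), "\n")
  }
  invisible(x)
}

# All 16 (first, second) combinations for the control condition, as a matrix.
control_doublets <- function(scheme) {
  as.matrix(expand.grid(first = scheme$first, second = scheme$second))
}

#' Generate one trial's shape sequence
#'
#' Builds the ordered stream of shapes for a single trial, including the
#' fade-in and fade-out periods that are presented but not triggered. Units
#' (doublets) are drawn uniformly among the admissible set: in the doublet
#' and control conditions the immediately preceding doublet is excluded; in
#' the random condition the immediately preceding shape is excluded.
#'
#' @param scheme A [make_pairing()] result.
#' @param n_core Number of triggered (non-fade) shapes; default 120 (20 s at
#'   6 Hz). Must be even for the paired conditions.
#' @param n_fade Number of fade shapes on each side; default 12 (2 s at 6 Hz).
#' @return A tibble of class `trial_sequence` with columns `position`,
#'   `shape_id`, `triggered`, and attributes `condition`, `scheme`,
#'   `n_core`, `n_total`.
#' @examples
#' set.seed(1)
#' seq <- generate_trial_sequence(make_pairing("doublet"))
#' table(seq$triggered)
#' @export
generate_trial_sequence <- function(scheme, n_core = 120L, n_fade = 12L) {
  stopifnot(inherits(scheme, "pairing_scheme"), n_core > 0L, n_fade >= 0L)
  condition <- scheme$condition
  n_total <- n_core + 2L * n_fade
  if (condition != "random" && (n_core %% 2L != 0L || n_fade %% 2L != 0L)) {
    stop("paired conditions need even shape counts (whole doublets)")
  }
  if (condition == "random") {
    shapes <- markov_no_repeat(n_total, states = N_SHAPES)
  } else if (condition == "doublet") {
    idx <- markov_no_repeat(n_total %/% 2L, states = 4L)
    shapes <- as.integer(rbind(scheme$first[idx], scheme$second[idx]))
  } else {
    dbl <- control_doublets(scheme)
    idx <- markov_no_repeat(n_total %/% 2L, states = nrow(dbl))
    shapes <- as.integer(rbind(dbl[idx, "first"], dbl[idx, "second"]))
  }
  out <- tibble::tibble(
    position = seq_len(n_total),
    shape_id = shapes,
    triggered = .data$position > n_fade & .data$position <= n_fade + n_core
  )
  structure(out,
    class = c("trial_sequence", class(out)),
    condition = condition, scheme = scheme,
    n_core = as.integer(n_core), n_total = as.integer(n_total)
  )
}

# Uniform no-repeat chain over 1..states: each draw uniform over the
# states other than the previous one.
markov_no_repeat <- function(n, states) {
  out <- integer(n)
  out[1L] <- sample.int(states, 1L)
  if (n > 1L) {
    # draw from 1..(states-1) and skip over the previous state
    u <- sample.int(states - 1L, n - 1L, replace = TRUE)
    for (i in 2L:n) {
      out[i] <- if (u[i - 1L] >= out[i - 1L]) u[i - 1L] + 1L else u[i - 1L]
    }
  }
  out
}

#' Empirical transitional probabilities of generated sequences
#'
#' Tabulates observed shape-to-shape transitions and summarizes the TP
#' structure. Transitions are counted within each trial (never across trial
#' boundaries). For the paired conditions, transitions from odd to even
#' positions are within-doublet and transitions from even to odd positions
#' are between-doublet; the summary scalars average the observed conditional
#' probability of each specific successor over the successors actually
#' observed.
#'
#' @param sequences A `trial_sequence`, a list of them (same condition), or a
#'   tibble with columns `position`, `shape_id` and optionally `trial`.
#' @param condition Condition label; taken from the sequence attribute when
#'   available.
#' @return An object of class `tp_table`: list with the row-normalized 8 x 8
#'   transition `matrix`, the within- and between-unit conditional matrices
#'   (`within`, `between`; NULL for random), and scalars `tp_within`,
#'   `tp_between` (`tp_within` is NA for the random condition, where
#'   `tp_between` is the plain shape-to-shape TP).
#' @examples
#' set.seed(1)
#' s <- generate_trial_sequence(make_pairing("doublet"), n_core = 2000, n_fade = 0)
#' empirical_tp(s)$tp_within
#' @export
empirical_tp <- function(sequences, condition = NULL) {
  if (inherits(sequences, "trial_sequence")) {
    condition <- condition %||% attr(sequences, "condition")
    sequences <- list(sequences)
  } else if (is.data.frame(sequences)) {
    if (is.null(condition)) stop("condition must be given for plain data frames")
    trial <- sequences$trial %||% rep(1L, nrow(sequences))
    sequences <- split(sequences[c("position", "shape_id")], trial)
  } else if (is.list(sequences) && length(sequences) > 0L) {
    condition <- condition %||% attr(sequences[[1L]], "condition")
  } else {
    stop("no sequences supplied")
  }
  condition <- match_condition(condition)

  pairs <- purrr::map(sequences, function(s) {
    s <- s[order(s$position), ]
    x <- s$shape_id
    tibble::tibble(
      from = x[-length(x)], to = x[-1L],
      within = s$position[-length(s$position)] %% 2L == 1L
    )
  })
  pairs <- dplyr::bind_rows(pairs)

  count_mat <- function(d) {
    m <- matrix(0, N_SHAPES, N_SHAPES, dimnames = list(1:N_SHAPES, 1:N_SHAPES))
    t <- table(factor(d$from, levels = 1:N_SHAPES), factor(d$to, levels = 1:N_SHAPES))
    m[] <- as.numeric(t)
    m
  }
  row_norm <- function(m) {
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    m
  }
  # mean observed P(specific successor | current), over observed successors
  mean_observed <- function(p, counts, off_diagonal = FALSE) {
    keep <- counts > 0
    if (off_diagonal) diag(keep) <- FALSE
    mean(p[keep])
  }

  full_counts <- count_mat(pairs)
  full <- row_norm(full_counts)

  if (condition == "random") {
    res <- list(
      condition = condition, matrix = full, within = NULL, between = NULL,
      tp_within = NA_real_,
      tp_between = mean_observed(full, full_counts, off_diagonal = TRUE)
    )
  } else {
    wc <- count_mat(pairs[pairs$within, ])
    bc <- count_mat(pairs[!pairs$within, ])
    w <- row_norm(wc)
    b <- row_norm(bc)
    res <- list(
      condition = condition, matrix = full, within = w, between = b,
      tp_within = mean_observed(w, wc),
      tp_between = mean_observed(b, bc)
    )
  }
  structure(res, class = "tp_table")
}

#' @export
print.tp_table <- function(x, ...) {
  cat("<tp_table> condition:", x$condition, "\n")
  cat(sprintf(
    "  tp_within = %s, tp_between = %.4f\n",
    ifelse(is.na(x$tp_within), "NA", sprintf("%.4f", x$tp_within)), x$tp_between
  ))
  invisible(x)
}

#' @describeIn empirical_tp Long-format tibble of the full transition matrix.
#' @param x A `tp_table`.
#' @param ... Unused.
#' @export
tidy.tp_table <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    from = rep(seq_len(nrow(m)), times = ncol(m)),
    to = rep(seq_len(ncol(m)), each = nrow(m)),
    probability = as.vector(m)
  )
}

#' Export a set of trial sequences as a tidy table
#'
#' @param sequences List of `trial_sequence` objects (one per trial).
#' @return Tibble with columns `trial`, `position`, `shape_id`, `triggered`.
#' @export
sequence_table <- function(sequences) {
  if (inherits(sequences, "trial_sequence")) sequences <- list(sequences)
  purrr::imap_dfr(sequences, function(s, i) {
    tibble::tibble(
      trial = as.integer(i), position = s$position,
      shape_id = s$shape_id, triggered = s$triggered
    )
  })
}
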