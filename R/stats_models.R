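# Trial-level linear mixed-model ladder for base-level SNR, doublet-level
# SNR and the doublet learning index, with simple-coded condition
# contrasts, Tukey post hocs and ICC reporting.
#
# The two SNR outcomes are right-skewed and modelled on the log10 scale;
# the learning index (a ratio of SNRs) is modelled untransformed. Models
# are fitted by ML for likelihood-ratio comparisons along the ladder and
# the selected model is refitted by REML for the reported estimates.

LADDER_STEPS <- c("order", "condition", "age", "condition_x_order")

# Simple coding: deviations from the grand mean, so the intercept of a
# balanced condition model is the unweighted mean of the condition means.
simple_coding <- function(k = 3L) {
  stats::contr.treatment(k) - 1 / k
}

#' Build the LMM analysis table
#'
#' Restricts valid-trial records to orders 1..`max_order`, log10-transforms
#' the two SNR outcomes, scales age to years (for comparably sized
#' coefficients) and attaches the simple-coded condition factor.
#'
#' @param records Valid-trial records ([valid_trial_records()] output or a
#'   tibble with subject_id, condition, age_days, order, snr_base,
#'   snr_doublet, learning_index).
#' @param max_order Highest trial order retained (default 9).
#' @return Tibble ready for [fit_ladder()], with columns `log_snr_base`,
#'   `log_snr_doublet`, `learning_index`, `age` (years) and a
#'   simple-coded `condition` factor.
#' @export
build_table <- function(records, max_order = 9L) {
  need <- c("subject_id", "condition", "age_days", "order",
            "snr_base", "snr_doublet", "learning_index")
  stopifnot(all(need %in% names(records)))
  out <- records |>
    dplyr::filter(.data$order <= max_order) |>
    dplyr::mutate(
      log_snr_base = log10(.data$snr_base),
      log_snr_doublet = log10(.data$snr_doublet),
      age = .data$age_days / 365.25,
      condition = factor(.data$condition, levels = intersect(CONDITIONS, unique(.data$condition)))
    )
  if (nrow(out) == 0L) stop("no records left after order restriction")
  if (nlevels(out$condition) >= 2L) {
    stats::contrasts(out$condition) <- simple_coding(nlevels(out$condition))
  }
  out
}

dv_column <- function(dv) {
  switch(dv,
    snr_base = "log_snr_base",
    snr_doublet = "log_snr_doublet",
    learning_index = "learning_index",
    stop("unknown dependent variable: ", dv)
  )
}

ladder_formula <- function(dv_col, terms) {
  rhs <- c("1", terms, "(1 | subject_id)")
  stats::as.formula(paste(dv_col, "~", paste(rhs, collapse = " + ")))
}

#' Fit the stepwise mixed-model ladder
#'
#' Starting from a random-intercept-only model, candidate fixed effects are
#' added in sequence (trial order, condition, age, then the condition by
#' order interaction, the last bringing in any missing main effects). Each
#' candidate is compared to the currently selected model by likelihood
#' ratio test on ML fits; a candidate is adopted when the LRT is
#' significant and its AIC is lower. The selected model is refitted with
#' REML for reporting.
#'
#' @param table A [build_table()] result.
#' @param dv One of `"snr_base"`, `"snr_doublet"`, `"learning_index"`.
#' @param alpha LRT level for adopting a step (default 0.05).
#' @return Object of class `snr_ladder`: `steps` (tibble of every
#'   comparison: formula, AIC, logLik, LRT chi-square, df, p, adopted),
#'   `selected` (term set of the final model), `fit` (REML refit, a
#'   `lmerModLmerTest`), `ml_fit`, `dv`, `singular` flag, and `data`.
#' @export
fit_ladder <- function(table, dv = c("snr_base", "snr_doublet", "learning_index"),
                       alpha = 0.05) {
  dv <- match.arg(dv)
  dvc <- dv_column(dv)
  stopifnot(dvc %in% names(table),
            dplyr::n_distinct(table$subject_id) >= 2L)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit_ml <- function(terms) {
    suppressMessages(lmerTest::lmer(ladder_formula(dvc, terms), data = table,
                                    REML = FALSE, control = ctrl))
  }

  current_terms <- character(0)
  current <- fit_ml(current_terms)
  steps <- list()
  steps[[1]] <- tibble::tibble(
    step = "intercept", formula = deparse1(stats::formula(current)),
    aic = AIC(current), loglik = as.numeric(logLik(current)),
    chisq = NA_real_, chi_df = NA_integer_, p_value = NA_real_, adopted = TRUE
  )
  for (step in LADDER_STEPS) {
    cand_terms <- switch(step,
      order = union(current_terms, "order"),
      condition = union(current_terms, "condition"),
      age = union(current_terms, "age"),
      condition_x_order = union(current_terms, c("order", "condition", "condition:order"))
    )
    if (setequal(cand_terms, current_terms)) next
    cand <- fit_ml(cand_terms)
    lrt <- anova(current, cand)
    chisq <- lrt$Chisq[2]
    chi_df <- lrt$Df[2]
    p <- lrt$`Pr(>Chisq)`[2]
    adopt <- isTRUE(p < alpha) && AIC(cand) < AIC(current)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = step, formula = deparse1(stats::formula(cand)),
      aic = AIC(cand), loglik = as.numeric(logLik(cand)),
      chisq = chisq, chi_df = as.integer(chi_df), p_value = p, adopted = adopt
    )
    if (adopt) {
      current <- cand
      current_terms <- cand_terms
    }
  }
  reml <- suppressMessages(lmerTest::lmer(ladder_formula(dvc, current_terms),
                                          data = table, REML = TRUE, control = ctrl))
  structure(
    list(
      steps = dplyr::bind_rows(steps),
      selected = if (length(current_terms)) current_terms else "intercept-only",
      fit = reml, ml_fit = current, dv = dv, data = table,
      singular = lme4::isSingular(reml)
    ),
    class = "snr_ladder"
  )
}

#' @export
print.snr_ladder <- function(x, ...) {
  cat("<snr_ladder> dv:", x$dv, "\n")
  cat("  selected terms:", paste(x$selected, collapse = " + "), "\n")
  cat(sprintf("  AIC (ML) = %.3f | logLik = %.3f | ICC = %.3f%s\n",
              AIC(x$ml_fit), as.numeric(logLik(x$ml_fit)), icc(x$fit),
              if (x$singular) " | singular fit" else ""))
  invisible(x)
}

#' @describeIn fit_ladder Fixed-effect estimates of the selected REML fit
#'   with Satterthwaite t tests and Wald 95% CIs.
#' @param x An `snr_ladder`.
#' @param ... Unused.
#' @export
tidy.snr_ladder <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  se <- s[, "Std. Error"]
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = se,
    df = s[, "df"],
    statistic = s[, "t value"],
    conf_low = s[, "Estimate"] - stats::qnorm(0.975) * se,
    conf_high = s[, "Estimate"] + stats::qnorm(0.975) * se,
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @describeIn fit_ladder One-row model-level summary (AIC, logLik, ICC,
#'   sizes, singularity).
#' @export
glance.snr_ladder <- function(x, ...) {
  tibble::tibble(
    dv = x$dv,
    selected = paste(x$selected, collapse = " + "),
    aic_ml = AIC(x$ml_fit),
    loglik_ml = as.numeric(logLik(x$ml_fit)),
    icc = icc(x$fit),
    n_obs = nrow(x$data),
    n_subjects = dplyr::n_distinct(x$data$subject_id),
    singular = x$singular
  )
}

#' Intraclass correlation of a random-intercept model
#'
#' Between-subject variance divided by total (between + residual) variance:
#' the proportion of outcome variance due to individual differences.
#'
#' @param model A fitted `lmerMod` (or an `snr_ladder`, whose REML fit is
#'   used).
#' @return ICC in `[0, 1]`.
#' @export
icc <- function(model) {
  if (inherits(model, "snr_ladder")) model <- model$fit
  vc <- as.data.frame(lme4::VarCorr(model))
  tau2 <- vc$vcov[vc$grp == "subject_id" & vc$var1 == "(Intercept)"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  tau2 / (tau2 + sigma2)
}

#' Tukey-adjusted post hoc contrasts
#'
#' Pairwise condition contrasts of the selected model (Tukey-adjusted,
#' Satterthwaite degrees of freedom), per-condition means with Wald CIs —
#' back-transformed (10^x) when the outcome is log10 SNR — plus, when the
#' condition-by-order interaction is in the model, pairwise comparisons of
#' the order slopes and condition comparisons at fixed orders.
#'
#' @param ladder An `snr_ladder` (condition must be in the selected model).
#' @param at_orders Orders at which conditions are compared when order is
#'   in the model (default 1, 5, 9).
#' @return Object of class `snr_contrasts`: tibbles `means`, `contrasts`,
#'   and (when applicable) `slopes`, `slope_contrasts`, `by_order`.
#' @export
post_hoc <- function(ladder, at_orders = c(1, 5, 9)) {
  stopifnot(inherits(ladder, "snr_ladder"))
  if (!"condition" %in% ladder$selected) {
    stop("condition is not in the selected model; no condition contrasts to test")
  }
  fit <- ladder$fit
  log_dv <- ladder$dv %in% c("snr_base", "snr_doublet")
  has_order <- "order" %in% ladder$selected
  has_inter <- "condition:order" %in% ladder$selected

  em <- emmeans::emmeans(fit, "condition", lmer.df = "satterthwaite")
  means <- tibble::as_tibble(summary(em, infer = c(TRUE, FALSE)))
  names(means)[names(means) == "emmean"] <- "mean"
  names(means)[names(means) == "lower.CL"] <- "conf_low"
  names(means)[names(means) == "upper.CL"] <- "conf_high"
  if (log_dv) {
    means$back_mean <- 10^means$mean
    means$back_conf_low <- 10^means$conf_low
    means$back_conf_high <- 10^means$conf_high
  }
  contrasts <- tibble::as_tibble(
    summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  )

  out <- list(means = means, contrasts = contrasts, dv = ladder$dv)
  if (has_inter) {
    tr <- emmeans::emtrends(fit, "condition", var = "order",
                            lmer.df = "satterthwaite")
    out$slopes <- tibble::as_tibble(summary(tr))
    out$slope_contrasts <- tibble::as_tibble(
      summary(emmeans::contrast(tr, method = "pairwise", adjust = "tukey"))
    )
  }
  if (has_order || has_inter) {
    by_order <- purrr::map_dfr(at_orders, function(k) {
      emk <- emmeans::emmeans(fit, "condition", at = list(order = k),
                              lmer.df = "satterthwaite")
      cmp <- summary(emmeans::contrast(emk, method = "pairwise", adjust = "tukey"))
      d <- tibble::as_tibble(cmp)
      d$order <- k
      d
    })
    out$by_order <- by_order
  }
  structure(out, class = "snr_contrasts")
}

#' @export
print.snr_contrasts <- function(x, ...) {
  cat("<snr_contrasts> dv:", x$dv, "\n")
  print(x$contrasts)
  invisible(x)
}

#' Simulate a trial-level SNR table from the generative mixed model
#'
#' Draws log10 SNR outcomes from a random-intercept model with
#' per-condition means and order slopes — the generative structure the
#' ladder is meant to recover — and returns a table shaped like
#' [valid_trial_records()] output. Defaults reproduce the magnitudes
#' typical of infant frequency-tagging cohorts: doublet-level log10-SNR
#' condition means of about 0.27 / 0.13 / -0.05 (doublet / control /
#' random), a gently decreasing base-level SNR over trials, and ICCs near
#' 0.23 (base) and 0.08 (doublet).
#'
#' @param n_per_condition Subjects per condition.
#' @param n_trials Valid trials per subject.
#' @param base_mean,base_slope Base-level log10 SNR intercept and per-order
#'   slope.
#' @param doublet_means,doublet_slopes Named per-condition doublet-level
#'   log10 SNR means and slopes.
#' @param base_sd_subject,base_sd_resid,doublet_sd_subject,doublet_sd_resid
#'   Between-subject and residual SDs of the two outcomes.
#' @param age_range Age range in days.
#' @return Tibble: subject_id, condition, age_days, order, snr_base,
#'   snr_doublet, learning_index.
#' @export
simulate_snr_table <- function(n_per_condition = 8L, n_trials = 9L,
                               base_mean = 0.25, base_slope = -0.025,
                               doublet_means = c(doublet = 0.272, control = 0.134, random = -0.047),
                               doublet_slopes = c(doublet = 0, control = 0, random = 0),
                               base_sd_subject = 0.152, base_sd_resid = 0.28,
                               doublet_sd_subject = 0.081, doublet_sd_resid = 0.28,
                               age_range = c(120, 195)) {
  subj <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(3L * n_per_condition)),
    condition = rep(CONDITIONS, each = n_per_condition),
    age_days = round(stats::runif(3L * n_per_condition, age_range[1], age_range[2])),
    b_base = stats::rnorm(3L * n_per_condition, 0, base_sd_subject),
    b_doublet = stats::rnorm(3L * n_per_condition, 0, doublet_sd_subject)
  )
  tidyr::crossing(subj, order = seq_len(n_trials)) |>
    dplyr::mutate(
      log_base = base_mean + base_slope * (.data$order - 1) + .data$b_base +
        stats::rnorm(dplyr::n(), 0, base_sd_resid),
      log_doublet = doublet_means[.data$condition] +
        doublet_slopes[.data$condition] * (.data$order - 1) + .data$b_doublet +
        stats::rnorm(dplyr::n(), 0, doublet_sd_resid),
      snr_base = 10^.data$log_base,
      snr_doublet = 10^.data$log_doublet,
      learning_index = .data$snr_doublet / .data$snr_base
    ) |>
    dplyr::select("subject_id", "condition", "age_days", "order",
                  "snr_base", "snr_doublet", "learning_index")
}
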