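#' Exact binomial test on the fraction of significant pairs
#'
#' Two-sided exact binomial test (minimum-likelihood method) of `k`
#' significant pairs among `n`, against the null probability `p0` — by
#' default the synchrony test's nominal false-positive rate, which is the
#' natural reading of "expected by chance".
#'
#' @param k_significant Number of significant pairs (0 <= k <= n).
#' @param n_pairs Total number of pairs (>= 1).
#' @param p0 Null probability (default 0.05).
#' @return List: `p_value`, `estimate` (k/n), `k`, `n`, `p0`.
#' @export
binomial_fraction_test <- function(k_significant, n_pairs, p0 = 0.05) {
  if (n_pairs < 1) stopf("n_pairs must be >= 1")
  if (k_significant < 0 || k_significant > n_pairs)
    stopf("k_significant must lie in [0, n_pairs]")
  bt <- stats::binom.test(k_significant, n_pairs, p = p0,
                          alternative = "two.sided")
  list(p_value = bt$p.value, estimate = k_significant / n_pairs,
       k = k_significant, n = n_pairs, p0 = p0)
}

#' Fisher exact test of synchrony enrichment among fast pairs
#'
#' Builds the 2x2 table (both units fast vs not) x (pair significant vs
#' not) and applies the two-sided exact hypergeometric test, asking
#' whether pairs of two fast-firing units are more likely to exhibit
#' synchronous firing.
#'
#' @param pairs Pair-level `data.frame` with columns `unit_a`, `unit_b`,
#'   `significant` (see [analyze_all_pairs()]).
#' @param rate_classes Named character vector mapping unit_id to
#'   "slow"/"fast" (see [classify_rates()]).
#' @return List: `p_value`, `odds_ratio`, `table`.
#' @export
fast_pair_enrichment <- function(pairs, rate_classes) {
  both_fast <- rate_classes[pairs$unit_a] == "fast" &
    rate_classes[pairs$unit_b] == "fast"
  if (anyNA(both_fast)) stopf("rate_classes must cover every unit in pairs")
  sig <- pairs$significant
  tab <- table(factor(both_fast, c(TRUE, FALSE)),
               factor(sig, c(TRUE, FALSE)),
               dnn = c("both_fast", "significant"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate margin: a row or column of the 2x2 table is empty")
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Chi-square heterogeneity of synchronous-pair fractions across groups
#'
#' Pearson chi-square test of independence on the groups x
#' (significant, not significant) contingency table — e.g. grouped by
#' patient, or by epoch within one patient.
#'
#' @param pairs Pair-level `data.frame` with a `significant` column.
#' @param group Grouping vector, same length as `nrow(pairs)`.
#' @return List: `p_value`, `statistic`, `df`, `table`.
#' @export
heterogeneity_test <- function(pairs, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2)
    stopf("need at least 2 groups for the heterogeneity test")
  tab <- table(group, factor(pairs$significant, c(TRUE, FALSE)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(p_value = ct$p.value, statistic = unname(ct$statistic),
       df = unname(ct$parameter), table = tab)
}

#' Heterogeneity tests by patient and by epoch within patient
#'
#' @param pairs Pair-level `data.frame` with `patient_id`, `epoch_id`,
#'   `significant`.
#' @return List with `by_patient` and `within_patient` (a chi-square
#'   result per multi-epoch patient, plus a combined p from Fisher's
#'   method across patients with >= 2 epochs).
#' @export
heterogeneity_tests <- function(pairs) {
  by_patient <- heterogeneity_test(pairs, pairs$patient_id)
  pats <- split(pairs, pairs$patient_id)
  per <- lapply(pats, function(pp) {
    if (length(unique(pp$epoch_id)) < 2 || nrow(pp) < 2) return(NULL)
    tryCatch(heterogeneity_test(pp, pp$epoch_id), error = function(e) NULL)
  })
  per <- Filter(Negate(is.null), per)
  combined <- if (length(per)) {
    chi <- -2 * sum(log(vapply(per, `[[`, 0, "p_value")))
    stats::pchisq(chi, df = 2 * length(per), lower.tail = FALSE)
  } else NA_real_
  list(by_patient = by_patient,
       within_patient = list(per_patient = per, combined_p = combined))
}

#' Linear models of anesthesia covariates on firing rate
#'
#' For each covariate, compares the intercept-only model of unit firing
#' rate with the single-covariate model using an F-ratio test (each
#' variable is added on its own, without interactions). The p-values are
#' corrected by controlling the false discovery rate (Benjamini-Hochberg)
#' at `q`. The incremental fraction of variance (single-covariate R^2) and
#' the fitted effect are reported per covariate, and the combined model of
#' all FDR-significant covariates gives the total explained variance.
#' Constant covariates are skipped with a note.
#'
#' @param rates Numeric vector of per-unit firing rates.
#' @param covariates `data.frame` of per-unit covariates (one row per
#'   unit; factors or numerics).
#' @param q FDR level (default 0.2).
#' @return An object of class `glm_report`: `table` (per-variable
#'   `F_statistic`, `p_value`, `significant_after_fdr`,
#'   `variance_fraction`, `effect_estimate`, `effect_label`),
#'   `total_variance_fraction`, `residuals` (of the combined
#'   significant-covariate model), `skipped`.
#' @export
anesthesia_glm <- function(rates, covariates, q = 0.2) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(rates))
  ok <- is.finite(rates) & stats::complete.cases(covariates)
  if (sum(ok) < 10) stopf("need at least 10 units with complete covariates")
  y <- rates[ok]
  cv <- covariates[ok, , drop = FALSE]
  for (nm in names(cv)) if (is.character(cv[[nm]]) || is.logical(cv[[nm]]))
    cv[[nm]] <- factor(cv[[nm]])
  skipped <- names(cv)[vapply(cv, function(col) length(unique(col)) < 2, TRUE)]
  vars <- setdiff(names(cv), skipped)
  fit0 <- stats::lm(y ~ 1)
  rows <- lapply(vars, function(nm) {
    fit1 <- stats::lm(y ~ cv[[nm]])
    an <- stats::anova(fit0, fit1)
    co <- stats::coef(fit1)
    data.frame(variable = nm,
               F_statistic = an$F[2], p_value = an$`Pr(>F)`[2],
               variance_fraction = summary(fit1)$r.squared,
               effect_estimate = if (length(co) == 2) unname(co[2]) else NA_real_,
               effect_label = if (length(co) == 2) names(co)[2] else
                 paste(names(co)[-1], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant_after_fdr <- tab$p_adjusted <= q
  sig <- tab$variable[tab$significant_after_fdr]
  if (length(sig)) {
    full <- stats::lm(y ~ ., data = cbind(y = y, cv[sig]))
    total_r2 <- summary(full)$r.squared
    resid <- stats::residuals(full)
  } else {
    total_r2 <- 0
    resid <- stats::residuals(fit0)
  }
  structure(list(table = tab, total_variance_fraction = total_r2,
                 residuals = resid, q = q, skipped = skipped,
                 n = sum(ok)), class = "glm_report")
}

#' @export
print.glm_report <- function(x, ...) {
  cat(sprintf("Anesthesia covariate screen (FDR q = %g, n = %d units)\n",
              x$q, x$n))
  print(x$table[c("variable", "F_statistic", "p_value",
                  "significant_after_fdr", "variance_fraction")],
        row.names = FALSE)
  cat(sprintf("Combined significant covariates explain %.1f%% of variance\n",
              100 * x$total_variance_fraction))
  invisible(x)
}

#' Dip test of the residual firing-rate distribution
#'
#' Applies [dip_test()] to the residuals of the combined
#' significant-covariate model, asking whether evidence of two or more
#' rate classes survives after accounting for anesthesia-related effects.
#'
#' @param report A `glm_report` from [anesthesia_glm()].
#' @param ... Passed to [dip_test()].
#' @return A `dip_result`.
#' @export
residual_multimodality <- function(report, ...) {
  stopifnot(inherits(report, "glm_report"))
  dip_test(report$residuals, ...)
}
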