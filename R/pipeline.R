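#' Pipeline run configuration
#'
#' Exactly one of `input_path` (an existing session file) or `generator`
#' (a [population_config()]) must be supplied. All analysis constants of
#' the reference protocol are surfaced here as defaults: +-2.8 SD / 1.1 ms
#' detection, 100 us duplicate rule, 2-s segments, 1/1024 s bins, 200
#' shuffles, 1-25 ms normalization window, 2 sp/s class boundary, 10 ms
#' ISI threshold, SD = 1 s rate kernel, FDR 0.2.
#'
#' @param input_path Optional path to a session file (see
#'   [load_session()]).
#' @param input_format Session file format.
#' @param generator Optional [population_config()].
#' @param ccg A [ccg_params()].
#' @param dedup_threshold_us Duplicate-spike threshold, microseconds.
#' @param rate_boundary Slow/fast boundary, sp/s.
#' @param isi_threshold_ms Burst-index ISI threshold, ms.
#' @param kernel_sd_s,discharge_z,discharge_min_s Discharge detector
#'   parameters.
#' @param fdr_q FDR level for the anesthesia screen.
#' @param binomial_p0 Null probability for the pair-fraction binomial test.
#' @param max_components Mixture-fit cap on component count.
#' @param dip_reference_n Monte Carlo reference samples for dip p-values.
#' @param seed Master seed for generation and permutation streams.
#' @param out_dir Output directory (created if needed); `NULL` for none.
#' @param make_figures Write diagnostic figures (PNG) to `out_dir`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_path = NULL, input_format = "csv",
                       generator = NULL, ccg = NULL,
                       dedup_threshold_us = 100, rate_boundary = 2,
                       isi_threshold_ms = 10, kernel_sd_s = 1,
                       discharge_z = 4, discharge_min_s = 3, fdr_q = 0.2,
                       binomial_p0 = 0.05, max_components = 6,
                       dip_reference_n = 2000, seed = 1L, out_dir = NULL,
                       make_figures = FALSE) {
  if (is.null(input_path) == is.null(generator))
    stopf("exactly one of input_path or generator must be given")
  if (!is.null(generator)) stopifnot(inherits(generator, "population_config"))
  if (is.null(ccg)) ccg <- ccg_params(seed = derive_seed(seed, 2))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate a session; remove cross-channel duplicate
#' spikes; compute per-unit metrics (rate, burst index, discharges);
#' analyze all within-epoch unit pairs with the segment-shuffle CCG test;
#' population statistics (dip tests, mixture fits, binomial / Fisher /
#' chi-square tests, anesthesia covariate screen). Deterministic for a
#' fixed seed. If `out_dir` is set, writes `unit_metrics.csv`,
#' `pairs.csv`, `population.json` and `manifest.json` (plus figures when
#' requested).
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_result`: `session`, `metrics`, `pairs`,
#'   `population`, `truth` (generator ground truth, when generated),
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(generator = population_config())) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$generator)) {
    gen <- generate_population(config$generator)
    session <- gen$session
    truth <- gen[c("units", "pairs")]
  } else {
    session <- load_session(config$input_path, config$input_format)
  }
  session <- dedup_session(session, config$dedup_threshold_us)
  metrics <- unit_metrics(session, rate_boundary = config$rate_boundary,
                          isi_threshold_ms = config$isi_threshold_ms,
                          kernel_sd_s = config$kernel_sd_s,
                          z_threshold = config$discharge_z,
                          min_duration_s = config$discharge_min_s)
  pair_list <- lapply(seq_along(session$epochs), function(i)
    analyze_all_pairs(session$epochs[[i]], config$ccg,
                      seed = derive_seed(config$seed, 5000 + i)))
  pairs <- do.call(rbind, c(pair_list, list(analyze_all_pairs(
    epoch("..empty", "..none", list()), config$ccg))))
  rownames(pairs) <- NULL
  population <- population_summary(metrics, pairs, session, config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("unitsync")),
    r_version = R.version.string,
    seed = config$seed,
    generated = !is.null(config$generator),
    n_epochs = length(session$epochs),
    n_units = nrow(metrics), n_pairs = nrow(pairs),
    ccg = unclass(config$ccg),
    dedup_threshold_us = config$dedup_threshold_us,
    rate_boundary = config$rate_boundary,
    isi_threshold_ms = config$isi_threshold_ms,
    fdr_q = config$fdr_q, binomial_p0 = config$binomial_p0)
  res <- structure(list(session = session, metrics = metrics, pairs = pairs,
                        population = population, truth = truth,
                        manifest = manifest), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_outputs(res, config)
  res
}

population_summary <- function(metrics, pairs, session, config) {
  rates <- metrics$mean_rate
  bi <- metrics$burst_index
  finite_bi <- bi[is.finite(bi)]
  rate_fit <- if (length(rates) >= 8) fit_gmm_aic(rates, config$max_components) else NULL
  burst_fit <- if (length(finite_bi) >= 8) fit_gmm_aic(finite_bi, config$max_components) else NULL
  rate_dip <- if (length(rates) >= 4)
    dip_test(rates, config$dip_reference_n) else NULL
  burst_dip <- if (length(finite_bi) >= 4)
    dip_test(finite_bi, config$dip_reference_n) else NULL
  both <- is.finite(rates) & is.finite(bi)
  rho <- if (sum(both) >= 3) stats::cor(rates[both], bi[both]) else NA_real_

  n_pairs <- nrow(pairs)
  analyzable <- pairs[!is.na(pairs$p_value), , drop = FALSE]
  k_sig <- sum(analyzable$significant, na.rm = TRUE)
  binom <- if (nrow(analyzable) >= 1)
    binomial_fraction_test(k_sig, nrow(analyzable), config$binomial_p0) else NULL
  classes <- stats::setNames(metrics$rate_class, metrics$unit_id)
  fisher <- tryCatch(fast_pair_enrichment(analyzable, classes),
                     error = function(e) NULL)
  het <- tryCatch(heterogeneity_tests(analyzable), error = function(e) NULL)

  covs <- covariate_frame(metrics, session)
  glm_rep <- tryCatch(anesthesia_glm(metrics$mean_rate, covs, config$fdr_q),
                      error = function(e) NULL)
  resid_dip <- if (!is.null(glm_rep))
    tryCatch(residual_multimodality(glm_rep, n_reference = config$dip_reference_n),
             error = function(e) NULL) else NULL
  list(
    n_units = nrow(metrics),
    n_epochs = length(session$epochs),
    mean_rate = mean(rates), median_rate = stats::median(rates),
    sd_rate = stats::sd(rates),
    n_slow = sum(metrics$rate_class == "slow"),
    n_fast = sum(metrics$rate_class == "fast"),
    slow_median_rate = stats::median(rates[metrics$rate_class == "slow"]),
    fast_median_rate = stats::median(rates[metrics$rate_class == "fast"]),
    rate_burst_rho = rho,
    rate_mixture = rate_fit, burst_mixture = burst_fit,
    rate_dip = rate_dip, burst_dip = burst_dip,
    n_pairs_raw = n_pairs, n_pairs_analyzable = nrow(analyzable),
    n_significant_pairs = k_sig,
    significant_fraction = if (nrow(analyzable)) k_sig / nrow(analyzable) else NA_real_,
    n_positive = sum(analyzable$sign == "positive", na.rm = TRUE),
    n_negative = sum(analyzable$sign == "negative", na.rm = TRUE),
    binomial = binom, fisher = fisher, heterogeneity = het,
    n_discharge_units = sum(metrics$n_discharges > 0, na.rm = TRUE),
    anesthesia = glm_rep, residual_dip = resid_dip)
}

# per-unit covariate frame from epoch-level anesthesia records
covariate_frame <- function(metrics, session) {
  key <- paste(metrics$patient_id, metrics$epoch_id)
  eps <- stats::setNames(session$epochs,
                         vapply(session$epochs, function(e)
                           paste(e$patient_id, e$epoch_id), ""))
  rows <- lapply(key, function(k) {
    cv <- eps[[k]]$covariates
    if (is.null(cv)) return(NULL)
    as.data.frame(unclass(cv), stringsAsFactors = FALSE)
  })
  if (any(vapply(rows, is.null, TRUE)))
    return(data.frame(row.names = seq_along(key)))
  do.call(rbind, rows)
}

write_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(config$out_dir, x)
  utils::write.csv(res$metrics, fp("unit_metrics.csv"), row.names = FALSE)
  utils::write.csv(res$pairs, fp("pairs.csv"), row.names = FALSE)
  pop <- res$population
  pop$rate_mixture <- unclass_trim(pop$rate_mixture)
  pop$burst_mixture <- unclass_trim(pop$burst_mixture)
  pop$rate_dip <- unclass(pop$rate_dip)
  pop$burst_dip <- unclass(pop$burst_dip)
  pop$residual_dip <- unclass(pop$residual_dip)
  pop$fisher$table <- NULL
  pop$heterogeneity$by_patient$table <- NULL
  pop$heterogeneity$within_patient$per_patient <- NULL
  if (!is.null(pop$anesthesia)) {
    pop$anesthesia <- list(table = pop$anesthesia$table,
                           total_variance_fraction =
                             pop$anesthesia$total_variance_fraction)
  }
  jsonlite::write_json(pop, fp("population.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  jsonlite::write_json(res$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (isTRUE(config$make_figures)) write_figures(res, config)
  invisible(NULL)
}

unclass_trim <- function(m) {
  if (is.null(m)) return(NULL)
  m <- unclass(m)
  m$assignments <- NULL
  m
}

write_figures <- function(res, config) {
  fp <- function(x) file.path(config$out_dir, x)
  m <- res$metrics
  png_dev <- function(f) grDevices::png(fp(f), width = 900, height = 650)
  png_dev("rate_histogram.png")
  graphics::hist(m$mean_rate, breaks = 30, col = "grey70",
                 main = "Mean firing rates", xlab = "rate (sp/s)")
  grDevices::dev.off()
  png_dev("rate_vs_burst.png")
  fin <- is.finite(m$burst_index)
  graphics::plot(m$mean_rate[fin], m$burst_index[fin],
                 xlab = "mean rate (sp/s)", ylab = "burst index",
                 main = "Rate vs burst index", pch = 19,
                 col = ifelse(m$rate_class[fin] == "fast", "firebrick",
                              "steelblue"))
  grDevices::dev.off()
  pk <- res$pairs$normalized_peak
  pk <- pk[is.finite(pk) & pk != 0]
  if (length(pk)) {
    png_dev("peak_heights.png")
    graphics::hist(log10(abs(pk)), breaks = 30, col = "grey70",
                   main = "CCG zero-delay peak heights",
                   xlab = "log10 |normalized peak|")
    grDevices::dev.off()
  }
  png_dev("rates_by_patient.png")
  graphics::boxplot(mean_rate ~ patient_id, data = m, las = 2,
                    ylab = "mean rate (sp/s)", main = "Rates by patient")
  grDevices::dev.off()
  invisible(NULL)
}

#' One-page text summary of a pipeline run
#'
#' @param res A `pipeline_result` from [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
summarize_run <- function(res) {
  stopifnot(inherits(res, "pipeline_result"))
  p <- res$population
  f <- function(fmt, ...) sprintf(fmt, ...)
  lines <- c(
    f("Units: %d in %d epochs (mean %.1f units/epoch)", p$n_units, p$n_epochs,
      p$n_units / max(1, p$n_epochs)),
    f("Mean rate %.1f sp/s (SD %.1f, median %.1f)", p$mean_rate, p$sd_rate,
      p$median_rate),
    f("Rate classes: %d slow (median %.2f sp/s), %d fast (median %.1f sp/s)",
      p$n_slow, p$slow_median_rate, p$n_fast, p$fast_median_rate),
    if (!is.null(p$rate_mixture))
      f("Rate mixture: K = %d (component medians %s); dip p = %.3g",
        p$rate_mixture$n_components,
        paste(signif(p$rate_mixture$component_medians, 3), collapse = ", "),
        p$rate_dip$p_value),
    if (!is.null(p$burst_mixture))
      f("Burst mixture: K = %d (component medians %s); dip p = %.3g",
        p$burst_mixture$n_components,
        paste(signif(p$burst_mixture$component_medians, 3), collapse = ", "),
        p$burst_dip$p_value),
    f("Rate-burst Pearson rho = %.2f", p$rate_burst_rho),
    f("Pairs: %d raw, %d analyzable, %d significant (%.0f%%; %d positive / %d negative)",
      p$n_pairs_raw, p$n_pairs_analyzable, p$n_significant_pairs,
      100 * (p$significant_fraction %||% NA_real_), p$n_positive, p$n_negative),
    if (!is.null(p$binomial))
      f("Binomial test vs p0 = %.2f: p = %.3g", p$binomial$p0,
        p$binomial$p_value),
    if (!is.null(p$fisher))
      f("Fast-pair synchrony enrichment (Fisher): p = %.3g, OR = %.2f",
        p$fisher$p_value, p$fisher$odds_ratio),
    if (!is.null(p$heterogeneity))
      f("Between-patient heterogeneity (chi-square): p = %.3g",
        p$heterogeneity$by_patient$p_value),
    f("Units with evolving discharges: %d (%.1f%%)", p$n_discharge_units,
      100 * p$n_discharge_units / max(1, p$n_units)),
    if (!is.null(p$anesthesia))
      f("Anesthesia covariates: %d significant after FDR %.1f, explaining %.0f%% of variance; residual dip p = %.3g",
        sum(p$anesthesia$table$significant_after_fdr), p$anesthesia$q,
        100 * p$anesthesia$total_variance_fraction,
        if (!is.null(p$residual_dip)) p$residual_dip$p_value else NA))
  lines <- unlist(lines)
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.pipeline_result <- function(x, ...) {
  summarize_run(x)
  invisible(x)
}
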