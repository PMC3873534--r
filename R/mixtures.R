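#' Fit a univariate Gaussian mixture with AIC-stopped component count
#'
#' Gaussians are added one at a time: component counts K = 1, 2, ... are
#' fitted by EM (unequal variances) and the first K whose AIC fails to
#' improve on the previous fit stops the search; the preceding fit is
#' returned. Non-finite observations are excluded before fitting. AIC is
#' `2 * (3K - 1) - 2 * loglik`.
#'
#' @param values Numeric sample (>= 8 finite observations).
#' @param max_components Largest K to consider.
#' @return An object of class `mixture_fit`: `n_components`, `weights`,
#'   `means`, `sds`, `aic` (vector over the fitted K), `loglik`,
#'   `assignments` (most likely component per finite observation) and
#'   `component_medians` (median of the observations assigned to each
#'   component, ordered by component mean).
#' @export
fit_gmm_aic <- function(values, max_components = 6) {
  x <- values[is.finite(values)]
  if (length(x) < 8) stopf("need at least 8 finite observations")
  if (stats::sd(x) == 0) {
    # degenerate constant sample: single component with floored SD
    return(structure(list(
      n_components = 1L, weights = 1, means = mean(x),
      sds = max(1e-8, stats::sd(x)), aic = NA_real_, loglik = NA_real_,
      assignments = rep(1L, length(x)), component_medians = stats::median(x),
      n = length(x)), class = "mixture_fit"))
  }
  fits <- list()
  aics <- numeric(0)
  for (k in seq_len(max_components)) {
    f <- fit_gmm_k(x, k)
    if (is.null(f)) break
    aic <- 2 * (3 * k - 1) - 2 * f$loglik
    if (k > 1 && aic >= aics[k - 1]) { aics[k] <- aic; break }
    fits[[k]] <- f
    aics[k] <- aic
  }
  best_k <- length(fits)
  f <- fits[[best_k]]
  ord <- order(f$means)
  assign_raw <- f$assignments
  assignments <- match(assign_raw, ord)
  med <- vapply(seq_len(best_k), function(c)
    stats::median(x[assignments == c]), 0)
  structure(list(n_components = best_k, weights = f$weights[ord],
                 means = f$means[ord], sds = f$sds[ord], aic = aics,
                 loglik = f$loglik, assignments = assignments,
                 component_medians = med, n = length(x)),
            class = "mixture_fit")
}

# single-K univariate EM fit; K = 1 is closed form, K >= 2 uses mclust's
# unequal-variance ("V") model. Returns NULL when the fit fails.
fit_gmm_k <- function(x, k) {
  if (k == 1) {
    mu <- mean(x); s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
    return(list(weights = 1, means = mu, sds = s,
                loglik = sum(stats::dnorm(x, mu, s, log = TRUE)),
                assignments = rep(1L, length(x))))
  }
  # Mclust() evaluates `mclustBIC` in the calling frame, so bind it here
  mclustBIC <- mclust::mclustBIC
  f <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = k, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(f) || !is.finite(f$loglik)) return(NULL)
  list(weights = as.numeric(f$parameters$pro),
       means = as.numeric(f$parameters$mean),
       sds = sqrt(rep_len(as.numeric(f$parameters$variance$sigmasq), k)),
       loglik = f$loglik,
       assignments = as.integer(f$classification))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture (AIC-stopped): K = %d, n = %d\n",
              x$n_components, x$n))
  cat(sprintf("  means: %s\n", paste(signif(x$means, 3), collapse = ", ")))
  cat(sprintf("  component medians: %s\n",
              paste(signif(x$component_medians, 3), collapse = ", ")))
  invisible(x)
}

#' Classify firing rates into slow and fast classes
#'
#' Slow iff the mean rate is below `boundary` sp/s; the boundary value
#' itself is fast.
#'
#' @param rates Numeric vector of mean rates (>= 0).
#' @param boundary Class boundary in sp/s (default 2).
#' @return Character vector of "slow"/"fast" labels.
#' @export
classify_rates <- function(rates, boundary = 2) {
  if (!length(rates)) return(character())
  if (any(rates < 0, na.rm = TRUE)) stopf("rates must be >= 0")
  ifelse(rates < boundary, "slow", "fast")
}
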