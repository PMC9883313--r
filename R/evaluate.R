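#' Full social-structure evaluation of an association matrix
#'
#' Runs the standard performance battery on one criterion's associations:
#' distribution summaries of the half-weight indices (mean, SD, share of
#' zero, moderate and strong dyads), coefficients of variation with
#' within-day permutation P values, an optional Mantel test against a group
#' membership (e.g. matriline) indicator, leading-eigenvector community
#' detection with modularity, and likelihood-based social differentiation.
#'
#' @param assoc an `"association_data"` object.
#' @param ids optional ID restriction (e.g. from [restrict_individuals()]).
#' @param membership optional named vector of group labels for the Mantel
#'   test.
#' @param n_permutations,n_trials settings for [permute_within_days()] (the
#'   Mantel test uses `n_permutations` label permutations).
#' @param seed seed for the permutation machinery (local to this call).
#' @return an object of class `"evaluation_report"`: a nested list with
#'   components `criterion`, `threshold`, `summary`, `cv`, `mantel` (or
#'   `NULL`), `communities` and `differentiation`.
#' @export
evaluate_social_structure <- function(assoc, ids = NULL, membership = NULL,
                                      n_permutations = 1000L,
                                      n_trials = 1000L, seed = NULL) {
  stopifnot(inherits(assoc, "association_data"))
  hw <- hwi_matrix(assoc, ids = ids)
  v <- hw$hwi[upper.tri(hw$hwi)]
  nz <- v[v > 0]
  summary_stats <- list(
    n_individuals = length(hw$ids),
    n_days = length(assoc$days),
    mean_hwi = mean(v), sd_hwi = stats::sd(v),
    mean_nonzero_hwi = if (length(nz)) mean(nz) else NA_real_,
    sd_nonzero_hwi = if (length(nz) > 1) stats::sd(nz) else NA_real_,
    pct_zero = 100 * mean(v == 0),
    pct_nonzero_below_half = 100 * mean(v > 0 & v < 0.5),
    pct_at_least_half = 100 * mean(v >= 0.5)
  )

  seeds <- if (is.null(seed)) c(NA, NA, NA) else seed + 0:2
  cv_all <- permute_within_days(
    assoc, n_permutations = n_permutations, n_trials = n_trials,
    statistic = "cv_all", ids = ids,
    seed = if (is.null(seed)) NULL else seeds[1])
  cv_nonzero <- permute_within_days(
    assoc, n_permutations = n_permutations, n_trials = n_trials,
    statistic = "cv_nonzero", ids = ids,
    seed = if (is.null(seed)) NULL else seeds[2])
  cv <- list(cv_all = cv_all$observed, p_all = cv_all$p_value,
             cv_nonzero = cv_nonzero$observed,
             p_nonzero = cv_nonzero$p_value,
             n_permutations = n_permutations, n_trials = n_trials)

  mantel <- NULL
  if (!is.null(membership)) {
    mantel <- mantel_association_test(
      hw, membership, n_permutations = n_permutations,
      seed = if (is.null(seed)) NULL else seeds[3])
  }
  communities <- newman_communities(hw)
  differentiation <- tryCatch(social_differentiation(assoc, ids = ids),
                              error = function(e) NULL)
  structure(
    list(criterion = assoc$criterion, threshold = assoc$threshold,
         summary = summary_stats, cv = cv, mantel = mantel,
         communities = communities, differentiation = differentiation,
         hwi = hw),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Social-structure evaluation (%s criterion%s)\n",
              x$criterion,
              if (is.null(x$threshold)) ""
              else sprintf(", threshold %d", x$threshold)))
  cat(sprintf("  %d individuals over %d days\n",
              s$n_individuals, s$n_days))
  cat(sprintf("  mean HWI %.3f +/- %.3f (non-zero %.3f +/- %.3f)\n",
              s$mean_hwi, s$sd_hwi, s$mean_nonzero_hwi, s$sd_nonzero_hwi))
  cat(sprintf("  %%HWI = 0: %.1f; %%0 < HWI < 0.5: %.1f; %%HWI >= 0.5: %.1f\n",
              s$pct_zero, s$pct_nonzero_below_half, s$pct_at_least_half))
  cat(sprintf("  CV %.3f (P = %.4g), non-zero CV %.3f (P = %.4g)\n",
              x$cv$cv_all, x$cv$p_all, x$cv$cv_nonzero, x$cv$p_nonzero))
  if (!is.null(x$mantel))
    cat(sprintf("  Mantel: matrix correlation %.3f, P = %.4g\n",
                x$mantel$matrix_correlation, x$mantel$p_value))
  cat(sprintf("  communities: %d clusters, Q = %.3f\n",
              x$communities$n_clusters, x$communities$q))
  if (!is.null(x$differentiation))
    cat(sprintf("  social differentiation S = %.3f%s\n",
                x$differentiation$s,
                if (x$differentiation$boundary) " (boundary fit)" else ""))
  invisible(x)
}

# flatten an evaluation report to plain lists for JSON serialization
report_to_list <- function(report) {
  out <- list(
    criterion = report$criterion,
    threshold = report$threshold,
    summary = report$summary,
    cv = report$cv,
    communities = list(
      q = report$communities$q,
      n_clusters = report$communities$n_clusters,
      cluster_sizes = report$communities$cluster_sizes,
      assignment = as.list(report$communities$assignment))
  )
  if (!is.null(report$mantel))
    out$mantel <- list(
      matrix_correlation = report$mantel$matrix_correlation,
      p_value = report$mantel$p_value,
      n_permutations = report$mantel$n_permutations)
  if (!is.null(report$differentiation))
    out$social_differentiation <- list(
      s = report$differentiation$s,
      alpha = report$differentiation$alpha,
      beta = report$differentiation$beta,
      boundary = report$differentiation$boundary)
  out
}
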