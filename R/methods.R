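#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted SEM
#'
#' One row per model parameter (free and fixed), with the estimate on the
#' internal pooled z-scored metric, its standard error, Wald z/p, and the
#' standardized solutions: `std` (the covariate-adjusted metric, in which
#' endogenous variables are scaled by their model-implied variance net of
#' declared covariates — the metric on which "corrected" associations are
#' reported) and `std_all` (total model-implied variance). `std_se` is the
#' delta-method standard error of `std`.
#'
#' @param x A `gsem_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `class`, `group`, `lhs`, `rhs`,
#'   `estimate`, `se`, `statistic`, `p`, `std`, `std_all`, `std_se`,
#'   `free`.
#' @method tidy gsem_fit
#' @export
tidy.gsem_fit <- function(x, ...) {
  ptab <- x$comp$ptab
  est <- ifelse(ptab$free, unname(x$theta)[ptab$theta_idx], ptab$value)
  se <- ifelse(ptab$free, unname(x$se)[ptab$theta_idx], NA_real_)
  stat <- est / se
  tibble::tibble(
    term = ptab$label,
    class = ptab$class,
    group = x$group_names[ptab$group],
    lhs = ptab$lhs, rhs = ptab$rhs,
    estimate = est, se = se, statistic = stat,
    p = 2 * pnorm(-abs(stat)),
    std = x$std$std_nox, std_all = x$std$std_all, std_se = x$std$std_se,
    free = ptab$free
  )
}

#' Glance at a fitted SEM
#'
#' @param x A `gsem_fit`.
#' @param ... Unused.
#' @return A one-row tibble: log-likelihood, chi-square vs the saturated
#'   model, df, fit indices (CFI, TLI, RMSEA, SRMR, AIC, saBIC), sample
#'   sizes, missingness-pattern count, and convergence status.
#' @method glance gsem_fit
#' @export
glance.gsem_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(loglik = x$loglik, loglik_sat = x$loglik_sat),
    x$indices,
    tibble::tibble(
      n = x$n, n_complete = x$n_complete, n_patterns = x$n_patterns,
      n_free = x$n_free, n_groups = length(x$group_names),
      converged = x$converged,
      n_warnings = length(x$warnings)
    )
  )
}

#' @export
print.gsem_fit <- function(x, ...) {
  cat("<gsem_fit> FIML structural equation model\n")
  cat(sprintf("  n = %d (%d complete, %d missingness patterns), groups = %d\n",
              x$n, x$n_complete, x$n_patterns, length(x$group_names)))
  cat(sprintf("  logLik %.3f, chisq(%d) = %.3f\n", x$loglik, x$df, x$chisq))
  ind <- x$indices
  cat(sprintf("  CFI %.3f  TLI %.3f  RMSEA %.4f  SRMR %.4f\n",
              ind$cfi, ind$tli, ind$rmsea, ind$srmr))
  if (!x$converged) cat("  WARNING: possible non-convergence\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Export a parameter table and fit indices
#'
#' Writes the tidy parameter table as TSV and the fit indices as JSON,
#' mirroring the run-report conventions of the pipeline.
#'
#' @param fit A `gsem_fit`.
#' @param prefix Path prefix; writes `<prefix>_parameters.tsv` and
#'   `<prefix>_indices.json`.
#' @return Invisibly, the two paths.
#' @export
export_fit <- function(fit, prefix) {
  ptsv <- paste0(prefix, "_parameters.tsv")
  pjson <- paste0(prefix, "_indices.json")
  readr::write_tsv(tidy(fit), ptsv)
  jsonlite::write_json(as.list(glance(fit)), pjson, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(ptsv, pjson))
}
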