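#' Fit indices from chi-square summaries
#'
#' Core incremental/absolute fit-index arithmetic. Conventions (recorded in
#' each fit's metadata because software differs): RMSEA uses the total-N
#' divisor, `sqrt(max(chisq - df, 0) / (df * N))`; saBIC uses the
#' `k * log((N + 2) / 24)` penalty; CFI and TLI are clamped to at most 1;
#' a saturated model (df = 0) has CFI = 1 and RMSEA = 0.
#'
#' @param chisq,df Model chi-square (vs the saturated model) and its df.
#' @param baseline_chisq,baseline_df Independence-baseline chi-square/df.
#' @param n Total sample size.
#' @param loglik,n_free Optional log-likelihood and free-parameter count
#'   (for AIC/saBIC).
#' @param srmr Optional precomputed SRMR to carry through.
#' @return A one-row tibble with `chisq, df, pvalue, cfi, tli, rmsea, srmr,
#'   aic, sabic`.
#' @export
#' @examples
#' fit_index_values(50, 5, 1000, 10, n = 1000)
fit_index_values <- function(chisq, df, baseline_chisq, baseline_df, n,
                             loglik = NA_real_, n_free = NA_real_,
                             srmr = NA_real_) {
  dM <- max(chisq - df, 0)
  dB <- max(baseline_chisq - baseline_df, 0)
  cfi <- if (df == 0) 1 else if (is.na(baseline_chisq)) NA_real_ else
    1 - dM / max(dB, dM, .Machine$double.eps)
  tli <- if (is.na(baseline_chisq) || df == 0) {
    if (df == 0) 1 else NA_real_
  } else {
    rB <- baseline_chisq / baseline_df
    rM <- chisq / df
    min((rB - rM) / (rB - 1), 1)
  }
  rmsea <- if (df == 0) 0 else sqrt(max(chisq - df, 0) / (df * n))
  tibble::tibble(
    chisq = chisq, df = df,
    pvalue = if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    cfi = min(cfi, 1), tli = tli, rmsea = rmsea, srmr = srmr,
    aic = -2 * loglik + 2 * n_free,
    sabic = -2 * loglik + n_free * log((n + 2) / 24)
  )
}

#' Fit indices of a fitted model
#'
#' @param fit A `gsem_fit`.
#' @param baseline Optional `gsem_fit` to use as the incremental-fit
#'   baseline instead of the automatically fitted independence model.
#' @return A one-row tibble (see [fit_index_values()]).
#' @export
fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "gsem_fit"))
  if (is.null(baseline)) return(fit$indices)
  fit_index_values(fit$chisq, fit$df, baseline$chisq, baseline$df,
                   n = fit$n, loglik = fit$loglik, n_free = fit$n_free,
                   srmr = fit$indices$srmr)
}

#' Whether a fit meets the preregistered adequacy thresholds
#'
#' CFI and TLI above 0.95; RMSEA and SRMR below 0.05.
#'
#' @param fit A `gsem_fit` (or a one-row indices tibble).
#' @return Logical.
#' @export
meets_fit_thresholds <- function(fit) {
  ind <- if (inherits(fit, "gsem_fit")) fit$indices else fit
  isTRUE(ind$cfi > 0.95 && ind$tli > 0.95 &&
           ind$rmsea < 0.05 && ind$srmr < 0.05)
}

#' Compare two nested model fits
#'
#' Likelihood-ratio (chi-square difference) test plus AIC and saBIC
#' differences, all reported as constrained minus free.
#'
#' @param free,constrained `gsem_fit` objects fitted to the same data, the
#'   second nested in the first.
#' @return A one-row tibble with `delta_chisq`, `delta_df`, `pvalue`,
#'   `delta_aic`, `delta_sabic` and per-criterion preference flags
#'   (`prefer_constrained_*`).
#' @export
compare_nested <- function(free, constrained) {
  stopifnot(inherits(free, "gsem_fit"), inherits(constrained, "gsem_fit"))
  if (constrained$n != free$n) {
    stop("fits are not on the same data (n differs)", call. = FALSE)
  }
  delta_df <- constrained$df - free$df
  if (delta_df < 0) {
    stop("models are not nested as (free, constrained): df must not decrease",
         call. = FALSE)
  }
  delta_chisq <- max(2 * (free$loglik - constrained$loglik), 0)
  pvalue <- if (delta_df > 0) {
    pchisq(delta_chisq, delta_df, lower.tail = FALSE)
  } else {
    as.numeric(delta_chisq <= 1e-8)
  }
  delta_aic <- constrained$indices$aic - free$indices$aic
  delta_sabic <- constrained$indices$sabic - free$indices$sabic
  tibble::tibble(
    delta_chisq = delta_chisq,
    delta_df = delta_df,
    pvalue = pvalue,
    delta_aic = delta_aic,
    delta_sabic = delta_sabic,
    prefer_constrained_chisq = pvalue > 0.05,
    prefer_constrained_aic = delta_aic < 0,
    prefer_constrained_sabic = delta_sabic < 0
  )
}
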