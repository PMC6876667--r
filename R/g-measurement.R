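cognitive_tests <- function() c("matrix_reasoning", "symbol_digit", "vnr", "tmtb_time")

# assemble model syntax for the g CFA with optional covariate attachment
# and residual-covariance pairs
g_cfa_syntax <- function(covariates = character(), resid_pairs = list(),
                         extra = character()) {
  tests <- cognitive_tests()
  lines <- paste0("g =~ ", paste(tests, collapse = " + "))
  for (pr in resid_pairs) lines <- c(lines, paste0(pr[1], " ~~ ", pr[2]))
  if (length(covariates)) {
    lines <- c(lines, paste0(tests, " ~ ", paste(covariates, collapse = " + ")))
  }
  paste(c(lines, extra), collapse = "\n")
}

#' Fit the latent g confirmatory factor model
#'
#' One-factor FIML CFA of the four cognitive tests (Matrix Reasoning,
#' Symbol-Digit, Verbal-Numerical Reasoning, Trail-Making part B time,
#' whose loading is negative because longer times mean worse performance).
#' If `auto_respecify` is set and any preregistered index fails (CFI/TLI
#' <= 0.95, RMSEA/SRMR >= 0.05), the top-modification-index residual
#' covariance among the tests is freed and the model refitted, up to
#' `max_added` additions.
#'
#' @param cohort Cohort tibble; subjects with at least one observed test
#'   enter the likelihood.
#' @param covariates Covariate set applied to the manifest variables inside
#'   the model (e.g. `c("age", "sex")`); empty for the uncorrected model.
#' @param auto_respecify Add MI-suggested residual covariances until the
#'   fit thresholds are met.
#' @param resid_pairs Residual-covariance pairs to include from the start
#'   (list of 2-vectors).
#' @param max_added Respecification cap; if exceeded the best fit is
#'   returned flagged (`thresholds_met = FALSE`).
#' @return A `g_factor_model`: list with the `gsem_fit` (`$fit`), the
#'   standardized loadings (`$loadings`), `$variance_explained`,
#'   `$pairs_added`, `$thresholds_met`, `$covariates`.
#' @export
fit_g_cfa <- function(cohort, covariates = c("age", "sex"),
                      auto_respecify = TRUE, resid_pairs = list(),
                      max_added = 3) {
  tests <- cognitive_tests()
  assert_columns(cohort, c(tests, covariates), "cohort")
  keep <- rowSums(!is.na(cohort[, tests])) >= 1
  dat <- cohort[keep, , drop = FALSE]

  pairs <- resid_pairs
  added <- list()
  fit <- fit_model(g_cfa_syntax(covariates, pairs), dat,
                   covariates = covariates)
  while (auto_respecify && !meets_fit_thresholds(fit) &&
         length(added) < max_added) {
    mi <- modification_indices(fit)
    mi <- mi[mi$lhs %in% tests & mi$rhs %in% tests, , drop = FALSE]
    if (!nrow(mi)) break
    top <- c(mi$lhs[1], mi$rhs[1])
    pairs <- c(pairs, list(top))
    added <- c(added, list(top))
    fit <- fit_model(g_cfa_syntax(covariates, pairs), dat,
                     covariates = covariates)
  }
  td <- tidy(fit)
  lo <- td[td$class == "loading", , drop = FALSE]
  loadings <- setNames(lo$std, lo$lhs)[tests]
  out <- list(fit = fit, loadings = loadings,
              variance_explained = variance_explained(loadings),
              pairs_added = added,
              thresholds_met = meets_fit_thresholds(fit),
              covariates = covariates, n = fit$n)
  class(out) <- "g_factor_model"
  out
}

#' @export
print.g_factor_model <- function(x, ...) {
  cat("<g_factor_model> one-factor CFA of the 4 cognitive tests\n")
  cat(sprintf("  n = %d, covariates: %s\n", x$n,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  cat("  standardized loadings:",
      paste(sprintf("%s = %.3f", names(x$loadings), x$loadings),
            collapse = ", "), "\n")
  cat(sprintf("  variance explained: %.1f%%\n", 100 * x$variance_explained))
  if (length(x$pairs_added)) {
    cat("  residual covariances added:",
        paste(vapply(x$pairs_added, paste, "", collapse = "~~"),
              collapse = ", "), "\n")
  }
  if (!x$thresholds_met) cat("  NOTE: preregistered fit thresholds not met\n")
  invisible(x)
}

#' @method tidy g_factor_model
#' @export
tidy.g_factor_model <- function(x, ...) tidy(x$fit)

#' @method glance g_factor_model
#' @export
glance.g_factor_model <- function(x, ...) glance(x$fit)

#' Factor scores from a fitted model
#'
#' Regression (Thomson) factor scores: the conditional expectation of the
#' latent variable given each subject's observed variables,
#' `E[eta | y_o] = C[eta, o] Sigma[o, o]^-1 (y_o - mu_o)`, evaluated per
#' missingness pattern. Scores have mean ~0 and, by construction of the
#' regression method, a standard deviation below the latent SD (shrinkage).
#'
#' @param fit A `gsem_fit` (single group).
#' @param data Data with the fit's observed variables.
#' @param latent Latent variable name.
#' @return Numeric vector of scores (NA when no indicator is observed).
#' @export
factor_scores <- function(fit, data, latent) {
  stopifnot(inherits(fit, "gsem_fit"), length(fit$group_names) == 1)
  model <- fit$model
  li <- match(latent, model$all)
  if (is.na(li)) stop("unknown latent variable: ", latent, call. = FALSE)
  X <- as.matrix(data[, model$observed, drop = FALSE])
  for (j in seq_len(ncol(X))) {
    sc <- fit$scaling[[model$observed[j]]]
    X[, j] <- (X[, j] - sc$mean) / sc$sd
  }
  mom <- group_moments(fit, 1)
  C <- symm(mom$C)
  obs_idx <- match(model$observed, model$all)
  mu <- mom$mu
  scores <- rep(NA_real_, nrow(X))
  obs <- !is.na(X)
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- which(obs[rows[1], ])
    if (!length(o)) next
    Soo_inv <- chol_info(C[obs_idx[o], obs_idx[o], drop = FALSE])$inv
    w <- drop(C[li, obs_idx[o]] %*% Soo_inv)
    scores[rows] <- sweep(X[rows, o, drop = FALSE], 2, mu[o]) %*% w
  }
  scores
}

#' Derive general factors of white-matter FA and MD
#'
#' Fits a one-factor FIML CFA over the 27 tract-averaged fractional
#' anisotropy values (and separately mean diffusivity), then attaches
#' per-subject regression-method factor scores as `gfa` and `gmd` columns.
#' Scores are centred at 0 with SD below 1 (regression-method shrinkage).
#'
#' @param cohort Cohort tibble with the `fa_*`/`md_*` tract columns.
#' @param tracts Optional character subset of tract stems to use.
#' @return The cohort with `gfa` and `gmd` columns added; the two
#'   `gsem_fit`s are attached as attributes `gfa_fit`, `gmd_fit`.
#' @export
derive_gfa_gmd <- function(cohort, tracts = NULL) {
  grp <- cohort_variable_groups()
  for (modality in c("fa", "md")) {
    cols <- intersect(grp[[modality]], names(cohort))
    if (!is.null(tracts)) {
      cols <- cols[sub("^(fa|md)_", "", cols) %in% tracts]
    }
    if (length(cols) < 3) {
      stop("too few ", toupper(modality), " tract columns present",
           call. = FALSE)
    }
    keep <- rowSums(!is.na(cohort[, cols])) >= 1
    syn <- paste0("wmf =~ ", paste(cols, collapse = " + "))
    fit <- tryCatch(
      fit_model(syn, cohort[keep, , drop = FALSE], se = FALSE,
                baseline = FALSE),
      error = function(e) stop("general-factor CFA failed for ",
                               toupper(modality), ": ", conditionMessage(e),
                               call. = FALSE))
    sc <- rep(NA_real_, nrow(cohort))
    sc[keep] <- factor_scores(fit, cohort[keep, , drop = FALSE], "wmf")
    # orient so the factor correlates positively with the mean tract value
    mt <- rowMeans(cohort[, cols], na.rm = TRUE)
    if (stats::cor(sc, mt, use = "complete.obs") < 0) sc <- -sc
    col <- paste0("g", modality)
    cohort[[col]] <- sc
    attr(cohort, paste0(col, "_fit")) <- fit
  }
  cohort
}
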