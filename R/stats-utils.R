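#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR-adjusted q-values for a family of p-values (a thin wrapper
#' over [stats::p.adjust()] with `method = "BH"`, kept as a named operation
#' so that every test family in the pipeline is adjusted the same way).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\]; `NA`s are
#'   propagated.
#' @return Vector of q-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.05))
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Tucker congruence coefficient
#'
#' Cosine similarity between two factor-loading vectors:
#' `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`. Values above 0.90 are
#' conventionally read as an extremely high similarity of factor
#' solutions.
#'
#' @param x,y Numeric loading vectors of equal length, neither all-zero.
#' @return The congruence coefficient (scalar in \[-1, 1\]).
#' @export
#' @examples
#' congruence(c(0.506, 0.539, 0.614, -0.719), c(0.522, 0.492, 0.569, -0.701))
congruence <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) stop("zero vector has no direction", call. = FALSE)
  sum(x * y) / sqrt(nx * ny)
}

#' First unrotated principal component
#'
#' First eigenvector of the complete-case correlation matrix, with the sign
#' fixed so that the majority of loadings are positive, plus the proportion
#' of total variance it explains (`lambda_1 / p`).
#'
#' @param data Data frame or matrix of numeric variables.
#' @return List with `loadings` (named) and `variance_proportion`.
#' @export
pca_first_component <- function(data) {
  X <- as.matrix(data)
  cc <- complete.cases(X)
  if (sum(cc) < 2) stop("need at least 2 complete cases", call. = FALSE)
  R <- stats::cor(X[cc, , drop = FALSE])
  eg <- eigen(R, symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (sum(v > 0) < sum(v < 0)) v <- -v
  # scale eigenvector to component loadings (correlations with the PC)
  loadings <- v * sqrt(eg$values[1])
  names(loadings) <- colnames(X)
  list(loadings = loadings, variance_proportion = eg$values[1] / ncol(X))
}

#' Variance explained by a factor
#'
#' Mean of the squared standardized loadings: the proportion of indicator
#' variance accounted for by the factor when indicators have unit
#' (conditional) variance.
#'
#' @param loadings Standardized loading vector.
#' @return Proportion in \[0, 1\].
#' @export
#' @examples
#' variance_explained(c(0.550, 0.626, 0.532, -0.794))  # ~0.40
variance_explained <- function(loadings) {
  if (!length(loadings)) stop("empty loading vector", call. = FALSE)
  mean(loadings^2)
}
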