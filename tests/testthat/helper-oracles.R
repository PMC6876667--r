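# Independent oracles used across the suite. These deliberately avoid the
# package's own RAM/likelihood code paths.

# Model-implied correlation between two generated cohort variables, from
# population-spec parameters by direct covariance algebra:
# y = c'z + s * (b g + l f + u), with z standardized covariates, f shared
# factors (corr matrix Rf), so
# cov(y1, y2) = c1'c2 + s1 s2 (b1 b2 + l1' Rf l2 [+ rescov]).
oracle_cov <- function(c1, c2, s1, s2, b1, b2, l1 = 0, l2 = 0, rf = 1,
                       rescov = 0) {
  sum(c1 * c2) + s1 * s2 * (b1 * b2 + drop(t(l1) %*% rf %*% l2) + rescov)
}

scale_factor <- function(eff) sqrt(1 - sum(eff^2))

# brute-force Benjamini-Hochberg step-up (literal definition)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  q[o] <- rev(cummin(rev(ranked)))
  pmin(q, 1)
}

# tetrad closed form for a 3-indicator one-factor model
tetrad_loadings <- function(s12, s13, s23) {
  c(sqrt(s12 * s13 / s23), sqrt(s12 * s23 / s13), sqrt(s13 * s23 / s12))
}

# data matrix with exact sample correlation matrix R (n > ncol)
exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z)))   # exactly identity covariance
  X <- Z %*% chol(R)
  colnames(X) <- paste0("y", seq_len(p))
  as.data.frame(X)
}

# complete-data normal-theory ML discrepancy fit for a CFA, by direct
# optimisation of F = log|Sigma| + tr(S Sigma^-1) over (lambda, theta);
# sample moments use the ML (n) denominator. Independent of the package's
# FIML path.
complete_ml_cfa <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n
  fml <- function(par) {
    lam <- par[1:p]; th <- par[(p + 1):(2 * p)]
    Sig <- tcrossprod(lam) + diag(th)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S)
  }
  opt <- stats::optim(c(rep(0.5, p), rep(0.5, p)), fml, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  lam <- opt$par[1:p]
  if (sum(lam) < 0) lam <- -lam
  list(lambda = lam, theta = opt$par[(p + 1):(2 * p)],
       mu = colMeans(X))
}

default_tests <- c("matrix_reasoning", "symbol_digit", "vnr", "tmtb_time")

small_cohort <- function(n = 3000, seed = 1, ...) {
  generate_cohort(default_population_spec(n = n, ...), seed = seed)
}
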