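`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom stats setNames rnorm runif pchisq pnorm qnorm sd var cov cor
#'   complete.cases optimise nlminb p.adjust quantile median
#' @importFrom rlang .data
NULL

# Symmetrise a matrix that should be symmetric up to numerical noise.
symm <- function(m) (m + t(m)) / 2

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(symm(m), symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

# log-determinant and inverse via Cholesky; returns NULL if not PD
chol_info <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  list(logdet = 2 * sum(log(diag(ch))), inv = chol2inv(ch))
}

# z-scoring helper returning the scaled vector plus the constants used
scale_info <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1
  list(z = (x - mu) / s, mean = mu, sd = s)
}

# deterministic child seeds (kept below 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

assert_columns <- function(data, cols, where = "input") {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 where, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
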