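#' Model-implied moments
#'
#' Computes the model-implied covariance matrix and mean vector of the
#' observed variables from a parameter vector, by the structural
#' composition `Sigma = F (I-A)^-1 S (I-A)^-T F'`, `mu = F (I-A)^-1 m`.
#'
#' @param model A `gsem_model`.
#' @param theta Named (or positional) vector of free-parameter values in
#'   the order of `compile_free_labels(model)`.
#' @return A list with `Sigma` (dimnamed covariance) and `mu`.
#' @export
implied_moments <- function(model, theta) {
  ptab <- model$ptab
  ptab$group <- 1L
  comp <- compile_ptab(ptab)
  theta <- align_theta(theta, comp)
  nall <- length(model$all)
  obs_idx <- match(model$observed, model$all)
  mats <- build_group_matrices(comp$ptab, theta, nall)
  mom <- ram_moments(mats, obs_idx)
  if (is.null(mom)) stop("singular (I - A): non-recursive misspecification",
                         call. = FALSE)
  Sigma <- symm(mom$Sigma)
  dimnames(Sigma) <- list(model$observed, model$observed)
  list(Sigma = Sigma, mu = setNames(mom$mu, model$observed))
}

#' Free-parameter labels of a model
#' @param model A `gsem_model`.
#' @return Character vector of unique free-parameter labels, in order.
#' @export
compile_free_labels <- function(model) {
  unique(model$ptab$label[model$ptab$free])
}

align_theta <- function(theta, comp) {
  if (!is.null(names(theta)) && all(comp$labels %in% names(theta))) {
    unname(theta[comp$labels])
  } else if (length(theta) == comp$k) {
    unname(theta)
  } else {
    stop("theta must be a vector of length ", comp$k,
         " or named with all free-parameter labels", call. = FALSE)
  }
}

#' FIML log-likelihood at a given parameter vector
#'
#' Evaluates the casewise full-information maximum-likelihood
#' log-likelihood: each subject contributes the multivariate-normal
#' log-density of their observed subvector, with subjects grouped by
#' missingness pattern (identical to per-subject evaluation).
#'
#' @inheritParams implied_moments
#' @param data A data frame containing the model's observed variables
#'   (used as-is: no internal rescaling).
#' @return The log-likelihood (scalar).
#' @export
fiml_loglik <- function(model, theta, data) {
  assert_columns(data, model$observed, "data")
  mom <- implied_moments(model, theta)
  X <- as.matrix(data[, model$observed, drop = FALSE])
  pats <- pattern_stats(X)
  res <- pattern_loglik(pats, mom$Sigma, mom$mu)
  if (is.null(res)) {
    stop("non-positive-definite implied covariance for a missingness pattern",
         call. = FALSE)
  }
  res$ll
}

#' Fit a structural-equation model by FIML
#'
#' Estimates a [build_model()] specification by full-information maximum
#' likelihood using all partially observed records, with optional multiple
#' groups and cross-group equality constraints. All observed variables are
#' internally z-scored (pooled over groups) for numerical stability;
#' reported estimates are on that internal metric, while the standardized
#' solutions (`std` = covariate-adjusted metric, `std_all` = total-variance
#' metric) are scale-free. Standard errors come from the observed
#' information (central finite differences of the analytic gradient);
#' standardized-solution standard errors by the delta method.
#'
#' Identification fixes every latent (residual) variance to 1 in group 1.
#' Under `group_equal = "loadings"` the latent variances of groups 2+ are
#' freed; under `"intercepts"` their latent means are freed, following the
#' usual measurement-invariance conventions.
#'
#' @param model A `gsem_model` or a model-syntax string.
#' @param data Data frame with the observed variables.
#' @param group Optional name of a grouping column (or a vector of group
#'   labels, one per row).
#' @param group_equal Character vector of parameter classes constrained
#'   equal across groups: any of `"loadings"`, `"intercepts"`,
#'   `"regressions"` (non-covariate directed paths), `"rescov"` (residual
#'   covariances), `"residuals"`.
#' @param covariates Covariate names (used when `model` is a syntax
#'   string).
#' @param se,baseline Logical: compute standard errors / fit the
#'   independence baseline model (needed for CFI/TLI).
#' @param control List of optimizer settings passed to [stats::nlminb()].
#' @return A `gsem_fit` object; see [tidy.gsem_fit()] and
#'   [glance.gsem_fit()].
#' @export
fit_model <- function(model, data, group = NULL,
                      group_equal = character(), covariates = character(),
                      se = TRUE, baseline = TRUE, control = list()) {
  if (is.character(model)) model <- build_model(model, covariates = covariates)
  assert_columns(data, model$observed, "data")

  # grouping
  if (is.null(group)) {
    glab <- factor(rep("all", nrow(data)))
  } else if (is.character(group) && length(group) == 1 && group %in% names(data)) {
    glab <- factor(data[[group]])
  } else {
    stopifnot(length(group) == nrow(data))
    glab <- factor(group)
  }
  gnames <- levels(glab)
  ngroups <- length(gnames)

  # pooled z-scoring
  X <- as.matrix(data[, model$observed, drop = FALSE])
  storage.mode(X) <- "double"
  scaling <- lapply(seq_len(ncol(X)), function(j) scale_info(X[, j]))
  names(scaling) <- model$observed
  for (j in seq_len(ncol(X))) X[, j] <- scaling[[j]]$z

  keep <- rowSums(!is.na(X)) > 0
  if (!all(keep)) {
    X <- X[keep, , drop = FALSE]
    glab <- glab[keep]
  }

  groups <- lapply(gnames, function(g) {
    pats <- pattern_stats(X[glab == g, , drop = FALSE])
    if (attr(pats, "n") < 1) stop("empty group: ", g, call. = FALSE)
    list(name = g, pats = pats, n = attr(pats, "n"),
         n_complete = attr(pats, "n_complete"),
         n_patterns = length(pats))
  })

  ptab <- expand_ptab(model, ngroups, gnames, group_equal)
  comp <- compile_ptab(ptab)
  nall <- length(model$all)
  obs_idx <- match(model$observed, model$all)
  objfun <- make_objective(comp, groups, nall, obs_idx)

  ctrl <- utils::modifyList(
    list(iter.max = 2000L, eval.max = 4000L, rel.tol = 1e-10), control)
  opt <- nlminb(comp$start,
                function(th) objfun(th, want_grad = FALSE)$obj,
                gradient = function(th) objfun(th)$grad,
                control = ctrl)
  theta <- opt$par
  theta <- fix_latent_sign(theta, comp, model)
  final <- objfun(theta)
  loglik <- -final$obj
  grad_norm <- max(abs(final$grad))
  converged <- opt$convergence == 0 || grad_norm < 1e-3

  # saturated model via EM, per group
  sat <- lapply(groups, function(g) em_saturated(g$pats, ncol(X)))
  ll_sat <- sum(vapply(sat, `[[`, numeric(1), "loglik"))
  chisq <- max(2 * (ll_sat - loglik), 0)
  p <- length(model$observed)
  n_moments <- ngroups * p * (p + 3) / 2
  df <- n_moments - comp$k
  N <- sum(vapply(groups, `[[`, numeric(1), "n"))

  warnings <- character()
  resvar_rows <- comp$ptab$class == "resvar" & comp$ptab$free
  if (any(resvar_rows)) {
    rv <- theta[comp$ptab$theta_idx[resvar_rows]]
    if (any(rv < 0)) {
      warnings <- c(warnings, sprintf(
        "Heywood case: %d negative residual variance(s)", sum(rv < 0)))
    }
  }
  if (!converged) {
    warnings <- c(warnings, sprintf(
      "possible non-convergence: nlminb code %d, |grad| = %.2e (%d iterations)",
      opt$convergence, grad_norm, opt$iterations))
  }

  # standard errors from observed information
  V <- NULL
  se_vec <- rep(NA_real_, comp$k)
  if (se) {
    H <- fd_hessian(function(th) objfun(th)$grad, theta)
    V <- safe_inverse(H)
    se_vec <- sqrt(pmax(diag(V), 0))
  }

  fit <- structure(list(
    model = model, comp = comp, groups = groups, group_names = gnames,
    group_equal = group_equal, theta = setNames(theta, comp$labels),
    vcov = V, se = setNames(se_vec, comp$labels),
    loglik = loglik, loglik_sat = ll_sat, chisq = chisq, df = df,
    n_moments = n_moments, n_free = comp$k, n = N,
    n_per_group = vapply(groups, `[[`, numeric(1), "n"),
    n_complete = sum(vapply(groups, `[[`, numeric(1), "n_complete")),
    n_patterns = sum(vapply(groups, `[[`, numeric(1), "n_patterns")),
    sat = sat, scaling = scaling, converged = converged,
    grad_norm = grad_norm, warnings = warnings,
    meta = list(rmsea_divisor = "N", sabic_constant = "k*log((N+2)/24)",
                srmr = "covariance-only, off-diagonal",
                identification = "latent (residual) variance fixed to 1",
                standardization = "nox (net of declared covariates) + all")
  ), class = "gsem_fit")

  fit$std <- std_solution(fit)
  if (baseline) {
    fit$baseline <- fit_baseline(fit)
    fit$indices <- fit_index_values(
      chisq = fit$chisq, df = fit$df,
      baseline_chisq = fit$baseline$chisq, baseline_df = fit$baseline$df,
      n = N, loglik = loglik, n_free = comp$k,
      srmr = srmr_value(fit))
  } else {
    fit$indices <- fit_index_values(
      chisq = fit$chisq, df = fit$df, baseline_chisq = NA_real_,
      baseline_df = NA_real_, n = N, loglik = loglik, n_free = comp$k,
      srmr = srmr_value(fit))
  }
  for (w in warnings) warning(w, call. = FALSE)
  fit
}

# multi-group parameter-table expansion with equality constraints
expand_ptab <- function(model, ngroups, gnames, group_equal) {
  base <- model$ptab
  shared_class <- c(
    if ("loadings" %in% group_equal) "loading",
    if ("intercepts" %in% group_equal) "intercept",
    if ("regressions" %in% group_equal) "regression",
    if ("rescov" %in% group_equal) "rescov",
    if ("residuals" %in% group_equal) "resvar")
  out <- vector("list", ngroups)
  for (g in seq_len(ngroups)) {
    pg <- base
    pg$group <- g
    if (g > 1) {
      loc <- !(pg$class %in% shared_class)
      pg$label[loc] <- paste0(pg$label[loc], "|", gnames[g])
      if ("loadings" %in% group_equal) {
        lv <- pg$class == "latvar"
        pg$free[lv] <- TRUE
        pg$value[lv] <- 1
      }
      if ("intercepts" %in% group_equal) {
        lm <- pg$class == "latmean"
        pg$free[lm] <- TRUE
        pg$value[lm] <- 0
      }
    }
    out[[g]] <- pg
  }
  dplyr::bind_rows(out)
}

# resolve factor sign indeterminacy: flip each latent so the sum of its
# loadings is positive (applied consistently across groups)
fix_latent_sign <- function(theta, comp, model) {
  ptab <- comp$ptab
  for (lat in model$latents) {
    li <- match(lat, model$all)
    load_rows <- ptab$matrix == "A" & ptab$col == li & ptab$free &
      ptab$class == "loading" & ptab$group == 1
    if (!any(load_rows)) next
    s <- sum(theta[ptab$theta_idx[load_rows]])
    if (s >= 0) next
    flip <- (ptab$matrix == "A" & (ptab$col == li | ptab$row == li)) |
      (ptab$matrix == "S" & xor(ptab$row == li, ptab$col == li)) |
      (ptab$matrix == "M" & ptab$row == li)
    idx <- unique(ptab$theta_idx[flip & ptab$free])
    idx <- idx[!is.na(idx)]
    theta[idx] <- -theta[idx]
  }
  theta
}

fd_hessian <- function(gradfun, theta, h_rel = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- h_rel * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (gradfun(tp) - gradfun(tm)) / (2 * h)
  }
  symm(H)
}

safe_inverse <- function(H) {
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(out)) return(out)
  eg <- eigen(symm(H), symmetric = TRUE)
  d <- eg$values
  d[d < 1e-10] <- Inf
  eg$vectors %*% diag(1 / d, length(d)) %*% t(eg$vectors)
}

# --- standardized solutions -------------------------------------------------

# per-group implied moments at the fitted parameters
group_moments <- function(fit, g) {
  ptab <- fit$comp$ptab
  pg <- ptab[ptab$group == g, , drop = FALSE]
  nall <- length(fit$model$all)
  obs_idx <- match(fit$model$observed, fit$model$all)
  mats <- build_group_matrices(pg, unname(fit$theta), nall)
  mom <- ram_moments(mats, obs_idx)
  c(mom, list(mats = mats, pg = pg))
}

# standard deviations used for standardization, per metric
std_sds <- function(fit, mom) {
  all_vars <- fit$model$all
  C <- symm(mom$C)
  sd_all <- sqrt(pmax(diag(C), 1e-12))
  covs <- intersect(fit$model$covariates, all_vars)
  sd_nox <- sd_all
  if (length(covs)) {
    xi <- match(covs, all_vars)
    yi <- setdiff(seq_along(all_vars), xi)
    Cxx_inv <- chol_info(C[xi, xi, drop = FALSE])$inv
    Ccond <- C[yi, yi, drop = FALSE] -
      C[yi, xi, drop = FALSE] %*% Cxx_inv %*% C[xi, yi, drop = FALSE]
    sd_nox[yi] <- sqrt(pmax(diag(Ccond), 1e-12))
  }
  list(all = sd_all, nox = sd_nox)
}

std_from_theta <- function(fit, theta) {
  ptab <- fit$comp$ptab
  nall <- length(fit$model$all)
  obs_idx <- match(fit$model$observed, fit$model$all)
  out_nox <- numeric(nrow(ptab))
  out_all <- numeric(nrow(ptab))
  for (g in seq_along(fit$group_names)) {
    rows <- which(ptab$group == g)
    pg <- ptab[rows, , drop = FALSE]
    mats <- build_group_matrices(pg, theta, nall)
    mom <- ram_moments(mats, obs_idx)
    sds <- std_sds(fit, mom)
    val <- ifelse(pg$free, theta[pg$theta_idx], pg$value)
    for (metric in c("nox", "all")) {
      sdv <- sds[[metric]]
      sv <- numeric(length(val))
      isA <- pg$matrix == "A"
      isS <- pg$matrix == "S"
      isM <- pg$matrix == "M"
      sv[isA] <- val[isA] * sdv[pg$col[isA]] / sdv[pg$row[isA]]
      sv[isS] <- val[isS] / (sdv[pg$row[isS]] * sdv[pg$col[isS]])
      sv[isM] <- val[isM] / sdv[pg$row[isM]]
      if (metric == "nox") out_nox[rows] <- sv else out_all[rows] <- sv
    }
  }
  list(nox = out_nox, all = out_all)
}

std_solution <- function(fit) {
  base <- std_from_theta(fit, unname(fit$theta))
  std_se <- rep(NA_real_, nrow(fit$comp$ptab))
  if (!is.null(fit$vcov)) {
    k <- length(fit$theta)
    J <- matrix(0, nrow(fit$comp$ptab), k)
    th <- unname(fit$theta)
    for (j in seq_len(k)) {
      h <- 1e-5 * max(1, abs(th[j]))
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      J[, j] <- (std_from_theta(fit, tp)$nox - std_from_theta(fit, tm)$nox) /
        (2 * h)
    }
    v <- rowSums((J %*% fit$vcov) * J)
    std_se <- sqrt(pmax(v, 0))
  }
  tibble::tibble(std_nox = base$nox, std_all = base$all, std_se = std_se)
}

srmr_value <- function(fit) {
  total <- 0
  wsum <- 0
  for (g in seq_along(fit$group_names)) {
    mom <- group_moments(fit, g)
    Simp <- symm(mom$Sigma)
    Sobs <- fit$sat[[g]]$Sigma
    di <- sqrt(diag(Sobs))
    dj <- sqrt(diag(Simp))
    p <- nrow(Sobs)
    resid <- Sobs / tcrossprod(di) - Simp / tcrossprod(dj)
    off <- resid[lower.tri(resid)]
    total <- total + fit$groups[[g]]$n * mean(off^2)
    wsum <- wsum + fit$groups[[g]]$n
  }
  sqrt(total / wsum)
}

# independence baseline: endogenous variables keep covariate regressions,
# intercepts and variances; all latent structure and residual covariances
# dropped
fit_baseline <- function(fit) {
  ptab <- fit$comp$ptab
  drop_class <- c("loading", "regression", "rescov")
  bp <- ptab
  kill <- bp$class %in% drop_class
  bp$free[kill] <- FALSE
  bp$value[kill] <- 0
  comp <- compile_ptab(bp)
  nall <- length(fit$model$all)
  obs_idx <- match(fit$model$observed, fit$model$all)
  objfun <- make_objective(comp, fit$groups, nall, obs_idx)
  opt <- nlminb(comp$start,
                function(th) objfun(th, want_grad = FALSE)$obj,
                gradient = function(th) objfun(th)$grad,
                control = list(iter.max = 1000L, rel.tol = 1e-10))
  ll <- -opt$objective
  chisq <- max(2 * (fit$loglik_sat - ll), 0)
  df <- fit$n_moments - comp$k
  list(loglik = ll, chisq = chisq, df = df, n_free = comp$k)
}
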