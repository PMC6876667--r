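# ---------------------------------------------------------------------------
# FIML covariance-structure engine.
#
# Models are held in RAM form over v = (observed, latent): directed paths A
# (A[i, j] is the path j -> i), symmetric (co)variances S, means/intercepts m.
# With E = (I - A)^-1 and F the observed-row selector,
#   Sigma = F E S E' F',   mu = F E m.
# The FIML log-likelihood is evaluated from missingness-pattern sufficient
# statistics (count, mean, ML covariance per pattern), so its cost does not
# grow with n; the analytic gradient is assembled from the pattern-weighted
# derivative matrices, so its cost does not grow with the parameter count
# beyond one O(p^2) contraction.
# ---------------------------------------------------------------------------

# --- pattern sufficient statistics -----------------------------------------

pattern_stats <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1, function(r) paste(which(r), collapse = ","))
  split_idx <- split(seq_len(nrow(X)), key)
  pats <- lapply(split_idx, function(rows) {
    o <- which(obs[rows[1], ])
    Xo <- X[rows, o, drop = FALSE]
    n <- length(rows)
    xbar <- colMeans(Xo)
    Xc <- sweep(Xo, 2, xbar)
    S <- crossprod(Xc) / n            # ML (n) denominator
    list(o = o, n = n, xbar = xbar, S = S)
  })
  names(pats) <- NULL
  attr(pats, "n") <- nrow(X)
  attr(pats, "n_complete") <- sum(rowSums(obs) == ncol(X))
  pats
}

# log-likelihood (and Sigma/mu-space weights) for one group given (Sigma, mu)
pattern_loglik <- function(pats, Sigma, mu, want_weights = FALSE) {
  p <- nrow(Sigma)
  ll <- 0
  G <- if (want_weights) matrix(0, p, p)
  gmu <- if (want_weights) numeric(p)
  for (pt in pats) {
    o <- pt$o
    So <- Sigma[o, o, drop = FALSE]
    ci <- chol_info(So)
    if (is.null(ci)) return(NULL)
    d <- pt$xbar - mu[o]
    Sinv <- ci$inv
    k <- length(o)
    quad <- sum(Sinv * pt$S) + drop(crossprod(d, Sinv %*% d))
    ll <- ll - pt$n / 2 * (k * log(2 * pi) + ci$logdet + quad)
    if (want_weights) {
      Did <- Sinv %*% d
      W <- pt$n / 2 * (Sinv %*% (pt$S + tcrossprod(d)) %*% Sinv - Sinv)
      G[o, o] <- G[o, o] + W
      gmu[o] <- gmu[o] + pt$n * Did
    }
  }
  list(ll = ll, G = G, gmu = gmu)
}

# --- parameter table machinery ---------------------------------------------

# Compile a (possibly multi-group) parameter table into fast index lists.
# ptab has columns matrix,row,col,class,free,value,label,group.
compile_ptab <- function(ptab) {
  labels <- unique(ptab$label[ptab$free])
  ptab$theta_idx <- ifelse(ptab$free, match(ptab$label, labels), NA_integer_)
  start <- vapply(labels, function(l) ptab$value[ptab$label == l][1], numeric(1))
  list(ptab = ptab, labels = labels, start = unname(start), k = length(labels))
}

build_group_matrices <- function(ptab_g, theta, nall) {
  A <- matrix(0, nall, nall)
  S <- matrix(0, nall, nall)
  m <- numeric(nall)
  val <- ifelse(ptab_g$free, theta[ptab_g$theta_idx], ptab_g$value)
  isA <- ptab_g$matrix == "A"
  isS <- ptab_g$matrix == "S"
  isM <- ptab_g$matrix == "M"
  A[cbind(ptab_g$row[isA], ptab_g$col[isA])] <- val[isA]
  S[cbind(ptab_g$row[isS], ptab_g$col[isS])] <- val[isS]
  S[cbind(ptab_g$col[isS], ptab_g$row[isS])] <- val[isS]
  m[ptab_g$row[isM]] <- val[isM]
  list(A = A, S = S, m = m)
}

ram_moments <- function(mats, obs_idx) {
  nall <- nrow(mats$A)
  E <- tryCatch(solve(diag(nall) - mats$A), error = function(e) NULL)
  if (is.null(E)) return(NULL)
  C <- E %*% mats$S %*% t(E)
  list(E = E, C = C,
       Sigma = C[obs_idx, obs_idx, drop = FALSE],
       Em = drop(E %*% mats$m),
       mu = drop(E %*% mats$m)[obs_idx])
}

# objective (-loglik) and analytic gradient over all groups
make_objective <- function(compiled, groups, nall, obs_idx) {
  ptab <- compiled$ptab
  k <- compiled$k
  by_group <- split(seq_len(nrow(ptab)), ptab$group)
  penalty <- 1e10

  eval_fun <- function(theta, want_grad = TRUE) {
    ll <- 0
    grad <- numeric(k)
    for (gi in seq_along(groups)) {
      pg <- ptab[by_group[[as.character(gi)]], , drop = FALSE]
      mats <- build_group_matrices(pg, theta, nall)
      mom <- ram_moments(mats, obs_idx)
      if (is.null(mom)) return(list(obj = penalty, grad = numeric(k)))
      res <- pattern_loglik(groups[[gi]]$pats, mom$Sigma, mom$mu,
                            want_weights = want_grad)
      if (is.null(res)) return(list(obj = penalty, grad = numeric(k)))
      ll <- ll + res$ll
      if (want_grad) {
        P <- mom$E[obs_idx, , drop = FALSE]   # p x nall
        T1 <- crossprod(P, res$G %*% P)       # dl/dS contractions
        # dl/dA_ij = 2 * (P' G R')_{ij} + pm_i * Em_j, with R = C[, obs]
        R <- mom$C[, obs_idx, drop = FALSE]   # nall x p
        K_A <- 2 * crossprod(P, res$G %*% t(R))
        pm <- drop(crossprod(P, res$gmu))
        fr <- pg$free
        if (any(fr)) {
          pf <- pg[fr, , drop = FALSE]
          v <- numeric(nrow(pf))
          isA <- pf$matrix == "A"
          isS <- pf$matrix == "S"
          isM <- pf$matrix == "M"
          if (any(isA)) {
            v[isA] <- K_A[cbind(pf$row[isA], pf$col[isA])] +
              pm[pf$row[isA]] * mom$Em[pf$col[isA]]
          }
          if (any(isS)) {
            iS <- pf$row[isS]; jS <- pf$col[isS]
            diagS <- iS == jS
            vs <- T1[cbind(iS, jS)] + T1[cbind(jS, iS)]
            vs[diagS] <- T1[cbind(iS, jS)][diagS]
            v[isS] <- vs
          }
          if (any(isM)) v[isM] <- pm[pf$row[isM]]
          agg <- rowsum(v, pf$theta_idx)
          ti <- as.integer(rownames(agg))
          grad[ti] <- grad[ti] + agg[, 1]
        }
      }
    }
    list(obj = -ll, grad = -grad)
  }
  eval_fun
}

# --- EM for the saturated (unstructured) model ------------------------------

em_saturated <- function(pats, p, max_iter = 500, tol = 1e-10) {
  N <- sum(vapply(pats, `[[`, numeric(1), "n"))
  # initialise from available-case moments
  T1 <- numeric(p); T0 <- numeric(p)
  for (pt in pats) {
    T1[pt$o] <- T1[pt$o] + pt$n * pt$xbar
    T0[pt$o] <- T0[pt$o] + pt$n
  }
  mu <- ifelse(T0 > 0, T1 / pmax(T0, 1), 0)
  Sg <- matrix(0, p, p)
  W0 <- matrix(0, p, p)
  for (pt in pats) {
    Sg[pt$o, pt$o] <- Sg[pt$o, pt$o] +
      pt$n * (pt$S + tcrossprod(pt$xbar - mu[pt$o]))
    W0[pt$o, pt$o] <- W0[pt$o, pt$o] + pt$n
  }
  Sg <- symm(Sg / pmax(W0, 1))
  diag(Sg)[diag(W0) == 0] <- 1
  ev_min <- min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-6) Sg <- Sg + diag(p) * (1e-6 - ev_min + 0.01)

  complete <- length(pats) == 1 && length(pats[[1]]$o) == p
  if (complete) {
    mu <- pats[[1]]$xbar
    Sg <- symm(pats[[1]]$S)
    res <- pattern_loglik(pats, Sg, mu)
    if (is.null(res)) {
      # singular sample covariance (collinear variables): minimal ridge so
      # the saturated reference is defined
      warning("singular sample covariance; saturated model ridged",
              call. = FALSE)
      ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
      Sg <- Sg + diag(p) * (abs(min(ev)) + 1e-8)
      res <- pattern_loglik(pats, Sg, mu)
    }
    return(list(mu = mu, Sigma = Sg, loglik = res$ll, iterations = 0L,
                converged = TRUE))
  }

  ll_old <- -Inf
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    res <- pattern_loglik(pats, Sg, mu)
    if (is.null(res)) { Sg <- Sg + diag(p) * 1e-4; next }
    ll <- res$ll
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pt in pats) {
      o <- pt$o
      mi <- setdiff(seq_len(p), o)
      n <- pt$n
      if (!length(mi)) {
        T1[o] <- T1[o] + n * pt$xbar
        T2[o, o] <- T2[o, o] + n * (pt$S + tcrossprod(pt$xbar))
        next
      }
      Soo_inv <- chol_info(Sg[o, o, drop = FALSE])$inv
      B <- Sg[mi, o, drop = FALSE] %*% Soo_inv
      d <- pt$xbar - mu[o]
      mm <- mu[mi] + drop(B %*% d)
      Cc <- Sg[mi, mi, drop = FALSE] - B %*% Sg[o, mi, drop = FALSE]
      T1[o] <- T1[o] + n * pt$xbar
      T1[mi] <- T1[mi] + n * mm
      T2[o, o] <- T2[o, o] + n * (pt$S + tcrossprod(pt$xbar))
      Tmo <- n * (tcrossprod(mm, pt$xbar) + B %*% pt$S)
      T2[mi, o] <- T2[mi, o] + Tmo
      T2[o, mi] <- T2[o, mi] + t(Tmo)
      T2[mi, mi] <- T2[mi, mi] +
        n * (Cc + tcrossprod(mm) + B %*% pt$S %*% t(B))
    }
    mu_new <- T1 / N
    Sg_new <- symm(T2 / N - tcrossprod(mu_new))
    if (!is_psd(Sg_new)) Sg_new <- Sg_new + diag(p) * 1e-8
    mu <- mu_new
    Sg <- Sg_new
  }
  list(mu = mu, Sigma = Sg, loglik = ll, iterations = it, converged = it < max_iter)
}
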