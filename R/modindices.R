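#' Modification indices for fixed residual covariances
#'
#' Univariate score (Lagrange-multiplier) tests for parameters currently
#' fixed at zero: for each candidate, the expected chi-square drop (1 df)
#' from freeing it, plus the expected parameter change (EPC). By default
#' the candidate set is all residual covariances among endogenous observed
#' variables that are not already free.
#'
#' The score for every candidate comes from the analytic gradient of the
#' FIML log-likelihood at the fitted solution; the curvature term is the
#' observed information of the extended parameter vector (finite
#' differences of the analytic gradient), computed once for all candidates.
#'
#' @param fit A converged `gsem_fit`.
#' @param candidates `"resid_cov"` (default) or a two-column matrix /
#'   data frame of variable-name pairs.
#' @return A tibble sorted by decreasing `mi`: `lhs`, `rhs`, `group`,
#'   `mi`, `epc`.
#' @export
modification_indices <- function(fit, candidates = "resid_cov") {
  stopifnot(inherits(fit, "gsem_fit"))
  model <- fit$model
  ptab <- fit$comp$ptab
  all_vars <- model$all
  obs_idx <- match(model$observed, all_vars)

  if (is.character(candidates) && identical(candidates, "resid_cov")) {
    endo <- unique(ptab$lhs[ptab$class %in% c("resvar")])
    endo <- intersect(endo, model$observed)
    if (length(endo) < 2) return(empty_mi())
    cand <- t(utils::combn(endo, 2))
  } else {
    cand <- as.matrix(candidates)
  }
  # drop pairs already free (in any group)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  scov <- ptab[ptab$matrix == "S" & ptab$free, , drop = FALSE]
  have <- key(scov$lhs, scov$rhs)
  keep <- !(key(cand[, 1], cand[, 2]) %in% have)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_mi())

  ngroups <- length(fit$group_names)
  rows <- list()
  for (g in seq_len(ngroups)) {
    for (r in seq_len(nrow(cand))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        matrix = "S", row = match(cand[r, 1], all_vars),
        col = match(cand[r, 2], all_vars),
        lhs = cand[r, 1], rhs = cand[r, 2], class = "rescov",
        free = TRUE, value = 0,
        label = paste0("MI:", cand[r, 1], "~~", cand[r, 2], "|g", g),
        group = g)
    }
  }
  ext <- dplyr::bind_rows(ptab, dplyr::bind_rows(rows))
  comp_ext <- compile_ptab(ext)
  k0 <- fit$n_free
  theta_ext <- c(unname(fit$theta), rep(0, comp_ext$k - k0))
  objfun <- make_objective(comp_ext, fit$groups, length(all_vars), obs_idx)

  grad <- -objfun(theta_ext)$grad          # gradient of loglik
  H <- fd_hessian(function(th) objfun(th)$grad, theta_ext)  # info of -ll
  Htt_inv <- safe_inverse(H[seq_len(k0), seq_len(k0), drop = FALSE])

  out <- list()
  for (j in seq.int(k0 + 1, comp_ext$k)) {
    lab <- comp_ext$labels[j]
    hj <- H[j, seq_len(k0)]
    v <- H[j, j] - drop(hj %*% Htt_inv %*% hj)
    if (!is.finite(v) || v <= 1e-12) {
      warning("singular information for candidate ", lab, "; skipped",
              call. = FALSE)
      next
    }
    info <- strsplit(sub("^MI:", "", lab), "\\|g")[[1]]
    pair <- strsplit(info[1], "~~")[[1]]
    out[[length(out) + 1]] <- tibble::tibble(
      lhs = pair[1], rhs = pair[2],
      group = fit$group_names[as.integer(info[2])],
      mi = grad[j]^2 / v, epc = grad[j] / v)
  }
  dplyr::arrange(dplyr::bind_rows(out), dplyr::desc(.data$mi))
}

empty_mi <- function() {
  tibble::tibble(lhs = character(), rhs = character(), group = character(),
                 mi = numeric(), epc = numeric())
}
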