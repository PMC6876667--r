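default_mri_covariates <- function() c("head_x", "head_y", "head_z")

# assemble syntax for a brain-g structural model: g CFA (+ MR~VNR residual
# covariance), g regressed on the brain predictors, covariates applied to
# every manifest variable within the model (head position only on MRI
# variables)
brain_g_syntax <- function(brain_vars, covariates = c("age", "sex"),
                           mri_covariates = default_mri_covariates(),
                           resid_pairs = list(c("matrix_reasoning", "vnr")),
                           brain_resid_pairs = list()) {
  lines <- c(
    g_cfa_syntax(covariates, resid_pairs),
    paste0("g ~ ", paste(brain_vars, collapse = " + "))
  )
  bcov <- c(covariates, mri_covariates)
  if (length(bcov)) {
    lines <- c(lines, paste0(brain_vars, " ~ ",
                             paste(bcov, collapse = " + ")))
  }
  for (pr in brain_resid_pairs) {
    lines <- c(lines, paste0(pr[1], " ~~ ", pr[2]))
  }
  paste(lines, collapse = "\n")
}

brain_g_rows <- function(cohort, brain_vars, covariates, mri_covariates) {
  tests <- cognitive_tests()
  has_cog <- rowSums(!is.na(cohort[, tests])) >= 1
  has_brain <- rowSums(!is.na(cohort[, brain_vars, drop = FALSE])) >= 1
  cohort[has_cog & has_brain, , drop = FALSE]
}

association_row <- function(fit, brain_var, model_context, group = "all") {
  td <- tidy(fit)
  row <- td[td$class == "regression" & td$rhs == brain_var &
              td$group == group, , drop = FALSE]
  tibble::tibble(
    variable = brain_var,
    beta = row$std, se = row$std_se, p = row$p,
    model = model_context, group = group,
    n = unname(fit$n_per_group[match(group, fit$group_names)] %||% fit$n)
  )
}

#' Bivariate association between a brain measure and latent g
#'
#' Fits one SEM: the g CFA (with the Matrix-Reasoning/VNR residual
#' covariance) plus a directed path from the single brain variable to g,
#' all manifest variables covariate-adjusted within the model (head
#' position on the MRI variable only). Subjects contributing at least one
#' cognitive test and the brain measure enter the likelihood. The reported
#' `beta` is the standardized (covariate-adjusted metric) path, which for
#' this single-predictor model equals the latent correlation.
#'
#' @param cohort Cohort tibble (cleaned).
#' @param brain_var Name of the brain column.
#' @param covariates Covariates for all manifest variables.
#' @param mri_covariates Additional covariates for the MRI variable.
#' @return A one-row association tibble: `variable`, `beta`, `se`, `p`,
#'   `model`, `group`, `n`, plus the fit as attribute `"fit"`.
#' @export
bivariate_brain_g <- function(cohort, brain_var,
                              covariates = c("age", "sex"),
                              mri_covariates = default_mri_covariates()) {
  assert_columns(cohort, c(cognitive_tests(), brain_var, covariates,
                           mri_covariates), "cohort")
  dat <- brain_g_rows(cohort, brain_var, covariates, mri_covariates)
  syn <- brain_g_syntax(brain_var, covariates, mri_covariates)
  fit <- fit_model(syn, dat, covariates = c(covariates, mri_covariates))
  out <- association_row(fit, brain_var, "individual")
  attr(out, "fit") <- fit
  out
}

#' Global brain-g association scan
#'
#' Runs the six bivariate global models (TBV, GM, NAWM, WMH, gFA, gMD) and
#' applies Benjamini-Hochberg FDR across them. `gfa`/`gmd` columns are
#' derived first via [derive_gfa_gmd()] when absent.
#'
#' @inheritParams bivariate_brain_g
#' @param measures Global measures to scan.
#' @return An `association_table` tibble (one row per measure) with FDR
#'   column `q`.
#' @export
global_brain_g <- function(cohort, measures = c("tbv", "gm", "nawm", "wmh",
                                                "gfa", "gmd"),
                           covariates = c("age", "sex"),
                           mri_covariates = default_mri_covariates()) {
  if (any(c("gfa", "gmd") %in% measures) && !("gfa" %in% names(cohort))) {
    cohort <- derive_gfa_gmd(cohort)
  }
  rows <- purrr::map(measures, function(v)
    bivariate_brain_g(cohort, v, covariates, mri_covariates))
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  as_association_table(out, family = "global")
}

#' Simultaneous (MIMIC) model of g on multiple global measures
#'
#' A single SEM in which all listed brain measures simultaneously predict
#' latent g (Multiple Indicators Multiple Causes). TBV is excluded from the
#' default predictor set to avoid part-whole overlap with the
#' tissue-specific volumes. Correlated residuals among the brain predictors
#' are added from modification indices until the preregistered fit
#' thresholds are met (capped). FDR is applied across the path estimates.
#'
#' @inheritParams bivariate_brain_g
#' @param predictors Brain measures entering simultaneously.
#' @param max_added Cap on MI-driven residual covariances.
#' @return List with `fit` (`gsem_fit`), `associations`
#'   (`association_table` with `q`), `r2` (proportion of g variance
#'   explained), `pairs_added`, `thresholds_met`.
#' @export
mimic_global <- function(cohort,
                         predictors = c("gm", "nawm", "wmh", "gfa", "gmd"),
                         covariates = c("age", "sex"),
                         mri_covariates = default_mri_covariates(),
                         max_added = 10) {
  if (length(predictors) < 1) stop("need at least one predictor", call. = FALSE)
  if (any(c("gfa", "gmd") %in% predictors) && !("gfa" %in% names(cohort))) {
    cohort <- derive_gfa_gmd(cohort)
  }
  dat <- brain_g_rows(cohort, predictors, covariates, mri_covariates)
  pairs <- list()
  fit <- fit_model(brain_g_syntax(predictors, covariates, mri_covariates,
                                  brain_resid_pairs = pairs),
                   dat, covariates = c(covariates, mri_covariates))
  while (!meets_fit_thresholds(fit) && length(pairs) < max_added &&
         length(predictors) > 1) {
    mi <- modification_indices(fit)
    mi <- mi[mi$lhs %in% predictors & mi$rhs %in% predictors, , drop = FALSE]
    if (!nrow(mi)) break
    pairs <- c(pairs, list(c(mi$lhs[1], mi$rhs[1])))
    fit <- fit_model(brain_g_syntax(predictors, covariates, mri_covariates,
                                    brain_resid_pairs = pairs),
                     dat, covariates = c(covariates, mri_covariates))
  }
  rows <- dplyr::bind_rows(purrr::map(predictors, function(v)
    association_row(fit, v, "simultaneous")))
  rows$q <- bh_fdr(rows$p)
  td <- tidy(fit)
  gvar <- td[td$class == "latvar" & td$lhs == "g", , drop = FALSE]
  r2 <- 1 - gvar$std[1]
  list(fit = fit, associations = as_association_table(rows, "global_mimic"),
       r2 = r2, pairs_added = pairs,
       thresholds_met = meets_fit_thresholds(fit))
}

#' Measurement invariance of g across age or sex groups
#'
#' Compares a configural multi-group CFA of the four cognitive tests with a
#' constrained version: weak invariance constrains the loadings equal
#' across groups (freeing the group-2 latent variance), strong invariance
#' additionally constrains the intercepts (freeing the group-2 latent
#' mean). The grouping covariate is dropped from the covariate set. For
#' weak invariance the Tucker congruence between the freely estimated group
#' loading vectors is reported.
#'
#' @param cohort Cohort tibble.
#' @param grouping `"age"` (median split of the cognitive-MRI overlap; see
#'   [age_split()]) or `"sex"`.
#' @param level `"weak"` or `"strong"`.
#' @param covariates Base covariate set; the grouping variable is removed.
#' @return List with `comparison` ([compare_nested()] row), `congruence`
#'   (weak level only), `fit_free`, `fit_constrained`, `boundary` (age
#'   grouping only).
#' @export
invariance_test <- function(cohort, grouping = c("age", "sex"),
                            level = c("weak", "strong"),
                            covariates = c("age", "sex")) {
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  covariates <- setdiff(covariates, grouping)
  boundary <- NULL
  if (grouping == "age") {
    sp <- age_split(cohort)
    glab <- ifelse(cohort$age <= sp$boundary, "middle", "older")
    boundary <- sp$boundary
  } else {
    glab <- ifelse(cohort$sex == 1, "female", "male")
  }
  tests <- cognitive_tests()
  keep <- rowSums(!is.na(cohort[, tests])) >= 1
  dat <- cohort[keep, , drop = FALSE]
  glab <- glab[keep]
  syn <- g_cfa_syntax(covariates, list(c("matrix_reasoning", "vnr")))
  fit_free <- fit_model(syn, dat, group = glab, covariates = covariates)
  ge <- if (level == "weak") "loadings" else c("loadings", "intercepts")
  fit_con <- fit_model(syn, dat, group = glab, group_equal = ge,
                       covariates = covariates)
  cmp <- compare_nested(fit_free, fit_con)
  phi <- NULL
  if (level == "weak") {
    td <- tidy(fit_free)
    lo <- td[td$class == "loading", , drop = FALSE]
    gs <- unique(lo$group)
    v1 <- setNames(lo$std[lo$group == gs[1]], lo$lhs[lo$group == gs[1]])[tests]
    v2 <- setNames(lo$std[lo$group == gs[2]], lo$lhs[lo$group == gs[2]])[tests]
    phi <- congruence(v1, v2)
  }
  list(comparison = cmp, congruence = phi, fit_free = fit_free,
       fit_constrained = fit_con, boundary = boundary,
       group_loadings = if (level == "weak") list(v1, v2))
}

#' Moderation of brain-g associations by age or sex group
#'
#' Two multi-group SEMs with the group g loadings set to equality: in the
#' first the brain-g path(s) are freely estimated per group, in the second
#' they are constrained equal. The likelihood-ratio test (plus AIC/saBIC
#' differences) indexes moderation; per-group standardized paths and the
#' per-group proportion of g variance explained are reported from the free
#' model.
#'
#' @inheritParams invariance_test
#' @param brain_model `"tbv"` (single path) or `"multi"` (GM, NAWM, WMH,
#'   gFA, gMD simultaneously, with MI-driven residual covariances added up
#'   to `max_added` before the group comparison).
#' @param mri_covariates Head-position covariates for MRI variables.
#' @param max_added Respecification cap for the multi-measure model.
#' @return List with `comparison`, `associations` (per-group rows from the
#'   free model), `r2` (named per-group), `fit_free`, `fit_constrained`.
#' @export
moderation_test <- function(cohort, grouping = c("age", "sex"),
                            brain_model = c("tbv", "multi"),
                            covariates = c("age", "sex"),
                            mri_covariates = default_mri_covariates(),
                            max_added = 10) {
  grouping <- match.arg(grouping)
  brain_model <- match.arg(brain_model)
  covariates <- setdiff(covariates, grouping)
  if (grouping == "age") {
    sp <- age_split(cohort)
    glab <- ifelse(cohort$age <= sp$boundary, "middle", "older")
  } else {
    glab <- ifelse(cohort$sex == 1, "female", "male")
  }
  preds <- if (brain_model == "tbv") "tbv" else
    c("gm", "nawm", "wmh", "gfa", "gmd")
  if (any(c("gfa", "gmd") %in% preds) && !("gfa" %in% names(cohort))) {
    cohort <- derive_gfa_gmd(cohort)
  }
  dat0 <- cohort
  keep <- rowSums(!is.na(dat0[, cognitive_tests()])) >= 1 &
    rowSums(!is.na(dat0[, preds, drop = FALSE])) >= 1
  dat <- dat0[keep, , drop = FALSE]
  glab <- glab[keep]

  # residual covariances among predictors chosen on the pooled sample
  pairs <- list()
  if (length(preds) > 1) {
    pooled <- fit_model(brain_g_syntax(preds, covariates, mri_covariates),
                        dat, covariates = c(covariates, mri_covariates))
    while (!meets_fit_thresholds(pooled) && length(pairs) < max_added) {
      mi <- modification_indices(pooled)
      mi <- mi[mi$lhs %in% preds & mi$rhs %in% preds, , drop = FALSE]
      if (!nrow(mi)) break
      pairs <- c(pairs, list(c(mi$lhs[1], mi$rhs[1])))
      pooled <- fit_model(brain_g_syntax(preds, covariates, mri_covariates,
                                         brain_resid_pairs = pairs),
                          dat, covariates = c(covariates, mri_covariates))
    }
  }
  syn <- brain_g_syntax(preds, covariates, mri_covariates,
                        brain_resid_pairs = pairs)
  allcov <- c(covariates, mri_covariates)
  fit_free <- fit_model(syn, dat, group = glab, group_equal = "loadings",
                        covariates = allcov)
  fit_con <- fit_model(syn, dat, group = glab,
                       group_equal = c("loadings", "regressions"),
                       covariates = allcov)
  cmp <- compare_nested(fit_free, fit_con)

  td <- tidy(fit_free)
  rows <- list()
  for (gname in fit_free$group_names) {
    for (v in preds) {
      rows[[length(rows) + 1]] <- association_row(fit_free, v,
        if (length(preds) == 1) "individual" else "simultaneous", gname)
    }
  }
  rows <- dplyr::bind_rows(rows)
  gvar <- td[td$class == "latvar" & td$lhs == "g", , drop = FALSE]
  r2 <- setNames(1 - gvar$std, gvar$group)
  list(comparison = cmp, associations = rows, r2 = r2,
       fit_free = fit_free, fit_constrained = fit_con, pairs_added = pairs)
}
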