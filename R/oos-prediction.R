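#' Average left/right homologues
#'
#' Replaces each `<family>_<structure>_l` / `_r` column pair with a single
#' `<family>_<structure>` column holding the mean of the available sides
#' (the single observed side is used when one is missing). Unpaired
#' columns (forceps minor/major, middle cerebellar peduncle) and all
#' non-regional columns pass through unchanged.
#'
#' @param cohort Cohort tibble.
#' @return The cohort with bilateral columns averaged.
#' @export
average_bilateral <- function(cohort) {
  nm <- names(cohort)
  paired <- grep("^(fa|md|cortical|subcortical)_.+_(l|r)$", nm, value = TRUE)
  stems <- unique(sub("_(l|r)$", "", paired))
  out <- cohort
  for (s in stems) {
    sides <- intersect(paste0(s, c("_l", "_r")), nm)
    if (length(sides) == 1) {
      # lone side: rename rather than average
      out[[s]] <- out[[sides]]
    } else {
      out[[s]] <- rowMeans(out[, sides], na.rm = TRUE)
      out[[s]][is.nan(out[[s]])] <- NA_real_
    }
    out[sides] <- NULL
  }
  out
}

composite_family_columns <- function(cohort, family) {
  cols <- regional_family_columns(family)
  stems <- unique(sub("_(l|r)$", "", cols))
  intersect(stems, names(cohort))
}

#' Train a weighted-composite prediction model
#'
#' Fits a MIMIC SEM on the training site in which the bilateral-averaged
#' regional measures of one family simultaneously predict latent g, with
#' in-model covariates (age, sex; head coordinates on the imaging
#' variables). Modification indices add correlated residuals among the
#' regional predictors until the preregistered fit criteria are met (capped
#' at `max_added`); if the cap is reached the model is returned flagged.
#' The composite weights are the training standardized path estimates.
#'
#' @param train_cohort Cohort rows of the training site (bilateral
#'   averaging is applied internally if still needed).
#' @param roi_family `"fa"`, `"md"`, `"cortical"` or `"subcortical"`.
#' @param tbv_mode `"none"` or `"roi_adjusted"` (each ROI additionally
#'   adjusted for TBV inside the training model).
#' @param covariates,mri_covariates Covariate recipe.
#' @param max_added Respecification cap.
#' @return A `composite_model`: weights, the training ROI means/SDs used
#'   for z-scoring, covariate recipe, `tbv_mode`, training-site fit
#'   summary, `thresholds_met`.
#' @export
train_composite <- function(train_cohort,
                            roi_family = c("fa", "md", "cortical",
                                           "subcortical"),
                            tbv_mode = c("none", "roi_adjusted"),
                            covariates = c("age", "sex"),
                            mri_covariates = default_mri_covariates(),
                            max_added = 10) {
  roi_family <- match.arg(roi_family)
  tbv_mode <- match.arg(tbv_mode)
  dat <- average_bilateral(train_cohort)
  rois <- composite_family_columns(dat, roi_family)
  if (!length(rois)) stop("no ", roi_family, " columns present", call. = FALSE)
  mri_cov <- mri_covariates
  if (tbv_mode == "roi_adjusted") mri_cov <- c(mri_cov, "tbv")

  keep <- rowSums(!is.na(dat[, cognitive_tests()])) >= 1 &
    rowSums(!is.na(dat[, rois, drop = FALSE])) >= 1
  dat <- dat[keep, , drop = FALSE]

  pairs <- list()
  fit <- fit_model(brain_g_syntax(rois, covariates, mri_cov),
                   dat, covariates = c(covariates, mri_cov))
  while (!meets_fit_thresholds(fit) && length(pairs) < max_added &&
         length(rois) > 1) {
    mi <- modification_indices(fit)
    mi <- mi[mi$lhs %in% rois & mi$rhs %in% rois, , drop = FALSE]
    if (!nrow(mi)) break
    pairs <- c(pairs, list(c(mi$lhs[1], mi$rhs[1])))
    fit <- fit_model(brain_g_syntax(rois, covariates, mri_cov,
                                    brain_resid_pairs = pairs),
                     dat, covariates = c(covariates, mri_cov))
  }
  td <- tidy(fit)
  w <- td[td$class == "regression" & td$rhs %in% rois, , drop = FALSE]
  weights <- setNames(w$std, w$rhs)[rois]
  scal <- lapply(rois, function(v) {
    c(mean = mean(dat[[v]], na.rm = TRUE), sd = stats::sd(dat[[v]], na.rm = TRUE))
  })
  names(scal) <- rois
  out <- list(
    roi_family = roi_family, rois = rois, weights = weights,
    scaling = scal, covariates = covariates, mri_covariates = mri_covariates,
    tbv_mode = tbv_mode, training_site = unique(as.character(dat$site)),
    pairs_added = pairs, thresholds_met = meets_fit_thresholds(fit),
    fit_summary = glance(fit), n_train = fit$n
  )
  class(out) <- "composite_model"
  out
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("<composite_model> %s family, %d ROIs (tbv_mode = %s)\n",
              x$roi_family, length(x$rois), x$tbv_mode))
  cat(sprintf("  trained on n = %d (site: %s); thresholds met: %s\n",
              x$n_train, paste(x$training_site, collapse = "/"),
              x$thresholds_met))
  invisible(x)
}

#' @method tidy composite_model
#' @export
tidy.composite_model <- function(x, ...) {
  tibble::tibble(roi = names(x$weights), weight = unname(x$weights))
}

#' Serialise a composite model to JSON
#' @param model A `composite_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composite_model <- function(model, path) {
  out <- unclass(model)
  out$weights <- as.list(out$weights)            # keep ROI names in JSON
  out$scaling <- lapply(out$scaling, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Evaluate a weighted composite out of sample
#'
#' Builds the per-subject weighted composite `sum_j w_j z_j` (z-scores use
#' the training-sample means/SDs), then fits one two-group SEM over the
#' training and test sites in which g is regressed on the composite, with
#' the g loadings and the Matrix-Reasoning/VNR residual covariance
#' constrained equal across sites. Optionally TBV enters the structural
#' regression as a covariate. Subjects missing all ROIs are excluded (count
#' reported); subjects with a partial ROI set contribute their available
#' terms.
#'
#' @param cohort Cohort containing both sites.
#' @param model A `composite_model`.
#' @param test_site Site label of the test sample.
#' @param tbv_covariate Add TBV to the structural regression.
#' @return A `composite_evaluation` tibble: one row per site (`role` =
#'   train/test) with the standardized association, SE, p, 95% CI and the
#'   complete-case n; the two-group fit is attached as attribute `"fit"`.
#' @export
evaluate_composite <- function(cohort, model, test_site = "newcastle",
                               tbv_covariate = FALSE) {
  dat <- average_bilateral(cohort)
  rois <- model$rois
  assert_columns(dat, rois, "cohort")
  Z <- as.matrix(dat[, rois, drop = FALSE])
  for (j in seq_along(rois)) {
    sc <- model$scaling[[rois[j]]]
    Z[, j] <- (Z[, j] - sc[["mean"]]) / sc[["sd"]]
  }
  W <- matrix(rep(unname(model$weights), each = nrow(Z)), nrow(Z))
  contrib <- Z * W
  n_avail <- rowSums(!is.na(contrib))
  composite <- rowSums(contrib, na.rm = TRUE)
  composite[n_avail == 0] <- NA_real_
  n_excluded <- sum(n_avail == 0)
  dat$mri_composite <- composite

  sites <- c(setdiff(model$training_site, test_site)[1], test_site)
  keep <- dat$site %in% sites & !is.na(dat$mri_composite) &
    rowSums(!is.na(dat[, cognitive_tests()])) >= 1
  dat <- dat[keep, , drop = FALSE]
  glab <- factor(ifelse(dat$site == test_site, "test", "train"),
                 levels = c("train", "test"))

  preds <- "mri_composite"
  extra <- character()
  if (tbv_covariate) preds <- c("mri_composite", "tbv")
  syn <- brain_g_syntax(preds, model$covariates, model$mri_covariates)
  fit <- fit_model(syn, dat, group = glab,
                   group_equal = c("loadings", "rescov"),
                   covariates = c(model$covariates, model$mri_covariates))
  rows <- dplyr::bind_rows(
    association_row(fit, "mri_composite", "composite", "train"),
    association_row(fit, "mri_composite", "composite", "test"))
  rows$role <- rows$group
  rows$ci_lower <- rows$beta - 1.96 * rows$se
  rows$ci_upper <- rows$beta + 1.96 * rows$se
  rows$roi_family <- model$roi_family
  rows$tbv_covariate <- tbv_covariate
  attr(rows, "fit") <- fit
  attr(rows, "n_excluded_no_roi") <- n_excluded
  class(rows) <- c("composite_evaluation", class(rows))
  rows
}

#' Attenuation of composite associations after TBV correction
#'
#' Percent attenuation of the standardized composite-g association when
#' total brain volume is accounted for, per site.
#'
#' @param eval_plain Evaluation without TBV correction.
#' @param eval_tbv Evaluation with a TBV correction (either mode).
#' @return Tibble with `role`, `beta_plain`, `beta_tbv`,
#'   `attenuation_pct`.
#' @export
tbv_attenuation <- function(eval_plain, eval_tbv) {
  a <- dplyr::select(tibble::as_tibble(eval_plain), "role", beta_plain = "beta")
  b <- dplyr::select(tibble::as_tibble(eval_tbv), "role", beta_tbv = "beta")
  dplyr::left_join(a, b, by = "role") |>
    dplyr::mutate(attenuation_pct =
                    100 * (1 - .data$beta_tbv / .data$beta_plain))
}

#' Plot a composite evaluation
#'
#' Train vs test standardized associations with 95% CIs.
#'
#' @param object A `composite_evaluation` (or several row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot composite_evaluation
#' @export
autoplot.composite_evaluation <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi_family, y = .data$beta,
                                  colour = .data$role)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = NULL, y = "standardized association with g",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
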