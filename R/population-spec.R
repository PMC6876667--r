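#' Default population specification for the synthetic cohort
#'
#' Returns the generating parameters of the synthetic cohort: the
#' standardised g loadings of the four cognitive tests (on the
#' covariate-adjusted metric), the Matrix-Reasoning/Verbal-Numerical
#' residual covariance, the standardised g associations of every global and
#' regional brain measure, covariate confounding effects, the three-site
#' structure, and the hierarchical block-missingness scheme. Defaults are
#' the published estimates of the emulated study (see
#' [reference_estimates()]); at `n = 29004` the expected MRI/cognitive
#' overlap is 18,426 and the expected number of subjects with at least one
#' cognitive test is 27,100.
#'
#' All structural parameters are defined on the conditional (net of
#' covariates) unit-variance metric, so they are the exact estimands of the
#' covariate-adjusted standardised solution reported by [fit_model()].
#'
#' @param n Number of subjects.
#' @param effect_scale Multiplier applied to all g loadings, brain-g paths
#'   and the residual correlation. `0` yields a null population (used by
#'   calibration tests); the default `1` is the study condition.
#' @param covariate_scale Multiplier on all covariate effects.
#' @param continuous If `TRUE`, cognitive scores are left continuous and
#'   Trail-Making time / WMH are generated on a (narrow-dispersion) normal
#'   scale instead of log-normal, so that the multivariate-normal model is
#'   exactly correctly specified. Used for distributional calibration
#'   checks; the study-condition default is `FALSE`.
#' @param age_moderation Optional list with elements `loadings_middle`,
#'   `loadings_older` (named loading vectors) and/or `path_scale_middle`,
#'   `path_scale_older` (multipliers on brain-g paths), applied above/below
#'   the age boundary; `NULL` for an age-invariant population.
#'
#' @return A `population_spec` list.
#' @export
#' @examples
#' spec <- default_population_spec(n = 2000)
#' spec$loadings
default_population_spec <- function(n = 29004, effect_scale = 1,
                                    covariate_scale = 1, continuous = FALSE,
                                    age_moderation = NULL) {
  ref <- reference_estimates()
  es <- effect_scale
  cs <- covariate_scale

  cov_eff <- function(age = 0, sex = 0, head = 0) {
    c(age = age, sex = sex, head_x = head, head_y = head, head_z = head) * cs
  }

  spec <- list(
    n = as.integer(n),
    loadings = ref$loadings_corrected * es,
    resid_corr = ref$resid_corr * es,
    brain_paths = c(tbv = 0.276, gm = 0.281, nawm = 0.246, wmh = -0.106) * es,
    wm_factor_targets = c(gfa = 0.090, gmd = -0.066) * es,
    regional = list(
      cortical = dplyr::mutate(cortical_roster_values(), beta = .data$beta * es),
      subcortical = dplyr::mutate(subcortical_roster_values(), beta = .data$beta * es),
      tracts = dplyr::mutate(tract_roster_values(),
                             beta_fa = .data$beta_fa * es,
                             beta_md = .data$beta_md * es)
    ),
    # shared residual factors: global anatomy (a0), white-matter FA/MD
    # factors, and left/right pair factors. These induce the residual
    # correlation structure among brain variables.
    # effect_scale = 0 yields a fully null population (no residual
    # dependence either), used by calibration tests
    shared = list(
      a0 = c(tbv = 0.90, gm = 0.85, nawm = 0.80, wmh = -0.25,
             cortical = 0.45, subcortical = 0.45) * es,
      ffa = 0.55 * es, fmd = 0.55 * es,
      pair = c(cortical = 0.45, subcortical = 0.45,
               fa = 0.35, md = 0.35) * es,
      factor_corr = {
        fc <- matrix(c(1, 0.15, -0.15,
                       0.15, 1, -0.50,
                       -0.15, -0.50, 1), 3, 3,
                     dimnames = rep(list(c("a0", "ffa", "fmd")), 2))
        fc[row(fc) != col(fc)] <- fc[row(fc) != col(fc)] * min(es, 1)
        fc
      }
    ),
    covariate_effects = list(
      cognitive = cov_eff(age = -0.15, sex = 0.05),
      tmtb = cov_eff(age = 0.15, sex = -0.05),
      volume = cov_eff(age = -0.15, sex = 0.25, head = 0.05),
      wmh = cov_eff(age = 0.25, sex = 0.05, head = 0.05),
      fa = cov_eff(age = -0.20, sex = 0.05, head = 0.05),
      md = cov_eff(age = 0.25, sex = -0.05, head = 0.05)
    ),
    site_probs = c(manchester = 22037, reading = 866, newcastle = 6101) / 29004,
    # hierarchical MCAR blocks reproducing the study's printed Ns:
    # MRI 20,330/29,004; VNR 26,983; >=1 cognitive test 27,100; overlap 18,426
    missing_blocks = list(
      p_mri = 0.7009,
      p_vnr_mri = 0.9006, p_vnr_nomri = 1.0,
      p_enh_mri_vnr = 0.590, p_enh_mri_novnr = 0.0584, p_enh_nomri = 0.537,
      p_dmri_mri = 0.9069, p_wmseg_mri = 0.9448
    ),
    tmtb_family = if (continuous) "normal" else "lognormal",
    tmtb_sigma = 0.348,
    wmh_sigma = 0.35,
    integer_scores = !continuous,
    age = list(mean = 63.13, sd = 7.48, min = 44, max = 81, split = 63.29),
    sex_p_female = 15024 / 29004,
    scales = list(
      matrix_reasoning = c(8.007, 2.115), symbol_digit = c(19.005, 5.247),
      vnr = c(6.713, 2.061), tmtb_median = 496, tmtb_normal = c(499, 50),
      tbv = c(1167674, 110960), gm = c(617300, 55448),
      nawm = c(545541, 61737), wmh_median = 2622, wmh_normal = c(2622, 500),
      fa = c(0.45, 0.04), md = c(0.75, 0.05),
      cortical = c(5000, 800),
      subcortical = list(
        accumbens = c(500, 90), amygdala = c(1300, 200), caudate = c(3500, 450),
        hippocampus = c(3800, 450), pallidum = c(1700, 220),
        putamen = c(4800, 550), thalamus = c(7800, 900)
      ),
      head = c(x = 3, y = 4, z = 5)
    ),
    age_moderation = age_moderation
  )
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

#' Validate a population specification
#'
#' Checks the structural invariants of a [default_population_spec()]-style
#' list: all standardised loadings/paths inside (-1, 1), positive residual
#' variances after accounting for shared factors and covariates, site
#' proportions summing to one, and all block probabilities in \[0, 1\].
#'
#' @param spec A `population_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_population_spec <- function(spec) {
  stopifnot(is.list(spec), spec$n >= 1)
  if (any(abs(spec$loadings) >= 1)) {
    stop("all standardised loadings must satisfy |lambda| < 1", call. = FALSE)
  }
  if (any(abs(spec$brain_paths) >= 1)) {
    stop("all standardised brain paths must satisfy |beta| < 1", call. = FALSE)
  }
  if (abs(sum(spec$site_probs) - 1) > 1e-8) {
    stop("site probabilities must sum to 1", call. = FALSE)
  }
  probs <- unlist(spec$missing_blocks)
  if (any(probs < 0 | probs > 1)) {
    stop("block missingness probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is_psd(spec$shared$factor_corr)) {
    stop("shared-factor correlation matrix must be positive semi-definite",
         call. = FALSE)
  }
  # unit-variance decompositions must leave positive unique variance
  sh <- spec$shared
  chk <- function(beta, shared2, cov2, what) {
    u <- 1 - beta^2 - shared2 - cov2
    if (any(u <= 0)) {
      stop(sprintf("non-positive unique variance in %s block", what),
           call. = FALSE)
    }
  }
  cov2 <- vapply(spec$covariate_effects, function(x) sum(x^2), numeric(1))
  chk(spec$loadings, 0, max(cov2[c("cognitive", "tmtb")]), "cognitive")
  chk(spec$brain_paths, sh$a0[c("tbv", "gm", "nawm", "wmh")]^2,
      max(cov2[c("volume", "wmh")]), "global")
  chk(spec$regional$tracts$beta_fa, sh$ffa^2 + sh$pair[["fa"]]^2,
      cov2[["fa"]], "FA")
  chk(spec$regional$tracts$beta_md, sh$fmd^2 + sh$pair[["md"]]^2,
      cov2[["md"]], "MD")
  chk(spec$regional$cortical$beta, sh$a0[["cortical"]]^2 + sh$pair[["cortical"]]^2,
      cov2[["volume"]], "cortical")
  chk(spec$regional$subcortical$beta,
      sh$a0[["subcortical"]]^2 + sh$pair[["subcortical"]]^2,
      cov2[["volume"]], "subcortical")
  invisible(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat("  n:", x$n, "\n")
  cat("  loadings:", paste(sprintf("%s=%.3f", names(x$loadings), x$loadings),
                           collapse = ", "), "\n")
  cat("  MR-VNR residual covariance:", x$resid_corr, "\n")
  cat("  global brain paths:",
      paste(sprintf("%s=%.3f", names(x$brain_paths), x$brain_paths),
            collapse = ", "), "\n")
  cat("  regional variables:",
      nrow(x$regional$cortical), "cortical,",
      nrow(x$regional$subcortical), "subcortical,",
      nrow(x$regional$tracts), "tracts (FA+MD)\n")
  cat("  sites:", paste(sprintf("%s=%.3f", names(x$site_probs), x$site_probs),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a population specification as YAML-like JSON
#'
#' The specification is serialised as human-readable JSON (a strict subset
#' of YAML) and schema-checked on reading via [validate_population_spec()].
#'
#' @param spec A `population_spec`.
#' @param path File path.
#' @return `write_population_spec()` returns `path` invisibly;
#'   `read_population_spec()` returns the validated `population_spec`.
#' @export
write_population_spec <- function(spec, path) {
  out <- unclass(spec)
  out$regional <- lapply(out$regional, function(d) as.data.frame(d))
  # named vectors as JSON objects so names survive the round trip
  named <- function(x) as.list(x)
  for (f in c("loadings", "brain_paths", "wm_factor_targets", "site_probs")) {
    out[[f]] <- named(out[[f]])
  }
  out$covariate_effects <- lapply(out$covariate_effects, named)
  out$shared$a0 <- named(out$shared$a0)
  out$shared$pair <- named(out$shared$pair)
  out$scales$head <- named(out$scales$head)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$regional <- lapply(raw$regional, tibble::as_tibble)
  raw$loadings <- unlist(raw$loadings)
  raw$brain_paths <- unlist(raw$brain_paths)
  raw$site_probs <- unlist(raw$site_probs)
  raw$wm_factor_targets <- unlist(raw$wm_factor_targets)
  raw$covariate_effects <- lapply(raw$covariate_effects, unlist)
  raw$shared$a0 <- unlist(raw$shared$a0)
  raw$shared$pair <- unlist(raw$shared$pair)
  raw$shared$factor_corr <- matrix(unlist(raw$shared$factor_corr), 3, 3,
                                   dimnames = rep(list(c("a0", "ffa", "fmd")), 2))
  raw$scales <- lapply(raw$scales, function(x) if (is.list(x)) lapply(x, unlist) else unlist(x))
  raw$scales$head <- unlist(raw$scales$head)
  if (length(raw$age_moderation) == 0) raw$age_moderation <- NULL
  class(raw) <- "population_spec"
  validate_population_spec(raw)
  raw
}
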