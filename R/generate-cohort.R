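#' Generate a synthetic cohort
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume: a standard-normal latent g per subject; four cognitive
#' indicators with the specified loadings and a correlated residual between
#' Matrix Reasoning and Verbal-Numerical Reasoning; global and regional
#' brain measures with their standardised g paths plus shared residual
#' factors (a global anatomy factor, FA/MD white-matter factors and
#' left/right pair factors); covariate confounding (age, sex, scanner head
#' position); three assessment sites; and the hierarchical block
#' missingness of the emulated study (enhanced cognitive battery, MRI,
#' diffusion MRI, WM segmentation). Identical `(spec, seed)` give
#' byte-identical output.
#'
#' Trail-Making part B time is generated log-normally (monotonically
#' decreasing in g) and reported as raw deci-seconds; integer cognitive
#' scores are produced by binning continuous latents to the published score
#' ranges. Blocks are assigned independently of all generated values, so
#' missingness is ignorable by construction.
#'
#' @param spec A `population_spec`, e.g. [default_population_spec()].
#' @param seed Integer seed.
#' @return A tibble (`CohortTable`): one row per subject; columns
#'   `subject_id`, covariates, cognitive scores, global volumes
#'   (`tbv`, `gm`, `wm`, `wmh`, `nawm`), 27 `fa_*`, 27 `md_*`,
#'   96 `cortical_*`, 14 `subcortical_*`. Cells may be `NA`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_population_spec(n = 500), seed = 1)
#' dim(cohort)
generate_cohort <- function(spec, seed = 1L) {
  validate_population_spec(spec)
  n <- spec$n
  set.seed(as.integer(seed))

  ## --- covariates --------------------------------------------------------
  a <- spec$age
  u <- runif(n, pnorm(a$min, a$mean, a$sd), pnorm(a$max, a$mean, a$sd))
  age <- qnorm(u, a$mean, a$sd)
  sex <- as.integer(runif(n) < spec$sex_p_female)  # 1 = female
  hs <- spec$scales$head
  head_x <- rnorm(n, 0, hs[["x"]])
  head_y <- rnorm(n, 0, hs[["y"]])
  head_z <- rnorm(n, 0, hs[["z"]])
  site <- sample(names(spec$site_probs), n, replace = TRUE,
                 prob = spec$site_probs)

  covz <- cbind(
    age = (age - a$mean) / a$sd,
    sex = (sex - spec$sex_p_female) /
      sqrt(spec$sex_p_female * (1 - spec$sex_p_female)),
    head_x = head_x / hs[["x"]],
    head_y = head_y / hs[["y"]],
    head_z = head_z / hs[["z"]]
  )

  ## --- latent factors ----------------------------------------------------
  g <- rnorm(n)
  fac <- matrix(rnorm(n * 3), n, 3) %*% chol(spec$shared$factor_corr)
  colnames(fac) <- c("a0", "ffa", "fmd")

  # age-moderated parameters (optional)
  older <- age > a$split
  lam <- matrix(rep(spec$loadings, each = n), n, 4,
                dimnames = list(NULL, names(spec$loadings)))
  path_scale <- rep(1, n)
  am <- spec$age_moderation
  if (!is.null(am)) {
    if (!is.null(am$loadings_middle)) {
      for (v in names(spec$loadings)) {
        lam[, v] <- ifelse(older, am$loadings_older[[v]], am$loadings_middle[[v]])
      }
    }
    if (!is.null(am$path_scale_middle)) {
      path_scale <- ifelse(older, am$path_scale_older, am$path_scale_middle)
    }
  }

  # structural part on the conditional unit-variance metric, then covariate
  # effects are added and the total rescaled to unit conditional variance
  with_cov <- function(ystar, eff) {
    s <- sqrt(1 - sum(eff^2))
    drop(covz %*% eff) + s * ystar
  }

  ## --- cognitive indicators ---------------------------------------------
  rc <- spec$resid_corr
  v_mr <- 1 - spec$loadings[["matrix_reasoning"]]^2
  v_vnr <- 1 - spec$loadings[["vnr"]]^2
  e1 <- rnorm(n); e2 <- rnorm(n)
  eps_mr <- sqrt(v_mr) * e1
  cross <- rc / sqrt(v_mr)
  eps_vnr <- cross * e1 + sqrt(pmax(v_vnr - cross^2, 1e-10)) * e2
  if (!is.null(am$loadings_middle)) {
    # group-specific loadings: recompute residual sds per subject
    v_mr_i <- 1 - lam[, "matrix_reasoning"]^2
    v_vnr_i <- 1 - lam[, "vnr"]^2
    eps_mr <- sqrt(v_mr_i) * e1
    cross_i <- rc / sqrt(v_mr_i)
    eps_vnr <- cross_i * e1 + sqrt(pmax(v_vnr_i - cross_i^2, 1e-10)) * e2
  }
  ystar <- list(
    matrix_reasoning = lam[, "matrix_reasoning"] * g + eps_mr,
    symbol_digit = lam[, "symbol_digit"] * g +
      sqrt(pmax(1 - lam[, "symbol_digit"]^2, 1e-10)) * rnorm(n),
    vnr = lam[, "vnr"] * g + eps_vnr,
    tmtb_time = lam[, "tmtb_time"] * g +
      sqrt(pmax(1 - lam[, "tmtb_time"]^2, 1e-10)) * rnorm(n)
  )
  ce <- spec$covariate_effects
  ytot <- list(
    matrix_reasoning = with_cov(ystar$matrix_reasoning, ce$cognitive),
    symbol_digit = with_cov(ystar$symbol_digit, ce$cognitive),
    vnr = with_cov(ystar$vnr, ce$cognitive),
    tmtb_time = with_cov(ystar$tmtb_time, ce$tmtb)
  )
  sc <- spec$scales
  bin <- function(y, mean_sd, lo, hi) {
    x <- mean_sd[1] + mean_sd[2] * y
    if (spec$integer_scores) x <- pmin(pmax(round(x), lo), hi)
    x
  }
  matrix_reasoning <- bin(ytot$matrix_reasoning, sc$matrix_reasoning, 0, 15)
  symbol_digit <- bin(ytot$symbol_digit, sc$symbol_digit, 0, Inf)
  vnr <- bin(ytot$vnr, sc$vnr, 0, 13)
  tmtb_time <- if (spec$tmtb_family == "lognormal") {
    exp(log(sc$tmtb_median) + spec$tmtb_sigma * ytot$tmtb_time)
  } else {
    pmax(sc$tmtb_normal[1] + sc$tmtb_normal[2] * ytot$tmtb_time, 1)
  }

  ## --- global brain volumes ---------------------------------------------
  sh <- spec$shared
  bp <- spec$brain_paths
  glob_star <- function(v, eff) {
    b <- bp[[v]] * path_scale
    l <- sh$a0[[v]]
    uvar <- pmax(1 - b^2 - l^2, 1e-10)
    with_cov(b * g + l * fac[, "a0"] + sqrt(uvar) * rnorm(n), eff)
  }
  tbv_z <- glob_star("tbv", ce$volume)
  gm_z <- glob_star("gm", ce$volume)
  nawm_z <- glob_star("nawm", ce$volume)
  wmh_z <- glob_star("wmh", ce$wmh)
  tbv <- sc$tbv[1] + sc$tbv[2] * tbv_z
  gm <- sc$gm[1] + sc$gm[2] * gm_z
  nawm <- sc$nawm[1] + sc$nawm[2] * nawm_z
  wmh <- if (spec$integer_scores || spec$tmtb_family == "lognormal") {
    exp(log(sc$wmh_median) + spec$wmh_sigma * wmh_z)
  } else {
    pmax(sc$wmh_normal[1] + sc$wmh_normal[2] * wmh_z, 1)
  }
  wm <- nawm + wmh

  ## --- white matter tracts ----------------------------------------------
  tr <- spec$regional$tracts
  pair_id <- ifelse(is.na(tr$hemi), paste0("solo_", tr$tract), tr$tract)
  pairs <- unique(pair_id)
  pair_fac_fa <- matrix(rnorm(n * length(pairs)), n,
                        dimnames = list(NULL, pairs))
  pair_fac_md <- matrix(rnorm(n * length(pairs)), n,
                        dimnames = list(NULL, pairs))
  tract_col <- function(beta, modality, pid) {
    lf <- if (modality == "fa") sh$ffa else sh$fmd
    lp <- sh$pair[[modality]]
    f <- if (modality == "fa") fac[, "ffa"] else fac[, "fmd"]
    pf <- if (modality == "fa") pair_fac_fa[, pid] else pair_fac_md[, pid]
    b <- beta * path_scale
    uvar <- pmax(1 - b^2 - lf^2 - lp^2, 1e-10)
    eff <- if (modality == "fa") ce$fa else ce$md
    z <- with_cov(b * g + lf * f + lp * pf + sqrt(uvar) * rnorm(n), eff)
    s <- if (modality == "fa") sc$fa else sc$md
    out <- s[1] + s[2] * z
    if (modality == "fa") out <- pmin(pmax(out, 0), 1)
    out
  }
  fa_cols <- lapply(seq_len(nrow(tr)), function(i)
    tract_col(tr$beta_fa[i], "fa", pair_id[i]))
  names(fa_cols) <- tr$fa_variable
  md_cols <- lapply(seq_len(nrow(tr)), function(i)
    tract_col(tr$beta_md[i], "md", pair_id[i]))
  names(md_cols) <- tr$md_variable

  ## --- cortical and subcortical volumes ----------------------------------
  region_cols <- function(roster, kind) {
    structures <- unique(roster$structure)
    pf <- matrix(rnorm(n * length(structures)), n,
                 dimnames = list(NULL, structures))
    la <- sh$a0[[kind]]
    lp <- sh$pair[[kind]]
    out <- lapply(seq_len(nrow(roster)), function(i) {
      b <- roster$beta[i] * path_scale
      uvar <- pmax(1 - b^2 - la^2 - lp^2, 1e-10)
      z <- with_cov(b * g + la * fac[, "a0"] +
                      lp * pf[, roster$structure[i]] + sqrt(uvar) * rnorm(n),
                    ce$volume)
      s <- if (kind == "cortical") sc$cortical
           else sc$subcortical[[roster$structure[i]]]
      s[1] + s[2] * z
    })
    names(out) <- roster$variable
    out
  }
  cort_cols <- region_cols(spec$regional$cortical, "cortical")
  subc_cols <- region_cols(spec$regional$subcortical, "subcortical")

  ## --- block missingness --------------------------------------------------
  mb <- spec$missing_blocks
  has_mri <- runif(n) < mb$p_mri
  has_vnr <- runif(n) < ifelse(has_mri, mb$p_vnr_mri, mb$p_vnr_nomri)
  p_enh <- ifelse(has_mri,
                  ifelse(has_vnr, mb$p_enh_mri_vnr, mb$p_enh_mri_novnr),
                  mb$p_enh_nomri)
  has_enh <- runif(n) < p_enh
  has_dmri <- has_mri & (runif(n) < mb$p_dmri_mri)
  has_wmseg <- has_mri & (runif(n) < mb$p_wmseg_mri)

  na_unless <- function(x, keep) replace(x, !keep, NA_real_)
  matrix_reasoning <- na_unless(matrix_reasoning, has_enh)
  symbol_digit <- na_unless(symbol_digit, has_enh)
  tmtb_time <- na_unless(tmtb_time, has_enh)
  vnr <- na_unless(vnr, has_vnr)
  tbv <- na_unless(tbv, has_mri)
  gm <- na_unless(gm, has_mri)
  wm <- na_unless(wm, has_wmseg)
  wmh <- na_unless(wmh, has_wmseg)
  nawm <- na_unless(nawm, has_wmseg)
  fa_cols <- lapply(fa_cols, na_unless, keep = has_dmri)
  md_cols <- lapply(md_cols, na_unless, keep = has_dmri)
  cort_cols <- lapply(cort_cols, na_unless, keep = has_mri)
  subc_cols <- lapply(subc_cols, na_unless, keep = has_mri)

  tibble::tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    age = age, sex = sex, site = site,
    head_x = head_x, head_y = head_y, head_z = head_z,
    matrix_reasoning = matrix_reasoning, symbol_digit = symbol_digit,
    vnr = vnr, tmtb_time = tmtb_time,
    tbv = tbv, gm = gm, wm = wm, wmh = wmh, nawm = nawm,
    !!!fa_cols, !!!md_cols, !!!cort_cols, !!!subc_cols
  )
}
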