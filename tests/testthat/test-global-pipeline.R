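# shared mid-sized cohort for the global-association tests
global_coh <- local({
  coh <- generate_cohort(default_population_spec(n = 12000), seed = 30)
  clean_cohort(coh)$cohort
})

test_that("bivariate association recovers the generating path", {
  spec <- default_population_spec()
  r <- bivariate_brain_g(global_coh, "tbv")
  expect_lt(abs(r$beta - spec$brain_paths[["tbv"]]), 3 * r$se + 0.005)
  expect_lt(r$p, 1e-10)
  expect_equal(r$model, "individual")
})

test_that("a null brain variable shows no association", {
  coh <- global_coh
  set.seed(31)
  coh$tbv <- ifelse(is.na(coh$tbv), NA, rnorm(nrow(coh), 1167674, 110960))
  out <- global_brain_g(coh, measures = c("tbv"))
  expect_lt(abs(out$beta), 0.03)
  expect_gt(out$p, 1e-4)
})

test_that("single-predictor MIMIC equals the bivariate model", {
  r_biv <- bivariate_brain_g(global_coh, "gm")
  mim <- mimic_global(global_coh, predictors = "gm")
  expect_equal(mim$associations$beta, r_biv$beta, tolerance = 1e-4)
  expect_equal(mim$r2, r_biv$beta^2, tolerance = 1e-3)
})

test_that("MIMIC R2 matches the quadratic-form closed form", {
  # standardized predictors with known correlation R and true weights b:
  # R2 = b' R b. Built directly on latent-free data with a perfect g proxy
  # replaced by the 4-test battery at high loadings.
  set.seed(32)
  n <- 20000
  Rm <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  b <- c(0.25, 0.1)
  Xb <- exact_cor_data(n, Rm, seed = 33)
  names(Xb) <- c("bv1", "bv2")
  eta <- as.matrix(Xb) %*% b
  r2_true <- drop(t(b) %*% Rm %*% b)
  g <- drop(eta) + rnorm(n, 0, sqrt(1 - r2_true))
  lam <- c(0.8, 0.75, 0.7, -0.8)
  d <- data.frame(
    matrix_reasoning = lam[1] * g + rnorm(n, 0, sqrt(1 - lam[1]^2)),
    symbol_digit = lam[2] * g + rnorm(n, 0, sqrt(1 - lam[2]^2)),
    vnr = lam[3] * g + rnorm(n, 0, sqrt(1 - lam[3]^2)),
    tmtb_time = lam[4] * g + rnorm(n, 0, sqrt(1 - lam[4]^2)),
    bv1 = Xb$bv1, bv2 = Xb$bv2)
  syn <- "g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time\ng ~ bv1 + bv2"
  fit <- fit_model(syn, d, se = FALSE)
  td <- tidy(fit)
  r2_hat <- 1 - td$std[td$class == "latvar" & td$lhs == "g"]
  expect_lt(abs(r2_hat - r2_true), 0.015)
  bhat <- td$std[td$class == "regression"]
  expect_lt(max(abs(bhat - b)), 0.02)
})

test_that("TBV stays out of the default simultaneous predictor set", {
  expect_false("tbv" %in% eval(formals(mimic_global)$predictors))
})

test_that("age invariance testing has the right df and congruence", {
  inv <- invariance_test(global_coh, "age", "weak")
  expect_equal(inv$comparison$delta_df, 3)
  expect_gt(inv$congruence, 0.98)
  expect_false("age" %in% inv$fit_free$model$covariates)
  expect_lt(abs(inv$boundary - 63.29), 1)
})

test_that("sex strong invariance constrains loadings and intercepts", {
  inv <- invariance_test(global_coh, "sex", "strong")
  expect_equal(inv$comparison$delta_df, 6)
  expect_false("sex" %in% inv$fit_constrained$model$covariates)
})

test_that("null moderation keeps its type-I error near alpha", {
  # scaled-down calibration (the acceptance suite runs the full 500)
  set.seed(34)
  nrep <- 30
  pvals <- numeric(nrep)
  spec <- default_population_spec(n = 2000, continuous = TRUE,
                                  covariate_scale = 0)
  for (r in seq_len(nrep)) {
    coh <- generate_cohort(spec, seed = 4000 + r)
    keep <- rowSums(!is.na(coh[, default_tests])) >= 1 & !is.na(coh$tbv)
    d <- coh[keep, ]
    glab <- rep(c("a", "b"), length.out = nrow(d))
    syn <- brain_g_syntax("tbv", covariates = character(),
                          mri_covariates = character())
    f_free <- fit_model(syn, d, group = glab, group_equal = "loadings",
                        se = FALSE, baseline = FALSE)
    f_con <- fit_model(syn, d, group = glab,
                       group_equal = c("loadings", "regressions"),
                       se = FALSE, baseline = FALSE)
    pvals[r] <- compare_nested(f_free, f_con)$pvalue
  }
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / nrep) + 0.01)
})

test_that("sex moderation of the TBV path reports per-group estimates", {
  mod <- moderation_test(global_coh, "sex", "tbv")
  expect_equal(mod$comparison$delta_df, 1)
  expect_equal(sort(unique(mod$associations$group)), c("female", "male"))
  # generating paths are equal across sexes: estimates within joint SEs
  a <- mod$associations
  diff <- abs(a$beta[1] - a$beta[2])
  joint_se <- sqrt(a$se[1]^2 + a$se[2]^2)
  expect_lt(diff, 3 * joint_se)
  expect_gt(mod$comparison$pvalue, 0.001)
})

test_that("age moderation detects group-specific brain paths", {
  spec <- default_population_spec(
    n = 12000,
    age_moderation = list(path_scale_middle = 0.6, path_scale_older = 1.4))
  coh <- clean_cohort(generate_cohort(spec, seed = 35))$cohort
  mod <- moderation_test(coh, "age", "tbv")
  expect_equal(mod$comparison$delta_df, 1)
  expect_lt(mod$comparison$pvalue, 0.01)
  a <- mod$associations
  expect_gt(a$beta[a$group == "older"], a$beta[a$group == "middle"])
  # constrained fit never beats the free fit on likelihood
  expect_lte(mod$fit_constrained$loglik, mod$fit_free$loglik + 1e-6)
})
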