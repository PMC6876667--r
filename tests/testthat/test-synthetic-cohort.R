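test_that("default population spec carries the published estimates", {
  spec <- default_population_spec()
  expect_equal(unname(spec$loadings),
               c(0.505, 0.479, 0.592, -0.666))
  expect_equal(spec$resid_corr, 0.170)
  expect_equal(unname(spec$brain_paths["tbv"]), 0.276)
  expect_equal(unname(spec$brain_paths["gm"]), 0.281)
  expect_equal(spec$age$min, 44)
  expect_equal(spec$age$max, 81)
  expect_equal(sum(spec$site_probs), 1)
  # rosters have the full region counts
  expect_equal(nrow(spec$regional$cortical), 96)
  expect_equal(nrow(spec$regional$subcortical), 14)
  expect_equal(nrow(spec$regional$tracts), 27)
})

test_that("spec validation rejects structural violations", {
  spec <- default_population_spec(n = 100)
  bad <- spec
  bad$loadings[1] <- 1.2
  expect_error(validate_population_spec(bad), "lambda")
  bad <- spec
  bad$site_probs <- c(manchester = 0.5, reading = 0.2, newcastle = 0.2)
  expect_error(validate_population_spec(bad), "sum to 1")
  bad <- spec
  bad$missing_blocks$p_mri <- 1.4
  expect_error(validate_population_spec(bad), "\\[0, 1\\]")
})

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- default_population_spec(n = 1500)
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 43)
  expect_false(identical(a, c))
})

test_that("cohort respects its structural invariants", {
  coh <- small_cohort(n = 4000, seed = 5)
  both <- !is.na(coh$wm) & !is.na(coh$wmh)
  expect_equal(coh$nawm[both], coh$wm[both] - coh$wmh[both])
  expect_true(all(coh$tmtb_time > 0, na.rm = TRUE))
  fa_cols <- grep("^fa_", names(coh), value = TRUE)
  expect_length(fa_cols, 27)
  expect_true(all(vapply(coh[fa_cols], function(x)
    all(x >= 0 & x <= 1, na.rm = TRUE), logical(1))))
  expect_length(grep("^md_", names(coh)), 27)
  expect_length(grep("^cortical_", names(coh)), 96)
  expect_length(grep("^subcortical_", names(coh)), 14)
  expect_true(all(coh$matrix_reasoning %in% c(0:15, NA)))
  expect_true(all(coh$vnr %in% c(0:13, NA)))
  expect_true(all(coh$age >= 44 & coh$age <= 81))
})

test_that("null population shows no spurious correlations", {
  spec <- default_population_spec(n = 10000, effect_scale = 0,
                                  covariate_scale = 0, continuous = TRUE)
  coh <- generate_cohort(spec, seed = 3)
  vars <- c(default_tests, "tbv", "gm")
  R <- cor(coh[, vars], use = "pairwise.complete.obs")
  off <- abs(R[upper.tri(R)])
  # pairwise ns vary by block; use the smallest informative pair
  n_min <- min(vapply(vars, function(v) sum(!is.na(coh[[v]])), numeric(1)))
  expect_lt(max(off), 3 / sqrt(n_min) * 2)
})

test_that("block missingness reproduces the study's sample figures", {
  spec <- default_population_spec()
  coh <- generate_cohort(spec, seed = 10)
  has_cog <- rowSums(!is.na(coh[, default_tests])) > 0
  overlap <- sum(!is.na(coh$gm) & has_cog)
  expect_lt(abs(overlap - 18426) / 18426, 0.02)
  expect_lt(abs(sum(has_cog) - 27100) / 27100, 0.02)
  expect_lt(abs(sum(!is.na(coh$vnr)) - 26983) / 26983, 0.02)
  expect_lt(abs(sum(!is.na(coh$gm)) - 20330) / 20330, 0.02)
})

test_that("empirical moments match the covariance-algebra oracle", {
  spec <- default_population_spec(n = 50000, continuous = TRUE)
  coh <- generate_cohort(spec, seed = 8)
  n <- spec$n
  ce <- spec$covariate_effects
  lam <- spec$loadings
  s_cog <- scale_factor(ce$cognitive)
  s_tmtb <- scale_factor(ce$tmtb)
  s_vol <- scale_factor(ce$volume)
  sh <- spec$shared

  # standardize raw columns back to the generator's unit-variance metric
  z <- function(v) as.numeric(scale(coh[[v]]))
  mc_tol <- function() 4 / sqrt(n)

  # corr(MR, SDS) = shared covariate part + s^2 lambda_mr lambda_sds
  r_hat <- cor(z("matrix_reasoning"), z("symbol_digit"),
               use = "complete.obs")
  r_oracle <- oracle_cov(ce$cognitive, ce$cognitive, s_cog, s_cog,
                         lam["matrix_reasoning"], lam["symbol_digit"])
  expect_lt(abs(r_hat - r_oracle), mc_tol() + 0.01)  # binned-free mode: 0.01 slack for clamping

  # corr(MR, VNR) includes the residual covariance
  r_hat <- cor(z("matrix_reasoning"), z("vnr"), use = "complete.obs")
  r_oracle <- oracle_cov(ce$cognitive, ce$cognitive, s_cog, s_cog,
                         lam["matrix_reasoning"], lam["vnr"],
                         rescov = spec$resid_corr)
  expect_lt(abs(r_hat - r_oracle), mc_tol() + 0.01)

  # corr(TBV, GM): shared anatomy factor + g paths + covariates
  r_hat <- cor(z("tbv"), z("gm"), use = "complete.obs")
  r_oracle <- oracle_cov(ce$volume, ce$volume, s_vol, s_vol,
                         spec$brain_paths["tbv"], spec$brain_paths["gm"],
                         l1 = sh$a0[["tbv"]], l2 = sh$a0[["gm"]])
  expect_lt(abs(r_hat - r_oracle), mc_tol() + 0.005)

  # corr(TMTb, TBV): negative loading times positive path
  r_hat <- cor(z("tmtb_time"), z("tbv"), use = "complete.obs")
  r_oracle <- oracle_cov(ce$tmtb, ce$volume, s_tmtb, s_vol,
                         lam["tmtb_time"], spec$brain_paths["tbv"])
  expect_lt(abs(r_hat - r_oracle), mc_tol() + 0.005)
})

test_that("population spec round-trips through its config file", {
  spec <- default_population_spec(n = 500)
  path <- withr::local_tempfile(fileext = ".json")
  write_population_spec(spec, path)
  back <- read_population_spec(path)
  expect_equal(back$loadings, spec$loadings)
  expect_equal(back$brain_paths, spec$brain_paths)
  expect_equal(back$missing_blocks, spec$missing_blocks)
  coh_a <- generate_cohort(spec, seed = 2)
  coh_b <- generate_cohort(back, seed = 2)
  expect_equal(coh_a, coh_b)
})
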