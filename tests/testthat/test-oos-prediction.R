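test_that("bilateral averaging follows the available-side rules", {
  coh <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    cortical_insula_l = c(100, NA, NA),
    cortical_insula_r = c(120, 120, NA),
    fa_fmin = c(0.4, 0.5, 0.6),
    age = c(50, 60, 70))
  out <- average_bilateral(coh)
  expect_equal(out$cortical_insula, c(110, 120, NA))
  expect_false("cortical_insula_l" %in% names(out))
  expect_equal(out$fa_fmin, coh$fa_fmin)   # unpaired column untouched
  expect_equal(out$age, coh$age)
})

test_that("averaging the full cortical roster yields 48 columns", {
  coh <- small_cohort(n = 200, seed = 50)
  out <- average_bilateral(coh)
  expect_length(grep("^cortical_", names(out)), 48)
  expect_length(grep("^subcortical_", names(out)), 7)
  expect_length(grep("^fa_", names(out)), 15)   # 12 pairs + 3 unpaired
  expect_length(grep("^md_", names(out)), 15)
})

test_that("training on known unique weights recovers them", {
  # ROIs with independent residuals (no shared anatomy factor), so the
  # MIMIC needs no respecification and the generating weights are the
  # estimands
  set.seed(51)
  n <- 8000
  b <- c(0.25, 0.15, 0.1)
  g <- rnorm(n)
  # construct ROIs as causes: g = sum b_j x_j + resid
  X <- matrix(rnorm(n * 3), n, 3)
  gg <- drop(X %*% b) + rnorm(n, 0, sqrt(1 - sum(b^2)))
  lam <- c(0.7, 0.65, 0.6, -0.7)
  d <- tibble::tibble(
    matrix_reasoning = lam[1] * gg + rnorm(n, 0, sqrt(1 - lam[1]^2)),
    symbol_digit = lam[2] * gg + rnorm(n, 0, sqrt(1 - lam[2]^2)),
    vnr = lam[3] * gg + rnorm(n, 0, sqrt(1 - lam[3]^2)),
    tmtb_time = lam[4] * gg + rnorm(n, 0, sqrt(1 - lam[4]^2)),
    subcortical_thalamus_l = X[, 1], subcortical_thalamus_r = X[, 1],
    subcortical_caudate_l = X[, 2], subcortical_caudate_r = X[, 2],
    subcortical_putamen_l = X[, 3], subcortical_putamen_r = X[, 3],
    site = "manchester")
  cm <- train_composite(d, "subcortical", covariates = character(),
                        mri_covariates = character())
  expect_true(cm$thresholds_met)
  expect_length(cm$pairs_added, 0)
  got <- cm$weights[c("subcortical_thalamus", "subcortical_caudate",
                      "subcortical_putamen")]
  expect_lt(max(abs(got - b)), 0.025)
})

test_that("single-ROI composite equals the bivariate association", {
  coh <- clean_cohort(generate_cohort(default_population_spec(n = 8000),
                                      seed = 52))$cohort
  cm <- train_composite(coh[coh$site == "manchester", ], "subcortical")
  one <- cm
  one$rois <- "subcortical_thalamus"
  one$weights <- c(subcortical_thalamus = 1)
  one$scaling <- cm$scaling["subcortical_thalamus"]
  ev <- evaluate_composite(coh, one, test_site = "newcastle")
  avg <- average_bilateral(coh)
  r_biv <- bivariate_brain_g(avg[avg$site == "manchester", ],
                             "subcortical_thalamus")
  expect_lt(abs(ev$beta[ev$role == "train"] - r_biv$beta), 0.02)
})

test_that("composite variance matches the quadratic form w'Rw", {
  set.seed(53)
  R <- matrix(0.4, 3, 3); diag(R) <- 1
  Z <- exact_cor_data(2000, R, seed = 54)
  w <- c(0.5, 0.3, -0.2)
  comp <- as.matrix(Z) %*% w
  expect_equal(var(comp)[1], drop(t(w) %*% R %*% w), tolerance = 1e-10)
})

test_that("matched sites give stable train/test estimates", {
  coh <- clean_cohort(generate_cohort(default_population_spec(n = 12000),
                                      seed = 55))$cohort
  cm <- suppressWarnings(train_composite(coh[coh$site == "manchester", ],
                                         "fa", max_added = 4))
  ev <- evaluate_composite(coh, cm, test_site = "newcastle")
  expect_equal(nrow(ev), 2)
  b_train <- ev$beta[ev$role == "train"]
  b_test <- ev$beta[ev$role == "test"]
  joint <- sqrt(sum(ev$se^2))
  # population paths are identical across sites by construction
  expect_lt(abs(b_train - b_test), 3 * joint)
  expect_gt(b_train, 0)
  # TBV correction attenuates but does not flip positive associations
  ev_tbv <- evaluate_composite(coh, cm, test_site = "newcastle",
                               tbv_covariate = TRUE)
  att <- tbv_attenuation(ev, ev_tbv)
  expect_true(all(ev_tbv$beta > 0))
  expect_true(all(att$attenuation_pct > -5))
})

test_that("composite models serialise to JSON", {
  coh <- clean_cohort(generate_cohort(default_population_spec(n = 3000),
                                      seed = 56))$cohort
  cm <- suppressWarnings(train_composite(coh[coh$site == "manchester", ],
                                         "subcortical", max_added = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_composite_model(cm, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$weights), cm$weights, tolerance = 1e-12)
  expect_equal(back$roi_family, "subcortical")
})
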