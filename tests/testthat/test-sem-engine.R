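test_that("model building counts parameters and df correctly", {
  m <- build_model("f =~ y1 + y2 + y3 + y4")
  # 4 loadings + 4 residual variances + 4 intercepts
  cnt <- count_parameters(m)
  expect_equal(cnt$n_free, 12)
  expect_equal(cnt$n_moments, 4 * 7 / 2)
  expect_equal(cnt$df, 2)
  # one residual covariance costs one df
  m2 <- build_model("f =~ y1 + y2 + y3 + y4\ny1 ~~ y2")
  expect_equal(count_parameters(m2)$df, 1)
  expect_error(build_model("a ~ b\n b ~ a"), "cyclic")
  expect_error(build_model(""), "empty")
})

test_that("two-group equality constraints drop the free count as labelled", {
  set.seed(1)
  d <- as.data.frame(matrix(rnorm(400 * 4), 400,
                            dimnames = list(NULL, paste0("y", 1:4))))
  d$grp <- rep(c("a", "b"), 200)
  syn <- "f =~ y1 + y2 + y3 + y4"
  # pure-noise data: fits may go Heywood, which is fine for df counting
  free <- suppressWarnings(
    fit_model(syn, d, group = "grp", se = FALSE, baseline = FALSE))
  con <- suppressWarnings(
    fit_model(syn, d, group = "grp", group_equal = "loadings",
              se = FALSE, baseline = FALSE))
  # label enumeration oracle: 4 loadings shared (-4) but the group-2
  # latent variance is freed (+1)
  expect_equal(free$n_free - con$n_free, 3)
  con2 <- suppressWarnings(
    fit_model(syn, d, group = "grp",
              group_equal = c("loadings", "intercepts"),
              se = FALSE, baseline = FALSE))
  expect_equal(free$n_free - con2$n_free, 6)
})

test_that("implied moments follow the structural composition", {
  m <- build_model("f =~ y1 + y2")
  labels <- compile_free_labels(m)
  theta <- setNames(numeric(length(labels)), labels)
  theta[c("f=~y1", "f=~y2")] <- c(0.6, 0.7)
  theta[c("y1~~y1", "y2~~y2")] <- c(0.5, 0.4)
  mom <- implied_moments(m, theta)
  expect_equal(mom$Sigma, matrix(c(0.36 + 0.5, 0.42, 0.42, 0.49 + 0.4), 2, 2,
                                 dimnames = list(c("y1", "y2"), c("y1", "y2"))))
  # zero loadings: diagonal Sigma
  theta[c("f=~y1", "f=~y2")] <- 0
  expect_equal(unname(implied_moments(m, theta)$Sigma),
               diag(c(0.5, 0.4)))
})

test_that("implied moments reproduce the published 4-test structure", {
  ref <- reference_estimates()
  lam <- unname(ref$loadings_corrected)
  m <- build_model(paste("g =~ y1 + y2 + y3 + y4", "y1 ~~ y3", sep = "\n"))
  labels <- compile_free_labels(m)
  theta <- setNames(numeric(length(labels)), labels)
  theta[paste0("g=~y", 1:4)] <- lam
  theta["y1~~y3"] <- ref$resid_corr
  theta[paste0("y", 1:4, "~~y", 1:4)] <- 1 - lam^2
  Sigma <- implied_moments(m, theta)$Sigma
  # hand-computed: lambda_i lambda_j off-diagonals, + rho for the MR-VNR pair
  for (i in 1:3) for (j in (i + 1):4) {
    expected <- lam[i] * lam[j] + if (i == 1 && j == 3) ref$resid_corr else 0
    expect_equal(unname(Sigma[i, j]), expected, tolerance = 1e-12)
  }
  expect_equal(unname(diag(Sigma)), rep(1, 4))
})

test_that("FIML log-likelihood matches closed-form densities", {
  m <- build_model("f =~ y1 + y2")
  labels <- compile_free_labels(m)
  theta <- setNames(numeric(length(labels)), labels)
  theta[c("y1~~y1", "y2~~y2")] <- 1

  # one subject, one variable, standard normal
  expect_equal(fiml_loglik(m, theta, data.frame(y1 = 0, y2 = NA)),
               -0.918939, tolerance = 1e-6)
  # a subject missing y2 contributes the univariate marginal of y1
  theta[c("f=~y1", "f=~y2")] <- c(0.6, 0.7)
  theta[c("y1~~y1", "y2~~y2")] <- c(0.64, 0.51)
  mom <- implied_moments(m, theta)
  x1 <- 0.3
  ll <- fiml_loglik(m, theta, data.frame(y1 = x1, y2 = NA))
  expect_equal(ll, dnorm(x1, 0, sqrt(mom$Sigma[1, 1]), log = TRUE),
               tolerance = 1e-10)

  # complete data, just-identified model: reaches the saturated maximum
  R <- matrix(c(1, .3, .4, .3, 1, .35, .4, .35, 1), 3, 3)
  d <- exact_cor_data(300, R, seed = 8)
  fit <- fit_model("f =~ y1 + y2 + y3", d, se = FALSE, baseline = FALSE)
  expect_equal(fit$df, 0)
  expect_lt(abs(fit$chisq), 1e-5)   # df = 0: model reaches saturated ll
})

test_that("likelihood is invariant to variable reordering", {
  coh <- small_cohort(n = 600, seed = 12)
  keep <- rowSums(!is.na(coh[, default_tests])) >= 1
  d <- coh[keep, ]
  f1 <- fit_model("g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time",
                  d, se = FALSE, baseline = FALSE)
  f2 <- fit_model("g =~ tmtb_time + vnr + symbol_digit + matrix_reasoning",
                  d, se = FALSE, baseline = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$loglik_sat, f2$loglik_sat, tolerance = 1e-6)
})

test_that("FIML on complete data equals complete-data ML", {
  set.seed(21)
  n <- 2000
  g <- rnorm(n)
  d <- data.frame(y1 = 0.6 * g + rnorm(n, 0, 0.8),
                  y2 = 0.7 * g + rnorm(n, 0, 0.7),
                  y3 = 0.5 * g + rnorm(n, 0, 0.9),
                  y4 = -0.6 * g + rnorm(n, 0, 0.8))
  fit <- fit_model("f =~ y1 + y2 + y3 + y4", d, se = FALSE, baseline = FALSE)
  oracle <- complete_ml_cfa(d)
  td <- tidy(fit)
  lam_fit <- td$estimate[td$class == "loading"]
  th_fit <- td$estimate[td$class == "resvar"]
  # oracle works on raw scale; fit on the z-scored metric -> rescale
  sds <- vapply(d, sd, numeric(1)) * sqrt((n - 1) / n)
  # compare standardized loadings instead (scale-free)
  lam_o <- oracle$lambda / sqrt(oracle$lambda^2 + oracle$theta)
  lam_f <- td$std[td$class == "loading"]
  expect_equal(lam_f, lam_o, tolerance = 1e-5)
})

test_that("fit recovers the tetrad closed form to 4 decimals", {
  R <- matrix(c(1, .2, .3, .2, 1, .35, .3, .35, 1), 3, 3)
  d <- exact_cor_data(600, R)
  fit <- fit_model("f =~ y1 + y2 + y3", d, se = FALSE, baseline = FALSE)
  td <- tidy(fit)
  expect_equal(td$std[td$class == "loading"],
               tetrad_loadings(.2, .3, .35), tolerance = 1e-4)
  expect_equal(tetrad_loadings(.2, .3, .35),
               c(0.4140, 0.4830, 0.7246), tolerance = 1e-4)
})

test_that("standardized solution is invariant to indicator rescaling", {
  coh <- small_cohort(n = 800, seed = 13)
  keep <- rowSums(!is.na(coh[, default_tests])) >= 1
  d <- coh[keep, c(default_tests, "age", "sex")]
  syn <- g_cfa_syntax(c("age", "sex"), list(c("matrix_reasoning", "vnr")))
  f1 <- fit_model(syn, d, covariates = c("age", "sex"), se = FALSE,
                  baseline = FALSE)
  d2 <- d
  d2$matrix_reasoning <- d2$matrix_reasoning * 1000 + 77
  d2$tmtb_time <- d2$tmtb_time / 360
  f2 <- fit_model(syn, d2, covariates = c("age", "sex"), se = FALSE,
                  baseline = FALSE)
  t1 <- tidy(f1); t2 <- tidy(f2)
  expect_equal(t1$std[t1$class == "loading"], t2$std[t2$class == "loading"],
               tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-5)
})

test_that("null data give near-zero loadings and chi-square near df", {
  set.seed(5)
  d <- as.data.frame(matrix(rnorm(16000), 4000, 4,
                            dimnames = list(NULL, paste0("y", 1:4))))
  fit <- fit_model("f =~ y1 + y2 + y3 + y4", d, se = FALSE, baseline = FALSE)
  td <- tidy(fit)
  # under the null only loading products are pinned: every implied
  # inter-test correlation must be at chance level
  lam <- td$std[td$class == "loading"]
  prods <- abs(outer(lam, lam))
  expect_lt(max(prods[upper.tri(prods)]), 3 * 3 / sqrt(4000))
  expect_lt(fit$chisq, qchisq(0.999, fit$df))
})

test_that("fit index arithmetic matches the worked example", {
  ind <- fit_index_values(chisq = 50, df = 5, baseline_chisq = 1000,
                          baseline_df = 10, n = 1000)
  expect_equal(round(ind$cfi, 4), 0.9545)
  expect_equal(round(ind$tli, 4), 0.9091)
  expect_equal(round(ind$rmsea, 4), 0.0949)
  # saturated model
  ind0 <- fit_index_values(0, 0, 100, 6, n = 500)
  expect_equal(ind0$cfi, 1)
  expect_equal(ind0$rmsea, 0)
  # information criteria definitions
  ind2 <- fit_index_values(10, 2, 100, 6, n = 200, loglik = -123.4,
                           n_free = 7)
  expect_equal(ind2$aic, -2 * -123.4 + 2 * 7)
  expect_equal(ind2$sabic, -2 * -123.4 + 7 * log((200 + 2) / 24))
})

test_that("nested comparison reports the chi-square difference test", {
  coh <- small_cohort(n = 1200, seed = 14)
  keep <- rowSums(!is.na(coh[, default_tests])) >= 1
  d <- coh[keep, ]
  syn <- "g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time"
  free <- fit_model(paste(syn, "matrix_reasoning ~~ vnr", sep = "\n"), d,
                    se = FALSE)
  con <- fit_model(syn, d, se = FALSE)
  cmp <- compare_nested(free, con)
  expect_equal(cmp$delta_df, 1)
  expect_gte(cmp$delta_chisq, 0)
  expect_equal(cmp$delta_chisq,
               2 * (free$loglik - con$loglik), tolerance = 1e-6)
  # identical models: no difference, p = 1
  cmp0 <- compare_nested(free, free)
  expect_equal(cmp0$delta_chisq, 0)
  expect_equal(cmp0$pvalue, 1)
  # the published age-invariance test statistic is significant
  expect_lt(pchisq(27.617, 3, lower.tail = FALSE), 0.001)
})

test_that("modification indices find the generating residual covariance", {
  spec <- default_population_spec(n = 20000, continuous = TRUE)
  coh <- generate_cohort(spec, seed = 15)
  keep <- rowSums(!is.na(coh[, default_tests])) >= 1
  d <- coh[keep, ]
  base <- fit_model("g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time",
                    d, se = FALSE)
  mi <- suppressWarnings(modification_indices(base))
  # the generating residual covariance is the top candidate
  expect_setequal(c(mi$lhs[1], mi$rhs[1]), c("matrix_reasoning", "vnr"))
  refit <- fit_model(
    "g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time
     matrix_reasoning ~~ vnr", d, se = FALSE)
  expect_gt(base$chisq - refit$chisq, 0)
  # candidates already free report nothing
  mi2 <- modification_indices(refit)
  expect_false(any(paste(mi2$lhs, mi2$rhs) %in%
                     c("matrix_reasoning vnr", "vnr matrix_reasoning")))
})

test_that("the score test matches the refit chi-square drop for local misfit", {
  # the quadratic (score-test) approximation is exact in the limit of a
  # small omitted parameter; check the 10% agreement there
  set.seed(44)
  n <- 50000
  g <- rnorm(n); u <- rnorm(n)
  d <- data.frame(y1 = 0.6 * g + 0.15 * u + rnorm(n, 0, sqrt(1 - .36 - .0225)),
                  y2 = 0.5 * g + rnorm(n, 0, sqrt(.75)),
                  y3 = 0.7 * g + 0.15 * u + rnorm(n, 0, sqrt(1 - .49 - .0225)),
                  y4 = -0.6 * g + rnorm(n, 0, 0.8))
  base <- fit_model("f =~ y1 + y2 + y3 + y4", d, se = FALSE)
  mi <- modification_indices(base)
  expect_setequal(c(mi$lhs[1], mi$rhs[1]), c("y1", "y3"))
  refit <- fit_model("f =~ y1 + y2 + y3 + y4\n y1 ~~ y3", d, se = FALSE)
  drop <- base$chisq - refit$chisq
  expect_lt(abs(mi$mi[1] - drop) / drop, 0.10)
  # expected parameter change agrees with the realized estimate
  est <- tidy(refit)$estimate[tidy(refit)$term == "y1~~y3"]
  expect_lt(abs(mi$epc[1] - est) / abs(est), 0.15)
})

test_that("model chi-square is calibrated for a correctly specified model", {
  # 60 replicates here (the acceptance suite runs 500): mean chi2 ~ df
  set.seed(99)
  nrep <- 60
  chis <- numeric(nrep)
  spec <- default_population_spec(n = 1500, continuous = TRUE)
  for (r in seq_len(nrep)) {
    coh <- generate_cohort(spec, seed = 1000 + r)
    d <- coh[, default_tests]
    fit <- fit_model(
      "g =~ matrix_reasoning + symbol_digit + vnr + tmtb_time
       matrix_reasoning ~~ vnr", d, se = FALSE, baseline = FALSE)
    chis[r] <- fit$chisq
  }
  df <- 1
  se_mean <- sqrt(2 * df / nrep)
  expect_lt(abs(mean(chis) - df), 3 * se_mean)
})
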