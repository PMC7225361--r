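test_that("covariate adjustment produces response-scale residuals", {
  set.seed(71)
  n <- 300
  x <- cbind(age = rnorm(n, 50, 10))
  y <- 1 + 0.05 * x[, 1] + rnorm(n)
  coh <- cohort_table(y, rbinom(n, 1, 0.5), x, "gaussian")
  adj <- adjust_covariates(coh)
  expect_lt(abs(sum(adj$residuals)), 1e-8)
  expect_lt(abs(sum(adj$residuals * x[, 1])), 1e-8)
  # intercept-only cases: centering on mean / prevalence
  coh0 <- cohort_table(y, coh$e, NULL, "gaussian")
  expect_equal(adjust_covariates(coh0)$residuals, as.numeric(y - mean(y)))
  yb <- rbinom(n, 1, 0.3)
  cohb <- cohort_table(yb, coh$e, NULL, "binomial")
  expect_equal(adjust_covariates(cohb)$residuals,
               as.numeric(yb - mean(yb)))
  expect_true(all(abs(adjust_covariates(cohb)$residuals) < 1))
})

test_that("OLS weights solve the normal equations and flag singularity", {
  set.seed(72)
  dos <- matrix(rbinom(50 * 5, 2, 0.4), 50, 5)
  panel <- make_panel(dos)
  eps <- rnorm(50)
  w <- fit_ols_weights(eps, panel)
  X <- cbind(1, unname(panel$dosages))  # panel may re-orient alleles
  oracle <- solve(crossprod(X), crossprod(X, eps))
  expect_equal(unname(c(w$beta0, w$beta)), drop(oracle), tolerance = 1e-10)
  # duplicated SNP column is exactly collinear
  panel_dup <- make_panel(cbind(dos, dos[, 1]))
  expect_error(fit_ols_weights(eps, panel_dup), "singular")
})

test_that("ridge weights agree with an independent coordinate-descent solver", {
  set.seed(73)
  sim <- make_sim_data(n = 300, L = 10, seed = 73)
  eps <- adjust_covariates(sim$cohort)
  lam <- 25
  w <- fit_penalized_weights(eps, sim$panel, "ridge", lambda = lam)
  G <- sim$panel$dosages
  # glmnet solves the same ridge objective once its lambda is mapped by n
  # and by the 1/n-denominator response SD it standardizes by internally
  n <- nrow(G)
  yc <- eps$residuals - mean(eps$residuals)
  s_n <- sqrt(sum(yc^2) / n)
  fit <- glmnet::glmnet(G, eps$residuals, alpha = 0,
                        lambda = lam * s_n / n,
                        standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(w$beta), unname(drop(as.matrix(fit$beta))),
               tolerance = 1e-6)
  # and with the closed form on centered data
  Gc <- scale(G, scale = FALSE)
  yc <- eps$residuals - mean(eps$residuals)
  closed <- solve(crossprod(Gc) + diag(lam, 10), crossprod(Gc, yc))
  expect_equal(unname(w$beta), unname(drop(closed)), tolerance = 1e-10)
})

test_that("penalty limits: ridge approaches OLS, large penalties collapse", {
  set.seed(74)
  dos <- matrix(rbinom(200 * 10, 2, 0.35), 200, 10)
  panel <- make_panel(dos)
  eps <- rnorm(200) + 0.1 * dos[, 3]
  ols <- fit_ols_weights(eps, panel)
  rr <- fit_penalized_weights(eps, panel, "ridge", lambda = 1e-8)
  expect_equal(rr$beta, ols$beta, tolerance = 1e-4)
  # a very large penalty reduces the model to intercept-only
  big <- fit_penalized_weights(eps, panel, "ridge", lambda = 1e12)
  expect_true(all(abs(big$beta) < 1e-6))
  lz <- fit_penalized_weights(eps, panel, "lasso", lambda = 1e12)
  expect_true(all(lz$beta == 0))
  expect_equal(lz$beta0, mean(eps))
})

test_that("lasso zeroes exactly at its entry penalty, below it selects", {
  set.seed(75)
  sim <- make_sim_data(n = 400, L = 12, seed = 75, multiplier = 4)
  eps <- adjust_covariates(sim$cohort)
  G <- sim$panel$dosages
  Gc <- scale(G, scale = FALSE)
  yc <- eps$residuals - mean(eps$residuals)
  lam_max <- 2 * max(abs(crossprod(Gc, yc)))
  at_max <- fit_penalized_weights(eps, sim$panel, "lasso",
                                  lambda = lam_max * 1.0001)
  expect_true(all(at_max$beta == 0))
  below <- fit_penalized_weights(eps, sim$panel, "lasso",
                                 lambda = lam_max * 0.5)
  expect_gt(sum(below$beta != 0), 0)
})

test_that("cross-validated penalties minimize the held-out MSE path", {
  sim <- make_sim_data(n = 400, L = 12, seed = 76, multiplier = 3)
  eps <- adjust_covariates(sim$cohort)
  for (m in c("ridge", "lasso", "enet")) {
    w <- fit_penalized_weights(eps, sim$panel, m, seed = 5)
    expect_equal(w$lambda, w$cv_mse_path$lambda[which.min(w$cv_mse_path$mse)])
    expect_equal(nrow(w$cv_mse_path), 100)
  }
  # fold assignment (and hence the fit) is deterministic given the seed
  w1 <- fit_penalized_weights(eps, sim$panel, "enet", seed = 9)
  w2 <- fit_penalized_weights(eps, sim$panel, "enet", seed = 9)
  expect_identical(w1$beta, w2$beta)
})

test_that("the GRS is standardized and flags degeneracy", {
  sim <- make_sim_data(n = 200, L = 6, seed = 77)
  eps <- adjust_covariates(sim$cohort)
  w <- fit_penalized_weights(eps, sim$panel, "ridge", lambda = 10)
  grs <- build_grs(sim$panel, w)
  expect_lt(abs(mean(grs$standardized)), 1e-8)
  expect_lt(abs(sd(grs$standardized) - 1), 1e-8)
  # affine relation between raw and standardized scores
  expect_equal(cor(grs$raw, grs$standardized), 1, tolerance = 1e-12)
  # single SNP with unit weight: the z-scored dosage
  p1 <- make_panel(sim$panel$dosages[, 1, drop = FALSE])
  w1 <- w; w1$beta <- c(rs1 = 1)
  g1 <- build_grs(p1, w1)
  d <- sim$panel$dosages[, 1]
  expect_equal(g1$standardized, (d - mean(d)) / sd(d))
  w0 <- w; w0$beta[] <- 0
  expect_error(build_grs(sim$panel, w0), class = "grsgxe_degenerate_grs")
})

test_that("interaction test matches the single-SNP Wald test when L = 1", {
  set.seed(78)
  panel <- simulate_ld_genotypes(600, 1, ld = ld_block_spec(1), maf = 0.3,
                                 seed = 78)
  g <- panel$dosages[, 1]
  e <- rbinom(600, 1, 0.5)
  y <- 0.2 * g + 0.3 * e + 0.25 * g * e + rnorm(600)
  coh <- cohort_table(y, e, NULL, "gaussian")
  res <- run_grs_pipeline(coh, panel, "ridge", seed = 1)
  # ridge shrinkage rescales the score, not the Wald z of its interaction
  expect_equal(res$p_value, single_snp_wald_p(coh, g), tolerance = 1e-6)
})

test_that("direction labels follow the sign of a significant interaction", {
  sim <- make_sim_data(n = 1500, L = 12, scenario = 9, multiplier = 4,
                       seed = 79)
  res <- run_grs_pipeline(sim$cohort, sim$panel, "ridge", seed = 2)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$gamma_int_hat, 0)
  expect_equal(res$direction, "attenuation")
  # non-significant results never claim a direction
  null_sim <- make_sim_data(n = 300, L = 12, seed = 80, null_int = TRUE)
  resn <- run_grs_pipeline(null_sim$cohort, null_sim$panel, "ridge",
                           seed = 2)
  if (resn$p_value >= 0.05) expect_equal(resn$direction, "none")
})

test_that("pipeline results are invariant to allele flips and score shifts", {
  sim <- make_sim_data(n = 500, L = 8, seed = 81, multiplier = 3)
  res <- run_grs_pipeline(sim$cohort, sim$panel, "ridge", seed = 3)
  # flip the coding of SNP 2 and refit from scratch
  dos2 <- sim$panel$dosages
  dos2[, 2] <- 2 - dos2[, 2]
  panel2 <- genotype_panel(dos2, sim$panel$variants, sim$panel$sample_ids)
  res2 <- run_grs_pipeline(sim$cohort, panel2, "ridge", seed = 3)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-10)
  expect_equal(res2$gamma_int_hat, res$gamma_int_hat, tolerance = 1e-10)
  # adding a constant to the raw score leaves the test untouched
  eps <- adjust_covariates(sim$cohort)
  w <- fit_penalized_weights(eps, sim$panel, "ridge", seed = 3)
  grs <- build_grs(sim$panel, w)
  shifted <- grs
  shifted$standardized <- (grs$raw + 5 - mean(grs$raw + 5)) /
    sd(grs$raw + 5)
  a <- test_grs_by_e(sim$cohort, grs)
  b <- test_grs_by_e(sim$cohort, shifted)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$gamma_int_hat, b$gamma_int_hat, tolerance = 1e-12)
})

test_that("degenerate lasso selections return a flagged null result", {
  sim <- make_sim_data(n = 300, L = 10, seed = 82, null_int = TRUE)
  coh <- sim$cohort
  coh$y <- rnorm(300, sd = 1e-8) + 5  # essentially constant phenotype
  expect_warning(
    res <- run_grs_pipeline(cohort_table(rep(1, 300), coh$e, NULL,
                                         "gaussian"),
                            sim$panel, "lasso", seed = 1),
    "constant"
  )
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "none")
})
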