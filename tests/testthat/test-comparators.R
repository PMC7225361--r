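test_that("sign-score weights are +/-1 for filtered SNPs and nu otherwise", {
  # independent SNPs so the non-causal ones genuinely fail the filter
  set.seed(91)
  panel <- simulate_ld_genotypes(800, 10, ld = ld_block_spec(rep(1, 10)),
                                 seed = 91)
  e <- rbinom(800, 1, 0.2)
  y <- 0.4 * panel$dosages[, 3] - 0.4 * panel$dosages[, 7] + rnorm(800)
  coh <- cohort_table(y, e, NULL, "gaussian")
  res <- sberia_test(coh, panel)
  scan <- attr(res, "marginal_scan")
  expect_equal(scan$selected, scan$p < 0.1)
  expect_true(all(scan$selected[c(3, 7)]))  # strong planted signals
  expect_false(all(scan$selected))          # noise SNPs mostly fail
  # filtered-out SNPs contribute exactly the nu offset; selected ones
  # contribute their marginal sign
  w <- ifelse(scan$selected, sign(scan$beta_hat), 0) + 1e-4
  expect_equal(unname(w[!scan$selected][1]), 1e-4)
  expect_equal(unname(w[3]), 1 + 1e-4)
  expect_equal(unname(w[7]), -1 + 1e-4)
})

test_that("the sign-score test stays defined when no SNP passes the filter", {
  set.seed(92)
  panel <- simulate_ld_genotypes(300, 6, seed = 92)
  coh <- cohort_table(rnorm(300), rbinom(300, 1, 0.5), NULL, "gaussian")
  res <- sberia_test(coh, panel, p_threshold = 1e-6)
  scan <- attr(res, "marginal_scan")
  expect_false(any(scan$selected))
  expect_true(is.finite(res$p_value))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("with one strongly associated SNP the sign-score p matches the Wald p", {
  set.seed(93)
  panel <- simulate_ld_genotypes(800, 1, ld = ld_block_spec(1), maf = 0.3,
                                 seed = 93)
  g <- panel$dosages[, 1]
  e <- rbinom(800, 1, 0.5)
  y <- 0.4 * g + 0.2 * e + 0.2 * g * e + rnorm(800)
  coh <- cohort_table(y, e, NULL, "gaussian")
  res <- sberia_test(coh, panel)
  expect_equal(res$p_value, single_snp_wald_p(coh, g), tolerance = 1e-6)
})

test_that("interaction Bayes factors behave like evidence", {
  # no evidence at z = 0: BF below 1, equal to the shrinkage factor
  expect_equal(compute_interaction_bf(0, 0.1, 0.04),
               sqrt(0.01 / (0.01 + 0.04)))
  expect_lt(compute_interaction_bf(0, 0.1, 0.04), 1)
  # strictly increasing in |z|
  z <- seq(0, 6, by = 0.5)
  bf <- compute_interaction_bf(z, 0.1, 0.04)
  expect_true(all(diff(bf) > 0))
  expect_equal(compute_interaction_bf(-3, 0.1, 0.04),
               compute_interaction_bf(3, 0.1, 0.04))
  # prior collapse: psi -> 0 gives BF -> 1
  expect_equal(compute_interaction_bf(2, 0.1, 1e-12), 1, tolerance = 1e-6)
  expect_error(compute_interaction_bf(Inf, 0.1, 0.04), "non-finite")
})

test_that("weighted chi-square tail probabilities match simulation", {
  lam <- c(3, 1.5, 0.5, 0.1)
  set.seed(94)
  draws <- colSums(lam * matrix(rchisq(4 * 200000, 1), 4))
  for (q in c(2, 5, 10, 20)) {
    expect_lt(abs(grsgxe:::mixture_chisq_p(q, lam) - mean(draws > q)),
              0.005)
  }
  # one-component mixture reduces to a scaled chi-square
  expect_equal(grsgxe:::mixture_chisq_p(7, 2),
               pchisq(3.5, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("variance-component test reduces to the single-SNP test at L = 1", {
  set.seed(95)
  rel_err <- replicate(8, {
    panel <- simulate_ld_genotypes(500, 1, ld = ld_block_spec(1),
                                   maf = 0.3, seed = sample.int(1e6, 1))
    g <- panel$dosages[, 1]
    e <- rbinom(500, 1, 0.5)
    y <- 0.1 * g + 0.2 * e + 0.15 * g * e + rnorm(500)
    coh <- cohort_table(y, e, NULL, "gaussian")
    p_vc <- iskat_test(coh, panel, seed = 1)$p_value
    p_wald <- single_snp_wald_p(coh, g)
    abs(p_vc - p_wald) / p_wald
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("the variance-component null distribution is exchangeable in E", {
  set.seed(96)
  qs <- replicate(60, {
    panel <- simulate_ld_genotypes(300, 8, seed = sample.int(1e6, 1))
    e <- rbinom(300, 1, 0.5)
    y <- 0.3 * e + rnorm(300)
    coh <- cohort_table(y, e, NULL, "gaussian")
    coh_perm <- cohort_table(y, sample(e), NULL, "gaussian")
    c(iskat_test(coh, panel, seed = 1)$Q,
      iskat_test(coh_perm, panel, seed = 1)$Q)
  })
  ks <- suppressWarnings(ks.test(qs[1, ], qs[2, ]))
  expect_gt(ks$p.value, 0.01)
})

test_that("adaptive BF combination tracks the single-SNP test at L = 1", {
  set.seed(97)
  ps <- t(replicate(25, {
    panel <- simulate_ld_genotypes(400, 1, ld = ld_block_spec(1),
                                   maf = 0.3, seed = sample.int(1e6, 1))
    g <- panel$dosages[, 1]
    e <- rbinom(400, 1, 0.5)
    b_int <- runif(1, 0, 0.25)
    y <- 0.1 * g + 0.2 * e + b_int * g * e + rnorm(400)
    coh <- cohort_table(y, e, NULL, "gaussian")
    res <- adabf_test(coh, panel, max_resamples = 4000,
                      stop_exceedances = 400, seed = 11)
    c(res$p_value, single_snp_wald_p(coh, g))
  }))
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.99)
})

test_that("adaptive BF resampling is seeded, bounded, and direction-free", {
  sim <- make_sim_data(n = 400, L = 8, seed = 98, multiplier = 3)
  r1 <- adabf_test(sim$cohort, sim$panel, seed = 7)
  r2 <- adabf_test(sim$cohort, sim$panel, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$n_resamples_used, r2$n_resamples_used)
  expect_true(r1$best_k >= 1 && r1$best_k <= 8)
  expect_true(all(r1$bf > 0))
  expect_null(r1$direction)
  expect_null(iskat_test(sim$cohort, sim$panel)$direction)
  # an overwhelming signal exhausts the budget and caps the p-value
  big <- make_sim_data(n = 2000, L = 8, seed = 99, multiplier = 10)
  rb <- adabf_test(big$cohort, big$panel, max_resamples = 500, seed = 3)
  expect_true(rb$capped)
  expect_equal(rb$p_value, 1 / 501)
})
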