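# Shared fixture builders and independent oracles used across test files.

# Tiny deterministic panel from an explicit dosage matrix.
make_panel <- function(dosages, positions = NULL, chromosome = "1") {
  L <- ncol(dosages)
  variants <- data.frame(
    id = paste0("rs", seq_len(L)),
    chromosome = chromosome,
    position = if (is.null(positions)) seq_len(L) * 1000 else positions,
    allele_minor = "A",
    allele_major = "G",
    stringsAsFactors = FALSE
  )
  genotype_panel(dosages, variants)
}

# A small simulated data set: panel + cohort with a planted interaction.
make_sim_data <- function(n = 500, L = 12, scenario = 1,
                          family = "gaussian", multiplier = 1,
                          seed = 1, null_int = FALSE) {
  panel <- simulate_ld_genotypes(n, L, seed = seed)
  causal <- assign_causal_snps(panel, 4, seed = seed + 1)
  eff <- sample_effects(scenario, family, seed = seed + 2,
                        effect_multiplier = multiplier,
                        null_interactions = null_int)
  e <- sample_exposure("binary", n, 0.2, seed = seed + 3)
  cohort <- simulate_trait(panel, causal, eff, e, seed = seed + 4)
  list(panel = panel, cohort = cohort, causal = causal, effects = eff)
}

# Independent Hardy-Weinberg oracle: absolute conditional probabilities of
# the heterozygote count given allele counts (Levene), summed directly.
hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  het <- seq(rare %% 2, rare, by = 2)
  # P(het) = n! / (nAA! het! naa!) * 2^het * nA! na! / (2n)!
  n_hom_rare <- (rare - het) / 2
  n_hom_common <- n - het - n_hom_rare
  logp <- lfactorial(n) - lfactorial(n_hom_common) - lfactorial(het) -
    lfactorial(n_hom_rare) + het * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp)
  p_obs <- p[match(n_Aa, het)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

# Bivariate standard-normal CDF by one-dimensional quadrature.
bvn_cdf <- function(x, y, rho) {
  if (abs(rho) < 1e-12) return(pnorm(x) * pnorm(y))
  f <- function(z) dnorm(z) * pnorm((y - rho * z) / sqrt(1 - rho^2))
  integrate(f, -Inf, x, rel.tol = 1e-10)$value
}

# Oracle dosage correlation of two SNPs sharing maf m whose latent normals
# have correlation rho, under the Gaussian-copula threshold construction.
copula_dosage_cor <- function(m, rho) {
  q <- c(-Inf, qnorm((1 - m)^2), qnorm((1 - m)^2 + 2 * m * (1 - m)), Inf)
  cdf <- function(x, y) {
    if (is.infinite(x) && x > 0) return(pnorm(min(y, Inf)))
    if (is.infinite(y) && y > 0) return(pnorm(min(x, Inf)))
    if (is.infinite(x) && x < 0) return(0)
    if (is.infinite(y) && y < 0) return(0)
    bvn_cdf(x, y, rho)
  }
  Exy <- 0
  for (a in 1:3) {
    for (b in 1:3) {
      pr <- cdf(q[a + 1], q[b + 1]) - cdf(q[a], q[b + 1]) -
        cdf(q[a + 1], q[b]) + cdf(q[a], q[b])
      Exy <- Exy + (a - 1) * (b - 1) * pr
    }
  }
  mu <- 2 * m
  v <- 2 * m * (1 - m)
  (Exy - mu^2) / v
}

# Wald p-value of the single-SNP interaction coefficient from the plain
# GLM y ~ g * e (+ covariates), normal reference.
single_snp_wald_p <- function(cohort, g) {
  dat <- data.frame(y = cohort$y, g = g, e = cohort$e)
  if (!is.null(cohort$x)) dat <- cbind(dat, cohort$x)
  fam <- if (cohort$family == "gaussian") gaussian() else binomial()
  fit <- glm(y ~ g * e + ., data = dat, family = fam)
  sm <- summary(fit)$coefficients
  z <- sm["g:e", 1] / sm["g:e", 2]
  2 * pnorm(-abs(z))
}
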