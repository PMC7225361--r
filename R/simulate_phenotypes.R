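#' The 14 interaction scenarios of the power study
#'
#' Sign patterns for the exposure main effect, the four SNP main effects,
#' and the four SNP-by-exposure interaction effects. "Exacerbation" means a
#' larger exposure strengthens the adverse (trait-increasing) influence of
#' the gene's risk alleles, "attenuation" that it weakens them, and
#' "cross-over" that it strengthens the effects of half of the causal SNPs
#' while weakening the others, leaving the aggregate direction undefined.
#'
#' @return A data frame with one row per scenario: `scenario` (1-14),
#'   `label`, `e_sign`, `g1..g4` (SNP main-effect signs, +1/-1), and
#'   `i1..i4` (interaction signs, +1/-1/0).
#' @export
scenario_table <- function() {
  sgn <- function(...) as.numeric(c(...))
  tab <- data.frame(
    scenario = 1:14,
    label = c("exacerbation", "attenuation", "exacerbation", "attenuation",
              "cross-over", "exacerbation", "attenuation",
              "exacerbation", "attenuation", "exacerbation", "attenuation",
              "cross-over", "exacerbation", "attenuation"),
    e_sign = c(rep(1, 7), rep(-1, 7)),
    stringsAsFactors = FALSE
  )
  g <- rbind(
    sgn(1, 1, 1, 1),    # 1
    sgn(1, 1, 1, 1),    # 2
    sgn(1, 1, 1, 1),    # 3
    sgn(1, 1, 1, 1),    # 4
    sgn(1, 1, 1, 1),    # 5
    sgn(1, 1, -1, -1),  # 6
    sgn(1, 1, -1, -1),  # 7
    sgn(1, 1, 1, 1),    # 8
    sgn(1, 1, 1, 1),    # 9
    sgn(1, 1, 1, 1),    # 10
    sgn(1, 1, 1, 1),    # 11
    sgn(1, 1, 1, 1),    # 12
    sgn(1, 1, -1, -1),  # 13
    sgn(1, 1, -1, -1)   # 14
  )
  i <- rbind(
    sgn(1, 1, 1, 1),     # 1
    sgn(-1, -1, -1, -1), # 2
    sgn(1, 1, 0, 0),     # 3
    sgn(-1, -1, 0, 0),   # 4
    sgn(1, 1, -1, -1),   # 5
    sgn(1, 1, -1, -1),   # 6
    sgn(-1, -1, 1, 1),   # 7
    sgn(1, 1, 1, 1),     # 8
    sgn(-1, -1, -1, -1), # 9
    sgn(1, 1, 0, 0),     # 10
    sgn(-1, -1, 0, 0),   # 11
    sgn(1, 1, -1, -1),   # 12
    sgn(1, 1, -1, -1),   # 13
    sgn(-1, -1, 1, 1)    # 14
  )
  colnames(g) <- paste0("g", 1:4)
  colnames(i) <- paste0("i", 1:4)
  cbind(tab, g, i)
}

#' Fetch one scenario row
#'
#' @param scenario_id integer in 1..14.
#' @return Single-row data frame from [scenario_table()].
#' @export
get_scenario <- function(scenario_id) {
  stopifnot(scenario_id %in% 1:14)
  scenario_table()[scenario_id, , drop = FALSE]
}

# Expected sign of the GRS-by-E interaction coefficient for a scenario:
# +1 exacerbation, -1 attenuation, NA cross-over.
scenario_true_sign <- function(scenario_id) {
  lab <- get_scenario(scenario_id)$label
  switch(lab, exacerbation = 1, attenuation = -1, `cross-over` = NA_real_)
}

#' Sample an exposure vector
#'
#' Binary exposures are Bernoulli with `P(E = 1) = p_exposed` (0.2 or 0.5
#' in the study conditions); continuous exposures are normal with mean 0
#' and standard deviation 0.5.
#'
#' @param kind `"binary"` or `"continuous"`.
#' @param n number of subjects.
#' @param p_exposed exposure prevalence for the binary kind.
#' @param sd_e standard deviation for the continuous kind (default 0.5).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_exposure <- function(kind = c("binary", "continuous"), n,
                            p_exposed = 0.2, sd_e = 0.5, seed = 1) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "binary") {
      stopifnot(p_exposed > 0, p_exposed < 1)
      rbinom(n, 1, p_exposed)
    } else {
      rnorm(n, 0, sd_e)
    }
  })
}

#' Sample effect sizes for a scenario
#'
#' SNP main-effect magnitudes `|beta_G|` are uniform on `[0.04, 0.08]` for
#' continuous traits or `[log 1.05, log 1.15]` (log odds ratios) for binary
#' traits; the exposure effect magnitude is 0.3 or `log 1.3`; interaction
#' magnitudes `|beta_Int|` are drawn from the same range as the main
#' effects, independently of them, and entries the scenario sets to zero
#' stay exactly zero. Signs follow the scenario's pattern.
#'
#' @param scenario scenario id (1-14) or a row of [scenario_table()].
#' @param family `"gaussian"` or `"binomial"`.
#' @param seed integer seed.
#' @param intercept binomial intercept on the log-odds scale; `log(0.1/0.9)`
#'   (prevalence 10%) by default, `log(0.4/0.6)` for prevalence 40%.
#' @param effect_multiplier scales all `|beta_G|` and `|beta_Int|`
#'   magnitudes (1 = the study conditions).
#' @param null_interactions set all interaction effects to 0 (type-I-error
#'   generation).
#' @return An object of class `effect_config`: `beta_G` (length 4),
#'   `beta_E`, `beta_Int` (length 4, zeros where absent), `intercept`,
#'   `trait_family`, `scenario`.
#' @export
sample_effects <- function(scenario, family = c("gaussian", "binomial"),
                           seed = 1, intercept = log(0.1 / 0.9),
                           effect_multiplier = 1,
                           null_interactions = FALSE) {
  family <- match.arg(family)
  sc <- if (is.data.frame(scenario)) scenario else get_scenario(scenario)
  rng <- if (family == "gaussian") c(0.04, 0.08) else log(c(1.05, 1.15))
  be_mag <- if (family == "gaussian") 0.3 else log(1.3)
  g_signs <- as.numeric(sc[paste0("g", 1:4)])
  i_signs <- as.numeric(sc[paste0("i", 1:4)])
  with_seed(seed, {
    beta_G <- g_signs * runif(4, rng[1], rng[2]) * effect_multiplier
    # Independent draw for the interactions; structural zeros stay zero.
    beta_Int <- i_signs * runif(4, rng[1], rng[2]) * effect_multiplier
    if (null_interactions) beta_Int <- rep(0, 4)
    structure(
      list(beta_G = beta_G, beta_E = sc$e_sign * be_mag,
           beta_Int = beta_Int, intercept = intercept,
           trait_family = family, scenario = sc$scenario),
      class = "effect_config"
    )
  })
}

#' Simulate a trait from genotypes, exposure, and effect sizes
#'
#' Continuous traits: `Y = sum_d beta_Gd G_d + beta_E E +
#' sum_d beta_Intd G_d E + eps` with standard-normal errors. Binary traits:
#' `Y ~ Bernoulli(expit(beta_0 + linear predictor))`, sampled marginally
#' per subject (cohort-style, no case-control ascertainment); the intercept
#' `log(0.1/0.9)` or `log(0.4/0.6)` calibrates disease prevalence to 10% or
#' 40% when all other effects are zero.
#'
#' @param panel a [genotype_panel()].
#' @param causal integer indices of the 4 causal SNPs.
#' @param effects an `effect_config` from [sample_effects()].
#' @param e exposure vector from [sample_exposure()].
#' @param seed integer seed for the error/Bernoulli draws.
#' @return A `simulated_cohort`: a [cohort_table()] plus `causal_indices`,
#'   `effect_config` attributes.
#' @export
simulate_trait <- function(panel, causal, effects, e, seed = 1) {
  G <- panel$dosages[, causal, drop = FALSE]
  n <- nrow(G)
  if (length(e) != n) stop("exposure length does not match panel")
  if (length(causal) != length(effects$beta_G)) {
    stop("number of causal SNPs does not match effect vector")
  }
  lp <- drop(G %*% effects$beta_G) + effects$beta_E * e +
    drop((G * e) %*% effects$beta_Int)
  with_seed(seed, {
    if (effects$trait_family == "gaussian") {
      y <- lp + rnorm(n)
      out <- cohort_table(y, e, NULL, "gaussian")
    } else {
      pr <- expit(effects$intercept + lp)
      y <- rbinom(n, 1, pr)
      out <- cohort_table(y, e, NULL, "binomial")
    }
    attr(out, "causal_indices") <- causal
    attr(out, "effect_config") <- effects
    class(out) <- c("simulated_cohort", class(out))
    out
  })
}
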