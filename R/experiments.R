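#' Configuration of a simulation study
#'
#' Bundles the study conditions: trait family, exposure model, scenarios,
#' gene size, sample size, replicate count, the set of tests to run, the
#' significance level, and the master seed. Per-replicate seeds are
#' derived from the master seed by counter, so the entire study is a pure
#' function of its configuration.
#'
#' @param trait_family `"gaussian"` or `"binomial"`.
#' @param e_kind `"binary"` or `"continuous"` exposure.
#' @param e_param exposure prevalence `P(E = 1)` for binary exposures
#'   (0.2 or 0.5 in the study conditions); the standard deviation (0.5)
#'   for continuous ones.
#' @param scenario_ids scenarios from [scenario_table()] to simulate.
#' @param gene_size SNPs per gene (48, 95, or 242 in the study
#'   conditions).
#' @param n_subjects subjects per replicate (default 2000).
#' @param n_replicates simulation replicates per scenario.
#' @param methods subset of `"ridge"`, `"lasso"`, `"enet"`, `"sberia"`,
#'   `"iskat"`, `"adabf"`.
#' @param alpha nominal significance level (default 0.05).
#' @param prevalence disease prevalence for binary traits (0.1 or 0.4).
#' @param effect_multiplier scales all SNP main and interaction effect
#'   magnitudes (1 = the study conditions).
#' @param master_seed integer master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(trait_family = c("gaussian", "binomial"),
                         e_kind = c("binary", "continuous"),
                         e_param = 0.2,
                         scenario_ids = 1,
                         gene_size = 48,
                         n_subjects = 2000,
                         n_replicates = 500,
                         methods = c("ridge", "lasso", "enet", "sberia"),
                         alpha = 0.05,
                         prevalence = 0.1,
                         effect_multiplier = 1,
                         master_seed = 1) {
  trait_family <- match.arg(trait_family)
  e_kind <- match.arg(e_kind)
  if (e_kind == "continuous" && missing(e_param)) e_param <- 0.5
  methods <- match.arg(methods,
                       c("ridge", "lasso", "enet", "sberia", "iskat",
                         "adabf", "ols"),
                       several.ok = TRUE)
  stopifnot(
    n_replicates >= 1, alpha > 0, alpha < 1,
    all(scenario_ids %in% 1:14), prevalence > 0, prevalence < 1
  )
  structure(
    list(trait_family = trait_family, e_kind = e_kind, e_param = e_param,
         scenario_ids = scenario_ids, gene_size = gene_size,
         n_subjects = n_subjects, n_replicates = n_replicates,
         methods = methods, alpha = alpha, prevalence = prevalence,
         effect_multiplier = effect_multiplier, master_seed = master_seed),
    class = "study_config"
  )
}

grs_methods <- c("ridge", "lasso", "enet", "ols")

# One simulated replicate: genotypes, causal assignment, effects,
# exposure, trait, then every requested test. Returns a per-method list
# with p, direction (+1/-1/NA at the configured alpha), and the selected
# SNP index set of the filtering methods.
run_replicate <- function(config, scenario_id, rep_index,
                          null_interactions = FALSE) {
  seed0 <- derive_seed(config$master_seed,
                       rep_index * 101L + scenario_id)
  panel <- simulate_ld_genotypes(config$n_subjects, config$gene_size,
                                 seed = seed0)
  causal <- assign_causal_snps(panel, 4, seed = seed0 + 1L)
  effects <- sample_effects(
    scenario_id, config$trait_family, seed = seed0 + 2L,
    intercept = qlogis_safe(config$prevalence),
    effect_multiplier = config$effect_multiplier,
    null_interactions = null_interactions
  )
  e <- sample_exposure(config$e_kind, config$n_subjects,
                       p_exposed = config$e_param,
                       sd_e = if (config$e_kind == "continuous")
                                config$e_param else 0.5,
                       seed = seed0 + 3L)
  cohort <- simulate_trait(panel, causal, effects, e, seed = seed0 + 4L)

  out <- list(causal = causal, effects = effects)
  for (m in config$methods) {
    res <- switch(m,
      ridge = , lasso = , enet = , ols =
        run_grs_pipeline(cohort, panel, method = m, seed = seed0 + 5L,
                         alpha = config$alpha),
      sberia = sberia_test(cohort, panel, alpha = config$alpha),
      iskat = iskat_test(cohort, panel, seed = seed0 + 5L),
      adabf = adabf_test(cohort, panel, seed = seed0 + 6L)
    )
    sel <- if (m %in% c("lasso", "enet")) {
      which(attr(res, "weights")$beta != 0)
    } else if (m == "sberia") {
      which(attr(res, "marginal_scan")$selected)
    } else NULL
    dir_sign <- if (m %in% c(grs_methods, "sberia")) {
      g <- res$gamma_int_hat
      if (is.na(g)) NA_real_ else sign(g)
    } else NA_real_
    out[[m]] <- list(p = res$p_value, dir_sign = dir_sign, selected = sel)
  }
  out
}

#' Type-I error study under the no-interaction null
#'
#' Simulates replicates from the null data-generating process (SNP main
#' effects and the exposure effect present, every interaction effect
#' exactly zero) and reports each method's empirical rejection rate at the
#' nominal level with Wilson confidence intervals. Scenarios 1 and 8 are
#' the natural null scenarios (positive and negative exposure effect).
#'
#' @param config a [study_config()].
#' @return An object of class `study_summary` (see [run_power_study()]).
#' @export
run_type1_study <- function(config) {
  summarize_study(config, null_interactions = TRUE)
}

#' Power study over interaction scenarios
#'
#' Simulates replicates with nonzero interaction effects. For the
#' GRS-based tests (ridge/lasso/enet/sberia) power counts a replicate as a
#' success only when the interaction is significant AND the fitted
#' coefficient has the scenario's true sign; the variance-component and
#' Bayes-factor tests provide no direction, so their power is plain
#' rejection. Sign-misspecification (wrong-sign fraction among
#' rejections) and marginal-filtering SEN/PPV are accumulated alongside.
#'
#' @param config a [study_config()].
#' @return An object of class `study_summary`: data frame `rates` with one
#'   row per scenario x method (`rejection_rate`, `power`,
#'   `sign_misspec`, `sen`, `ppv`, CI bounds), plus the replicate-level
#'   records in `replicates`.
#' @export
run_power_study <- function(config) {
  summarize_study(config, null_interactions = FALSE)
}

summarize_study <- function(config, null_interactions) {
  rows <- list()
  reps_store <- list()
  for (sc in config$scenario_ids) {
    true_sign <- if (null_interactions) NA_real_ else scenario_true_sign(sc)
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      run_replicate(config, sc, r, null_interactions = null_interactions)
    })
    reps_store[[as.character(sc)]] <- reps
    for (m in config$methods) {
      p <- vapply(reps, function(x) x[[m]]$p, numeric(1))
      dirs <- vapply(reps, function(x) x[[m]]$dir_sign, numeric(1))
      rej <- p < config$alpha
      n_rep <- length(p)
      rejection_rate <- mean(rej)
      ci <- wilson_ci(sum(rej), n_rep)
      directional <- m %in% c(grs_methods, "sberia")
      if (null_interactions || !directional || is.na(true_sign)) {
        power <- if (directional && !null_interactions) NA_real_
                 else rejection_rate
        misspec <- NA_real_
      } else {
        power <- mean(rej & dirs == true_sign, na.rm = FALSE)
        misspec <- if (sum(rej) == 0) NA_real_
                   else sum(rej & dirs != true_sign) / sum(rej)
      }
      filt <- m %in% c("lasso", "enet", "sberia")
      if (filt) {
        sens <- vapply(reps, function(x) {
          filter_metrics(x[[m]]$selected, x$causal)["sen"]
        }, numeric(1))
        ppvs <- vapply(reps, function(x) {
          filter_metrics(x[[m]]$selected, x$causal)["ppv"]
        }, numeric(1))
        sen <- mean(sens)
        ppv <- mean(ppvs, na.rm = TRUE)
      } else {
        sen <- ppv <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, method = m, n_replicates = n_rep,
        rejection_rate = rejection_rate,
        ci_lower = ci["lower"], ci_upper = ci["upper"],
        power = power, sign_misspec = misspec, sen = sen, ppv = ppv,
        row.names = NULL
      )
    }
  }
  structure(
    list(rates = do.call(rbind, rows), config = config,
         null = null_interactions, replicates = reps_store),
    class = "study_summary"
  )
}

#' @export
print.study_summary <- function(x, ...) {
  cat(if (x$null) "Type-I error study\n" else "Power study\n")
  print(x$rates, digits = 3)
  invisible(x)
}

#' Sign-misspecification fraction among rejections
#'
#' Fraction of null-hypothesis rejections whose fitted interaction sign
#' contradicts the scenario's true interaction direction. Undefined for
#' cross-over scenarios, where the true aggregate sign itself is
#' undefined.
#'
#' @param summary a `study_summary` from [run_power_study()].
#' @param scenario_id scenario to extract.
#' @param method a directional method (`"ridge"`, `"lasso"`, `"enet"`,
#'   `"sberia"`).
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the method
#'   had no rejections.
#' @export
sign_misspecification <- function(summary, scenario_id, method) {
  if (is.na(scenario_true_sign(scenario_id))) {
    stop("sign-misspecification is undefined for cross-over scenarios: ",
         "the true interaction sign is unclear")
  }
  rows <- summary$rates
  hit <- rows$scenario == scenario_id & rows$method == method
  if (!any(hit)) stop("scenario/method not present in the study summary")
  out <- rows$sign_misspec[hit]
  if (is.na(out)) warning("no rejections: sign-misspecification undefined")
  out
}

#' Sensitivity and positive predictive value of marginal filtering
#'
#' `sen` is the fraction of the true trait-associated SNPs recovered by
#' the filter; `ppv` is the fraction of selected SNPs that are truly
#' trait-associated (`NA` when nothing is selected). For lasso/enet the
#' selected set is the SNPs with nonzero weights; for the sign-score test
#' it is the SNPs passing the marginal p < 0.1 filter.
#'
#' @param selected integer indices of the selected SNPs (possibly empty).
#' @param causal integer indices of the true causal SNPs.
#' @return Named numeric vector `c(sen, ppv)`.
#' @export
filter_metrics <- function(selected, causal) {
  tp <- length(intersect(selected, causal))
  c(sen = tp / length(causal),
    ppv = if (length(selected) == 0) NA_real_ else tp / length(selected))
}
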