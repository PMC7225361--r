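---
title: "Testing and interpreting gene-environment interaction with penalized genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing and interpreting gene-environment interaction with penalized genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A candidate gene that is robustly associated with a complex trait — *FTO*
with body-mass index is the canonical example — usually harbors many
common variants in strong linkage disequilibrium (LD). A natural
epidemiological question is whether an environmental factor E (regular
exercise, diet, adiposity) *attenuates* or *exacerbates* the adverse
influence of such a gene. Most set-based gene-environment interaction
(G×E) tests answer only "is there interaction?" with a p-value; they are
silent about its direction. A genetic risk score (GRS) reduces the gene
to a single axis — a weighted allele count oriented so that a larger
score always means a higher expected trait value — and the sign of its
interaction with E then has a direct reading: positive means E
strengthens the gene's adverse effect, negative means E weakens it.

`grsgxe` implements this two-stage GRS framework with internally
estimated weights, three competing set-based tests under a common
interface, and the simulation machinery needed to study all of them.

## The two-stage model

Let $Y_i$ be the phenotype (continuous or binary), $G_{ij} \in \{0,1,2\}$
the minor-allele count at SNP $j = 1..L$ of the gene, $E_i$ the exposure,
and $\mathbf{X}_i$ covariates.

**Stage one (weights).** The phenotype is first adjusted for covariates
alone: $g[E(Y_i)] = \alpha_0 + \boldsymbol\alpha'\mathbf{X}_i$, giving
response-scale residuals $\hat\varepsilon_i = Y_i - \hat\mu_{0i}$. The
residuals are then regressed on all $L$ SNPs jointly,

$$\hat{\boldsymbol\beta} = \arg\min_{\boldsymbol\beta}
\sum_i \Big(\hat\varepsilon_i - \beta_0 - \sum_j \beta_j G_{ij}\Big)^2
+ \lambda \, P(\boldsymbol\beta),$$

with $P$ the ridge ($\sum_j \beta_j^2$), lasso ($\sum_j |\beta_j|$), or
elastic-net ($\sum_j [\tfrac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|]$,
$\alpha = 0.5$) penalty and an unpenalized intercept. Because the SNPs of
a gene are strongly collinear, the unpenalized normal equations are often
singular — this is precisely why the penalty is there, and why no LD
pruning is needed. $\lambda$ is chosen to minimize the 10-fold
cross-validated mean squared held-out error over 100 log-spaced values.
The more conservative one-standard-error rule is deliberately *not* used:
a single gene explains little phenotypic variance, and at that
signal-to-noise level the 1-SE rule routinely selects zero SNPs.

**Stage two (test).** The raw score $GRS_i' = \sum_j \hat\beta_j G_{ij}$
is standardized to a Z-score and the GLM

$$g[E(Y_i)] = \gamma_0 + \gamma_G\,GRS_i + \gamma_E E_i +
\gamma_{Int}\,GRS_i \times E_i + \boldsymbol\gamma_C'\mathbf{X}_i$$

is fitted on the whole sample. The two-sided Wald test of
$H_0: \gamma_{Int} = 0$ is the interaction test; a significant positive
$\hat\gamma_{Int}$ is reported as *exacerbation*, a significant negative
one as *attenuation*. For binary traits $\exp(\hat\gamma_{Int})$ is the
odds-ratio modifier per SD of GRS. No data splitting is used: under the
null of no SNP-by-environment interaction the stage-one weights and the
stage-two interaction estimate are asymptotically independent, so
re-using the sample does not inflate the type-I error — a property the
type-I-error study verifies empirically rather than assumes.

Estimation with the sign constraint $\gamma_G > 0$ could add power but is
out of scope; the unconstrained GLM is used throughout.

## Competing tests

* **Sign-score test (`sberia_test`)** — stage one fits $L$ *separate*
  single-SNP regressions; SNP $j$ gets weight
  $I(p_j < 0.1)\,\mathrm{sign}(\hat\beta_j) + \nu$ with $\nu = 10^{-4}$.
  Stage two keeps all $L$ SNP main effects in the model (the score's own
  main effect would be collinear with them) and Wald-tests the
  GRS-by-E product. Because its filter looks at one SNP at a time it
  ignores LD, which costs accuracy in the direction call.
* **Variance-component score test (`iskat_test`)** — treats the per-SNP
  interaction coefficients as random with variance $\tau$ and score-tests
  $\tau = 0$. The null model (covariates, E, all SNP main effects) is fit
  with ridge regularization so it survives within-gene LD; the statistic
  is $Q = \|S^{*\prime} r\|^2$ with $S^*$ the interaction columns
  projected off the null design. The projection is a deliberate
  refinement: without it, main-effect signal that the ridge penalty
  leaves in the residuals leaks into the score and biases it; with it,
  the single-SNP case agrees with the classic score test exactly. The
  null distribution is a weighted sum of $\chi^2_1$ variables; tail
  probabilities come from Imhof's inversion integral evaluated piecewise
  with an analytic truncation bound (exact $\chi^2$ for one eigenvalue,
  Liu moment matching as a guarded fallback).
* **Adaptive Bayes-factor combination (`adabf_test`)** — fits the
  single-SNP interaction model per SNP, converts each Wald summary to a
  shrinkage-form Bayes factor
  $\sqrt{se^2/(se^2+\psi)}\exp\!\big(z^2\psi/2(se^2+\psi)\big)$ with
  prior variance $\psi = 0.04$ (prior SD 0.2, a weakly informative
  default exposed as a parameter), scans the partial sums of the $k$
  largest log-BFs over all $k$, and assesses the minimum per-$k$
  resampling p-value against multivariate-normal null z-scores whose
  correlation is estimated from the LD of the interaction score
  contributions. Resampling stops early once 50 null exceedances accrue
  (the Monte-Carlo p-value $(x+1)/(B+1)$ is then already resolved far
  above any interesting threshold); an exhausted budget with no
  exceedance reports the bound $1/(B+1)$ with a `capped` flag.

The variance-component and Bayes-factor tests never report a direction —
their alternatives are sign-free, and the package keeps that distinction
rather than inventing one.

## The simulators

**Genotypes.** Real candidate-gene panels cannot be redistributed, so
`simulate_ld_genotypes()` builds LD-structured panels by a Gaussian
copula: latent normal vectors with AR(1) correlation $\rho$ inside LD
blocks (independent across blocks), cut at the Hardy-Weinberg quantiles
of each SNP's minor allele frequency to give 0/1/2 dosages. Defaults —
blocks of about 12 SNPs, $\rho = 0.8$, MAF uniform on $[0.05, 0.5]$ —
reproduce the two features that actually matter to these methods: common
variant HWE marginals and strong local collinearity that makes $G'G$
near-singular. What the copula does *not* emulate is the irregular,
long-range, heterogeneous LD of real genes, allele-frequency/LD coupling,
or haplotype structure; passing tests on these panels therefore
demonstrate statistical validity and relative orderings, not numerical
equality with results on any real gene.

**Phenotypes.** Continuous traits follow
$Y_i = \sum_{d=1}^4 \beta_{G_d} G_{id} + \beta_E E_i +
\sum_d \beta_{Int_d} G_{id} E_i + \varepsilon_i$ with standard-normal
errors; binary traits follow the logistic analogue with intercept
$\log(0.1/0.9)$ or $\log(0.4/0.6)$, i.e. 10% or 40% prevalence, sampled
marginally per subject (cohort sampling, no case-control ascertainment).
Four causal SNPs are drawn uniformly per replicate; either all four or
only two also interact with E. Effect magnitudes: $|\beta_{G_d}|$ and
$|\beta_{Int_d}|$ uniform on $[0.04, 0.08]$ (continuous) or
$[\log 1.05, \log 1.15]$ (binary, read as per-allele log odds ratios for
main and interaction effects alike); $|\beta_E| = 0.3$ or $\log 1.3$.
Interaction magnitudes are drawn independently of the main effects so
the marginal-filtering methods get no free help. Exposures are
Bernoulli(0.2) or Bernoulli(0.5), or Normal(0, 0.5). The 14 sign
scenarios returned by `scenario_table()` cover exacerbation, attenuation,
and cross-over patterns under positive and negative exposure effects.

**Studies.** `run_type1_study()` / `run_power_study()` drive everything:
fresh genotypes, causal assignment, effects, exposure, and trait per
replicate, all seeds derived from one master seed by counter, so a study
is a pure function of its configuration. Power for the directional
(GRS-based) tests counts a replicate only when the interaction is
significant *and* its sign is correct; the sign-free tests count plain
rejections. Sign-misspecification is the wrong-sign fraction among
rejections, undefined by construction for cross-over scenarios.
Sensitivity (SEN) and positive predictive value (PPV) of the marginal
filtering use the nonzero-weight set (lasso/enet) or the $p<0.1$ set
(sign-score), against the 4 planted causal SNPs.

## Numerical choices worth knowing

* **Penalty scale.** The objective above — total RSS plus
  $\lambda P(\boldsymbol\beta)$ — is canonical, and all reported
  $\lambda$ values live on that scale. The ridge path is solved in
  closed form through an eigendecomposition. The lasso/enet paths use
  coordinate descent via glmnet (convergence threshold $10^{-8}$);
  because glmnet internally standardizes
  the response by its $1/n$-denominator SD and that rescales only the
  $\ell_2$ half of its penalty, the mapping uses an adjusted mixing
  weight $\tilde\alpha = \alpha / (\alpha + (1-\alpha)s_n)$ and
  $\lambda_{glmnet} = \lambda\,\alpha / (2n\tilde\alpha)$. This was
  verified against KKT conditions and closed forms; without it, fitted
  weights correspond to a slightly different mixing than requested.
* **Grids.** 100 log-spaced penalties from $\lambda_{max}$ (the smallest
  all-zero penalty, $2\max_j |G_{c,j}'\hat\varepsilon_c|/\alpha$, for
  lasso/enet; 1000 times the lasso entry point as a data-scaled cap for
  ridge, which never zeroes exactly) down to $10^{-4}\lambda_{max}$.
* **Folds.** Near-equal random fold sizes from a seeded permutation;
  the fold assignment, and hence the whole pipeline, is deterministic
  given (data, seed).
* **Degenerate scores.** When lasso/enet select no SNP the GRS is
  undefined; inside study loops this is reported as $p = 1$, direction
  `none`, with a machine-readable `degenerate` flag instead of an error.
* **Binary stage one** uses squared-error loss on the response-scale
  residuals (no IRLS); the GLM appears only in stage two.
* **Standardization** uses the sample SD with denominator $n-1$, on the
  whole sample, before the stage-two fit.
* **Missing genotypes** are mean-imputed per SNP before any regression;
  QC filters (call rate ≥ 95%, exact HWE $p \ge 5.7\times10^{-7}$,
  MAF ≥ 1%) are applied sequentially in that order, each counted against
  the survivors of the previous step. Gene regions are extracted with
  50 kb flanks, inclusive at both ends, on 1-based BIM coordinates.

## Scale of the shipped studies

The simulation studies run at desk scale: $n = 2000$ subjects per
replicate, a 48-SNP gene, 2000 replicates for size (500 for the
resampling-based comparators) and 500 for power, with a doubled
effect-size multiplier in the power-ordering checks so the orderings are
visible at this sample size. Rates and orderings are robust under this
reduction, but absolute power values are not comparable to studies run
at biobank scale ($n \approx 18{,}000$, 10,000/1,000 replicates); the
configuration object exposes `n_subjects`, `n_replicates`, `gene_size`,
and `effect_multiplier` to scale everything back up.

## Known limitations

* The copula genotype model understates LD heterogeneity; SEN/PPV
  absolute levels in particular depend on it.
* The variance-component and Bayes-factor tests are reimplementations
  faithful to their published descriptions, not to any specific release
  of the original software; internal tuning (ridge penalty selection,
  BF prior, resampling schedule) is documented above and in the help
  pages rather than inherited.
* Covariates enter simulation only through real-data mode; simulated
  traits contain none by design.
* Computation-time benchmarking is logged but never asserted.
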