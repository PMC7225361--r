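#' Sign-score set-based interaction test (SBERIA)
#'
#' Two-stage competitor built on marginal filtering: stage one regresses
#' the phenotype on each SNP separately (adjusting for covariates) and
#' records the coefficient `beta_j` and its p-value `p_j`; the GRS weight
#' of SNP j is `I(p_j < 0.1) * sign(beta_j) + nu`, i.e. +1/-1 for SNPs
#' passing the liberal marginal filter and only the tiny offset `nu`
#' otherwise. Stage two fits a GLM containing all L SNP main effects, the
#' exposure, the covariates, and the standardized-GRS-by-exposure product
#' term, and Wald-tests that term. The all-SNP main effects make a GRS
#' main-effect term redundant (the score is a linear combination of the
#' dosage columns), so none is included.
#'
#' @param cohort a [cohort_table()].
#' @param panel a [genotype_panel()].
#' @param p_threshold marginal p-value filter (default 0.1).
#' @param nu small offset added to every weight (default 1e-4) so the
#'   score is defined even when no SNP passes the filter.
#' @param alpha significance level for the direction label.
#' @return A `gxe_result` (method `"sberia"`) with the stage-one marginal
#'   scan attached as attribute `"marginal_scan"` (a data frame with
#'   `beta_hat`, `p`, `selected`) and any dropped aliased stage-two
#'   columns as attribute `"dropped"`.
#' @export
sberia_test <- function(cohort, panel, p_threshold = 0.1, nu = 1e-4,
                        alpha = 0.05) {
  G <- imputed_dosages(panel)
  n <- nrow(G)
  L <- ncol(G)
  y <- cohort$y
  gaussian_trait <- cohort$family == "gaussian"
  Xadj <- if (is.null(cohort$x)) matrix(1, n, 1)
          else cbind(1, cohort$x)

  beta_hat <- numeric(L)
  p_val <- numeric(L)
  if (gaussian_trait) {
    # Residualize y and every SNP on the covariates once, then each
    # single-SNP fit reduces to a simple regression with df = n - p - 1.
    qx <- qr(Xadj)
    My <- qr.resid(qx, y)
    MG <- qr.resid(qx, G)
    sxx <- colSums(MG^2)
    df <- n - ncol(Xadj) - 1
    beta_hat <- colSums(MG * My) / sxx
    rss <- sum(My^2) - beta_hat^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    p_val <- 2 * stats::pt(-abs(beta_hat / se), df)
  } else {
    for (j in seq_len(L)) {
      dat <- data.frame(y = y, g = G[, j])
      if (!is.null(cohort$x)) dat <- cbind(dat, cohort$x)
      fit <- glm(y ~ ., data = dat, family = binomial())
      sm <- summary(fit)$coefficients
      beta_hat[j] <- sm["g", 1]
      p_val[j] <- 2 * pnorm(-abs(sm["g", 3]))
    }
  }
  selected <- p_val < p_threshold
  w <- ifelse(selected, sign(beta_hat), 0) + nu
  raw <- drop(G %*% w)
  s <- sd(raw)
  if (s == 0) stop("constant SBERIA score: interaction is inestimable")
  score <- (raw - mean(raw)) / s

  # Stage two: all SNP main effects + E + GRS x E (+ covariates).
  if (gaussian_trait) {
    X <- cbind(`(Intercept)` = 1, E = cohort$e, grs_by_e = score * cohort$e,
               G, cohort$x)
    sm <- lm_wald(X, y)
    names(sm$coef) <- colnames(X)
    dropped <- colnames(X)[is.na(sm$coef)]
    if (is.na(sm$coef["grs_by_e"])) {
      stop("SBERIA stage-two design rank-deficient: interaction column ",
           "aliased after dropping: ", paste(dropped, collapse = ", "))
    }
    est <- unname(sm$coef["grs_by_e"])
    se <- sm$se[3]
    gE <- unname(sm$coef["E"])
  } else {
    dat <- data.frame(y = y, E = cohort$e, grs_by_e = score * cohort$e)
    dat <- cbind(dat, as.data.frame(G))
    if (!is.null(cohort$x)) dat <- cbind(dat, cohort$x)
    fit <- glm(y ~ ., data = dat, family = binomial())
    cf <- coef(fit)
    dropped <- names(cf)[is.na(cf)]
    if (is.na(cf["grs_by_e"])) {
      stop("SBERIA stage-two design rank-deficient: interaction column ",
           "aliased after dropping: ", paste(dropped, collapse = ", "))
    }
    smc <- summary(fit)$coefficients
    est <- smc["grs_by_e", 1]
    se <- smc["grs_by_e", 2]
    gE <- unname(smc["E", 1])
  }
  p <- 2 * pnorm(-abs(est / se))
  res <- new_gxe_result(
    gamma_int_hat = est, se = se, p_value = p,
    gamma_G_hat = NA_real_, gamma_E_hat = gE,
    alpha = alpha, n = n, family = cohort$family,
    method = "sberia", L = L
  )
  attr(res, "marginal_scan") <- data.frame(
    id = panel$variants$id, beta_hat = beta_hat, p = p_val,
    selected = selected
  )
  attr(res, "dropped") <- dropped
  res
}
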