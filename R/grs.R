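#' Covariate adjustment of the phenotype
#'
#' Regresses the phenotype on the non-genetic covariates alone (linear model
#' for continuous traits, logistic for binary) and returns the
#' response-scale residuals `eps_i = Y_i - mu0_i`, where `mu0_i` is the
#' fitted mean under the covariate-only model. With no covariates this is
#' centering on the sample mean (gaussian) or the sample prevalence
#' (binomial).
#'
#' @param cohort a [cohort_table()].
#' @return An object of class `adjusted_phenotype`: list with `residuals`
#'   (length n), `coefficients` of the null fit, and `fitted` means.
#' @export
adjust_covariates <- function(cohort) {
  y <- cohort$y
  if (is.null(cohort$x)) {
    if (cohort$family == "gaussian") {
      mu <- rep(mean(y), length(y))
      cf <- c(`(Intercept)` = mean(y))
    } else {
      mu <- rep(mean(y), length(y))
      cf <- c(`(Intercept)` = qlogis_safe(mean(y)))
    }
  } else {
    dat <- data.frame(y = y, cohort$x, check.names = FALSE)
    fit <- glm(y ~ ., data = dat,
               family = if (cohort$family == "gaussian") gaussian()
                        else binomial())
    if (cohort$family == "binomial" && !fit$converged) {
      stop("covariate-only logistic fit failed to converge ",
           "(possible separation)")
    }
    mu <- fitted(fit)
    cf <- coef(fit)
  }
  structure(
    list(residuals = as.numeric(y - mu), coefficients = cf,
         fitted = as.numeric(mu), family = cohort$family),
    class = "adjusted_phenotype"
  )
}

qlogis_safe <- function(p) {
  p <- min(max(p, 1e-12), 1 - 1e-12)
  log(p / (1 - p))
}

# n x L dosage matrix with per-SNP mean imputation of missing calls.
imputed_dosages <- function(panel) {
  G <- panel$dosages
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  G
}

#' Unpenalized least-squares SNP weights
#'
#' Exact OLS solution of the regression of the covariate-adjusted phenotype
#' on all L SNP dosages plus an intercept. Serves as the zero-penalty limit
#' of the ridge weights; with the strong local LD typical of a gene the
#' normal equations are often singular, which is the failure mode the
#' penalized fits exist to avoid.
#'
#' @param eps an [adjust_covariates()] result (or a numeric residual
#'   vector).
#' @param panel a [genotype_panel()].
#' @return A `penalized_weights` object with `method = "ols"`.
#' @export
fit_ols_weights <- function(eps, panel) {
  y <- residual_vector(eps)
  G <- imputed_dosages(panel)
  X <- cbind(`(Intercept)` = 1, G)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("singular design: SNP dosages are exactly collinear; ",
         "use a penalized method (ridge/lasso/enet)")
  }
  beta <- qr.coef(qr_x, y)
  new_weights(beta[1], beta[-1], "ols", lambda = 0, alpha_mix = NA_real_,
              cv_path = NULL, snp_ids = panel$variants$id)
}

residual_vector <- function(eps) {
  if (inherits(eps, "adjusted_phenotype")) eps$residuals else as.numeric(eps)
}

new_weights <- function(beta0, beta, method, lambda, alpha_mix, cv_path,
                        snp_ids) {
  names(beta) <- snp_ids
  structure(
    list(beta0 = unname(beta0), beta = beta, method = method,
         lambda = lambda, alpha_mix = alpha_mix, cv_mse_path = cv_path),
    class = "penalized_weights"
  )
}

#' @export
print.penalized_weights <- function(x, ...) {
  cat(sprintf(
    "penalized_weights: %s, L = %d, lambda = %.4g, %d nonzero slopes\n",
    x$method, length(x$beta), x$lambda, sum(x$beta != 0)
  ))
  invisible(x)
}

# Penalty grid on the total-RSS objective scale: 100 log-spaced values from
# lambda_max down to lambda_max * 1e-4. For lasso/enet lambda_max is the
# smallest penalty with all slopes zero; ridge never zeroes exactly, so its
# grid is capped at 1000x the lasso entry point.
lambda_grid <- function(Gc, yc, method, alpha_mix, n_lambda = 100) {
  g_max <- max(abs(crossprod(Gc, yc)))
  lam_max <- switch(method,
    lasso = 2 * g_max,
    enet = 2 * g_max / alpha_mix,
    ridge = 2000 * g_max
  )
  lam_max <- max(lam_max, .Machine$double.eps)
  exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_lambda))
}

# Closed-form ridge path. Minimizes RSS + lambda * sum(beta^2) with an
# unpenalized intercept: beta = (Gc'Gc + lambda I)^{-1} Gc'yc on centered
# data. Returns an L x n_lambda slope matrix.
# Closed-form univariate elastic net from centered cross-products
# (glmnet requires at least two predictors, so the L = 1 case is solved
# directly): g = <Gc, yc>, sxx = ||Gc||^2.
enet_path_1d_cp <- function(g, sxx, lambdas, alpha) {
  beta <- vapply(lambdas, function(l) {
    num <- abs(2 * g) - l * alpha
    if (num <= 0) 0 else sign(g) * num / (2 * sxx + l * (1 - alpha))
  }, numeric(1))
  matrix(beta, nrow = 1)
}

#' Penalized SNP-weight estimation with cross-validated penalty
#'
#' Regresses the covariate-adjusted phenotype on all L SNP dosages jointly,
#' minimizing the total residual sum of squares plus a penalty:
#' `lambda * sum(beta_j^2)` (ridge), `lambda * sum(|beta_j|)` (lasso), or
#' `lambda * sum((1 - alpha)/2 beta_j^2 + alpha |beta_j|)` (elastic net,
#' `alpha = 0.5` by default), with an unpenalized intercept. The penalty is
#' chosen as the minimizer of the 10-fold cross-validated mean squared
#' held-out prediction error over an internally generated log-spaced grid
#' of 100 values; the more conservative one-standard-error rule is not used
#' because at single-gene scale it tends to select zero SNPs. Binary traits
#' use the same squared-error criterion on the response-scale residuals.
#'
#' Ridge solves the closed form exactly; lasso and elastic net use
#' coordinate descent via \pkg{glmnet} with the penalty mapped onto the
#' total-RSS scale (`lambda_glmnet = lambda / (2n)`). Reported `lambda` is
#' always on the total-RSS scale.
#'
#' @param eps an [adjust_covariates()] result or numeric residual vector.
#' @param panel a [genotype_panel()].
#' @param method `"ridge"`, `"lasso"`, or `"enet"`.
#' @param alpha_mix elastic-net mixing weight in `[0, 1]` (0.5 for enet).
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param lambda optional fixed penalty (total-RSS scale); skips
#'   cross-validation.
#' @return A `penalized_weights` object: `beta0`, `beta` (length L, may
#'   contain exact zeros for lasso/enet), `method`, `lambda`, `alpha_mix`,
#'   and the `(lambda, mse)` cross-validation path.
#' @export
fit_penalized_weights <- function(eps, panel,
                                  method = c("ridge", "lasso", "enet"),
                                  alpha_mix = 0.5, folds = 10, seed = 1,
                                  lambda = NULL) {
  method <- match.arg(method)
  y <- residual_vector(eps)
  G <- imputed_dosages(panel)
  n <- nrow(G)
  L <- ncol(G)
  if (folds > n) stop("more cross-validation folds than observations")
  snp_ids <- panel$variants$id
  if (sd(y) == 0) {
    warning("constant adjusted phenotype: all SNP weights set to 0")
    return(new_weights(mean(y), rep(0, L), method, lambda = Inf,
                       alpha_mix = if (method == "ridge") 0
                                   else if (method == "lasso") 1
                                   else alpha_mix,
                       cv_path = NULL, snp_ids = snp_ids))
  }
  alpha_eff <- switch(method, ridge = 0, lasso = 1, enet = alpha_mix)
  gbar <- colMeans(G)
  # center the dosages once: slopes are unaffected (the intercept absorbs
  # the shift) and glmnet's coordinate descent converges much faster on
  # mean-zero columns
  G <- sweep(G, 2, gbar)
  lambdas <- if (is.null(lambda)) {
    lambda_grid(G, y - mean(y), method, alpha_eff)
  } else {
    as.numeric(lambda)
  }

  # Slopes and intercepts for every lambda on (uncentered) data; both the
  # closed-form ridge path and glmnet fit an unpenalized intercept, so no
  # explicit centering copies are needed.
  fit_path <- function(Gtr, ytr, lams) {
    ntr <- length(ytr)
    mg <- colMeans(Gtr)
    my <- mean(ytr)
    if (method == "ridge" || ncol(Gtr) == 1) {
      # centered cross-products without materializing centered matrices
      cp <- crossprod(Gtr) - ntr * tcrossprod(mg)
      gy <- drop(crossprod(Gtr, ytr)) - ntr * mg * my
      B <- if (method == "ridge") {
        eg <- eigen(cp, symmetric = TRUE)
        gty <- drop(crossprod(eg$vectors, gy))
        eg$vectors %*% (gty / outer(eg$values, lams, "+"))
      } else {
        enet_path_1d_cp(gy, cp[1, 1], lams, alpha_eff)
      }
      b0 <- my - drop(crossprod(mg, B))
    } else {
      # glmnet standardizes the response by its 1/n-denominator SD, which
      # rescales the l2 half of its penalty (but not the l1 half). Solving
      # the printed total-RSS objective at penalty lambda_p and mixing
      # alpha therefore needs an adjusted mixing weight and penalty:
      #   alpha_tilde = alpha / (alpha + (1 - alpha) * s_n)
      #   lambda_glmnet = lambda_p * alpha / (2 n alpha_tilde)
      s_n <- sqrt(sum((ytr - my)^2) / ntr)
      at <- alpha_eff / (alpha_eff + (1 - alpha_eff) * s_n)
      fit <- glmnet::glmnet(Gtr, ytr, family = "gaussian",
                            alpha = at,
                            lambda = lams * alpha_eff / (2 * ntr * at),
                            standardize = FALSE, intercept = TRUE,
                            thresh = 1e-8)
      B <- as.matrix(fit$beta)
      b0 <- as.numeric(fit$a0)
    }
    list(B = B, b0 = b0)
  }

  cv_path <- NULL
  if (is.null(lambda)) {
    fold_id <- make_folds(n, folds, seed)
    sq_err <- matrix(NA_real_, n, length(lambdas))
    for (k in seq_len(folds)) {
      te <- fold_id == k
      fit <- fit_path(G[!te, , drop = FALSE], y[!te], lambdas)
      pred <- G[te, , drop = FALSE] %*% fit$B +
        rep(fit$b0, each = sum(te))
      sq_err[te, seq_len(ncol(pred))] <- (y[te] - pred)^2
    }
    mse <- colMeans(sq_err)
    cv_path <- data.frame(lambda = lambdas, mse = mse)
    lambda_star <- lambdas[which.min(mse)]
  } else {
    lambda_star <- lambdas[1]
  }

  fit <- fit_path(G, y, if (is.null(lambda)) lambdas else lambda_star)
  idx <- if (is.null(lambda)) which.min(cv_path$mse) else 1L
  idx <- min(idx, ncol(fit$B))
  beta <- fit$B[, idx]
  beta0 <- fit$b0[idx] - sum(gbar * beta)  # undo the column centering
  new_weights(beta0, beta, method, lambda_star, alpha_eff, cv_path, snp_ids)
}

#' Build and standardize a genetic risk score
#'
#' The raw score of subject i is `GRS'_i = sum_j beta_j G_ij` (the
#' intercept is excluded); it is then transformed into a Z-score with
#' sample mean 0 and sample standard deviation 1 (denominator n - 1). By
#' construction of the weights, a larger standardized GRS is associated
#' with an increased phenotype.
#'
#' @param panel a [genotype_panel()].
#' @param weights a `penalized_weights` object.
#' @return An object of class `grs_vector`: list with `raw` and
#'   `standardized` score vectors and the generating `weights`.
#' @export
build_grs <- function(panel, weights) {
  G <- imputed_dosages(panel)
  if (length(weights$beta) != ncol(G)) {
    stop("weight vector length does not match the panel")
  }
  if (all(weights$beta == 0)) {
    stop(structure(
      class = c("grsgxe_degenerate_grs", "error", "condition"),
      list(message = paste0(
        "degenerate GRS: all SNP weights are exactly zero (",
        weights$method, " selected no SNPs)"), call = sys.call())
    ))
  }
  raw <- drop(G %*% weights$beta)
  s <- sd(raw)
  if (s == 0) {
    stop(structure(
      class = c("grsgxe_degenerate_grs", "error", "condition"),
      list(message = "degenerate GRS: raw score is constant",
           call = sys.call())
    ))
  }
  structure(
    list(raw = raw, standardized = (raw - mean(raw)) / s,
         weights = weights),
    class = "grs_vector"
  )
}

#' Test GRS-by-environment interaction
#'
#' Fits the generalized linear model
#' `g[E(Y)] = gamma_0 + gamma_G GRS + gamma_E E + gamma_Int GRS x E +
#' gamma_C' X` (identity link for continuous traits, logit for binary) and
#' performs the two-sided Wald test of `H0: gamma_Int = 0`. A significant
#' positive `gamma_Int` is labelled "exacerbation" (the exposure
#' strengthens the adverse influence of the gene), a significant negative
#' one "attenuation"; non-significant results carry direction "none". For
#' binary traits `exp(gamma_Int)` is the odds-ratio modifier per standard
#' deviation of GRS.
#'
#' @param cohort a [cohort_table()].
#' @param grs a [build_grs()] result (or numeric score vector).
#' @param alpha significance level used to declare a direction
#'   (default 0.05).
#' @return An object of class `gxe_result`: `gamma_int_hat`, `se`,
#'   `p_value`, `direction`, `gamma_G_hat`, `gamma_E_hat`, `n`, `family`.
#' @export
test_grs_by_e <- function(cohort, grs, alpha = 0.05) {
  score <- if (inherits(grs, "grs_vector")) grs$standardized
           else as.numeric(grs)
  e <- cohort$e
  if (sd(e) == 0) stop("constant exposure: interaction is inestimable")
  if (sd(score) == 0) stop("constant GRS: interaction is inestimable")
  if (cohort$family == "gaussian") {
    X <- cbind(1, score, e, if (!is.null(cohort$x)) cohort$x, score * e)
    sm <- lm_wald(X, cohort$y)
    k <- ncol(X)
    est <- sm$coef[k]
    se <- sm$se[k]
    gG <- sm$coef[2]
    gE <- sm$coef[3]
  } else {
    dat <- data.frame(y = cohort$y, GRS = score, E = e)
    if (!is.null(cohort$x)) dat <- cbind(dat, cohort$x)
    fit <- glm(y ~ GRS * E + ., data = dat, family = binomial())
    sm <- summary(fit)$coefficients
    if (!"GRS:E" %in% rownames(sm)) {
      stop("interaction term could not be estimated")
    }
    est <- sm["GRS:E", 1]
    se <- sm["GRS:E", 2]
    gG <- unname(sm["GRS", 1])
    gE <- unname(sm["E", 1])
  }
  z <- est / se
  # Two-sided Wald test (normal reference, as in standard GLM output).
  p <- 2 * pnorm(-abs(z))
  new_gxe_result(
    gamma_int_hat = est, se = se, p_value = p,
    gamma_G_hat = gG, gamma_E_hat = gE,
    alpha = alpha, n = length(cohort$y), family = cohort$family
  )
}

# Least-squares fit with Wald standard errors from the QR factorization.
# Rank-deficient designs get NA coefficients/SEs for aliased columns.
lm_wald <- function(X, y) {
  qr_x <- qr(X)
  cf <- qr.coef(qr_x, y)
  r <- qr.resid(qr_x, y)
  df <- length(y) - qr_x$rank
  s2 <- sum(r^2) / df
  se <- rep(NA_real_, ncol(X))
  keep <- qr_x$pivot[seq_len(qr_x$rank)]
  R <- qr.R(qr_x)[seq_len(qr_x$rank), seq_len(qr_x$rank), drop = FALSE]
  se[keep] <- sqrt(s2 * diag(chol2inv(R)))
  list(coef = unname(cf), se = se, df = df)
}

new_gxe_result <- function(gamma_int_hat, se, p_value, gamma_G_hat,
                           gamma_E_hat, alpha, n, family,
                           degenerate = FALSE, method = NULL,
                           lambda = NULL, alpha_mix = NULL, L = NULL) {
  direction <- if (degenerate || p_value >= alpha) {
    "none"
  } else if (gamma_int_hat > 0) "exacerbation" else "attenuation"
  structure(
    list(gamma_int_hat = gamma_int_hat, se = se, p_value = p_value,
         direction = direction, gamma_G_hat = gamma_G_hat,
         gamma_E_hat = gamma_E_hat, alpha = alpha, n = n, family = family,
         degenerate = degenerate, method = method, lambda = lambda,
         alpha_mix = alpha_mix, L = L),
    class = "gxe_result"
  )
}

#' @export
print.gxe_result <- function(x, ...) {
  cat(sprintf(
    "GRS x E interaction: gamma_Int = %.4f (SE %.4f), p = %.4g [%s]%s\n",
    x$gamma_int_hat, x$se, x$p_value, x$direction,
    if (isTRUE(x$degenerate)) " (degenerate GRS)" else ""
  ))
  if (x$family == "binomial" && is.finite(x$gamma_int_hat)) {
    cat(sprintf("  per-SD odds-ratio modifier exp(gamma_Int) = %.4f\n",
                exp(x$gamma_int_hat)))
  }
  invisible(x)
}

#' Run the full two-stage GRS interaction test
#'
#' Composition of [adjust_covariates()], [fit_penalized_weights()] (or
#' [fit_ols_weights()]), [build_grs()], and [test_grs_by_e()] on the whole
#' sample, without data splitting: under the null of no SNP-by-environment
#' interaction the estimated weights and the stage-two interaction
#' statistic are asymptotically independent, so reusing the sample
#' preserves the type-I error rate.
#'
#' If lasso/enet select zero SNPs the GRS is degenerate; the result then
#' carries `p_value = 1`, direction `"none"`, and `degenerate = TRUE`
#' rather than an error, so study loops keep running.
#'
#' @param cohort a [cohort_table()].
#' @param panel a [genotype_panel()].
#' @param method `"ridge"`, `"lasso"`, `"enet"`, or `"ols"`.
#' @param seed integer seed (cross-validation fold assignment).
#' @param alpha significance level for the direction label.
#' @param ... passed to [fit_penalized_weights()].
#' @return A `gxe_result` with the stage-one `method`, `lambda`,
#'   `alpha_mix`, and `L` recorded; the fitted weights are attached as
#'   attribute `"weights"`.
#' @export
run_grs_pipeline <- function(cohort, panel,
                             method = c("ridge", "lasso", "enet", "ols"),
                             seed = 1, alpha = 0.05, ...) {
  method <- match.arg(method)
  eps <- adjust_covariates(cohort)
  w <- if (method == "ols") {
    fit_ols_weights(eps, panel)
  } else {
    fit_penalized_weights(eps, panel, method = method, seed = seed, ...)
  }
  res <- tryCatch({
    grs <- build_grs(panel, w)
    test_grs_by_e(cohort, grs, alpha = alpha)
  }, grsgxe_degenerate_grs = function(cnd) {
    new_gxe_result(gamma_int_hat = NA_real_, se = NA_real_, p_value = 1,
                   gamma_G_hat = NA_real_, gamma_E_hat = NA_real_,
                   alpha = alpha, n = length(cohort$y),
                   family = cohort$family, degenerate = TRUE)
  })
  res$method <- method
  res$lambda <- w$lambda
  res$alpha_mix <- w$alpha_mix
  res$L <- length(w$beta)
  attr(res, "weights") <- w
  res
}
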