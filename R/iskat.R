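# Ridge fit of theta for design W with penalty lam on the columns flagged
# by `pen` (logical). Gaussian closed form.
ridge_solve <- function(W, y, pen, lam) {
  M <- crossprod(W)
  diag(M)[pen] <- diag(M)[pen] + lam
  solve(M, crossprod(W, y))
}

# Penalized IRLS for a logistic null model; penalty lam on `pen` columns.
pen_irls <- function(W, y, pen, lam, start = NULL, maxit = 50, tol = 1e-9) {
  theta <- if (is.null(start)) {
    c(qlogis_safe(mean(y)), rep(0, ncol(W) - 1))
  } else start
  for (it in seq_len(maxit)) {
    eta <- drop(W %*% theta)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    M <- crossprod(W, W * w)
    diag(M)[pen] <- diag(M)[pen] + lam
    theta_new <- drop(solve(M, crossprod(W, w * z)))
    if (max(abs(theta_new - theta)) < tol * (1 + max(abs(theta)))) {
      theta <- theta_new
      break
    }
    theta <- theta_new
  }
  eta <- drop(W %*% theta)
  mu <- expit(eta)
  list(theta = theta, mu = mu, w = pmax(mu * (1 - mu), 1e-8))
}

#' Variance-component score test for gene-environment interaction
#'
#' Treats the per-SNP interaction coefficients as random effects with mean
#' zero and variance `tau` and score-tests `H0: tau = 0`. The null model
#' contains the intercept, covariates, the exposure main effect, and all L
#' SNP main effects; the SNP main effects are fit with ridge
#' regularization (penalty chosen by 10-fold cross-validation) so the null
#' fit survives the strong LD-induced collinearity within a gene. The
#' score statistic is `Q = || S' r ||^2`, where `r` are the null-model
#' response residuals and `S` is the column-centered matrix of
#' SNP-by-exposure products. Under the null `Q` is distributed as a
#' weighted sum of one-degree chi-squares with weights given by the
#' eigenvalues of the null covariance of `S' r`; the tail probability is
#' computed by exact characteristic-function inversion with a
#' moment-matching fallback.
#'
#' This test returns no interaction direction: the variance-component
#' alternative `tau > 0` is sign-free.
#'
#' @param cohort a [cohort_table()].
#' @param panel a [genotype_panel()].
#' @param folds cross-validation folds for the null-model ridge penalty.
#' @param seed integer seed for the fold assignment.
#' @param n_lambda size of the penalty grid.
#' @return An object of class `vc_result`: `Q`, `eigenvalues`, `p_value`,
#'   `lambda` (null-model penalty), `n`, `L`.
#' @export
iskat_test <- function(cohort, panel, folds = 10, seed = 1, n_lambda = 30) {
  G <- imputed_dosages(panel)
  n <- nrow(G)
  L <- ncol(G)
  y <- cohort$y
  e <- cohort$e
  Z <- if (is.null(cohort$x)) cbind(`(Intercept)` = rep(1, n), E = e)
       else cbind(`(Intercept)` = 1, cohort$x, E = e)
  p_unpen <- ncol(Z)
  if (n <= p_unpen + L + 1) stop("sample too small for the null model")
  W <- cbind(Z, G)
  pen <- c(rep(FALSE, p_unpen), rep(TRUE, L))
  gaussian_trait <- cohort$family == "gaussian"

  # Penalty grid scaled to the marginal SNP-phenotype covariances.
  yc <- y - mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  g_max <- max(abs(crossprod(Gc, yc)))
  lambdas <- exp(seq(log(2000 * g_max), log(1e-3 * g_max),
                     length.out = n_lambda))

  fold_id <- make_folds(n, folds, seed)
  cv_mse <- matrix(NA_real_, folds, n_lambda)
  for (k in seq_len(folds)) {
    te <- fold_id == k
    Wtr <- W[!te, , drop = FALSE]
    ytr <- y[!te]
    if (gaussian_trait) {
      M0 <- crossprod(Wtr)
      b0 <- crossprod(Wtr, ytr)
      for (l in seq_len(n_lambda)) {
        M <- M0
        diag(M)[pen] <- diag(M)[pen] + lambdas[l]
        theta <- solve(M, b0)
        pred <- drop(W[te, , drop = FALSE] %*% theta)
        cv_mse[k, l] <- mean((y[te] - pred)^2)
      }
    } else {
      start <- NULL
      for (l in seq_len(n_lambda)) {  # warm start down the grid
        fit <- pen_irls(Wtr, ytr, pen, lambdas[l], start = start)
        start <- fit$theta
        mu_te <- expit(drop(W[te, , drop = FALSE] %*% fit$theta))
        cv_mse[k, l] <- mean((y[te] - mu_te)^2)
      }
    }
  }
  lam <- lambdas[which.min(colMeans(cv_mse))]

  # Interaction columns, projected off the (weighted) column space of the
  # null design. The projection makes the score exactly insensitive to
  # whatever main-effect signal the ridge penalty leaves in the residuals:
  # any null-model misfit lies in span(W) and S* is orthogonal to it.
  S <- sweep(G * e, 2, colMeans(G * e))
  project_off <- function(S, W, w) {
    sw <- sqrt(w)
    B <- qr.coef(qr(sw * W), sw * S)
    B[is.na(B)] <- 0  # aliased directions: any minimizer projects the same
    S - W %*% B
  }
  if (gaussian_trait) {
    theta <- ridge_solve(W, y, pen, lam)
    r <- y - drop(W %*% theta)
    M <- crossprod(W)
    diag(M)[pen] <- diag(M)[pen] + lam
    edf <- sum(diag(solve(M, crossprod(W))))
    sigma2 <- sum(r^2) / max(n - edf, 1)
    Sp <- project_off(S, W, rep(1, n))
    # A = (I - H) S* with H the (symmetric) ridge hat matrix
    A <- Sp - W %*% solve(M, crossprod(W, Sp))
    lam_k <- sigma2 * eigen(crossprod(A), symmetric = TRUE,
                            only.values = TRUE)$values
  } else {
    fit <- pen_irls(W, y, pen, lam)
    r <- y - fit$mu
    w <- fit$w
    M <- crossprod(W, W * w)
    diag(M)[pen] <- diag(M)[pen] + lam
    Sp <- project_off(S, W, w)
    # (I - Hw)' S* with Hw = W M^{-1} W' diag(w)
    HtS <- w * (W %*% solve(M, crossprod(W, Sp)))
    A <- sqrt(w) * (Sp - HtS)
    lam_k <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
  }
  Q <- sum(drop(crossprod(Sp, r))^2)
  if (!is.finite(Q)) stop("non-finite score statistic")
  lam_k <- pmax(lam_k, 0)
  p <- mixture_chisq_p(Q, lam_k)
  structure(
    list(Q = Q, eigenvalues = lam_k, p_value = p, lambda = lam,
         n = n, L = L, family = cohort$family),
    class = "vc_result"
  )
}

#' @export
print.vc_result <- function(x, ...) {
  cat(sprintf(
    "variance-component G x E score test: Q = %.3f, p = %.4g (L = %d)\n",
    x$Q, x$p_value, x$L
  ))
  invisible(x)
}
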