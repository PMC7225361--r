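expit <- function(x) 1 / (1 + exp(-x))

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Derive a replicate-level seed from a master seed by counter. Keeps values
# in the 32-bit signed range required by set.seed().
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 48271 + counter * 16807) %% 2147483647L)
}

# Deterministic, near-balanced 10-fold assignment.
make_folds <- function(n, folds, seed) {
  stopifnot(folds >= 2, folds <= n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

# Save/restore the RNG state so internal seeding does not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr with a local RNG seeded by `seed`, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}
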