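#' LD block specification for the genotype simulator
#'
#' @param block_sizes integer vector of SNPs per LD block (all >= 1).
#' @param within_block_rho latent AR(1) correlation between adjacent SNPs
#'   inside a block, in `[0, 1)`.
#' @param maf_range length-2 vector `(low, high)` of the minor allele
#'   frequency range, `0.01 <= low <= high <= 0.5`.
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(block_sizes, within_block_rho = 0.8,
                          maf_range = c(0.05, 0.5)) {
  stopifnot(
    all(block_sizes >= 1),
    within_block_rho >= 0, within_block_rho < 1,
    length(maf_range) == 2,
    maf_range[1] >= 0.01, maf_range[1] <= maf_range[2], maf_range[2] <= 0.5
  )
  structure(
    list(block_sizes = as.integer(block_sizes),
         within_block_rho = within_block_rho,
         maf_range = maf_range),
    class = "ld_block_spec"
  )
}

# Split a gene of L SNPs into blocks of ~`target` SNPs each.
default_blocks <- function(L, target = 12) {
  n_blocks <- max(1L, round(L / target))
  sizes <- rep(L %/% n_blocks, n_blocks)
  extra <- L - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Simulate an LD-structured common-variant genotype panel
#'
#' Gaussian-copula construction: for each subject a latent normal vector is
#' drawn with AR(1) correlation `rho` between adjacent SNPs inside each LD
#' block and independence across blocks. For SNP j with minor allele
#' frequency m_j the latent value is cut at the standard-normal quantiles of
#' `(1 - m_j)^2` and `(1 - m_j)^2 + 2 m_j (1 - m_j)`, yielding dosages
#' 0/1/2 with exact Hardy-Weinberg marginal proportions. Blockwise latent
#' correlation reproduces the local collinearity of real genes that makes
#' the unpenalized normal equations near-singular.
#'
#' @param n_subjects number of subjects.
#' @param n_snps gene size in SNPs (the simulation genes of interest have
#'   48, 95, and 242 common SNPs).
#' @param ld an [ld_block_spec()]; by default blocks of ~12 SNPs with
#'   `rho = 0.8` and MAFs uniform on `[0.05, 0.5]`.
#' @param maf optional vector of per-SNP MAFs (recycled); overrides the
#'   `maf_range` sampling.
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return A [genotype_panel()] with variant positions `1..n_snps` on
#'   chromosome `"1"`.
#' @export
simulate_ld_genotypes <- function(n_subjects, n_snps,
                                  ld = NULL, maf = NULL, seed = 1) {
  stopifnot(n_subjects >= 1, n_snps >= 1)
  if (is.null(ld)) ld <- ld_block_spec(default_blocks(n_snps))
  if (sum(ld$block_sizes) != n_snps) {
    stop("block sizes must sum to n_snps")
  }
  with_seed(seed, {
    m <- if (is.null(maf)) {
      runif(n_snps, ld$maf_range[1], ld$maf_range[2])
    } else {
      rep_len(maf, n_snps)
    }
    rho <- ld$within_block_rho
    z <- matrix(0, n_subjects, n_snps)
    j <- 0L
    for (b in ld$block_sizes) {
      e <- matrix(rnorm(n_subjects * b), n_subjects, b)
      z[, j + 1L] <- e[, 1L]
      if (b > 1L) {
        s <- sqrt(1 - rho^2)
        for (k in 2:b) {
          z[, j + k] <- rho * z[, j + k - 1L] + s * e[, k]
        }
      }
      j <- j + b
    }
    # HWE thresholds per SNP: P(0) = (1-m)^2, P(0 or 1) = (1-m)^2 + 2m(1-m).
    q0 <- qnorm((1 - m)^2)
    q1 <- qnorm((1 - m)^2 + 2 * m * (1 - m))
    dos <- sweep(z, 2, q0, ">") + sweep(z, 2, q1, ">")
    storage.mode(dos) <- "double"
    variants <- data.frame(
      id = sprintf("sim%d", seq_len(n_snps)),
      chromosome = "1",
      position = seq_len(n_snps),
      allele_minor = "A",
      allele_major = "B",
      stringsAsFactors = FALSE
    )
    genotype_panel(dos, variants)
  })
}

#' Randomly assign trait-associated SNPs
#'
#' Uniform draw without replacement over the SNPs of a panel; each
#' simulation replicate designates 4 trait-associated SNPs by default.
#'
#' @param panel a [genotype_panel()] (or an integer giving L directly).
#' @param n_causal number of causal SNPs (default 4).
#' @param seed integer seed.
#' @return Sorted integer vector of SNP column indices.
#' @export
assign_causal_snps <- function(panel, n_causal = 4, seed = 1) {
  L <- if (inherits(panel, "genotype_panel")) ncol(panel$dosages)
       else as.integer(panel)
  if (n_causal > L) stop("n_causal exceeds the number of SNPs")
  with_seed(seed, sort(sample.int(L, n_causal)))
}
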