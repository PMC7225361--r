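#' Construct a genotype panel
#'
#' A genotype panel holds an n x L additive-model dosage matrix (each entry
#' counts copies of the minor allele, 0/1/2, `NA` for missing calls) together
#' with per-variant metadata. Dosages are re-oriented on construction so that
#' every column counts the allele that is minor in the analyzed sample
#' (sample MAF <= 0.5); per-variant MAF, call rate, and the exact
#' Hardy-Weinberg p-value are (re)computed from the data.
#'
#' @param dosages n x L integer matrix with entries in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `id`, `chromosome`, `position`,
#'   `allele_minor`, `allele_major` (one row per column of `dosages`).
#'   Missing metadata columns are filled with placeholders.
#' @param sample_ids character vector of length n.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `variants` (with `maf`, `call_rate`, `hwe_p` columns), and
#'   `sample_ids`.
#' @export
genotype_panel <- function(dosages, variants = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% c(0, 1, 2, NA))) {
    stop("dosages must contain only 0, 1, 2, or NA")
  }
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  L <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(variants)) {
    variants <- data.frame(
      id = paste0("snp", seq_len(L)),
      chromosome = "1",
      position = seq_len(L),
      allele_minor = "A",
      allele_major = "B",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(variants) == L, length(sample_ids) == n)
  for (col in c("id", "chromosome", "allele_minor", "allele_major")) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_character_
    variants[[col]] <- as.character(variants[[col]])
  }
  if (is.null(variants$position)) variants$position <- seq_len(L)

  # Orient every SNP to count the sample-minor allele.
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    tmp <- variants$allele_minor[flip]
    variants$allele_minor[flip] <- variants$allele_major[flip]
    variants$allele_major[flip] <- tmp
  }
  variants$maf <- colMeans(dosages, na.rm = TRUE) / 2
  variants$call_rate <- colMeans(!is.na(dosages))
  variants$hwe_p <- vapply(seq_len(L), function(j) {
    g <- dosages[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  colnames(dosages) <- variants$id
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d subjects x %d variants (MAF %.3f-%.3f)\n",
    nrow(x$dosages), ncol(x$dosages),
    min(x$variants$maf), max(x$variants$maf)
  ))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

subset_panel <- function(panel, keep) {
  genotype_panel(
    panel$dosages[, keep, drop = FALSE],
    panel$variants[keep, , drop = FALSE],
    panel$sample_ids
  )
}

#' Read a PLINK 1 binary fileset
#'
#' Reads `prefix.bed`, `prefix.bim`, and `prefix.fam` (SNP-major bed
#' layout) into a [genotype_panel()]. Dosages are oriented to count the
#' sample-minor allele regardless of which allele the BIM codes as A1;
#' missing genotype calls are preserved as `NA`.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) {
    if (!file.exists(p)) stop("PLINK file not found: ", p)
  }
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chromosome", "id", "cm", "position",
                                  "a1", "a2"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  L <- nrow(bim)
  sample_ids <- as.character(fam[[2]])

  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file (bad magic number): ", paths[1])
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major bed files are supported: ", paths[1])
  }
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3 + bytes_per_snp * L
  if (length(raw) != expected) {
    stop(sprintf(
      "bed file size mismatch for %s: expected %d bytes, found %d",
      paths[1], expected, length(raw)
    ))
  }
  body <- as.integer(raw[-(1:3)])
  # Unpack 2-bit genotype codes: 00 hom A1, 01 missing, 10 het, 11 hom A2.
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = L)
  shift <- c(0L, 2L, 4L, 6L)
  body <- matrix(body, nrow = bytes_per_snp, ncol = L)
  for (k in 1:4) {
    codes[seq(k, by = 4, length.out = bytes_per_snp), ] <-
      bitwAnd(bitwShiftR(body, shift[k]), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # Dosage of A1: 00 -> 2 copies, 10 -> 1, 11 -> 0, 01 -> missing.
  dos <- matrix(NA_real_, n, L)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  variants <- data.frame(
    id = as.character(bim$id),
    chromosome = as.character(bim$chromosome),
    position = bim$position,
    allele_minor = as.character(bim$a1),
    allele_major = as.character(bim$a2),
    stringsAsFactors = FALSE
  )
  genotype_panel(dos, variants, sample_ids)
}

#' Write a genotype panel as a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: writes `prefix.bed` (SNP-major), `prefix.bim`,
#' and `prefix.fam`. A1 in the BIM is the minor allele, so dosages
#' round-trip exactly.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- nrow(panel$dosages)
  L <- ncol(panel$dosages)
  v <- panel$variants
  bim <- data.frame(v$chromosome, v$id, 0, v$position,
                    v$allele_minor, v$allele_major)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  # code: dosage 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(1L, 4 * ceiling(n / 4), L)  # pad positions read as missing
  d <- panel$dosages
  cd <- matrix(1L, n, L)
  cd[!is.na(d) & d == 2] <- 0L
  cd[!is.na(d) & d == 1] <- 2L
  cd[!is.na(d) & d == 0] <- 3L
  code[seq_len(n), ] <- cd
  bytes_per_snp <- ceiling(n / 4)
  idx <- function(k) seq(k, by = 4, length.out = bytes_per_snp)
  packed <- bitwOr(
    bitwOr(code[idx(1), , drop = FALSE],
           bitwShiftL(code[idx(2), , drop = FALSE], 2L)),
    bitwOr(bitwShiftL(code[idx(3), , drop = FALSE], 4L),
           bitwShiftL(code[idx(4), , drop = FALSE], 6L))
  )
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(packed)), con)
  invisible(prefix)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for departure from Hardy-Weinberg proportions,
#' summing the probabilities of all heterozygote counts (conditional on the
#' observed allele counts) that are no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("HWE test undefined: all genotype counts are zero")
  n_minor <- 2 * n_aa + n_Aa
  n_major <- 2 * n_AA + n_Aa
  if (n_minor > n_major) {  # symmetric; work with the rarer allele
    tmp <- n_minor; n_minor <- n_major; n_major <- tmp
  }
  # Feasible heterozygote counts share the parity of the rare-allele count.
  het <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het | allele counts) up to a constant (conditional distribution of
  # heterozygotes given allele counts; Levene/Haldane form).
  logp <- het * log(2) -
    lfactorial((n_minor - het) / 2) -
    lfactorial(het) -
    lfactorial((n_major - het) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- min(n_Aa, n_minor)  # observed het count (after allele relabeling)
  p_obs <- p[match(obs, het)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Quality-control filter for a genotype panel
#'
#' Applies the three per-SNP filters sequentially — call rate, exact
#' Hardy-Weinberg p-value, then minor allele frequency — with each removal
#' count taken against the survivors of the previous step.
#'
#' @param panel a [genotype_panel()].
#' @param min_call_rate minimum genotyping call rate (default 0.95).
#' @param hwe_threshold minimum exact HWE p-value (default 5.7e-7).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return A list with elements `panel` (the filtered panel) and `report`
#'   (class `qc_report`: removal counts per filter and `n_retained`).
#' @export
qc_filter <- function(panel, min_call_rate = 0.95, hwe_threshold = 5.7e-7,
                      min_maf = 0.01) {
  stopifnot(
    min_call_rate >= 0, min_call_rate <= 1,
    hwe_threshold >= 0, hwe_threshold <= 1,
    min_maf >= 0, min_maf <= 1
  )
  v <- panel$variants
  L <- nrow(v)
  pass_cr <- v$call_rate >= min_call_rate
  n_cr <- sum(!pass_cr)
  pass_hwe <- pass_cr & !is.na(v$hwe_p) & v$hwe_p >= hwe_threshold
  n_hwe <- sum(pass_cr) - sum(pass_hwe)
  pass_maf <- pass_hwe & v$maf >= min_maf
  n_maf <- sum(pass_hwe) - sum(pass_maf)
  if (!any(pass_maf)) {
    stop("no variants retained after quality-control filtering")
  }
  report <- structure(
    list(n_removed_callrate = n_cr, n_removed_hwe = n_hwe,
         n_removed_maf = n_maf, n_retained = sum(pass_maf), n_input = L),
    class = "qc_report"
  )
  list(panel = subset_panel(panel, which(pass_maf)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0("QC: %d variants in; removed %d (call rate), %d (HWE), ",
           "%d (MAF); %d retained\n"),
    x$n_input, x$n_removed_callrate, x$n_removed_hwe, x$n_removed_maf,
    x$n_retained
  ))
  invisible(x)
}

#' @rdname qc_filter
#' @param x a `qc_report`.
#' @export
qc_report_json <- function(x) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE)
}

#' Extract the variants of a gene region with flanks
#'
#' Retains variants on the stated chromosome whose 1-based position lies in
#' `[start - flank, end + flank]`, inclusive at both ends.
#'
#' @param panel a [genotype_panel()].
#' @param chromosome chromosome label matching the variant metadata.
#' @param start,end 1-based gene boundaries in base pairs, `start <= end`.
#' @param flank flanking width in base pairs added on both sides
#'   (default 50000, covering nearby regulatory sequence).
#' @return A [genotype_panel()] restricted to the window.
#' @export
extract_gene_region <- function(panel, chromosome, start, end,
                                flank = 50000) {
  stopifnot(start <= end, flank >= 0)
  v <- panel$variants
  keep <- v$chromosome == as.character(chromosome) &
    v$position >= start - flank & v$position <= end + flank
  if (!any(keep)) {
    stop(sprintf("no variants on chromosome %s in [%d, %d]",
                 chromosome, start - flank, end + flank))
  }
  subset_panel(panel, which(keep))
}

#' Construct a cohort table
#'
#' Phenotype, exposure, and optional covariates for the analysis sample,
#' aligned row-for-row with a genotype panel.
#'
#' @param y numeric phenotype vector; for `family = "binomial"` it must be
#'   coded 0/1.
#' @param e exposure vector (binary 0/1 or continuous).
#' @param x covariate matrix (n x p) or `NULL` for none.
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(y, e, x = NULL, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  y <- as.numeric(y)
  e <- as.numeric(e)
  stopifnot(length(y) == length(e))
  if (!is.null(x)) {
    x <- as.matrix(x)
    stopifnot(nrow(x) == length(y))
    if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  }
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial phenotype must be coded 0/1")
  }
  structure(list(y = y, e = e, x = x, family = family),
            class = "cohort_table")
}

#' Read a delimited phenotype/exposure/covariate table
#'
#' @param path tab- or comma-delimited text file with a header row.
#' @param pheno_col,env_col column names of the phenotype and exposure.
#' @param covar_cols character vector of covariate column names (may be
#'   empty).
#' @param family `"gaussian"` or `"binomial"`.
#' @param id_col optional sample-id column; if given, returned in the
#'   `sample_ids` attribute for alignment against a genotype panel.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, pheno_col, env_col, covar_cols = character(),
                        family = c("gaussian", "binomial"), id_col = NULL) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(pheno_col, env_col, covar_cols, id_col)) {
    if (!col %in% names(tab)) stop("column not found in cohort file: ", col)
  }
  x <- if (length(covar_cols)) {
    as.matrix(tab[, covar_cols, drop = FALSE])
  } else NULL
  out <- cohort_table(tab[[pheno_col]], tab[[env_col]], x, family)
  if (!is.null(id_col)) attr(out, "sample_ids") <- as.character(tab[[id_col]])
  out
}
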