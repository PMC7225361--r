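test_that("PLINK bed/bim/fam round-trips dosages, MAF, and call rate", {
  dos <- rbind(
    c(0, 1, 2),
    c(1, 0, 2),
    c(2, 0, 1),
    c(0, NA, 2),
    c(1, 1, 2)
  )
  panel <- make_panel(dos)
  prefix <- file.path(withr::local_tempdir(), "fix")
  write_plink(panel, prefix)
  back <- read_plink(prefix)
  expect_equal(back$dosages, panel$dosages, ignore_attr = FALSE)
  # hand counts: SNP1 minor-allele count 4 of 10 alleles
  expect_equal(back$variants$maf[1], 4 / 10)
  # one missing call among five subjects
  expect_equal(back$variants$call_rate[2], 1 - 1 / 5)
  expect_equal(back$sample_ids, panel$sample_ids)
})

test_that("alleles coded on the major strand are re-oriented to the minor", {
  # column 1 counts an allele at frequency 0.8: must be flipped
  dos <- cbind(c(2, 2, 2, 1, 1), c(0, 0, 1, 0, 1))
  panel <- make_panel(dos)
  expect_true(all(panel$variants$maf <= 0.5))
  expect_equal(unname(panel$dosages[, 1]), c(0, 0, 0, 1, 1))
  # flipped column swapped its allele labels
  expect_equal(panel$variants$allele_minor[1], "G")
  expect_equal(panel$variants$allele_major[2], "G")
})

test_that("read_plink reports missing and truncated files by name", {
  expect_error(read_plink("/nonexistent/prefix"), "nonexistent")
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "trunc")
  write_plink(make_panel(matrix(c(0, 1, 2, 1), 4, 3)), prefix)
  bed <- paste0(prefix, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))
  writeBin(raw[-length(raw)], bed)
  expect_error(read_plink(prefix), "size mismatch")
})

test_that("exact HWE p-values match direct enumeration of the conditional law", {
  # extreme all-heterozygote sample: overwhelming departure
  expect_lt(hwe_exact_p(0, 100, 0), 1e-10)
  # counts at exact HWE proportions are unremarkable
  expect_gte(hwe_exact_p(490, 420, 90), 0.05)
  cases <- list(c(25, 50, 25), c(490, 420, 90), c(10, 30, 60),
                c(5, 0, 5), c(80, 15, 5), c(1, 2, 3))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_oracle_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10)
  }
  expect_error(hwe_exact_p(0, 0, 0), "zero")
})

test_that("QC filters are sequential, counted stepwise, and idempotent", {
  set.seed(4)
  n <- 60
  good <- replicate(5, rbinom(n, 2, 0.3))
  low_cr <- rbinom(n, 2, 0.3)
  low_cr[1:6] <- NA                     # call rate 0.9 < 0.95
  bad_hwe <- rep(1, n)                  # all heterozygous
  rare <- c(1, rep(0, n - 1))           # maf ~0.008 < 0.01
  panel <- make_panel(cbind(good, low_cr, bad_hwe, rare))
  out <- qc_filter(panel)
  expect_equal(out$report$n_removed_callrate, 1)
  expect_equal(out$report$n_removed_hwe, 1)
  expect_equal(out$report$n_removed_maf, 1)
  expect_equal(out$report$n_retained, 5)
  expect_equal(out$report$n_retained + out$report$n_removed_callrate +
                 out$report$n_removed_hwe + out$report$n_removed_maf,
               out$report$n_input)
  # pass-through panel is returned unchanged
  clean <- qc_filter(make_panel(good))
  expect_equal(clean$panel$dosages, make_panel(good)$dosages)
  expect_equal(clean$report$n_removed_maf, 0)
  # idempotence
  twice <- qc_filter(out$panel)
  expect_equal(twice$panel$dosages, out$panel$dosages)
  expect_equal(twice$report$n_retained, out$report$n_retained)
  # all filtered away -> explicit error
  expect_error(qc_filter(make_panel(cbind(rare))), "no variants retained")
})

test_that("gene-region extraction is inclusive at the flanked boundaries", {
  start <- 53737875
  end <- 54148379
  pos <- c(start - 50001, start - 50000, start, end, end + 50000,
           end + 50001)
  dos <- matrix(rbinom(6 * 10, 2, 0.3), 10, 6)
  panel <- make_panel(dos, positions = pos, chromosome = "16")
  reg <- extract_gene_region(panel, "16", start, end, flank = 50000)
  expect_equal(reg$variants$position,
               c(start - 50000, start, end, end + 50000))
  # window bounds match the 50-kb flanked gene span on chr16
  expect_true(all(reg$variants$position >= 53687875))
  expect_true(all(reg$variants$position <= 54198379))
  # zero-flank region is a subset of the flanked region
  reg0 <- extract_gene_region(panel, "16", start, end, flank = 0)
  expect_true(all(reg0$variants$id %in% reg$variants$id))
  expect_error(extract_gene_region(panel, "2", start, end), "no variants")
})

test_that("delimited cohort tables load with named columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pheno.tsv")
  df <- data.frame(iid = paste0("S", 1:8), bmi = rnorm(8),
                   exercise = rbinom(8, 1, 0.5), age = 31:38)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  coh <- read_cohort(path, "bmi", "exercise", "age", "gaussian",
                     id_col = "iid")
  expect_equal(coh$y, df$bmi)
  expect_equal(coh$e, as.numeric(df$exercise))
  expect_equal(dim(coh$x), c(8, 1))
  expect_equal(attr(coh, "sample_ids"), df$iid)
  expect_error(read_cohort(path, "missing_col", "exercise"), "missing_col")
})
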