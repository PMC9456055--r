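test_that("phased VCF genotypes are parsed into haplotype codes", {
  co <- read_phased_cohort(tiny_vcf(c("0|1", "1|1")))
  expect_equal(co$samples, c("S1", "S2"))
  expect_equal(co$markers$alt_freq, 0.75)  # 3 ALT of 4 haplotypes
  expect_equal(co$markers$maf, 0.25)

  co <- read_phased_cohort(tiny_vcf(c("./.", "1|1")))
  expect_true(is.na(co$hap1[1, 1]))
  expect_equal(co$markers$n_hap, 2L)
  expect_equal(co$markers$alt_freq, 1)
})

test_that("unphased heterozygotes are rejected or set missing", {
  vcf <- tiny_vcf(c("0/1", "1|1"))
  expect_error(read_phased_cohort(vcf), "sample S1 at 1:100")
  co <- read_phased_cohort(vcf, require_phase = FALSE)
  expect_true(is.na(co$hap1[1, 1]))
  expect_equal(co$hap1[2, 1], 1L)
  # homozygous unphased genotypes are phase-irrelevant and accepted
  co2 <- read_phased_cohort(tiny_vcf(c("1/1", "0|0")))
  expect_equal(co2$hap1[, 1], c(S1 = 1L, S2 = 0L))
})

test_that("multiallelic records are rejected by default, splittable on request", {
  vcf <- tiny_vcf(c("0|1", "1|2"), alt = "G,T")
  expect_error(read_phased_cohort(vcf), "multiallelic")
  co <- read_phased_cohort(vcf, multiallelic = "split")
  expect_equal(nrow(co$markers), 2L)
  expect_setequal(co$markers$alt, c("G", "T"))
  g_col <- which(co$markers$alt == "G")
  t_col <- which(co$markers$alt == "T")
  # S1 0|1 is fully observed at the G-allele record
  expect_equal(unname(co$hap1[1, g_col]), 0L)
  expect_equal(unname(co$hap2[1, g_col]), 1L)
  # a haplotype carrying the other ALT is unrepresentable in the decomposed
  # biallelic record, and missing-as-a-unit masks its partner too
  expect_true(is.na(co$hap1[2, g_col]))
  expect_true(all(is.na(co$hap1[, t_col])))
  expect_equal(co$markers$alt_freq[g_col], 0.5)
})

test_that("write(read(vcf)) round-trips phased GT fields exactly", {
  lines <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
             paste(c("1", "100", "rs1", "A", "G", ".", "PASS", "RSQR=0.95",
                     "GT", "0|1", "1|1", "./."), collapse = "\t"),
             paste(c("2", "200", ".", "C", "T", ".", "PASS", ".",
                     "GT", "0|0", "1|0", "0|1"), collapse = "\t"))
  vcf <- write_vcf_file(lines)
  out <- tempfile(fileext = ".vcf")
  write_phased_cohort(read_phased_cohort(vcf), out)
  gt_cols <- function(f) {
    body <- grep("^#", readLines(f), invert = TRUE, value = TRUE)
    vapply(strsplit(body, "\t"), function(x) paste(x[10:12], collapse = " "), "")
  }
  expect_identical(gt_cols(out), gt_cols(vcf))
})

test_that("marker quality filter implements the two-threshold rule", {
  mk <- data.frame(chrom = "1", pos = 1:4, rsid = "", ref = "A", alt = "G",
                   rsqr = c(0.35, 0.35, 0.65, NA))
  # engineer MAFs via genotype counts: 100 samples
  n <- 100
  h <- function(k) c(rep(1L, k), rep(0L, n - k))
  hap1 <- cbind(h(2), h(0), h(0), h(50))   # with hap2 below: maf .02/.005/.005/.25
  hap2 <- cbind(h(2), h(1), h(1), h(0))
  co <- cohort_genotypes(sprintf("S%03d", 1:n), mk, hap1, hap2)
  expect_equal(co$markers$maf, c(0.02, 0.005, 0.005, 0.25))
  kept <- filter_markers_by_quality(co)
  # MAF>=1% & rsqr>0.3 kept; MAF<1% needs rsqr>0.6; missing rsqr kept
  expect_equal(kept$markers$pos, c(1L, 3L, 4L))
  expect_equal(kept$samples, co$samples)
  # idempotence
  expect_identical(filter_markers_by_quality(kept)$markers, kept$markers)
})

test_that("allele frequencies are estimated on the requested subset", {
  mk <- data.frame(chrom = "1", pos = 1:2, rsid = "", ref = "A", alt = "G")
  co <- cohort_genotypes(c("A", "B"), mk,
                         hap1 = matrix(c(1L, 0L, 0L, 0L), 2),
                         hap2 = matrix(c(0L, 0L, 0L, 0L), 2))
  af <- estimate_allele_frequencies(co)
  expect_equal(af$alt_freq, c(0.25, 0))
  expect_equal(af$maf, c(0.25, 0))
  expect_equal(af$n_hap, c(4L, 4L))
  af_b <- estimate_allele_frequencies(co, "B")
  expect_equal(af_b$alt_freq, c(0, 0))
  expect_error(estimate_allele_frequencies(co, character(0)), "empty")

  # all-missing site reports NA with n_hap 0
  co2 <- cohort_genotypes(c("A", "B"), mk[1, ],
                          hap1 = matrix(NA_integer_, 2),
                          hap2 = matrix(NA_integer_, 2))
  expect_true(is.na(estimate_allele_frequencies(co2)$alt_freq))
})

test_that("frequency estimates recover a known truth within binomial error", {
  truth <- 0.528
  n <- 1577
  se <- sqrt(truth * (1 - truth) / (2 * n))
  mk <- data.frame(chrom = "1", pos = 1, rsid = "rs396991", ref = "A", alt = "C")
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    co <- cohort_genotypes(sprintf("S%04d", 1:n), mk,
                           hap1 = matrix(rbinom(n, 1L, truth), n),
                           hap2 = matrix(rbinom(n, 1L, truth), n))
    af <- estimate_allele_frequencies(co)$alt_freq
    hits <- hits + (abs(af - truth) <= 3 * se)
  }
  expect_gte(hits, 99L)
})

test_that("reported frequencies always satisfy the MAF identity", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    m <- sample(3:10, 1)
    mk <- data.frame(chrom = "1", pos = seq_len(m), rsid = "", ref = "A", alt = "G")
    hap <- function() matrix(sample(c(0L, 1L, NA), n * m, TRUE,
                                    prob = c(.6, .3, .1)), n, m)
    co <- cohort_genotypes(sprintf("S%03d", seq_len(n)), mk, hap(), hap())
    af <- estimate_allele_frequencies(co)
    ok <- !is.na(af$alt_freq)
    expect_true(all(af$alt_freq[ok] >= 0 & af$alt_freq[ok] <= 1))
    expect_true(all(af$maf[ok] >= 0 & af$maf[ok] <= 0.5))
    expect_equal(af$maf[ok], pmin(af$alt_freq[ok], 1 - af$alt_freq[ok]))
  }
})
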