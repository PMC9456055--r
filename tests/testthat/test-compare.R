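load_all_annotations <- function() {
  rbind(load_clinical_annotations(pgx_extdata("clinical_annotations_high.tsv")),
        load_clinical_annotations(pgx_extdata("clinical_annotations_low_synthetic.tsv")))
}

test_that("allele-frequency comparison reproduces printed deltas", {
  st <- read.delim(pgx_extdata("af_study.tsv"))
  rf <- read.delim(pgx_extdata("af_reference.tsv"))
  fc <- compare_allele_frequencies(st, rf, load_all_annotations())
  row <- function(rs) fc[fc$rsid == rs, ]
  expect_equal(row("rs396991")$delta, 0.211)
  expect_equal(row("rs2359612")$delta, -0.114)
  expect_equal(row("rs2274567")$delta, 0.413)
  # sorted by |delta| descending
  expect_true(all(diff(abs(fc$delta)) <= 1e-12))
  # identical tables: all deltas 0, ratios 1
  id <- compare_allele_frequencies(st, st, load_all_annotations())
  expect_true(all(id$delta == 0))
  expect_true(all(id$ratio == 1))
})

test_that("comparison handles swapped, ambiguous and missing variants", {
  st <- data.frame(chrom = "1", pos = c(1L, 2L, 3L),
                   rsid = c("rsA", "rsB", "rsC"),
                   ref = c("A", "A", "G"), alt = c("G", "T", "C"),
                   alt_freq = c(0.6, 0.4, 0.3), stringsAsFactors = FALSE)
  rf <- data.frame(chrom = "1", pos = c(1L, 2L), rsid = c("rsA", "rsB"),
                   ref = c("G", "T"), alt = c("A", "A"),
                   alt_freq = c(0.7, 0.5), stringsAsFactors = FALSE)
  ann <- data.frame(annotation_id = 1:3, rsid = c("rsA", "rsB", "rsC"),
                    gene = "G", evidence_level = "3",
                    phenotype_category = "Other", drugs = "x",
                    pediatric = FALSE, high_evidence = FALSE,
                    stringsAsFactors = FALSE)
  expect_warning(fc <- compare_allele_frequencies(st, rf, ann),
                 "strand-ambiguous")
  # rsA swapped ref/alt: reference frequency flipped to 1 - 0.7
  expect_equal(fc$af_ref[fc$rsid == "rsA"], 0.3)
  expect_equal(fc$delta[fc$rsid == "rsA"], 0.3)
  # rsB is A/T (strand-ambiguous under a swap): dropped; rsC absent
  expect_setequal(attr(fc, "skipped"), c("rsB", "rsC"))

  # antisymmetry under study/reference exchange
  st2 <- st[1, ]; rf2 <- data.frame(chrom = "1", pos = 1L, rsid = "rsA",
                                    ref = "A", alt = "G", alt_freq = 0.25)
  f1 <- compare_allele_frequencies(st2, rf2, ann[1, ])
  f2 <- compare_allele_frequencies(rf2, st2, ann[1, ])
  expect_equal(f1$delta, -f2$delta)
  expect_equal(f1$ratio, 1 / f2$ratio)
})

test_that("the differentiation screen partitions by evidence and delta", {
  st <- read.delim(pgx_extdata("af_study.tsv"))
  rf <- read.delim(pgx_extdata("af_reference.tsv"))
  fc <- compare_allele_frequencies(st, rf, load_all_annotations())
  scr <- screen_differentiated_variants(fc)
  expect_equal(nrow(scr$high_abs), 13L)
  expect_equal(nrow(scr$high_up), 5L)
  expect_true(all(abs(scr$high_abs$delta) >= 0.05))
  expect_true(all(scr$low_up$delta >= 0.10))
  expect_true(all(scr$low_down$delta <= -0.10))

  # below-threshold high-evidence row lands in no tier
  toy <- data.frame(delta = c(0.049, 0.25, 0.12, -0.15, 0.05),
                    high_evidence = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  s2 <- screen_differentiated_variants(toy)
  expect_equal(nrow(s2$high_abs), 0L)
  expect_equal(s2$low_up$delta, c(0.25, 0.12))
  expect_equal(s2$low_down$delta, -0.15)

  # monotonicity: raising a cutoff never grows a tier
  s3 <- screen_differentiated_variants(fc, high_cut = 0.10)
  expect_lte(nrow(s3$high_abs), nrow(scr$high_abs))
  s4 <- screen_differentiated_variants(fc, low_up_cut = 0.25)
  expect_lte(nrow(s4$low_up), nrow(scr$low_up))
})

test_that("two-sided Fisher p-values match independent oracles", {
  expect_equal(fisher_exact_2x2(5, 10, 5, 10), 1.0)
  expect_equal(fisher_exact_2x2(0, 100, 0, 100), 1.0)
  # first-principles enumeration oracle on the worked example
  expect_equal(fisher_exact_2x2(3, 10, 7, 10), fisher_enum_oracle(3, 10, 7, 10),
               tolerance = 1e-14)
  expect_error(fisher_exact_2x2(1, 0, 1, 5), "positive")
  expect_error(fisher_exact_2x2(6, 5, 1, 5), "counts")

  set.seed(19)
  for (i in 1:200) {
    na <- sample(1:30, 1); nb <- sample(1:30, 1)
    a <- sample(0:na, 1); b <- sample(0:nb, 1)
    mine <- fisher_exact_2x2(a, na, b, nb)
    ft <- stats::fisher.test(matrix(c(a, na - a, b, nb - b), 2))$p.value
    expect_lt(abs(mine - min(ft, 1)), 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(23)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15))
    # q order respects p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("phenotype-frequency comparison reconstructs counts and tests them", {
  summ <- list(gene_phenotype = data.frame(gene = "G", phenotype = c("A", "B"),
                                           count = c(856, 721),
                                           frequency = c(0.543, 0.457)),
               cohort_size = 1577)
  class(summ) <- "pgx_cohort_summary"
  ref_equal <- data.frame(gene = "G", phenotype = c("A", "B"),
                          frequency = c(856, 721) / 1577, n_ref = 1577)
  out <- compare_phenotype_frequencies(summ, ref_equal)
  expect_true(all(out$p_value == 1))
  expect_true(all(!out$significant))

  # a phenotype absent from one side is tested against zero
  ref_extra <- rbind(ref_equal,
                     data.frame(gene = "G", phenotype = "C",
                                frequency = 0.10, n_ref = 1577))
  out2 <- compare_phenotype_frequencies(summ, ref_extra)
  expect_equal(out2$count_study[out2$phenotype == "C"], 0L)
  expect_equal(out2$count_ref[out2$phenotype == "C"], 158L)
  expect_lt(out2$p_value[out2$phenotype == "C"], 0.001)
  expect_true(all(out2$q_value >= out2$p_value - 1e-15))

  expect_error(compare_phenotype_frequencies(
    summ, data.frame(gene = "G", phenotype = "A", frequency = 0.5)), "n_ref")

  # randomized tables agree with the enumeration oracle
  set.seed(29)
  for (i in 1:20) {
    n_s <- sample(20:60, 1); n_r <- sample(20:60, 1)
    c_s <- sample(0:n_s, 1); c_r <- sample(0:n_r, 1)
    s <- list(gene_phenotype = data.frame(gene = "G", phenotype = "A",
                                          count = c_s, frequency = c_s / n_s),
              cohort_size = n_s)
    class(s) <- "pgx_cohort_summary"
    r <- data.frame(gene = "G", phenotype = "A", frequency = c_r / n_r,
                    n_ref = n_r)
    got <- compare_phenotype_frequencies(s, r)
    expect_equal(got$p_value[got$phenotype == "A"],
                 fisher_enum_oracle(c_s, n_s, c_r, n_r), tolerance = 1e-12)
  }
})
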