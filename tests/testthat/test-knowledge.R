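test_that("allele definitions load and validate", {
  defs <- g1_defs()
  expect_equal(length(defs$sites), 1L)
  expect_equal(nrow(defs$sites$G1), 2L)
  expect_equal(nrow(defs$alleles$G1), 3L)
  expect_equal(defs$reference_allele[["G1"]], "*1")

  vk <- vkorc1_defs()
  expect_equal(nrow(vk$sites$VKORC1), 1L)
  expect_setequal(vk$alleles$VKORC1$allele, c("-1639G", "-1639A"))
  expect_equal(vk$reference_allele[["VKORC1"]], "-1639G")
})

test_that("malformed allele definitions are rejected with named errors", {
  expect_error(load_allele_definitions(write_def_file(c(
    "G1\t*1\t1\t\t\t\t\t\t",
    "G1\t*2\t0\t1\t100\trs1\tA\tG\tG",
    "G1\t*2\t0\t1\t100\trs1\tA\tG\tG"))), "duplicate allele")
  # zero reference alleles
  expect_error(load_allele_definitions(write_def_file(
    "G1\t*2\t0\t1\t100\trs1\tA\tG\tG")), "exactly one reference")
  # two reference alleles
  expect_error(load_allele_definitions(write_def_file(c(
    "G1\t*1\t1\t\t\t\t\t\t",
    "G1\t*1b\t1\t\t\t\t\t\t"))), "exactly one reference")
  # ref == alt at a site
  expect_error(load_allele_definitions(write_def_file(c(
    "G1\t*1\t1\t\t\t\t\t\t",
    "G1\t*2\t0\t1\t100\trs1\tA\tA\tA"))), "must differ")
  # required allele neither ref nor alt
  expect_error(load_allele_definitions(write_def_file(c(
    "G1\t*1\t1\t\t\t\t\t\t",
    "G1\t*2\t0\t1\t100\trs1\tA\tG\tC"))), "required_allele")
})

test_that("the bundled 14-gene fixture covers the expected genes", {
  defs <- toy_defs()
  expect_setequal(names(defs$sites),
                  c("CFTR", "CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6",
                    "CYP3A5", "CYP4F2", "DPYD", "IFNL3", "NUDT15",
                    "SLCO1B1", "TPMT", "UGT1A1", "VKORC1"))
  expect_true(all(vapply(names(defs$sites), function(g) {
    sum(defs$alleles[[g]]$is_reference) == 1L
  }, TRUE)))
})

test_that("allele definitions round-trip through serialization", {
  defs <- toy_defs()
  path <- tempfile(fileext = ".tsv")
  write_allele_definitions(defs, path)
  defs2 <- load_allele_definitions(path)
  expect_equal(names(defs$sites), names(defs2$sites))
  for (g in names(defs$sites)) {
    expect_equal(defs$sites[[g]], defs2$sites[[g]])
    expect_equal(defs$alleles[[g]], defs2$alleles[[g]])
    expect_equal(defs$defining[[g]][order(defs$defining[[g]]$allele,
                                          defs$defining[[g]]$site_id), ],
                 defs2$defining[[g]][order(defs2$defining[[g]]$allele,
                                           defs2$defining[[g]]$site_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("phenotype map lookups are symmetric in the allele pair", {
  map <- toy_map()
  hit <- phenotype_lookup(map, "VKORC1", "-1639A", "-1639A")
  expect_equal(hit$phenotype, "Decreased warfarin dose")
  expect_true(hit$nontypical)
  a <- phenotype_lookup(map, "VKORC1", "-1639G", "-1639A")
  b <- phenotype_lookup(map, "VKORC1", "-1639A", "-1639G")
  expect_equal(a, b)
  expect_null(phenotype_lookup(map, "VKORC1", "-1639A", "*99"))
})

test_that("phenotype map round-trips and rejects invalid flags", {
  map <- toy_map()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_phenotype_map(map, p1, p2)
  map2 <- load_phenotype_map(p1, p2)
  expect_equal(map$entries[order(map$entries$key), c("gene", "phenotype", "key")],
               map2$entries[order(map2$entries$key), c("gene", "phenotype", "key")],
               ignore_attr = TRUE)

  # reserved label flagged nontypical
  ents <- tempfile(fileext = ".tsv"); flags <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tallele1\tallele2\tphenotype",
               "G1\t*1\t*1\tNot available"), ents)
  writeLines(c("gene\tphenotype\tnontypical",
               "G1\tNot available\t1"), flags)
  expect_error(load_phenotype_map(ents, flags), "reserved")

  # entry without a flag row
  writeLines(c("gene\tallele1\tallele2\tphenotype",
               "G1\t*1\t*1\tNormal Metabolizer"), ents)
  writeLines("gene\tphenotype\tnontypical", flags)
  expect_error(load_phenotype_map(ents, flags), "no nontypical flag")

  # malformed pair
  writeLines(c("gene\tallele1\tallele2\tphenotype",
               "G1\t*1\t\tNormal Metabolizer"), ents)
  expect_error(load_phenotype_map(ents, flags), "line 2")
})

test_that("gene-drug table filtering keeps only requested CPIC levels", {
  gd <- toy_gene_drug()
  expect_equal(sort(gd$drug[gd$gene == "CYP2C19"]),
               sort(c("amitriptyline", "citalopram", "sertraline",
                      "clopidogrel", "escitalopram", "imipramine",
                      "clomipramine", "doxepin", "trimipramine",
                      "voriconazole")))

  mixed <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tdrug\tcpic_level",
               "CYP2C19\tclopidogrel\tA",
               "CYP2C19\tlansoprazole\tB",
               "CYP2C19\tClopidogrel \tA"), mixed)
  out <- load_gene_drug_table(mixed)
  expect_equal(nrow(out), 1L)  # level filter + case-insensitive dedup
  expect_equal(out$drug, "clopidogrel")
  expect_equal(nrow(load_gene_drug_table(mixed, c("A", "B"))), 2L)

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\tdrug\tcpic_level", empty)
  expect_equal(nrow(load_gene_drug_table(empty)), 0L)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tdrug\tcpic_level", "G1\tx\tZ"), bad)
  expect_error(load_gene_drug_table(bad), "unknown CPIC level")
})

test_that("clinical annotations parse with a correct evidence partition", {
  ann <- load_clinical_annotations(pgx_extdata("clinical_annotations_high.tsv"))
  rit <- ann[ann$annotation_id == "1444608384", ]
  expect_equal(rit$rsid, "rs396991")
  expect_equal(rit$gene, "FCGR3A")
  expect_equal(rit$evidence_level, "2B")
  expect_equal(rit$phenotype_category, "Efficacy")
  expect_equal(rit$drugs, "rituximab")
  expect_false(rit$pediatric)
  expect_true(rit$high_evidence)

  # high/low partition is exhaustive and disjoint over the declared levels
  lv <- c("1A", "1B", "2A", "2B", "3", "4")
  expect_equal(is_high_evidence(lv), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(is_high_evidence("5"), "invalid evidence level")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c(paste("annotation_id", "rsid", "gene", "evidence_level",
                     "phenotype_category", "drugs", "pediatric", sep = "\t"),
               "1\trs1\tG1\t5\tDosage\tx\t0"), bad)
  expect_error(load_clinical_annotations(bad), "invalid evidence level")
})
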