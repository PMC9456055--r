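# shared fixture builders; everything is generated in code at test time

toy_defs_path <- function() pgx_extdata("toy_knowledge/allele_definitions.tsv")
toy_map_path <- function() pgx_extdata("toy_knowledge/phenotype_map.tsv")
toy_drug_path <- function() pgx_extdata("toy_knowledge/gene_drugs.tsv")

toy_defs <- function() load_allele_definitions(toy_defs_path())
toy_map <- function() load_phenotype_map(toy_map_path())
toy_gene_drug <- function() load_gene_drug_table(toy_drug_path())

# write a throwaway allele-definition TSV from row strings
write_def_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste("gene", "allele", "is_reference", "chrom", "pos", "rsid",
                     "ref", "alt", "required_allele", sep = "\t"), rows), path)
  path
}

# minimal two-site toy gene: *1 (ref), *2 = s1 ALT, *3 = s1+s2 ALT
g1_defs <- function() {
  load_allele_definitions(write_def_file(c(
    "G1\t*1\t1\t\t\t\t\t\t",
    "G1\t*2\t0\t1\t100\trs1\tA\tG\tG",
    "G1\t*3\t0\t1\t100\trs1\tA\tG\tG",
    "G1\t*3\t0\t1\t200\trs2\tC\tT\tT")))
}

# one-site VKORC1 promoter definition (-1639G reference, -1639A variant)
vkorc1_defs <- function() {
  load_allele_definitions(write_def_file(c(
    "VKORC1\t-1639G\t1\t\t\t\t\t\t",
    "VKORC1\t-1639A\t0\t16\t31107689\trs9923231\tC\tT\tT")))
}

write_vcf_file <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# hand-written 2-sample single-site VCF with configurable GTs
tiny_vcf <- function(gts, info = ".", alt = "G",
                     samples = paste0("S", seq_along(gts))) {
  write_vcf_file(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", alt, ".", "PASS", info, "GT", gts),
          collapse = "\t")))
}

# uniform background marker table for relatedness simulations
background_markers <- function(m, lo = 0.3, hi = 0.5, seed = 1) {
  set.seed(seed)
  data.frame(chrom = "20", pos = seq_len(m), rsid = "", ref = "A", alt = "G",
             alt_freq = stats::runif(m, lo, hi), stringsAsFactors = FALSE)
}

# independent step-up BH oracle, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# two-sided Fisher p by first-principles enumeration (choose() products,
# no dhyper), for small tables
fisher_enum_oracle <- function(a, na, b, nb) {
  k <- a + b
  support <- max(0, k - nb):min(na, k)
  prob <- vapply(support, function(x) {
    choose(na, x) * choose(nb, k - x) / choose(na + nb, k)
  }, 0)
  p_obs <- prob[match(a, support)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
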