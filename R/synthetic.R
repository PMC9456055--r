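# Synthetic phased cohorts with known star-allele truth, for end-to-end
# validation of the caller, profiler and relatedness stages.

#' Simulation configuration
#'
#' Describes a synthetic phased diploid cohort: per-gene star-allele
#' haplotype frequencies (haplotypes drawn i.i.d., i.e. Hardy-Weinberg
#' equilibrium within each gene, linkage equilibrium across genes), optional
#' neutral background markers, per-genotype missingness and unphasing rates,
#' trio structure, and variant-site pairs locked into perfect LD (r^2 = 1,
#' one underlying draw).
#'
#' @param n_samples Number of unrelated individuals.
#' @param seed Integer seed; one seeded generator drives the whole run.
#' @param hap_freqs Named list: gene -> named numeric vector of star-allele
#'   frequencies (each summing to 1 within 1e-9).
#' @param missingness_rate Per-genotype probability of being set missing
#'   (default 0).
#' @param unphase_rate Per-heterozygous-genotype probability of losing phase
#'   (default 0; homozygotes carry no phase information).
#' @param trio_count Number of father/mother/child trios appended by
#'   [simulate_trios()] (default 0).
#' @param ld_locked_pairs List of length-2 character vectors of `site_id`s
#'   (`"chrom:pos:ref:alt"`); the second site of each pair copies the
#'   haplotype carriage of the first.
#' @param background_sites Optional data frame `chrom`, `pos`, `rsid`,
#'   `ref`, `alt`, `alt_freq`: extra biallelic markers in linkage
#'   equilibrium, drawn i.i.d. per haplotype at the given truth frequency
#'   (emulating a genome-wide random marker set).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples, seed = 1L, hap_freqs = NULL,
                              missingness_rate = 0, unphase_rate = 0,
                              trio_count = 0L, ld_locked_pairs = list(),
                              background_sites = NULL) {
  stopifnot(n_samples >= 1, missingness_rate >= 0, missingness_rate <= 1,
            unphase_rate >= 0, unphase_rate <= 1, trio_count >= 0)
  if (!is.null(hap_freqs)) {
    for (g in names(hap_freqs)) {
      if (abs(sum(hap_freqs[[g]]) - 1) > 1e-9) {
        pgx_stop("haplotype frequencies of gene ", g, " must sum to 1")
      }
    }
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 hap_freqs = hap_freqs,
                 missingness_rate = missingness_rate,
                 unphase_rate = unphase_rate,
                 trio_count = as.integer(trio_count),
                 ld_locked_pairs = ld_locked_pairs,
                 background_sites = background_sites),
            class = "simulation_config")
}

#' Default star-allele haplotype frequencies for the bundled toy genes
#'
#' Frequencies chosen to emulate a South-European cohort: the VKORC1
#' promoter variant haplotype at 0.509 and the CYP4F2 *3 haplotype at 0.415
#' follow the study population, the remaining genes use typical European
#' star-allele frequencies on the toy definitions.
#'
#' @param defs A `gene_definition_set` (used to validate gene/allele names).
#' @return Named list of named frequency vectors, one per gene.
#' @export
default_hap_freqs <- function(defs) {
  raw <- list(
    CFTR    = c("*1" = 0.988, "F508del" = 0.010, "G551D" = 0.002),
    CYP2B6  = c("*1" = 0.72, "*6" = 0.25, "*4" = 0.03),
    CYP2C19 = c("*1" = 0.63, "*2" = 0.15, "*17" = 0.22),
    CYP2C9  = c("*1" = 0.80, "*2" = 0.13, "*3" = 0.07),
    CYP2D6  = c("*1" = 0.88, "*4" = 0.12),
    CYP3A5  = c("*1" = 0.112, "*3" = 0.888),
    CYP4F2  = c("*1" = 0.585, "*3" = 0.415),
    DPYD    = c("*1" = 0.962, "*2A" = 0.038),
    IFNL3   = c("*1" = 0.676, "*2" = 0.324),
    NUDT15  = c("*1" = 0.99, "*3" = 0.01),
    SLCO1B1 = c("*1" = 0.71, "*5" = 0.16, "*14" = 0.13),
    TPMT    = c("*1" = 0.963, "*2" = 0.002, "*3A" = 0.035),
    UGT1A1  = c("*1" = 0.70, "*28" = 0.30),
    VKORC1  = c("-1639G" = 0.491, "-1639A" = 0.509))
  raw <- raw[intersect(names(raw), names(defs$alleles))]
  for (g in names(defs$alleles)) {
    if (is.null(raw[[g]])) {
      # genes outside the bundled set: uniform over their declared alleles
      a <- defs$alleles[[g]]$allele
      raw[[g]] <- stats::setNames(rep(1 / length(a), length(a)), a)
    }
  }
  raw
}

# render a vector of star-allele names into a sites x n code matrix
render_haplotypes <- function(alleles_drawn, defs, gene) {
  st <- defs$sites[[gene]]
  req <- allele_requirements(defs, gene)
  codes <- matrix(0L, nrow(st), length(alleles_drawn),
                  dimnames = list(st$site_id, NULL))
  for (a in unique(alleles_drawn)) {
    r <- req[[a]]
    if (is.null(r)) pgx_stop("allele ", a, " not defined for gene ", gene)
    if (length(r)) codes[names(r), alleles_drawn == a] <- r
  }
  codes
}

simulate_engine <- function(config, defs, samples, drawn_by_gene) {
  n <- length(samples)
  mats <- list(); marker_rows <- list(); truth_rows <- list()
  for (g in names(defs$sites)) {
    d <- drawn_by_gene[[g]]
    h1 <- render_haplotypes(d$h1, defs, g)
    h2 <- render_haplotypes(d$h2, defs, g)
    cp <- canonical_pair(d$h1, d$h2, defs$reference_allele[[g]])
    truth_rows[[g]] <- data.frame(sample = samples, gene = g,
                                  allele1 = cp$allele1, allele2 = cp$allele2,
                                  stringsAsFactors = FALSE)
    if (nrow(defs$sites[[g]])) {
      mats[[g]] <- list(h1 = t(h1), h2 = t(h2))
      marker_rows[[g]] <- defs$sites[[g]][, c("chrom", "pos", "rsid", "ref", "alt")]
    }
  }
  bg <- config$background_sites
  if (!is.null(bg) && nrow(bg)) {
    b1 <- matrix(stats::rbinom(n * nrow(bg), 1L,
                               rep(bg$alt_freq, each = n)), n, nrow(bg))
    b2 <- matrix(stats::rbinom(n * nrow(bg), 1L,
                               rep(bg$alt_freq, each = n)), n, nrow(bg))
    mats[["<background>"]] <- list(h1 = b1, h2 = b2)
    marker_rows[["<background>"]] <- bg[, c("chrom", "pos", "rsid", "ref", "alt")]
  }
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL
  H1 <- do.call(cbind, lapply(mats, `[[`, "h1"))
  H2 <- do.call(cbind, lapply(mats, `[[`, "h2"))
  ids <- site_id(markers$chrom, markers$pos, markers$ref, markers$alt)
  colnames(H1) <- colnames(H2) <- ids

  for (pair in config$ld_locked_pairs) {
    if (!all(pair %in% ids)) {
      pgx_stop("ld_locked_pairs site not simulated: ",
               paste(setdiff(pair, ids), collapse = ", "))
    }
    H1[, pair[2]] <- H1[, pair[1]]
    H2[, pair[2]] <- H2[, pair[1]]
  }

  truth_freq <- data.frame(site_id = ids,
                           alt_freq = (colSums(H1) + colSums(H2)) / (2 * n),
                           stringsAsFactors = FALSE)

  phased <- matrix(TRUE, n, length(ids))
  if (config$missingness_rate > 0) {
    miss <- matrix(stats::runif(n * length(ids)) < config$missingness_rate,
                   n, length(ids))
    H1[miss] <- NA_integer_; H2[miss] <- NA_integer_
  }
  if (config$unphase_rate > 0) {
    het <- !is.na(H1) & !is.na(H2) & H1 != H2
    unph <- het & matrix(stats::runif(n * length(ids)) < config$unphase_rate,
                         n, length(ids))
    phased[unph] <- FALSE
  }
  cohort <- cohort_genotypes(samples, markers, H1, H2, phased)
  truth <- list(diplotypes = do.call(rbind, truth_rows),
                site_freq = truth_freq)
  rownames(truth$diplotypes) <- NULL
  list(cohort = cohort, truth = truth)
}

#' Simulate a phased cohort with known star-allele truth
#'
#' Per sample and gene, two haplotypes are drawn i.i.d. from the configured
#' star-allele frequency table (Hardy-Weinberg) and rendered to site-level
#' allele codes through the gene's defining sites; background markers, LD
#' locks, missingness and unphasing are applied as configured. The run is
#' fully deterministic given the seed, which is recorded in the VCF header.
#'
#' @param config A [simulation_config].
#' @param defs A `gene_definition_set`.
#' @param vcf_path Where to write the VCF (default: a tempfile).
#' @return A list: `vcf` (path), `truth` (list with `diplotypes` -- the
#'   sample x gene truth table in canonical order -- and `site_freq`, the
#'   realized pre-missingness ALT frequencies), and `cohort`, the in-memory
#'   [cohort_genotypes].
#' @export
simulate_cohort <- function(config, defs,
                            vcf_path = tempfile(fileext = ".vcf")) {
  if (is.null(config$hap_freqs)) config$hap_freqs <- default_hap_freqs(defs)
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  drawn <- lapply(names(defs$sites), function(g) {
    f <- config$hap_freqs[[g]]
    if (is.null(f)) pgx_stop("no haplotype frequencies for gene ", g)
    if (!all(names(f) %in% defs$alleles[[g]]$allele)) {
      pgx_stop("frequency given for unknown allele of gene ", g, ": ",
               paste(setdiff(names(f), defs$alleles[[g]]$allele), collapse = ", "))
    }
    list(h1 = sample(names(f), n, replace = TRUE, prob = f),
         h2 = sample(names(f), n, replace = TRUE, prob = f))
  })
  names(drawn) <- names(defs$sites)
  sim <- simulate_engine(config, defs, samples, drawn)
  write_phased_cohort(sim$cohort, vcf_path,
                      extra_header = paste0("##pgxprofiler_sim_seed=",
                                            config$seed))
  list(vcf = vcf_path, truth = sim$truth, cohort = sim$cohort)
}

#' Simulate unrelated individuals plus parent-parent-child trios
#'
#' Unrelated founders are simulated as in [simulate_cohort()]; each trio
#' adds two further founders and a child that inherits one haplotype from
#' each parent (chosen at random per gene and per background marker, i.e.
#' free recombination), so the expected parent-child IBD proportion is 0.5
#' by construction.
#'
#' @inheritParams simulate_cohort
#' @return As [simulate_cohort()], plus `pedigree`: data frame `father`,
#'   `mother`, `child`.
#' @export
simulate_trios <- function(config, defs,
                           vcf_path = tempfile(fileext = ".vcf")) {
  if (config$trio_count < 1L) pgx_stop("trio_count must be >= 1")
  if (is.null(config$hap_freqs)) config$hap_freqs <- default_hap_freqs(defs)
  set.seed(config$seed)
  n <- config$n_samples
  t <- config$trio_count
  samples <- c(sprintf("S%04d", seq_len(n)),
               as.vector(rbind(sprintf("F%03d", seq_len(t)),
                               sprintf("M%03d", seq_len(t)),
                               sprintf("C%03d", seq_len(t)))))
  n_founder_like <- n + 2L * t
  total <- n + 3L * t
  is_child <- grepl("^C", samples)
  fa <- match(sprintf("F%03d", seq_len(t)), samples)
  mo <- match(sprintf("M%03d", seq_len(t)), samples)
  ch <- match(sprintf("C%03d", seq_len(t)), samples)

  drawn <- lapply(names(defs$sites), function(g) {
    f <- config$hap_freqs[[g]]
    if (is.null(f)) pgx_stop("no haplotype frequencies for gene ", g)
    h1 <- character(total); h2 <- character(total)
    founders <- !is_child
    h1[founders] <- sample(names(f), sum(founders), replace = TRUE, prob = f)
    h2[founders] <- sample(names(f), sum(founders), replace = TRUE, prob = f)
    pick <- function(i) ifelse(stats::runif(length(i)) < 0.5, h1[i], h2[i])
    h1[ch] <- pick(fa)   # paternal transmitted haplotype
    h2[ch] <- pick(mo)   # maternal transmitted haplotype
    list(h1 = h1, h2 = h2)
  })
  names(drawn) <- names(defs$sites)

  # background markers: transmit per site (free recombination)
  bg <- config$background_sites
  sim_cfg <- config
  sim_cfg$background_sites <- NULL
  sim <- simulate_engine(sim_cfg, defs, samples, drawn)
  cohort <- sim$cohort
  if (!is.null(bg) && nrow(bg)) {
    m <- nrow(bg)
    B1 <- matrix(stats::rbinom(total * m, 1L, rep(bg$alt_freq, each = total)),
                 total, m)
    B2 <- matrix(stats::rbinom(total * m, 1L, rep(bg$alt_freq, each = total)),
                 total, m)
    for (k in seq_len(t)) {
      from_f <- stats::runif(m) < 0.5
      B1[ch[k], ] <- ifelse(from_f, B1[fa[k], ], B2[fa[k], ])
      from_m <- stats::runif(m) < 0.5
      B2[ch[k], ] <- ifelse(from_m, B1[mo[k], ], B2[mo[k], ])
    }
    if (config$missingness_rate > 0) {
      miss <- matrix(stats::runif(total * m) < config$missingness_rate, total, m)
      B1[miss] <- NA_integer_; B2[miss] <- NA_integer_
    }
    markers <- rbind(cohort$markers[, c("chrom", "pos", "rsid", "ref", "alt")],
                     bg[, c("chrom", "pos", "rsid", "ref", "alt")])
    H1 <- cbind(cohort$hap1, B1); H2 <- cbind(cohort$hap2, B2)
    PH <- cbind(cohort$phased, matrix(TRUE, total, m))
    cohort <- cohort_genotypes(samples, markers, H1, H2, PH)
  }
  pedigree <- data.frame(father = samples[fa], mother = samples[mo],
                         child = samples[ch], stringsAsFactors = FALSE)
  write_phased_cohort(cohort, vcf_path,
                      extra_header = paste0("##pgxprofiler_sim_seed=",
                                            config$seed))
  list(vcf = vcf_path, truth = sim$truth, cohort = cohort,
       pedigree = pedigree)
}

#' Construct a cohort of phenotype calls from target marginal counts
#'
#' Deterministically assigns phenotype labels to synthetic sample
#' identifiers so that the per-gene marginal counts reproduce a printed
#' summary table exactly (used to validate [cohort_summary()] arithmetic
#' against published cohort tables).
#'
#' @param target_counts Data frame `gene`, `phenotype`, `count`; per gene,
#'   counts must sum to the (common) cohort size.
#' @param map A `phenotype_map` supplying the nontypical flags.
#' @return Data frame of phenotype calls `sample`, `gene`, `phenotype`,
#'   `nontypical` covering every sample x gene.
#' @export
build_table2_cohort <- function(target_counts, map) {
  sums <- tapply(target_counts$count, target_counts$gene, sum)
  size <- unique(as.vector(sums))
  if (length(size) != 1L) {
    pgx_stop("per-gene counts must sum to one common cohort size (got ",
             paste(size, collapse = ", "), ")")
  }
  samples <- sprintf("S%04d", seq_len(size))
  fkey <- paste(map$flags$gene, map$flags$phenotype, sep = "\r")
  out <- list()
  for (g in unique(target_counts$gene)) {
    rows <- target_counts[target_counts$gene == g, , drop = FALSE]
    rows <- rows[order(rows$phenotype), , drop = FALSE]
    phenotype <- rep(rows$phenotype, rows$count)
    j <- match(paste(g, phenotype, sep = "\r"), fkey)
    nontypical <- !is.na(j) & map$flags$nontypical[j]
    nontypical[phenotype %in% RESERVED_PHENOTYPES] <- FALSE
    out[[g]] <- data.frame(sample = samples, gene = g, phenotype = phenotype,
                           nontypical = nontypical, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
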