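# Phased cohort genotypes: VCF I/O, post-imputation marker filtering,
# allele-frequency estimation.

#' Construct a phased cohort genotype container
#'
#' The container holds, per sample and marker, a pair of haplotype allele
#' codes (0 = reference, 1 = alternate, `NA` = missing; a genotype with any
#' missing allele is missing as a unit) plus per-marker metadata. Allele
#' frequencies and MAF are (re)computed from the stored haplotypes.
#'
#' @param samples Character vector of sample identifiers.
#' @param markers Data frame with columns `chrom`, `pos`, `rsid`, `ref`,
#'   `alt` and optionally `rsqr` (imputation quality, `NA` for directly
#'   genotyped markers).
#' @param hap1,hap2 Integer matrices (samples x markers) of allele codes.
#' @param phased Logical matrix (samples x markers); homozygous and missing
#'   genotypes are phase-irrelevant and treated as phased.
#' @return An object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(samples, markers, hap1, hap2, phased = NULL) {
  n <- length(samples); m <- nrow(markers)
  if (anyDuplicated(samples)) pgx_stop("duplicated sample identifiers")
  for (h in list(hap1, hap2)) {
    if (!is.matrix(h) || nrow(h) != n || ncol(h) != m) {
      pgx_stop("haplotype matrices must be samples x markers (", n, " x ", m, ")")
    }
    if (!all(h %in% c(0L, 1L, NA_integer_))) {
      pgx_stop("haplotype allele codes must be 0, 1 or NA")
    }
  }
  if (is.null(phased)) phased <- matrix(TRUE, n, m)
  # missing-as-a-unit: if either allele is missing, both are
  miss <- is.na(hap1) | is.na(hap2)
  hap1[miss] <- NA_integer_; hap2[miss] <- NA_integer_
  if (!"rsqr" %in% names(markers)) markers$rsqr <- NA_real_
  markers$site_id <- site_id(markers$chrom, markers$pos, markers$ref, markers$alt)
  dimnames(hap1) <- dimnames(hap2) <- dimnames(phased) <-
    list(samples, markers$site_id)
  obj <- structure(list(samples = samples, markers = markers,
                        hap1 = hap1, hap2 = hap2, phased = phased),
                   class = "cohort_genotypes")
  recompute_marker_stats(obj)
}

recompute_marker_stats <- function(cohort) {
  alt <- colSums(cohort$hap1 == 1L, na.rm = TRUE) +
    colSums(cohort$hap2 == 1L, na.rm = TRUE)
  nh <- colSums(!is.na(cohort$hap1)) + colSums(!is.na(cohort$hap2))
  af <- ifelse(nh > 0L, alt / nh, NA_real_)
  cohort$markers$alt_freq <- af
  cohort$markers$maf <- pmin(af, 1 - af)
  cohort$markers$n_hap <- as.integer(nh)
  cohort
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("<cohort_genotypes> ", length(x$samples), " samples x ",
      nrow(x$markers), " markers; ",
      sum(is.na(x$hap1)), " missing genotypes\n", sep = "")
  invisible(x)
}

subset_markers <- function(cohort, keep) {
  cohort$markers <- cohort$markers[keep, , drop = FALSE]
  rownames(cohort$markers) <- NULL
  cohort$hap1 <- cohort$hap1[, keep, drop = FALSE]
  cohort$hap2 <- cohort$hap2[, keep, drop = FALSE]
  cohort$phased <- cohort$phased[, keep, drop = FALSE]
  cohort
}

subset_samples <- function(cohort, keep) {
  i <- match(keep, cohort$samples)
  if (anyNA(i)) pgx_stop("unknown sample(s): ", paste(keep[is.na(i)], collapse = ", "))
  cohort$samples <- cohort$samples[i]
  cohort$hap1 <- cohort$hap1[i, , drop = FALSE]
  cohort$hap2 <- cohort$hap2[i, , drop = FALSE]
  cohort$phased <- cohort$phased[i, , drop = FALSE]
  recompute_marker_stats(cohort)
}

#' Read a phased multi-sample VCF
#'
#' Loads biallelic records from a VCF 4.2 file (plain text or gzipped); only
#' the GT subfield is interpreted. Heterozygous unphased genotypes violate
#' the phased-input requirement of exact haplotype matching and are rejected
#' by default; homozygous and missing genotypes carry no phase information
#' and are accepted regardless of separator.
#'
#' @param vcf_path Path to the VCF.
#' @param region_set Optional restriction: a `gene_definition_set` (keep only
#'   its declared sites) or a data frame with `chrom`, `start`, `end`.
#' @param require_phase If `TRUE` (default) a heterozygous unphased genotype
#'   is an error naming sample and site; if `FALSE` it is set missing.
#' @param multiallelic `"reject"` (default: error on records with more than
#'   one ALT allele) or `"split"` (one biallelic record per ALT allele;
#'   haplotypes carrying another ALT are set missing).
#' @param rsq_key INFO key holding the imputation quality (default `"RSQR"`);
#'   markers without the key are treated as directly genotyped.
#' @return A [cohort_genotypes] object.
#' @export
read_phased_cohort <- function(vcf_path, region_set = NULL,
                               require_phase = TRUE,
                               multiallelic = c("reject", "split"),
                               rsq_key = "RSQR") {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(vcf_path)) pgx_stop("VCF not found: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  if (nrow(v@gt) == 0L || !"FORMAT" %in% colnames(v@gt)) {
    pgx_stop("VCF has no genotype columns")
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, TRUE))) {
    pgx_stop("every record must carry a GT FORMAT field")
  }
  samples <- colnames(v@gt)[-1L]

  markers <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                        rsid = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                      "", fix[, "ID"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  gt <- t(vcfR::extract.gt(v, element = "GT"))  # samples x markers
  gt[is.na(gt)] <- "./."

  multi <- grepl(",", markers$alt, fixed = TRUE)
  if (any(multi) && multiallelic == "reject") {
    pgx_stop("multiallelic record at ", markers$chrom[multi][1], ":",
             markers$pos[multi][1],
             " (set multiallelic = \"split\" to decompose)")
  }

  parse_block <- function(gt_block, alt_code) {
    # gt_block: character matrix samples x markers, one target ALT code
    sep_phased <- grepl("|", gt_block, fixed = TRUE)
    al <- strsplit(gsub("|", "/", gt_block, fixed = TRUE), "/", fixed = TRUE)
    a1 <- vapply(al, function(x) x[1] %||% ".", "")
    a2 <- vapply(al, function(x) if (length(x) > 1L) x[2] else ".", "")
    conv <- function(a, code) ifelse(a == ".", NA_integer_,
                              ifelse(a == "0", 0L,
                              ifelse(a == code, 1L, NA_integer_)))
    h1 <- matrix(conv(a1, alt_code), nrow(gt_block), ncol(gt_block))
    h2 <- matrix(conv(a2, alt_code), nrow(gt_block), ncol(gt_block))
    list(h1 = h1, h2 = h2, phased = matrix(sep_phased, nrow(gt_block)))
  }

  if (any(multi) && multiallelic == "split") {
    pieces <- lapply(which(multi), function(j) {
      alts <- strsplit(markers$alt[j], ",", fixed = TRUE)[[1]]
      do.call(rbind, lapply(seq_along(alts), function(k) {
        data.frame(j = j, alt = alts[k], code = as.character(k),
                   stringsAsFactors = FALSE)
      }))
    })
    pieces <- do.call(rbind, pieces)
    mk2 <- markers[pieces$j, , drop = FALSE]
    mk2$alt <- pieces$alt
    markers <- rbind(markers[!multi, , drop = FALSE], mk2)
    gt_bi <- gt[, !multi, drop = FALSE]
    gt_mu <- gt[, pieces$j, drop = FALSE]
    pb <- parse_block(gt_bi, "1")
    pm_list <- lapply(seq_len(nrow(pieces)), function(i) {
      parse_block(gt_mu[, i, drop = FALSE], pieces$code[i])
    })
    h1 <- cbind(pb$h1, do.call(cbind, lapply(pm_list, `[[`, "h1")))
    h2 <- cbind(pb$h2, do.call(cbind, lapply(pm_list, `[[`, "h2")))
    ph <- cbind(pb$phased, do.call(cbind, lapply(pm_list, `[[`, "phased")))
  } else {
    pb <- parse_block(gt, "1")
    h1 <- pb$h1; h2 <- pb$h2; ph <- pb$phased
  }

  het <- !is.na(h1) & !is.na(h2) & h1 != h2
  unphased_het <- het & !ph
  if (any(unphased_het)) {
    if (require_phase) {
      w <- which(unphased_het, arr.ind = TRUE)[1, ]
      pgx_stop("unphased heterozygous genotype for sample ", samples[w[1]],
               " at ", markers$chrom[w[2]], ":", markers$pos[w[2]],
               "; phased input is required")
    }
    h1[unphased_het] <- NA_integer_
    h2[unphased_het] <- NA_integer_
  }
  # homozygous/missing genotypes are phase-irrelevant; their original
  # separator is kept so that writing round-trips the GT field

  rsqr <- rep(NA_real_, nrow(markers))
  info <- fix[, "INFO"]
  pat <- paste0("(?:^|;)", rsq_key, "=([^;]+)")
  hit <- regmatches(info, regexec(pat, info))
  vals <- vapply(hit, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  if (any(multi) && multiallelic == "split") {
    vals <- c(vals[!multi], vals[pieces$j])
  }
  rsqr <- suppressWarnings(as.numeric(vals))
  markers$rsqr <- rsqr

  cohort <- cohort_genotypes(samples, markers, h1, h2, ph)
  if (!is.null(region_set)) {
    if (inherits(region_set, "gene_definition_set")) {
      ids <- unlist(lapply(region_set$sites, function(s) s$site_id),
                    use.names = FALSE)
      keep <- cohort$markers$site_id %in% ids
    } else {
      keep <- rep(FALSE, nrow(cohort$markers))
      for (i in seq_len(nrow(region_set))) {
        keep <- keep | (cohort$markers$chrom == region_set$chrom[i] &
                          cohort$markers$pos >= region_set$start[i] &
                          cohort$markers$pos <= region_set$end[i])
      }
    }
    cohort <- subset_markers(cohort, keep)
  }
  cohort
}

#' Write a phased cohort back to VCF
#'
#' Emits a VCF 4.2 with GT-only genotype columns; the phase separator of each
#' genotype is restored, so `write(read(vcf))` round-trips GT fields of
#' phased biallelic records exactly.
#'
#' @param cohort A [cohort_genotypes] object.
#' @param path Output path.
#' @param extra_header Optional character vector of additional `##` header
#'   lines (e.g. provenance comments).
#' @export
write_phased_cohort <- function(cohort, path, extra_header = character()) {
  mk <- cohort$markers
  a1 <- ifelse(is.na(cohort$hap1), ".", as.character(cohort$hap1))
  a2 <- ifelse(is.na(cohort$hap2), ".", as.character(cohort$hap2))
  sep <- ifelse(cohort$phased, "|", "/")
  gt <- matrix(paste0(a1, sep, a2), nrow(cohort$hap1))
  info <- ifelse(is.na(mk$rsqr), ".", paste0("RSQR=", format(mk$rsqr)))
  body <- cbind(mk$chrom, mk$pos, ifelse(nzchar(mk$rsid), mk$rsid, "."),
                mk$ref, mk$alt, ".", "PASS", info, "GT", t(gt))
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=RSQR,Number=1,Type=Float,Description=\"Imputation quality\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              extra_header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Post-imputation marker quality filter
#'
#' Retains markers with imputation quality above `rsq_common` when the
#' estimated MAF is at least `maf_cut`, or above `rsq_rare` when the MAF is
#' below `maf_cut`. Markers without an imputation quality value are treated
#' as directly genotyped and always retained. The sample set is unchanged
#' and the filter is idempotent.
#'
#' @param cohort A [cohort_genotypes] object.
#' @param rsq_common Quality threshold for common markers (default 0.3).
#' @param rsq_rare Quality threshold for rare markers (default 0.6).
#' @param maf_cut MAF boundary between the two rules (default 0.01).
#' @return The filtered [cohort_genotypes].
#' @export
filter_markers_by_quality <- function(cohort, rsq_common = 0.3,
                                      rsq_rare = 0.6, maf_cut = 0.01) {
  mk <- cohort$markers
  keep <- is.na(mk$rsqr) |
    (mk$rsqr > rsq_common & mk$maf >= maf_cut) |
    (mk$rsqr > rsq_rare & mk$maf < maf_cut)
  keep[is.na(keep)] <- TRUE  # markers with no called haplotype carry no MAF
  subset_markers(cohort, keep)
}

#' Estimate allele frequencies on a sample subset
#'
#' ALT-allele frequency per site computed over the non-missing haplotypes of
#' the given subset (typically the unrelated individuals retained by
#' [prune_related()]).
#'
#' @param cohort A [cohort_genotypes] object.
#' @param subset Sample identifiers to use (default: all samples).
#' @return Data frame `chrom`, `pos`, `rsid`, `ref`, `alt`, `alt_freq`,
#'   `maf`, `n_hap`; sites where every genotype is missing report `NA`
#'   frequencies with `n_hap = 0`.
#' @export
estimate_allele_frequencies <- function(cohort, subset = cohort$samples) {
  if (length(subset) == 0L) pgx_stop("empty sample subset")
  sub <- subset_samples(cohort, subset)
  sub$markers[, c("chrom", "pos", "rsid", "ref", "alt",
                  "alt_freq", "maf", "n_hap")]
}
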