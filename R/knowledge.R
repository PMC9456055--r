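# Knowledge tables: star-allele definitions, diplotype->phenotype map,
# CPIC gene-drug pairs, PharmGKB-style clinical annotations.

VALID_CPIC_LEVELS <- c("A", "B", "C", "D")
VALID_EVIDENCE_LEVELS <- c("1A", "1B", "2A", "2B", "3", "4")
HIGH_EVIDENCE_LEVELS <- c("1A", "1B", "2A", "2B")
# phenotype labels that are reserved for uncallable/unclassified diplotypes
# and can never count as nontypical
RESERVED_PHENOTYPES <- c("Not available", "Indeterminate")

#' Load star-allele definitions
#'
#' Reads a tab-separated allele-definition table (one row per allele and
#' defining site; the reference allele of each gene appears as a single row
#' with empty site columns) and returns a validated definition set. The
#' dialect is schema-compatible with flattened PharmCAT allele-definition
#' exports: columns `gene`, `allele`, `is_reference`, `chrom`, `pos`, `rsid`,
#' `ref`, `alt`, `required_allele`, with 1-based positions as in VCF.
#'
#' @param path Path to the definition TSV.
#' @return An object of class `gene_definition_set`: a list with per-gene
#'   `sites` (ordered data frames of defining variant sites), `alleles`
#'   (allele names and reference flags) and `defining` (required allele per
#'   defining site), plus `reference_allele`, the reference star allele of
#'   each gene.
#' @examples
#' defs <- load_allele_definitions(pgx_extdata("toy_knowledge/allele_definitions.tsv"))
#' names(defs$sites)
#' @export
load_allele_definitions <- function(path) {
  raw <- read_tsv(path, colClasses = "character")
  need <- c("gene", "allele", "is_reference", "chrom", "pos", "rsid",
            "ref", "alt", "required_allele")
  missing_cols <- setdiff(need, names(raw))
  # ragged reference-only rows may drop trailing columns entirely
  for (m in missing_cols) raw[[m]] <- NA_character_
  raw$is_reference <- raw$is_reference %in% c("1", "TRUE", "true", "T")
  has_site <- !is.na(raw$chrom) & nzchar(trimws(raw$chrom))

  sites <- list(); alleles <- list(); defining <- list(); ref_allele <- character()
  for (g in unique(raw$gene)) {
    rows <- raw[raw$gene == g, , drop = FALSE]
    dup <- duplicated(paste(rows$allele,
                            ifelse(has_site[raw$gene == g],
                                   site_id(rows$chrom, rows$pos, rows$ref, rows$alt),
                                   "<reference>")))
    if (any(dup)) {
      pgx_stop("duplicate allele definition row for gene ", g,
               ", allele ", rows$allele[dup][1])
    }
    al <- unique(rows[, c("allele", "is_reference")])
    if (anyDuplicated(al$allele)) {
      pgx_stop("duplicate allele '", al$allele[duplicated(al$allele)][1],
               "' declared for gene ", g, " with conflicting reference flags")
    }
    n_ref <- sum(al$is_reference)
    if (n_ref != 1L) {
      pgx_stop("gene ", g, " must declare exactly one reference allele (found ",
               n_ref, ")")
    }
    srow <- rows[has_site[raw$gene == g], , drop = FALSE]
    st <- unique(srow[, c("chrom", "pos", "rsid", "ref", "alt")])
    st$pos <- as.integer(st$pos)
    if (nrow(st) && any(is.na(st$pos) | st$pos < 1L)) {
      pgx_stop("gene ", g, ": positions must be integers >= 1")
    }
    if (nrow(st) && any(st$ref == st$alt)) {
      pgx_stop("gene ", g, ": ref and alt allele must differ at every site")
    }
    st <- st[order(st$pos), , drop = FALSE]
    st$site_id <- site_id(st$chrom, st$pos, st$ref, st$alt)
    if (anyDuplicated(st$site_id)) {
      pgx_stop("gene ", g, ": duplicated site (chrom,pos,ref,alt)")
    }
    rownames(st) <- NULL
    def <- data.frame(allele = srow$allele,
                      site_id = site_id(srow$chrom, as.integer(srow$pos),
                                        srow$ref, srow$alt),
                      required = srow$required_allele,
                      stringsAsFactors = FALSE)
    if (nrow(def)) {
      ok <- def$required == st$ref[match(def$site_id, st$site_id)] |
        def$required == st$alt[match(def$site_id, st$site_id)]
      if (any(!ok)) {
        pgx_stop("gene ", g, ": required_allele must be the ref or alt ",
                 "allele of its site")
      }
    }
    sites[[g]] <- st
    alleles[[g]] <- al[order(!al$is_reference, al$allele), , drop = FALSE]
    rownames(alleles[[g]]) <- NULL
    defining[[g]] <- def
    ref_allele[[g]] <- al$allele[al$is_reference]
  }
  all_sites <- do.call(rbind, lapply(sites, function(s) s["site_id"]))
  if (!is.null(all_sites) && anyDuplicated(all_sites$site_id)) {
    pgx_stop("a (chrom,pos,ref,alt) site is declared by more than one gene")
  }
  structure(list(sites = sites, alleles = alleles, defining = defining,
                 reference_allele = ref_allele),
            class = "gene_definition_set")
}

#' @export
print.gene_definition_set <- function(x, ...) {
  cat("<gene_definition_set> ", length(x$sites), " genes, ",
      sum(vapply(x$sites, nrow, 0L)), " sites, ",
      sum(vapply(x$alleles, nrow, 0L)), " star alleles\n", sep = "")
  invisible(x)
}

#' Write star-allele definitions
#'
#' Serializes a `gene_definition_set` back to the TSV dialect read by
#' [load_allele_definitions()] (semantically lossless round trip).
#'
#' @param defs A `gene_definition_set`.
#' @param path Output path.
#' @export
write_allele_definitions <- function(defs, path) {
  rows <- list()
  for (g in names(defs$alleles)) {
    al <- defs$alleles[[g]]
    st <- defs$sites[[g]]
    for (i in seq_len(nrow(al))) {
      a <- al$allele[i]
      def <- defs$defining[[g]][defs$defining[[g]]$allele == a, , drop = FALSE]
      if (nrow(def) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, allele = a, is_reference = as.integer(al$is_reference[i]),
          chrom = "", pos = "", rsid = "", ref = "", alt = "",
          required_allele = "", stringsAsFactors = FALSE)
      } else {
        m <- match(def$site_id, st$site_id)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, allele = a, is_reference = as.integer(al$is_reference[i]),
          chrom = st$chrom[m], pos = st$pos[m], rsid = st$rsid[m],
          ref = st$ref[m], alt = st$alt[m], required_allele = def$required,
          stringsAsFactors = FALSE)
      }
    }
  }
  write_tsv(do.call(rbind, rows), path)
}

#' Load the diplotype-to-phenotype map
#'
#' Reads the unordered diplotype -> phenotype entries (`gene`, `allele1`,
#' `allele2`, `phenotype`) together with the per-gene nontypical flag table
#' (`gene`, `phenotype`, `nontypical`). A phenotype is *nontypical* when
#' CPIC guidance recommends an alternate dosage or drug for it; the flag is
#' data, not logic, so populations using different guidance can swap tables.
#' The reserved labels `"Not available"` and `"Indeterminate"` must never be
#' flagged nontypical.
#'
#' @param path Path to the diplotype entries TSV.
#' @param flags_path Path to the flag TSV; defaults to `phenotype_flags.tsv`
#'   next to `path`.
#' @return An object of class `phenotype_map` with elements `entries`
#'   (data frame keyed by unordered allele pair) and `flags`.
#' @export
load_phenotype_map <- function(path,
                               flags_path = file.path(dirname(path),
                                                      "phenotype_flags.tsv")) {
  entries <- read_tsv(path, colClasses = "character")
  need <- c("gene", "allele1", "allele2", "phenotype")
  if (!all(need %in% names(entries))) {
    pgx_stop("phenotype map must have columns ", paste(need, collapse = ", "))
  }
  bad <- !nzchar(trimws(entries$allele1)) | !nzchar(trimws(entries$allele2))
  if (any(bad)) {
    pgx_stop("malformed diplotype pair on line ", which(bad)[1] + 1L,
             " of ", path)
  }
  flags <- read_tsv(flags_path)
  if (!all(c("gene", "phenotype", "nontypical") %in% names(flags))) {
    pgx_stop("flag table must have columns gene, phenotype, nontypical")
  }
  flags$nontypical <- as.logical(as.integer(flags$nontypical))
  reserved_bad <- flags$phenotype %in% RESERVED_PHENOTYPES & flags$nontypical
  if (any(reserved_bad)) {
    pgx_stop("reserved phenotype '", flags$phenotype[reserved_bad][1],
             "' cannot be flagged nontypical")
  }
  # every mapped phenotype needs a flag row for its gene
  fkey <- paste(flags$gene, flags$phenotype, sep = "\r")
  ekey <- paste(entries$gene, entries$phenotype, sep = "\r")
  miss <- !(ekey %in% fkey)
  if (any(miss)) {
    pgx_stop("phenotype '", entries$phenotype[miss][1], "' of gene ",
             entries$gene[miss][1], " has no nontypical flag row")
  }
  entries$key <- paste(entries$gene, pair_key(entries$allele1, entries$allele2),
                       sep = "\r")
  if (anyDuplicated(entries$key)) {
    k <- entries$key[duplicated(entries$key)][1]
    pgx_stop("duplicate diplotype entry: ", sub("\r", " ", k))
  }
  structure(list(entries = entries, flags = flags), class = "phenotype_map")
}

#' @export
print.phenotype_map <- function(x, ...) {
  cat("<phenotype_map> ", length(unique(x$entries$gene)), " genes, ",
      nrow(x$entries), " diplotype entries, ",
      sum(x$flags$nontypical), " nontypical phenotype flags\n", sep = "")
  invisible(x)
}

#' Write a phenotype map
#'
#' @param map A `phenotype_map`.
#' @param path,flags_path Output paths for the entries and flag tables.
#' @export
write_phenotype_map <- function(map, path,
                                flags_path = file.path(dirname(path),
                                                       "phenotype_flags.tsv")) {
  write_tsv(map$entries[, c("gene", "allele1", "allele2", "phenotype")], path)
  fl <- map$flags
  fl$nontypical <- as.integer(fl$nontypical)
  write_tsv(fl, flags_path)
  invisible(path)
}

#' Look up the phenotype of one diplotype
#'
#' The lookup is symmetric in the two alleles.
#'
#' @param map A `phenotype_map`.
#' @param gene Gene symbol.
#' @param allele1,allele2 Star-allele names.
#' @return A list with `phenotype` and `nontypical`, or `NULL` when the pair
#'   is absent from the map.
#' @export
phenotype_lookup <- function(map, gene, allele1, allele2) {
  key <- paste(gene, pair_key(allele1, allele2), sep = "\r")
  i <- match(key, map$entries$key)
  if (is.na(i)) return(NULL)
  ph <- map$entries$phenotype[i]
  j <- which(map$flags$gene == gene & map$flags$phenotype == ph)
  list(phenotype = ph, nontypical = isTRUE(map$flags$nontypical[j[1]]))
}

#' Load the CPIC gene-drug table
#'
#' Reads `gene`, `drug`, `cpic_level` rows and keeps those whose CPIC
#' evidence level is in `level_filter` (default: level A only, the pairs with
#' evidence sufficient for a prescribing recommendation). Drug names are
#' trimmed and lower-cased so case variants collapse; rows are deduplicated
#' on (gene, drug).
#'
#' @param path Path to the TSV.
#' @param level_filter Character vector of CPIC levels to retain.
#' @return A data frame with columns `gene`, `drug`, `cpic_level`.
#' @export
load_gene_drug_table <- function(path, level_filter = "A") {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("gene", "drug", "cpic_level") %in% names(df))) {
    pgx_stop("gene-drug table must have columns gene, drug, cpic_level")
  }
  df$cpic_level <- trimws(df$cpic_level)
  bad <- !(df$cpic_level %in% VALID_CPIC_LEVELS)
  if (any(bad)) {
    pgx_stop("unknown CPIC level '", df$cpic_level[bad][1], "' (expected ",
             paste(VALID_CPIC_LEVELS, collapse = "/"), ")")
  }
  df$drug <- normalize_drug(df$drug)
  df <- df[df$cpic_level %in% level_filter, , drop = FALSE]
  df <- df[!duplicated(paste(df$gene, df$drug, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Load clinical variant-drug annotations
#'
#' Reads PharmGKB-style clinical annotations: `annotation_id`, `rsid`,
#' `gene`, `evidence_level` (1A/1B/2A/2B/3/4), `phenotype_category`,
#' `drugs` (semicolon-separated), `pediatric` (0/1).
#'
#' @param path Path to the TSV.
#' @return A data frame with one row per annotation; `high_evidence` is
#'   `TRUE` for tiers 1A/1B/2A/2B.
#' @export
load_clinical_annotations <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("annotation_id", "rsid", "gene", "evidence_level",
            "phenotype_category", "drugs", "pediatric")
  if (!all(need %in% names(df))) {
    pgx_stop("clinical annotation table must have columns ",
             paste(need, collapse = ", "))
  }
  df$evidence_level <- trimws(df$evidence_level)
  bad <- !(df$evidence_level %in% VALID_EVIDENCE_LEVELS)
  if (any(bad)) {
    pgx_stop("invalid evidence level '", df$evidence_level[bad][1],
             "' (expected ", paste(VALID_EVIDENCE_LEVELS, collapse = "/"), ")")
  }
  df$pediatric <- as.integer(df$pediatric) == 1L
  df$drugs <- vapply(strsplit(df$drugs, ";", fixed = TRUE),
                     function(d) paste(normalize_drug(d), collapse = ";"), "")
  df$high_evidence <- is_high_evidence(df$evidence_level)
  df
}

#' High- vs low-evidence annotation tiers
#'
#' @param level Character vector of evidence levels.
#' @return Logical: `TRUE` for 1A/1B/2A/2B, `FALSE` for 3/4.
#' @export
is_high_evidence <- function(level) {
  bad <- !(level %in% VALID_EVIDENCE_LEVELS)
  if (any(bad)) pgx_stop("invalid evidence level '", level[bad][1], "'")
  level %in% HIGH_EVIDENCE_LEVELS
}
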