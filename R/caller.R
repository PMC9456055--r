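# Star-allele diplotype calling by exact haplotype matching.

# required-allele codes (0 = ref, 1 = alt) per allele for one gene, as a
# list of named integer vectors keyed by site_id
allele_requirements <- function(defs, gene) {
  st <- defs$sites[[gene]]
  def <- defs$defining[[gene]]
  al <- defs$alleles[[gene]]
  out <- lapply(al$allele, function(a) {
    d <- def[def$allele == a, , drop = FALSE]
    if (nrow(d) == 0L) return(integer(0))
    m <- match(d$site_id, st$site_id)
    stats::setNames(as.integer(d$required == st$alt[m]), d$site_id)
  })
  names(out) <- al$allele
  out
}

#' Match one haplotype against a gene's star-allele definitions
#'
#' A star allele matches a haplotype iff every one of its defining sites is
#' observed and carries the required allele, and every other declared site of
#' the gene that is observed carries the reference allele. The reference
#' allele (empty defining set) therefore matches exactly the all-reference
#' haplotype. Exact matching only: nothing is inferred at missing sites.
#'
#' @param haplotype Integer vector of allele codes (0/1/`NA`) over the gene's
#'   declared site list, in declared site order (or named by `site_id`).
#' @param defs A `gene_definition_set`.
#' @param gene Gene symbol.
#' @return A list with `gene`, `matched_alleles` (character, ordered by
#'   number of defining sites satisfied, then name), `n_defining_matched`
#'   (per matched allele) and `complete` (all declared sites observed).
#' @export
match_haplotype <- function(haplotype, defs, gene) {
  st <- defs$sites[[gene]]
  if (is.null(st)) pgx_stop("gene ", gene, " not in definition set")
  if (length(haplotype) != nrow(st)) {
    pgx_stop("haplotype has ", length(haplotype), " codes but gene ", gene,
             " declares ", nrow(st), " sites")
  }
  if (!is.null(names(haplotype))) haplotype <- haplotype[st$site_id]
  req <- allele_requirements(defs, gene)
  observed <- !is.na(haplotype)
  matched <- character(0); ndef <- integer(0)
  for (a in names(req)) {
    r <- req[[a]]
    idx <- match(names(r), st$site_id)
    def_ok <- length(r) == 0L ||
      (all(observed[idx]) && all(haplotype[idx] == r))
    other <- setdiff(which(observed), idx)
    other_ok <- all(haplotype[other] == 0L)
    if (def_ok && other_ok) {
      matched <- c(matched, a)
      ndef <- c(ndef, length(r))
    }
  }
  ord <- order(-ndef, matched)
  list(gene = gene, matched_alleles = matched[ord],
       n_defining_matched = ndef[ord],
       complete = all(observed))
}

# resolve one haplotype to a single allele name, or NA (no match /
# incomplete), or the sentinel "<ambiguous>" when the defining-site-count
# tie-break leaves more than one candidate
resolve_haplotype <- function(haplotype, defs, gene) {
  m <- match_haplotype(haplotype, defs, gene)
  if (!m$complete || length(m$matched_alleles) == 0L) return(NA_character_)
  best <- m$matched_alleles[m$n_defining_matched == max(m$n_defining_matched)]
  if (length(best) > 1L) return("<ambiguous>")
  best[1]
}

#' Call the star-allele diplotype of one sample at one gene
#'
#' Both phased haplotypes are matched with [match_haplotype()]. A call is
#' produced only when each haplotype resolves to exactly one allele; a
#' missing declared site or a zero-match haplotype yields status
#' `"not_available"`, and a haplotype that still matches several alleles
#' after the most-defining-sites tie-break yields `"ambiguous"`. The reported
#' pair is in canonical order (reference allele first, then lexicographic),
#' so the call is invariant under swapping the two physical haplotypes.
#'
#' @param hap1,hap2 Integer code vectors over the gene's declared sites.
#' @param defs A `gene_definition_set`.
#' @param gene Gene symbol.
#' @param sample Optional sample identifier carried through.
#' @return A one-row data frame: `sample`, `gene`, `allele1`, `allele2`,
#'   `status` (`"called"`, `"not_available"` or `"ambiguous"`); the allele
#'   columns are `NA` unless `status == "called"`.
#' @export
call_diplotype <- function(hap1, hap2, defs, gene, sample = NA_character_) {
  a <- resolve_haplotype(hap1, defs, gene)
  b <- resolve_haplotype(hap2, defs, gene)
  if (identical(a, "<ambiguous>") || identical(b, "<ambiguous>")) {
    status <- "ambiguous"; a1 <- NA_character_; a2 <- NA_character_
  } else if (is.na(a) || is.na(b)) {
    status <- "not_available"; a1 <- NA_character_; a2 <- NA_character_
  } else {
    status <- "called"
    cp <- canonical_pair(a, b, defs$reference_allele[[gene]])
    a1 <- cp$allele1; a2 <- cp$allele2
  }
  data.frame(sample = sample, gene = gene, allele1 = a1, allele2 = a2,
             status = status, stringsAsFactors = FALSE)
}

#' Call diplotypes for every sample and gene of a cohort
#'
#' Cohort markers are matched to the declared defining sites by exact
#' (chrom, pos, ref, alt) identity; declared sites absent from the cohort are
#' treated as missing for every sample (a gene with no site present yields
#' `not_available` calls for all samples, with a warning).
#'
#' @param cohort A [cohort_genotypes] object.
#' @param defs A `gene_definition_set`.
#' @return Data frame with one row per sample x gene: `sample`, `gene`,
#'   `allele1`, `allele2`, `status`.
#' @export
call_cohort <- function(cohort, defs) {
  out <- vector("list", length(defs$sites))
  names(out) <- names(defs$sites)
  n <- length(cohort$samples)
  for (g in names(defs$sites)) {
    st <- defs$sites[[g]]
    idx <- match(st$site_id, cohort$markers$site_id)
    if (all(is.na(idx)) && nrow(st) > 0L) {
      warning("gene ", g, ": no defining site present in the cohort; ",
              "all calls not_available", call. = FALSE)
    }
    grab <- function(hap) {
      h <- matrix(NA_integer_, n, nrow(st),
                  dimnames = list(cohort$samples, st$site_id))
      pres <- !is.na(idx)
      if (any(pres)) h[, pres] <- hap[, idx[pres], drop = FALSE]
      h
    }
    r1 <- resolve_haplotypes_matrix(grab(cohort$hap1), defs, g)
    r2 <- resolve_haplotypes_matrix(grab(cohort$hap2), defs, g)
    amb <- r1 == "<ambiguous>" | r2 == "<ambiguous>"
    na <- !amb & (is.na(r1) | is.na(r2))
    status <- ifelse(amb & !is.na(amb), "ambiguous",
                     ifelse(is.na(r1) | is.na(r2), "not_available", "called"))
    status[is.na(status)] <- "not_available"
    cp <- canonical_pair(r1, r2, defs$reference_allele[[g]])
    a1 <- ifelse(status == "called", cp$allele1, NA_character_)
    a2 <- ifelse(status == "called", cp$allele2, NA_character_)
    out[[g]] <- data.frame(sample = cohort$samples, gene = g,
                           allele1 = a1, allele2 = a2, status = status,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$sample, cohort$samples), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# vectorized counterpart of resolve_haplotype: h is a samples x sites code
# matrix for one gene; returns one allele name, NA, or "<ambiguous>" per row
resolve_haplotypes_matrix <- function(h, defs, gene) {
  st <- defs$sites[[gene]]
  req <- allele_requirements(defs, gene)
  n <- nrow(h)
  if (nrow(st) == 0L) {
    # degenerate gene with no declared site: only the reference matches
    return(rep(defs$reference_allele[[gene]], n))
  }
  complete <- rowSums(is.na(h)) == 0L
  alleles <- names(req)
  M <- matrix(FALSE, n, length(alleles), dimnames = list(NULL, alleles))
  ndef <- vapply(req, length, 0L)
  for (a in alleles) {
    r <- req[[a]]
    didx <- match(names(r), st$site_id)
    if (length(didx)) {
      eq <- h[, didx, drop = FALSE] ==
        matrix(r, n, length(didx), byrow = TRUE)
      cnt <- rowSums(eq)  # NA if any defining site missing
      def_ok <- !is.na(cnt) & cnt == length(didx)
    } else {
      def_ok <- rep(TRUE, n)
    }
    oidx <- setdiff(seq_len(nrow(st)), didx)
    other_ok <- if (length(oidx)) {
      rowSums(h[, oidx, drop = FALSE] != 0L, na.rm = TRUE) == 0L
    } else rep(TRUE, n)
    M[, a] <- def_ok & other_ok
  }
  nd_mat <- sweep(ifelse(M, 1, NA), 2L, ndef, `*`)
  best <- suppressWarnings(apply(nd_mat, 1L, max, na.rm = TRUE))
  n_best <- rowSums(nd_mat == best, na.rm = TRUE)
  res <- rep(NA_character_, n)
  for (i in which(complete & is.finite(best))) {
    if (n_best[i] > 1L) {
      res[i] <- "<ambiguous>"
    } else {
      cand <- alleles[M[i, ] & ndef == best[i]]
      res[i] <- sort(cand)[1]
    }
  }
  res
}

#' Per-gene diplotype and haplotype frequency tables
#'
#' @param calls Output of [call_cohort()].
#' @return A list with `diplotypes` (gene, allele1, allele2, count,
#'   frequency) and `haplotypes` (gene, allele, count, frequency); counts
#'   over called samples/haplotypes, frequencies over all samples of the
#'   cohort (so per-gene diplotype counts plus uncalled samples conserve the
#'   cohort size).
#' @export
diplotype_frequencies <- function(calls) {
  n_samples <- length(unique(calls$sample))
  called <- calls[calls$status == "called", , drop = FALSE]
  key <- paste(called$gene, called$allele1, called$allele2, sep = "\r")
  tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(tab$key, "\r", fixed = TRUE)
  dip <- data.frame(gene = vapply(parts, `[`, "", 1L),
                    allele1 = vapply(parts, `[`, "", 2L),
                    allele2 = vapply(parts, `[`, "", 3L),
                    count = tab$Freq,
                    frequency = tab$Freq / n_samples,
                    stringsAsFactors = FALSE)
  dip <- dip[order(dip$gene, -dip$count), , drop = FALSE]
  hkey <- c(paste(called$gene, called$allele1, sep = "\r"),
            paste(called$gene, called$allele2, sep = "\r"))
  htab <- as.data.frame(table(hkey), stringsAsFactors = FALSE)
  hparts <- strsplit(htab$hkey, "\r", fixed = TRUE)
  hap <- data.frame(gene = vapply(hparts, `[`, "", 1L),
                    allele = vapply(hparts, `[`, "", 2L),
                    count = htab$Freq,
                    frequency = htab$Freq / (2 * n_samples),
                    stringsAsFactors = FALSE)
  hap <- hap[order(hap$gene, -hap$count), , drop = FALSE]
  rownames(dip) <- rownames(hap) <- NULL
  list(diplotypes = dip, haplotypes = hap)
}
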