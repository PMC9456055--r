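# Study-vs-reference allele-frequency comparison, tiered differentiation
# screen, Fisher exact testing with BH-FDR.

EVIDENCE_RANK <- c("1A" = 1, "1B" = 2, "2A" = 3, "2B" = 4, "3" = 5, "4" = 6)

#' Compare study and reference allele frequencies at annotated variants
#'
#' Joins the study and reference ALT-allele frequency tables on rsid (or on
#' (chrom, pos, ref, alt) when rsids are absent) for every clinically
#' annotated variant, harmonizing swapped ref/alt declarations by flipping
#' the reference frequency, and dropping strand-ambiguous A/T and C/G sites
#' that need flipping, with a warning. `delta` is signed on the study
#' table's ALT allele; `ratio` is `af_study / af_ref` (`NA` when
#' `af_ref = 0`). Rows are sorted by `|delta|` descending. Annotated
#' variants missing from either table are returned in the `skipped`
#' attribute rather than raising an error.
#'
#' @param study,reference Data frames with columns `chrom`, `pos`, `rsid`,
#'   `ref`, `alt`, `alt_freq` (as from [estimate_allele_frequencies()] or
#'   an external frequency export).
#' @param annotations Clinical annotations (from
#'   [load_clinical_annotations()]); each annotated rsid contributes one
#'   output row carrying its strongest (lowest-tier) evidence level.
#' @return Data frame `chrom`, `pos`, `rsid`, `gene`, `ref`, `alt`,
#'   `af_study`, `af_ref`, `delta`, `ratio`, `evidence_level`,
#'   `high_evidence`; attribute `skipped` lists unresolvable rsids.
#' @export
compare_allele_frequencies <- function(study, reference, annotations) {
  ann <- annotations[order(EVIDENCE_RANK[annotations$evidence_level]), ,
                     drop = FALSE]
  ann <- ann[!duplicated(ann$rsid), , drop = FALSE]

  skey <- if (all(nzchar(study$rsid))) study$rsid else
    site_id(study$chrom, study$pos, study$ref, study$alt)
  rkey <- if (all(nzchar(reference$rsid))) reference$rsid else
    site_id(reference$chrom, reference$pos, reference$ref, reference$alt)

  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(ann))) {
    rs <- ann$rsid[i]
    si <- match(rs, skey); ri <- match(rs, rkey)
    if (is.na(si) || is.na(ri)) {
      skipped <- c(skipped, rs)
      next
    }
    af_ref <- reference$alt_freq[ri]
    same <- study$ref[si] == reference$ref[ri] &
      study$alt[si] == reference$alt[ri]
    flipped <- study$ref[si] == reference$alt[ri] &
      study$alt[si] == reference$ref[ri]
    if (!same && flipped) {
      pair <- sort(c(study$ref[si], study$alt[si]))
      if (identical(pair, c("A", "T")) || identical(pair, c("C", "G"))) {
        warning("dropping strand-ambiguous site ", rs, call. = FALSE)
        skipped <- c(skipped, rs)
        next
      }
      af_ref <- 1 - af_ref
    } else if (!same) {
      warning("allele mismatch at ", rs, "; skipped", call. = FALSE)
      skipped <- c(skipped, rs)
      next
    }
    af_study <- study$alt_freq[si]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = study$chrom[si], pos = study$pos[si], rsid = rs,
      gene = ann$gene[i], ref = study$ref[si], alt = study$alt[si],
      af_study = af_study, af_ref = af_ref,
      delta = af_study - af_ref,
      ratio = if (af_ref > 0) af_study / af_ref else NA_real_,
      evidence_level = ann$evidence_level[i],
      high_evidence = ann$high_evidence[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), rsid = character(0),
               gene = character(0), ref = character(0), alt = character(0),
               af_study = numeric(0), af_ref = numeric(0), delta = numeric(0),
               ratio = numeric(0), evidence_level = character(0),
               high_evidence = logical(0))
  out <- out[order(-abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Tiered allele-frequency differentiation screen
#'
#' High-evidence variants (tiers 1A/1B/2A/2B) are screened on
#' \eqn{|\Delta| \ge} `high_cut` and additionally on
#' \eqn{\Delta \ge} `high_up_cut`; low-evidence variants (tiers 3/4) on
#' \eqn{\Delta \ge} `low_up_cut` (more frequent in the study population) and
#' \eqn{\Delta \le} `low_down_cut` (less frequent).
#'
#' @param rows Output of [compare_allele_frequencies()].
#' @param high_cut Absolute-delta cutoff for the high-evidence tier
#'   (default 0.05).
#' @param high_up_cut Signed-delta cutoff for the strongly elevated
#'   high-evidence subset (default 0.10).
#' @param low_up_cut,low_down_cut Signed-delta cutoffs for the low-evidence
#'   tiers (defaults 0.10 and -0.10).
#' @return A list of data frames `high_abs`, `high_up`, `low_up`,
#'   `low_down`, plus `all` with a `tier` label column.
#' @export
screen_differentiated_variants <- function(rows, high_cut = 0.05,
                                           high_up_cut = 0.10,
                                           low_up_cut = 0.10,
                                           low_down_cut = -0.10) {
  hi <- rows$high_evidence
  high_abs <- rows[hi & abs(rows$delta) >= high_cut, , drop = FALSE]
  high_up <- rows[hi & rows$delta >= high_up_cut, , drop = FALSE]
  low_up <- rows[!hi & rows$delta >= low_up_cut, , drop = FALSE]
  low_down <- rows[!hi & rows$delta <= low_down_cut, , drop = FALSE]
  all <- rows
  all$tier <- ifelse(hi,
                     ifelse(all$delta >= high_up_cut, "high_up",
                            ifelse(abs(all$delta) >= high_cut, "high_abs", "none")),
                     ifelse(all$delta >= low_up_cut, "low_up",
                            ifelse(all$delta <= low_down_cut, "low_down", "none")))
  list(high_abs = high_abs, high_up = high_up,
       low_up = low_up, low_down = low_down, all = all)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Tests equality of two binomial proportions (`count_a` of `n_a` vs
#' `count_b` of `n_b`) by the hypergeometric point-probability rule: the
#' two-sided p-value is the sum of the probabilities of all tables with the
#' same margins that are no more probable than the observed one (with the
#' customary relative tolerance on ties).
#'
#' @param count_a,count_b Success counts.
#' @param n_a,n_b Totals.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(count_a, n_a, count_b, n_b) {
  if (n_a <= 0 || n_b <= 0) pgx_stop("totals must be positive")
  if (count_a < 0 || count_a > n_a || count_b < 0 || count_b > n_b) {
    pgx_stop("counts must lie in [0, total]")
  }
  k <- count_a + count_b            # successes in the pooled margin
  lo <- max(0L, k - n_b); hi <- min(n_a, k)
  support <- lo:hi
  dens <- stats::dhyper(support, n_a, n_b, k)
  p_obs <- dens[match(count_a, support)]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the input order (wraps the standard BH
#' procedure, with input validation).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, `q >= p`, clipped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    pgx_stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare per-gene phenotype frequencies between two cohorts
#'
#' The reference is supplied as phenotype frequencies with its cohort size;
#' reference counts are reconstructed as `round(freq * n_ref)` so that an
#' exact test is possible. Each (gene, phenotype) present in either cohort
#' is tested with [fisher_exact_2x2()] (absent side counted 0) and the
#' p-values are BH-adjusted across all rows.
#'
#' @param summary_study A `pgx_cohort_summary` (or its `gene_phenotype`
#'   table plus `cohort_size`).
#' @param reference_freqs Data frame `gene`, `phenotype`, `frequency`,
#'   `n_ref`.
#' @param alpha Significance level (default 0.05).
#' @param use_q Flag significance on the BH q-value (default) or on the raw
#'   p-value.
#' @return Data frame `gene`, `phenotype`, `count_study`, `n_study`,
#'   `count_ref`, `n_ref`, `freq_delta`, `p_value`, `q_value`,
#'   `significant`.
#' @export
compare_phenotype_frequencies <- function(summary_study, reference_freqs,
                                          alpha = 0.05, use_q = TRUE) {
  if (inherits(summary_study, "pgx_cohort_summary")) {
    gp <- summary_study$gene_phenotype
    n_study <- summary_study$cohort_size
  } else {
    gp <- summary_study$gene_phenotype
    n_study <- summary_study$cohort_size
    if (is.null(gp) || is.null(n_study)) {
      pgx_stop("summary_study must carry gene_phenotype and cohort_size")
    }
  }
  if (!"n_ref" %in% names(reference_freqs) ||
      any(is.na(reference_freqs$n_ref))) {
    pgx_stop("reference table must carry n_ref (frequencies alone cannot ",
             "drive an exact test)")
  }
  skey <- paste(gp$gene, gp$phenotype, sep = "\r")
  rkey <- paste(reference_freqs$gene, reference_freqs$phenotype, sep = "\r")
  keys <- union(skey, rkey)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  genes <- vapply(parts, `[`, "", 1L)
  phenos <- vapply(parts, `[`, "", 2L)
  si <- match(keys, skey); ri <- match(keys, rkey)
  count_study <- ifelse(is.na(si), 0L, gp$count[si])
  n_ref <- reference_freqs$n_ref[ifelse(is.na(ri), 1L, ri)]
  # a phenotype absent from the reference still needs that gene's n_ref
  gene_nref <- tapply(reference_freqs$n_ref, reference_freqs$gene, `[`, 1L)
  n_ref[is.na(ri)] <- gene_nref[genes[is.na(ri)]]
  if (any(is.na(n_ref))) pgx_stop("missing n_ref for gene ",
                                  genes[is.na(n_ref)][1])
  count_ref <- ifelse(is.na(ri), 0L,
                      as.integer(round(reference_freqs$frequency[ri] *
                                         reference_freqs$n_ref[ri])))
  p <- mapply(fisher_exact_2x2, count_study, n_study, count_ref, n_ref)
  q <- bh_adjust(p)
  out <- data.frame(gene = genes, phenotype = phenos,
                    count_study = count_study, n_study = n_study,
                    count_ref = count_ref, n_ref = as.integer(n_ref),
                    freq_delta = count_study / n_study - count_ref / n_ref,
                    p_value = p, q_value = q,
                    significant = if (use_q) q < alpha else p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
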