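# Phenotype assignment, per-individual burden and cohort summaries.

#' Map diplotype calls to phenotypes
#'
#' Each called diplotype is looked up in the phenotype map (the lookup is
#' unordered in the allele pair). Calls with status `not_available` (or
#' `ambiguous`) receive the phenotype `"Not available"`; called pairs absent
#' from the map receive `"Indeterminate"`. Both reserved labels are never
#' nontypical.
#'
#' @param calls Data frame of diplotype calls (as from [call_cohort()] or
#'   [call_diplotype()]).
#' @param map A `phenotype_map`.
#' @return Data frame `sample`, `gene`, `phenotype`, `nontypical`.
#' @export
assign_phenotype <- function(calls, map) {
  missing_gene <- setdiff(unique(calls$gene), unique(map$entries$gene))
  if (length(missing_gene)) {
    pgx_stop("gene(s) absent from the phenotype map: ",
             paste(missing_gene, collapse = ", "))
  }
  key <- paste(calls$gene, pair_key(calls$allele1, calls$allele2), sep = "\r")
  i <- match(key, map$entries$key)
  phenotype <- ifelse(calls$status != "called", "Not available",
                      ifelse(is.na(i), "Indeterminate",
                             map$entries$phenotype[i]))
  fkey <- paste(map$flags$gene, map$flags$phenotype, sep = "\r")
  j <- match(paste(calls$gene, phenotype, sep = "\r"), fkey)
  nontypical <- !is.na(j) & map$flags$nontypical[j]
  nontypical[phenotype %in% RESERVED_PHENOTYPES] <- FALSE
  data.frame(sample = calls$sample, gene = calls$gene,
             phenotype = phenotype, nontypical = nontypical,
             stringsAsFactors = FALSE)
}

#' Nontypical-response burden of one individual
#'
#' Counts the genes with a nontypical phenotype (at most one contribution
#' per gene) and collects the level-A drugs linked to any of those genes;
#' a drug shared by several nontypical genes is counted once.
#'
#' @param calls Phenotype calls of a single sample (one row per gene).
#' @param gene_drug Level-A gene-drug table (as from
#'   [load_gene_drug_table()]).
#' @return A list with `sample`, `n_nontypical_genes` and `at_risk_drugs`
#'   (character vector, sorted).
#' @export
individual_burden <- function(calls, gene_drug) {
  if (anyDuplicated(calls$gene)) {
    pgx_stop("duplicate gene in the calls of sample ", calls$sample[1])
  }
  nt_genes <- calls$gene[calls$nontypical]
  drugs <- sort(unique(gene_drug$drug[gene_drug$gene %in% nt_genes]))
  list(sample = calls$sample[1] %||% NA_character_,
       n_nontypical_genes = length(nt_genes),
       at_risk_drugs = drugs)
}

#' Per-sample burden table for a cohort
#'
#' Vectorized cohort-wide version of [individual_burden()].
#'
#' @param phenotype_calls Data frame of phenotype calls for all samples.
#' @param gene_drug Level-A gene-drug table.
#' @return Data frame `sample`, `n_nontypical_genes`, `n_drugs`, `drugs`
#'   (semicolon-separated).
#' @export
cohort_burden <- function(phenotype_calls, gene_drug) {
  if (anyDuplicated(paste(phenotype_calls$sample, phenotype_calls$gene))) {
    pgx_stop("duplicate (sample, gene) rows in phenotype calls")
  }
  samples <- unique(phenotype_calls$sample)
  nt <- phenotype_calls[phenotype_calls$nontypical, , drop = FALSE]
  n_genes <- table(factor(nt$sample, levels = samples))
  drug_by_gene <- split(gene_drug$drug, gene_drug$gene)
  drugs <- lapply(split(nt$gene, factor(nt$sample, levels = samples)),
                  function(g) sort(unique(unlist(drug_by_gene[g]))))
  data.frame(sample = samples,
             n_nontypical_genes = as.integer(n_genes[samples]),
             n_drugs = vapply(drugs[samples], length, 0L),
             drugs = vapply(drugs[samples], paste, "", collapse = ";"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate a burden table into its distribution
#'
#' @param burden Output of [cohort_burden()].
#' @return Data frame `n_individuals`, `n_drugs` (rows with
#'   `n_drugs >= 1` only, descending), plus attribute `cohort_size`.
#' @export
burden_distribution <- function(burden) {
  tab <- table(burden$n_drugs[burden$n_drugs >= 1L])
  out <- data.frame(n_individuals = as.integer(tab),
                    n_drugs = as.integer(names(tab)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_drugs), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cohort_size") <- nrow(burden)
  out
}

#' Summary statistics of a burden distribution
#'
#' @param dist Data frame `n_individuals`, `n_drugs` (one row per observed
#'   number of at-risk drugs >= 1).
#' @param cohort_size Total cohort size; individuals absent from the rows
#'   contribute zero drugs. Defaults to the `cohort_size` attribute.
#' @return A list: `n_ge1` (individuals at risk for at least one drug),
#'   `pct_ge1` (percentage of the cohort, 2 decimals), `mean_drugs`
#'   (mean number of at-risk drugs over the whole cohort).
#' @export
summarize_burden_distribution <- function(dist,
                                          cohort_size = attr(dist, "cohort_size")) {
  if (is.null(cohort_size)) pgx_stop("cohort_size is required")
  if (any(dist$n_drugs < 1L)) pgx_stop("distribution rows must have n_drugs >= 1")
  n_ge1 <- sum(dist$n_individuals)
  if (n_ge1 > cohort_size) {
    pgx_stop("distribution counts (", n_ge1, ") exceed the cohort size (",
             cohort_size, ")")
  }
  list(n_ge1 = n_ge1,
       pct_ge1 = round_half_up(100 * n_ge1 / cohort_size, 2),
       mean_drugs = sum(dist$n_individuals * dist$n_drugs) / cohort_size)
}

#' Cohort-level phenotype and drug-risk summary
#'
#' Produces the per-gene phenotype count/frequency table, the fraction of
#' the cohort carrying at least one nontypical diplotype, the mean number of
#' at-risk drugs per individual, the per-gene at-risk fractions, and the
#' per-drug at-risk fractions (an individual is at risk for a drug when any
#' gene linked to that drug carries a nontypical phenotype, so individuals
#' are unioned, not summed, across genes).
#'
#' @param phenotype_calls Phenotype calls for every sample x gene.
#' @param gene_drug Level-A gene-drug table.
#' @param risk_threshold Fraction above which a drug is reported in
#'   `drugs_over_threshold` (default 0.40).
#' @return An object of class `pgx_cohort_summary`: list with
#'   `cohort_size`, `gene_phenotype` (gene, phenotype, count, frequency to 8
#'   decimals), `gene_risk` (gene, n_at_risk, pct), `fraction_ge1`,
#'   `mean_drugs`, `drug_risk` (drug, n_at_risk, fraction),
#'   `drugs_over_threshold`, and `burden` (per-sample table).
#' @export
cohort_summary <- function(phenotype_calls, gene_drug, risk_threshold = 0.40) {
  samples <- unique(phenotype_calls$sample)
  n <- length(samples)
  if (n == 0L) pgx_stop("empty cohort")
  genes <- unique(phenotype_calls$gene)
  per_gene <- table(factor(phenotype_calls$gene, levels = genes))
  if (any(per_gene != n)) {
    pgx_stop("phenotype calls must cover every sample for every gene")
  }

  key <- paste(phenotype_calls$gene, phenotype_calls$phenotype, sep = "\r")
  tab <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(tab$key, "\r", fixed = TRUE)
  gene_phenotype <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    phenotype = vapply(parts, `[`, "", 2L),
    count = tab$Freq,
    frequency = round_half_up(tab$Freq / n, 8),
    stringsAsFactors = FALSE)
  gene_phenotype <- gene_phenotype[order(gene_phenotype$gene,
                                         -gene_phenotype$count), , drop = FALSE]
  rownames(gene_phenotype) <- NULL

  nt <- phenotype_calls[phenotype_calls$nontypical, , drop = FALSE]
  gene_risk <- data.frame(
    gene = genes,
    n_at_risk = vapply(genes, function(g) length(unique(nt$sample[nt$gene == g])), 0L),
    stringsAsFactors = FALSE)
  gene_risk$pct <- round_half_up(100 * gene_risk$n_at_risk / n, 2)

  burden <- cohort_burden(phenotype_calls, gene_drug)
  fraction_ge1 <- sum(burden$n_nontypical_genes >= 1L) / n
  mean_drugs <- mean(burden$n_drugs)

  drugs <- sort(unique(gene_drug$drug))
  drug_risk <- data.frame(drug = drugs, n_at_risk = 0L,
                          stringsAsFactors = FALSE)
  if (nrow(nt)) {
    for (k in seq_along(drugs)) {
      g <- gene_drug$gene[gene_drug$drug == drugs[k]]
      drug_risk$n_at_risk[k] <- length(unique(nt$sample[nt$gene %in% g]))
    }
  }
  drug_risk$fraction <- drug_risk$n_at_risk / n
  drug_risk <- drug_risk[order(-drug_risk$fraction, drug_risk$drug), , drop = FALSE]
  rownames(drug_risk) <- NULL

  structure(list(cohort_size = n,
                 gene_phenotype = gene_phenotype,
                 gene_risk = gene_risk,
                 fraction_ge1 = fraction_ge1,
                 mean_drugs = mean_drugs,
                 drug_risk = drug_risk,
                 drugs_over_threshold =
                   drug_risk$drug[drug_risk$fraction > risk_threshold],
                 burden = burden),
            class = "pgx_cohort_summary")
}

#' @export
print.pgx_cohort_summary <- function(x, ...) {
  cat("<pgx_cohort_summary> ", x$cohort_size, " individuals, ",
      length(unique(x$gene_phenotype$gene)), " genes\n",
      "  >=1 nontypical diplotype: ",
      sprintf("%.2f%%", 100 * x$fraction_ge1), "\n",
      "  mean at-risk drugs per individual: ",
      sprintf("%.2f", x$mean_drugs), "\n",
      "  drugs over risk threshold: ",
      length(x$drugs_over_threshold), "\n", sep = "")
  invisible(x)
}
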