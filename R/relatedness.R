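# Pairwise IBD estimation (method of moments on IBS counts) and greedy
# pruning to an unrelated subset.

#' Estimate pairwise genome-wide IBD proportion
#'
#' Method-of-moments estimator in the PLINK tradition: for each pair of
#' individuals, the observed identity-by-state (IBS) counts over the marker
#' set are combined with allele-frequency-based expectations to solve for
#' the IBD state probabilities \eqn{P(IBD=0), P(IBD=1), P(IBD=2)}, and
#' \eqn{\hat\pi = P(IBD=1)/2 + P(IBD=2)}, clipped to [0, 1]. Markers should
#' be common (the default subset keeps MAF > 0.05) and approximately in
#' linkage equilibrium. Missing genotypes are excluded pairwise, with the
#' expectation sums restricted accordingly.
#'
#' @param cohort A [cohort_genotypes] object.
#' @param marker_subset Site ids (or marker indices) to use; default: all
#'   markers with MAF > 0.05.
#' @return An object of class `pi_matrix`: list with `samples` and `pi`, a
#'   symmetric matrix with unit diagonal.
#' @export
estimate_pairwise_pi <- function(cohort, marker_subset = NULL) {
  mk <- cohort$markers
  if (is.null(marker_subset)) {
    keep <- which(!is.na(mk$maf) & mk$maf > 0.05)
  } else if (is.character(marker_subset)) {
    keep <- match(marker_subset, mk$site_id)
    if (anyNA(keep)) pgx_stop("unknown site id in marker_subset")
  } else {
    keep <- as.integer(marker_subset)
  }
  if (length(keep) < 50L) {
    pgx_stop("insufficient markers for IBD estimation (", length(keep),
             " usable, need >= 50)")
  }
  g <- cohort$hap1[, keep, drop = FALSE] + cohort$hap2[, keep, drop = FALSE]
  p <- mk$alt_freq[keep]
  q <- 1 - p
  n <- nrow(g)

  # indicator matrices per genotype class; missing handled via validity mask
  valid <- !is.na(g)
  gz <- g; gz[!valid] <- 0L
  A0 <- (gz == 0L) & valid
  A1 <- (gz == 1L) & valid
  A2 <- (gz == 2L) & valid
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  storage.mode(valid) <- "double"

  N_ibs0 <- A0 %*% t(A2) + A2 %*% t(A0)
  N_same <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  M_val <- valid %*% t(valid)
  N_ibs1 <- M_val - N_same - N_ibs0

  # per-marker conditional IBS-state probabilities given IBD state
  e00 <- 2 * p^2 * q^2                 # P(IBS0 | IBD0)
  e10 <- 4 * p^3 * q + 4 * p * q^3     # P(IBS1 | IBD0)
  e20 <- p^4 + q^4 + 4 * p^2 * q^2     # P(IBS2 | IBD0)
  e11 <- 2 * p^2 * q + 2 * p * q^2     # P(IBS1 | IBD1)
  e21 <- p^3 + q^3 + p^2 * q + p * q^2 # P(IBS2 | IBD1)

  wsum <- function(e) valid %*% (e * t(valid))  # pairwise sum over valid markers
  E00 <- wsum(e00); E10 <- wsum(e10); E20 <- wsum(e20)
  E11 <- wsum(e11); E21 <- wsum(e21)

  N_ibs2 <- N_same  # identical genotypes
  P0 <- N_ibs0 / E00
  P1 <- (N_ibs1 - P0 * E10) / E11
  P2 <- (N_ibs2 - P0 * E20 - P1 * E21) / M_val
  P0 <- pmin(pmax(P0, 0), 1)
  P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  pi_hat <- pmin(pmax(P1 / 2 + P2, 0), 1)
  diag(pi_hat) <- 1
  pi_hat <- (pi_hat + t(pi_hat)) / 2
  dimnames(pi_hat) <- list(cohort$samples, cohort$samples)
  structure(list(samples = cohort$samples, pi = pi_hat), class = "pi_matrix")
}

#' @export
print.pi_matrix <- function(x, ...) {
  off <- x$pi[upper.tri(x$pi)]
  cat("<pi_matrix> ", length(x$samples), " samples; off-diagonal pi: ",
      "median ", signif(stats::median(off), 3),
      ", max ", signif(max(off), 3), "\n", sep = "")
  invisible(x)
}

#' Write / read a pi matrix as a pair list
#'
#' Long-format TSV `sample_i`, `sample_j`, `pi` over the upper triangle.
#'
#' @param pi A `pi_matrix`.
#' @param path Output path.
#' @export
write_pi_matrix <- function(pi, path) {
  ut <- which(upper.tri(pi$pi), arr.ind = TRUE)
  write_tsv(data.frame(sample_i = pi$samples[ut[, 1]],
                       sample_j = pi$samples[ut[, 2]],
                       pi = pi$pi[ut]), path)
}

#' Prune a cohort to an unrelated subset
#'
#' For each pair with \eqn{\pi} above the threshold, the offspring is
#' preferentially removed when the pair belongs to a trio; remaining flagged
#' pairs are resolved by iteratively removing the individual with the
#' largest summed \eqn{\pi} over its still-flagged relationships, ties
#' broken by sample-identifier order, until no flagged pair remains.
#'
#' @param pi A `pi_matrix`.
#' @param pedigree Optional pedigree: data frame with columns `father`,
#'   `mother`, `child` (one row per trio), or `NULL`.
#' @param threshold Pi cutoff above which a pair is considered related
#'   (default 0.05).
#' @return Character vector of retained sample identifiers (original order);
#'   no retained pair has pi above the threshold.
#' @export
prune_related <- function(pi, pedigree = NULL, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  samples <- pi$samples
  P <- pi$pi
  diag(P) <- 0
  flagged <- P > threshold
  removed <- character(0)

  if (!is.null(pedigree) && nrow(pedigree)) {
    bad <- !(unlist(pedigree[, c("father", "mother", "child")]) %in% samples)
    if (any(bad)) pgx_stop("pedigree identifiers not in the pi matrix")
    if (any(pedigree$child == pedigree$father |
            pedigree$child == pedigree$mother)) {
      pgx_stop("a trio child cannot be its own parent")
    }
    # first pass: drop every trio offspring involved in any flagged pair
    kids <- pedigree$child
    involved <- kids[rowSums(flagged[kids, , drop = FALSE]) > 0L]
    removed <- c(removed, involved)
    flagged[involved, ] <- FALSE
    flagged[, involved] <- FALSE
  }

  # iterative greedy: recompute summed pi over remaining flagged pairs
  while (any(flagged)) {
    s <- rowSums(P * flagged)
    s[rowSums(flagged) == 0L] <- -Inf
    worst <- which(s == max(s))
    worst <- worst[order(samples[worst])][1]  # deterministic tie-break
    removed <- c(removed, samples[worst])
    flagged[worst, ] <- FALSE
    flagged[, worst] <- FALSE
  }
  setdiff(samples, removed)
}
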