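---
title: "Methods: population pharmacogenetic profiling from phased genotypes"
author: "pgxprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacogenetic profiling from phased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxprofiler)
```

## The problem

Many clinically used drugs are metabolized, transported, or targeted by
proteins whose genes carry common functional haplotypes ("star alleles":
named combinations of variant alleles on one chromosome, with `*1`
conventionally the reference haplotype). An individual's *diplotype* -- the
pair of star alleles carried at one gene -- predicts a drug-response
phenotype (e.g. "Poor Metabolizer", "Decreased warfarin dose"), and CPIC
guidelines attach prescribing recommendations to many of these phenotypes.
Profiling a genotyped population therefore answers questions that matter for
planning a pharmacogenetic screening program: what fraction of individuals
carry at least one diplotype with a *nontypical* response (one for which
guidance recommends an alternate dose or drug), to how many drugs is the
average individual expected to respond atypically, and which clinically
annotated variants are strongly frequency-differentiated relative to a
reference population.

`pgxprofiler` implements this pipeline end to end on phased cohort VCFs:
knowledge-table loading, post-imputation marker filtering, IBD-based
relatedness pruning, exact-match diplotype calling, phenotype mapping and
burden summaries, and a study-vs-reference allele-frequency differentiation
screen with Fisher exact testing and Benjamini-Hochberg FDR control. A
companion simulator generates phased cohorts with known star-allele truth so
that every stage is testable without access to any real cohort.

## Diplotype calling

Calling is *exact matching*, in the tradition of PharmCAT-style engines: a
star allele matches a haplotype iff every one of its defining sites is
observed and carries the required allele, **and** every other declared site
of the gene that is observed carries the reference allele. The reference
star allele (empty defining set) consequently matches exactly the
all-reference haplotype. This makes matches almost always unique: an allele
defined by a subset of another allele's sites (e.g. `*2` = site 1, `*3` =
sites 1+2) cannot fire when the superset fires, because the extra observed
ALT site violates the all-other-sites-reference condition.

Three deliberate choices:

* **Missing data never produce a call.** If either haplotype of a sample
  has a missing declared site, the diplotype is `not_available`. Exact
  matching cannot certify a haplotype it cannot see; the large
  "Not available" phenotype classes that result are reported as such, never
  imputed away. Under simulation this guarantees that genotype missingness
  degrades calls to `not_available` and never to a *wrong* called diplotype
  (a property the test suite checks at missingness 0, 0.05 and 0.2).
* **Tie-breaking.** If a haplotype still matches several alleles, the one
  satisfying the most defining sites wins; if that count is tied between
  distinct alleles the call is reported as `ambiguous` rather than picking a
  winner silently (candidates are listed in lexicographic order for
  determinism). With the bundled definitions ambiguity cannot arise; it is
  reachable only with redundant definition tables.
* **Canonical pair order.** Diplotypes are unordered; calls are reported
  with the reference allele first, then lexicographically, so a call is
  invariant under swapping the two physical haplotypes.

Structural variants and copy number (relevant to CYP2D6 in particular) are
out of scope; genes whose alleles require them inherit that limitation.

## Phenotypes, nontypicality and burden

Nontypical status is **data, not logic**: the phenotype map carries one flag
per (gene, phenotype), because nontypicality is defined by external CPIC
guidance, not derivable from the genotype. The reserved labels
`"Not available"` (uncallable) and `"Indeterminate"` (called pair absent
from the map) are never nontypical -- a conservative choice that matches how
published summary tables mark their atypical classes.

The per-individual burden counts *genes* (at most one contribution per
gene), and the set of at-risk drugs is the union over level-A gene-drug
pairs of that individual's nontypical genes, so a drug linked to several
affected genes (warfarin, typically) is counted once. Per-drug population
risk is likewise the unioned fraction of individuals nontypical in at least
one gene linked to the drug, not the maximum single-gene fraction: being at
risk is an individual-level event. Percentages are reported to 2 decimals
and frequencies to 8 decimals, rounding half away from zero, matching the
conventions of the published tables the package reproduces.

Only gene-drug pairs with CPIC evidence level A are counted by default
(`load_gene_drug_table(level_filter = "A")`); drug names are compared
case-insensitively after trimming, since source tables mix cases.

## Relatedness pruning

Allele frequencies must be estimated on unrelated individuals. Pairwise
relatedness is summarized by the genome-wide IBD proportion
$\hat\pi = P(\mathrm{IBD}{=}1)/2 + P(\mathrm{IBD}{=}2)$, estimated with the
standard PLINK-style method of moments: observed IBS counts per pair are
equated to their allele-frequency expectations and solved state by state,
each probability clipped to $[0,1]$. The estimator assumes common markers
(default subset: MAF > 0.05) in approximate linkage equilibrium; missing
genotypes are excluded pairwise with the expectation sums restricted to the
markers both samples observe.

Pruning at $\pi > 0.05$ follows a two-stage greedy rule: first remove every
trio offspring involved in any flagged pair; then iteratively remove the
individual with the largest summed $\pi$ over the remaining flagged pairs
(recomputed after each removal; ties broken by sample identifier), until no
flagged pair remains. The iterative form makes the procedure deterministic
and leaves, by construction, no retained pair above the threshold.

## Population comparison

The differentiation screen joins study and reference ALT-frequency tables on
rsid, harmonizing swapped ref/alt declarations by flipping the reference
frequency and dropping strand-ambiguous A/T and C/G sites that would need
flipping. `delta` is signed on the study table's declared ALT allele.
High-evidence variants (PharmGKB tiers 1A/1B/2A/2B) are screened at
$|\Delta| \ge 0.05$ with an elevated subset at $\Delta \ge 0.10$;
low-evidence variants (tiers 3/4) at $\Delta \ge 0.10$ and
$\Delta \le -0.10$. All cutoffs are arguments.

Phenotype-frequency differences are tested with a two-sided Fisher exact
test using the point-probability rule (sum of hypergeometric outcomes no
more probable than the observed table, with the customary $1+10^{-7}$
relative tie tolerance, so results coincide with `stats::fisher.test` to
machine precision -- the suite verifies agreement to $10^{-12}$ on random
tables). Because exact tests need counts and external summaries publish
frequencies, the reference cohort size is a required input and reference
counts are reconstructed as `round(freq * n_ref)`; p-values obtained this
way are faithful to the reconstruction, not to the unpublished raw counts.
BH q-values come from the standard step-up procedure (`stats::p.adjust`),
validated against an independently coded step-up reference.

## The synthetic cohort generator

The simulator emulates the statistical structure of a phased,
family-enriched cohort:

* per gene, two haplotypes per individual drawn i.i.d. from a configured
  star-allele frequency table (Hardy-Weinberg equilibrium), rendered to
  site-level alleles through the gene's defining sites;
* optional neutral background markers in linkage equilibrium with given
  truth frequencies, standing in for the genome-wide random SNP set used
  for IBD estimation;
* designated site pairs locked to $r^2 = 1$ (one underlying draw), mirroring
  known perfectly correlated variant pairs such as the two VKORC1 promoter
  tags;
* trios whose child receives one transmitted haplotype per parent (chosen
  per gene and per background marker, i.e. free recombination), giving
  parent-child $\pi = 0.5$ by construction;
* per-genotype missingness, and unphasing applied only to heterozygotes
  (homozygotes carry no phase information).

One seeded generator drives a run; the seed is written into the VCF header,
and identical configurations are byte-identical. Default haplotype
frequencies put the VKORC1 promoter-variant haplotype at 0.509 and CYP4F2
`*3` at 0.415 (study-population values); the remaining genes use typical
European star-allele frequencies on the toy definitions. What the generator
does **not** emulate: background LD beyond the explicit locks, demographic
history, genotyping or imputation error structure beyond the missingness and
unphasing knobs, and structural variation. Passing recovery tests therefore
demonstrates correctness of the calling and estimation machinery, not
robustness to every artifact of real data.

## Bundled knowledge tables

The package ships **toy** knowledge tables under
`inst/extdata/toy_knowledge/`: 14 pharmacogenes (CFTR, CYP2B6, CYP2C19,
CYP2C9, CYP2D6, CYP3A5, CYP4F2, DPYD, IFNL3, NUDT15, SLCO1B1, TPMT, UGT1A1,
VKORC1) with one to three defining sites each, schema-compatible with
flattened PharmCAT-style exports, so loaders written against the toy tables
work unchanged on real exports in the same dialect. Phenotype labels,
nontypical flags, level-A drug lists, published per-gene phenotype counts
and the burden distribution mirror published cohort summary tables;
allele-frequency fixtures carry published study/reference frequencies for
37 clinically annotated variants (reference *alleles* at those sites, and
the evidence levels of most low-evidence variants, are not published and
are synthetic stand-ins, marked as such in the file names and here).
Composite or unusual allele labels are treated as opaque names.

## Numerical and degenerate-input choices

* Site identity is exact `(chrom, pos, ref, alt)` string match, 1-based as
  in VCF; no indel normalization (mismatches surface as "site absent").
* Frequency denominators exclude missing haplotypes; a genotype with one
  missing allele is missing as a unit; an all-missing site reports `NA`
  frequency with `n_hap = 0`.
* The marker quality filter keeps imputation quality > 0.3 at MAF >= 1%,
  > 0.6 below, and always keeps markers without a quality value (directly
  genotyped); it is idempotent.
* Unphased heterozygotes are an error by default (exact matching requires
  phase) and can be demoted to missing; unphased homozygotes are accepted.
* IBD estimation refuses fewer than 50 usable markers; degenerate
  expectation denominators cannot arise at MAF > 0.05.
* Empty cohorts, duplicate (sample, gene) rows, counts exceeding totals and
  invalid evidence levels are hard errors, not warnings.

## Problem sizes used in the tests

The validation suite runs at desk scale: caller-recovery checks use 500
individuals over the 14 toy genes at three seeds; the Fisher null
calibration uses 2000 simulated binomial(500, 0.3) tables; BH validation
uses 1000 random vectors; the relatedness check uses 100 unrelated
individuals plus 50 trios over 40,000 background markers at MAF 0.3-0.5, a
size at which the moment estimator's sampling noise for unrelated pairs
(max $\hat\pi \approx 0.035$ across the ~31,000 pairs) sits safely below
the 0.05 pruning threshold while parent-child pairs estimate at
$0.500 \pm 0.01$.

## Known limitations

* No structural-variant or copy-number awareness, hence no reliable CYP2D6
  calling on real data.
* Exact matching only: no probabilistic or partial haplotype matching, no
  phase inference.
* Burden statistics weight all drugs equally; without prescription data the
  population at *clinical* risk cannot be derived from genetics alone.
* Reconstructed reference counts make the phenotype-comparison p-values
  conditional on the published rounding of reference frequencies.
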