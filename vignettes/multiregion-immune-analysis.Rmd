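---
title: "Multi-region tumor immune analysis with tilscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region tumor immune analysis with tilscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscape)
```

## The scientific setting

When several spatially separated samples are taken from one patient's
tumor(s), three layers of data can be profiled in parallel: the T cell
receptor beta (TCRB) repertoire of the infiltrating lymphocytes (TILs),
the somatic mutations of the tumor cells, and gene expression of the
tissue.  `tilscape` implements the integrative analysis of such a design:

1. **Repertoire statistics** — how clonal is each sample's TIL
   population, and how much do samples share?
2. **Mutation phylogeny** — after a strict filtering cascade, which
   mutations are shared between tumor masses, and what ancestral tree do
   the binary mutation profiles imply?
3. **Pathway activity** — which pathways' single-sample activity scores
   track the per-sample repertoire diversity?
4. **Signature and survival** — which genes from those pathways are
   expressed stably across regions, and does their pattern stratify an
   independent patient cohort by prognosis?

A companion set of seeded generators simulates each input with the
statistical structure the analysis assumes, so the full pipeline is
exercised end to end without any external data.

## Repertoire statistics

A clonotype is identified by its CDR3 nucleotide sequence together with
the V and J segment call (amino-acid keying is available via `key_by`);
counts are authoritative and frequencies are always recomputed from them.
The central quantities are:

* **Shannon-Wiener diversity** `H = -sum(p_i * log(p_i))` over clonotype
  frequencies, in nats.  The natural logarithm, unnormalized, is the
  ecological convention; `H` is bounded by `log(richness)`.
* **TOP-N expanded clones** (default N = 250), with ties broken by
  count, then CDR3 sequence, then V segment, so results are
  reproducible.
* **Two overlap definitions.**  `pairwise_topn_overlap()` compares TOP-N
  lists: `100 * |topN(A) n topN(B)| / min(N, |topN(A)|, |topN(B)|)`
  (symmetric).  `topn_vs_full_overlap()` asks what fraction of A's TOP-N
  occurs *anywhere* in B (asymmetric).  The adaptive denominator keeps
  samples with fewer than N clones comparable; overlap is unweighted set
  overlap on clone identity.
* **Sample comparison tests.**  Kruskal-Wallis on each sample's
  off-diagonal overlap values (asymptotic chi-square p), and a two-sided
  Wilcoxon rank-sum comparison of diversity between groups, computed by
  exact enumeration of all group assignments on midranks when the
  combined n is at most 10.

## The mutation filtering cascade and parsimony tree

Candidate somatic calls pass four post-calling filters: germline depth
at least 10x, zero germline non-reference reads, a protein-altering
annotation (missense, nonsense/stopgain, stoploss, frameshift and
non-frameshift indels, canonical splice), and a *cluster* rule — when
two or more candidates fall within 100 bp on one contig all of them are
removed as likely alignment artifacts.  The window is configurable
(`analysis_config()`); rejected calls carry every failed rule, and the
retained set does not depend on input order.

The filtered binary presence/absence matrix feeds a germline-rooted
maximum parsimony reconstruction.  All rooted topologies over the
samples (with an implicit all-absent germline leaf) are searched by
branch-and-bound over stepwise leaf insertion — exact for up to 12
samples, which covers multi-region designs.  The Fitch score of a
candidate topology is computed by the classic two-state set operations;
`fitch_length()` exposes this scorer directly so the search can be
audited against exhaustive enumeration.  Determinism comes from two
conventions:

* among equally parsimonious topologies, the lexicographically smallest
  canonical Newick string wins;
* ambiguous ancestral states take the parent's state (the classic Fitch
  top-down refinement).  This places changes as *late* (as far from the
  root) as possible; it provably attains the Fitch score, so edge
  lengths — integer mutation counts — always sum to the parsimony score.
  We prefer this late-placement rule to the accelerated (ACCTRAN)
  alternative because it is the direct refinement of the first-pass
  sets, needs no extra bookkeeping, and makes the germline trunk
  interpretation conservative.

Samples without any detected mutation are removed before the search
(an all-absent column carries no topological information and would sit
at the germline).  Mutations are classified as `shared` (at least one
sample of every mass), `mass_specific` (two or more samples of exactly
one mass) or `region_unique` (exactly one sample).

## Single-sample pathway activity and the diversity screen

Pathway activity per sample is scored from scratch by a rank-based
random walk over kernel-smoothed expression statistics (the gene set
variation approach for continuous intensity data):

1. For gene *i* in sample *j*,
   `z_ij = (1/n) * sum_k pnorm((x_ij - x_ik) / h_i)` with bandwidth
   `h_i = s_i / 4`; a constant gene takes 0.5 everywhere.  The statistic
   is invariant to per-gene increasing affine rescaling.
2. Per sample, genes are ranked by decreasing `z` (ties broken by gene
   name) and weighted `w = |p/2 - rank|` — symmetric, so both extremes
   of the ranking are influential.
3. Walking the ranked list, in-set genes add `w^tau / sum(w^tau)`
   (tau = 1), out-of-set genes subtract `1/(p - m)`; the score is the
   maximum positive plus the minimum negative deviation of the walk.

Sets with fewer than 5 mapped genes are skipped.  The screen then
correlates each set's score vector with per-sample Shannon diversity
(Spearman) and flags sets with rho strictly above 0.75; p-values are
reported but, following the study design, the flag uses rho alone and no
multiplicity correction is applied.

For sample sizes up to 10 without ties the Spearman p-value is *exact*:
the permutation null of the rank statistic is enumerated once per
sample size in compiled code and cached, so screening hundreds of
pathways costs one enumeration.  With ties, or beyond n = 10, the usual
t approximation on `n - 2` degrees of freedom is used.

**A caveat worth knowing.**  With ~200 candidate pathways and only 10
samples, the exact null probability of rho > 0.75 is about 0.008 per
pathway, so roughly 1–2 pathways are expected to pass the screen by
chance even with no signal at all.  A rho-only threshold at this sample
size is a *ranking* device, not an error-controlled test; the simulation
suite quantifies exactly this behavior.

## Stable-gene signature and survival stratification

From the genes of the screen-passing pathways, the coefficient of
variation `CV = sd/mean` across the multi-region samples measures how
strongly intratumor heterogeneity moves a gene.  Genes with
`log2(CV) < -5.5` (CV below ~0.022 on the log2-intensity scale used
throughout; zero-variance genes are always selected) form the stable
signature.  The cutoff is kept as the configured constant; for new
datasets `find_cv_knee()` locates the bend of the sorted log2(CV) curve
by the maximum-distance-to-chord heuristic.  The CV is computed on the
same normalized log2 scale as every other expression analysis — the
-5.5 cutoff is only plausible on that scale.

Patients of an independent cohort are stratified by hierarchical
clustering over the z-scored signature genes with distance
1 - Pearson correlation and average linkage (the prevailing convention
for expression heatmaps; Euclidean/Ward are available), cut at k = 2.
Labels are relabeled deterministically (larger cluster first, ties by
alphabetically first member) so they do not depend on column order.
The clusters are compared by Kaplan-Meier estimation and the two-group
log-rank test via the survival package.  One practical note: survival's
internal tie handling merges event times closer than a relative
tolerance, so comparisons across monotone *rescalings* of time are exact
only while times stay within a modest dynamic range.

## What the generators emulate — and what they do not

All generators are pure functions of their configuration and seed; they
restore the caller's RNG state on exit.

* `simulate_repertoires()` — right-skewed clone abundances (truncated
  discrete power law, exponent 2.5 by default, in the 2–3 range typical
  of clone-size distributions; log-normal alternative), pairwise sharing
  realized through nested clone pools (a pool common to all samples
  including blood, a tumor-only pool, sample-private remainder), and one
  hyperexpanded public clone planted at 10% of the blood repertoire.
  Defaults are ten tumor regions of 10,000 clones plus blood with
  tumor-tumor sharing 0.15 and tumor-blood 0.06 — a desk-scale tenth of
  the study's ~95,000 clones per sample at its observed average overlap
  ratios.  Clone sequences are arbitrary unique strings: no V(D)J
  recombination biology, no sequencing error, no abundance correlation
  between shared clones across samples.
* `simulate_mutation_matrix()` — a trunk-and-branch two-mass phylogeny
  (defaults 9 trunk, 22 + 13 branch mutations over 3 + 7 samples)
  with optional per-sample privates and false-negative dropout.
  `simulate_perfect_phylogeny()` instead plants a *random binary*
  topology with at least one mutation per edge, making the planted tree
  the unique parsimony optimum — the right fixture for recovery tests.
  No copy number, no subclonal fractions, no sequencing depth model.
* `simulate_expression()` — i.i.d. Gaussian background around gene
  baselines; planted sets whose genes track a supplied diversity vector
  at a target correlation (`effect = noise_sd * rho / sqrt(1 - rho^2)`);
  stable genes built with total CV in (0.004, 0.012) — below the -5.5
  cutoff with margin even after sampling noise in the sample CV — while
  still tracking diversity.  Null sets draw from background genes only,
  so a false flag is a genuine statistical accident, not contamination.
* `simulate_cohort()` — two balanced latent classes; signature genes
  shifted by 3 sd between classes with alternating sign (a uniform
  shift would be invisible to the shift-invariant correlation distance;
  alternating signs reproduce the high/low blocks of signature
  heatmaps); exponential event times with hazard ratio 3 and class-1
  median 20 months; ~30% of patients censored uniformly before their
  event.

Because the generators realize their planted parameters essentially
exactly, passing tests demonstrate that the *statistical machinery* is
correct and has the expected operating characteristics — not that real
microarray noise, PCR amplification bias, or tumor-cellularity effects
are handled; those are out of scope throughout.

## Numerical and design conventions

* Clonotype identity: CDR3 nucleotide + V + J (amino-acid option);
  duplicate rows merge by summing counts and never change a statistic.
* Frequency-spectrum default bin edges: 0, 1e-5, 1e-4, 1e-3, 1e-2, 1.
* Overlap denominators use `min(N, available clones)`.
* Common clones rank by mean frequency across samples (max optional).
* All tab-delimited I/O is UTF-8, unquoted, '.' decimal; allele columns
  are read as character so `T` alleles survive type conversion.
* The exact Spearman null table (up to 10!) is computed once per sample
  size per session in C++ and cached.
* Tolerances: frequencies must re-sum to 1 within 1e-9; oracle
  equivalence tests assert 1e-12 agreement.

The test suite sizes its simulations to exercise each property at
meaningful scale while keeping a full run at a few minutes: 1,000-case
oracle sweeps for the scalar statistics, 100 planted-tree recoveries,
100 screen replicates, 200 + 400 survival replicates.  The acceptance
script (`scripts/acceptance.R`) re-derives the headline quantities from
scratch at similar sizes.

## A worked end-to-end run

```{r example, eval = FALSE}
# 1. repertoires: diversity and overlap
rep_sim <- simulate_repertoires(seed = 1)
divs <- vapply(rep_sim$tables, function(t) shannon_diversity(t)$shannon_di,
               numeric(1))
ov <- pairwise_topn_overlap(rep_sim$tables, n = 250)

# 2. mutations: classes and tree
mut <- simulate_mutation_matrix(seed = 1)
classify_mutations(mut$matrix, mut$mass_of_sample)$counts
tree <- build_parsimony_tree(mut$matrix)

# 3. pathway screen against tumor diversity
tumor_divs <- divs[setdiff(names(divs), "blood")]
names(tumor_divs) <- sprintf("sample_%02d", seq_along(tumor_divs))
expr <- simulate_expression(tumor_divs, seed = 1)
screen <- diversity_pathway_screen(
  gsva_scores(expr$matrix, expr$sets), tumor_divs)

# 4. stable genes and survival stratification
candidates <- unique(unlist(expr$sets[screen$term[screen$pass]]))
sig <- gene_cv_selection(expr$matrix, candidates)
cohort <- simulate_cohort(seed = 1)
labels <- cluster_patients(cohort$expression)
logrank_test(cohort$survival$time, cohort$survival$event, labels)
```

## Known limitations

* The parsimony search is exact but exponential; beyond 12 samples a
  heuristic mode would be required and is deliberately not implemented.
* The screen's rho threshold performs no error control (see the caveat
  above); treat the passing list as a ranked shortlist.
* CV-based selection assumes positive means on the analysis scale; data
  centered per gene must not be fed to `gene_cv_selection()`.
* The clonotype reader accepts common column synonyms of repertoire-tool
  exports but not arbitrary schemas.
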