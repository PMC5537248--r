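# tilscape

Integrative analysis of multi-region tumor samples profiled on three
layers at once: the T cell receptor beta (TCRB) repertoire of the
tumor-infiltrating lymphocytes (TILs), somatic mutations from exome
sequencing, and expression microarrays.  The package is aimed at
researchers asking how intratumoral genomic heterogeneity relates to the
local immune context — do regions that differ in mutations also differ
in their T cell clones, and does the local immune activity, rather than
the mutation burden, track repertoire diversity?

## What it computes

**Repertoire statistics.**  Per-sample Shannon-Wiener diversity
`H = -Σ p_i ln p_i` over clonotype frequencies; clone-frequency spectra;
cumulative frequency of the TOP-N most expanded clones (default N = 250);
two pairwise overlap matrices — TOP-N vs TOP-N,
`100·|topN(A) ∩ topN(B)| / min(N, |topN(A)|, |topN(B)|)`, and the
asymmetric fraction of A's TOP-N detectable anywhere in B's full
repertoire; clones public to every sample; Kruskal-Wallis and exact
Wilcoxon rank-sum comparisons between samples and sample groups.

**Somatic mutation filtering and phylogeny.**  A post-calling cascade
(germline depth ≥ 10× with zero non-reference reads, protein-altering
annotation, removal of ≥ 2 candidates within a 100 bp window) feeding a
binary mutation presence/absence matrix; mutation classification as
shared / mass-specific / region-unique across tumor masses; and an exact
germline-rooted maximum parsimony tree (branch-and-bound Fitch search,
≤ 12 samples) whose integer branch lengths are mutation counts summing
to the parsimony score.

**Pathway activity and the diversity screen.**  From-scratch
single-sample gene-set variation scores: per-gene Gaussian-kernel CDF
statistics (`z_ij = n⁻¹ Σ_k Φ((x_ij − x_ik)/h_i)`, `h_i = s_i/4`),
symmetric rank weights `|p/2 − rank|`, and a max-deviation random walk
per sample and gene set.  Each set's score vector is screened against
per-sample Shannon diversity by Spearman correlation — exact permutation
p-values for n ≤ 10 via a cached compiled enumeration — with sets
flagged at rho > 0.75.

**Stable-gene signature and survival.**  Coefficient-of-variation
filtering of candidate genes (`log2(CV) < −5.5` on log2 intensities)
extracts the stably expressed signature; an independent cohort is split
by hierarchical clustering (1 − Pearson, average linkage, k = 2) over
the signature genes and compared by Kaplan-Meier curves and the
log-rank test.

**Synthetic data.**  Seeded generators emulate every input: power-law
clone repertoires with planted sharing pools and a dominant public
clone, trunk-and-branch mutation phylogenies with dropout, expression
with pathway-structured diversity signal and planted stable genes, and
two-class survival cohorts — so every stage is testable offline.

## Worked example

```r
library(tilscape)

rep_sim <- simulate_repertoires(n_tumor_samples = 4,
                                clones_per_sample = 5000, seed = 1)
round(vapply(rep_sim$tables,
             function(t) shannon_diversity(t)$shannon_di, numeric(1)), 3)
#> tumor_1 tumor_2 tumor_3 tumor_4   blood
#>   7.482   7.498   7.315   7.548   7.351

mut <- simulate_mutation_matrix(seed = 1)   # 9 trunk + 22/13 branch
classify_mutations(mut$matrix, mut$mass_of_sample)$counts
#>        shared mass_specific region_unique
#>             9            35             0

tree <- build_parsimony_tree(mut$matrix)
tree$score
#> [1] 44

cohort <- simulate_cohort(seed = 1)         # 50 patients, two classes
labels <- cluster_patients(cohort$expression)
lr <- logrank_test(cohort$survival$time, cohort$survival$event, labels)
c(chi_square = round(lr$chi_square, 2), p = signif(lr$p_value, 3))
#> chi_square          p
#>    8.89000    0.00287
```

The diversity values hover near `ln(5000) ≈ 8.5` minus the loss from
clonal expansion; the 9 shared vs 35 tumor-specific mutations reproduce
the planted two-mass architecture, and the parsimony score of 44 equals
the mutation count because the planted matrix is conflict-free.  The
log-rank p below 0.01 shows the recovered expression clusters separating
the two planted hazard classes.

See `vignettes/multiregion-immune-analysis.Rmd` for the models,
conventions and limitations in detail.

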