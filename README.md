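# mgeflow

Phages, plasmids and phage-plasmids (P-Ps, elements that transfer like a
phage and replicate like a plasmid) constantly exchange genes. Because these
replicons recombine so much, their exchanges cannot be traced with
phylogenies; `mgeflow` instead detects *recent* exchanges as pairs of highly
similar proteins carried by otherwise very dissimilar elements, and then
quantifies the flow of genes within and between the three element types.
It is aimed at comparative genomicists who already have an all-vs-all
protein alignment of their mobile-element collection (MMseqs2/BLAST tabular
output) and per-element gene inventories.

## What it computes

**Element similarity (wGRR).** For two elements *A* and *B* with gene counts
`#A`, `#B` and *P* bidirectional best hits (BBHs), the weighted gene
repertoire relatedness is

```
wGRR(A,B) = sum_i id(A_i, B_i) / min(#A, #B)
```

where `id(A_i, B_i)` is the protein identity of the *i*-th BBH. BBHs are
extracted from hits with e-value < 1e-4, identity > 35% and ≥ 50% coverage
of both proteins. A group-level network averages wGRR over all member pairs
of two groups (edges kept above 0.025).

**Recombining genes (RGs).** A BBH with identity > 80% covering > 80% of
both proteins, between elements with wGRR ≤ 0.1, marks both genes as
recombining. Element pairs with more than 25 such BBHs are excluded
(secondary-chromosome artifacts). Remaining genes are non-recombining
(NRG), or NRG-nh when they have no homolog at all.

**Exchange types.** RGs are clustered into families (single linkage at
≥ 80% identity / ≥ 80% coverage). Each family marks, at most once, each of
the six exchange types (phage-phage, plasmid-plasmid, P-P–P-P, and the
three between-type pairs) it spans. Counts are calibrated against a null
that permutes element-type labels (preserving their proportions).

**Functional enrichment.** Per annotation track, RG vs NRG (and
between-type vs within-type RG) category counts are tested with Fisher's
exact test and Benjamini-Hochberg correction, and effect sizes reported as
the bounded difference-sum ratio

```
R = (O − E_H0) / (O + E_H0)  ∈ [−1, 1]
```

with `O` the observed category percentage in the focal group and `E_H0` the
percentage among all genes pooled.

**Reference-group screen.** A collection can be screened for relatives of a
reference P-P group (wGRR ≥ 0.1 and ≥ 10 homologs to a member), profiled
against the group's conserved gene families (80/80 matching), filtered to
close relatives (≥ 75% of families), and reduced to a strict persistent
genome (families single-copy in ≥ 90% of genomes).

**Synthetic collections.** `simulate_mge_collection()` generates element,
gene, alignment (m8) and annotation tables with planted transfers and a
ground-truth log, verifying by construction that same-group pairs have
wGRR > 0.1 and planted donor-recipient pairs wGRR ≤ 0.1, so detector
sensitivity and false-call rates are exact.

## Worked example

```r
library(mgeflow)

sim <- simulate_mge_collection(simulation_config())   # seed 1729
res <- run_gene_flow(sim$elements, sim$genes,
                     hits_from_m8(sim$alignment, sim$genes),
                     sim$annotations)
glance(res)
#> # A tibble: 1 × 6
#>   n_genes  n_rg n_nrg n_nrg_nh n_rg_families n_excluded_pairs
#> 1    3719   114  1993     1612            57                0

evaluate_recovery(sim$truth, res$classification, sim$elements)$summary
#> # A tibble: 1 × 7
#>   n_planted_genes n_detectable n_detected sensitivity n_false_calls ...
#> 1             114          114        114           1             0
```

All 114 genes touched by the 50 planted transfer events (57 gene pairs,
some in multi-gene transposon blocks) are recovered as RGs and no
vertically inherited gene is miscalled. The planted `defense` enrichment
among transferred genes is picked up by the enrichment stage:

```r
res$enrichment |>
  dplyr::filter(grouping == "rg_vs_nrg", track == "function",
                category == "defense")
#>   category     O  E_H0        p        q r_diff_sum direction
#> 1 defense   61.4  8.54 6.23e-51 3.12e-50      0.756      over
```

61.4% of recombining genes carry the planted category against 8.5% of all
genes, giving a strongly positive difference-sum ratio. Exchange-type
counts sit near their permutation-null expectation because transfers were
planted without regard to element type (`tidy(res$null_calibration)`).

Plots: `autoplot(res$null_calibration)`, `autoplot(res$group_graph)`,
`plot_rg_fractions(res$rg_fractions)`, `plot_enrichment(res$enrichment)`.

A thin command-line wrapper is provided in `inst/scripts/mgeflow.R`
(`simulate`, `run`, `evaluate` subcommands).

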