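# metevol

Tools for analysing **when and how metastases diverge** from their primary
tumour, given multi-region sequencing data summarised as mutation-cluster
trees with phylogenetic cancer cell fractions (phyloCCF). The package is
aimed at cancer-genomics analysts working with multi-region WES cohorts
(primary tumour regions plus lymph-node or recurrence/progression samples)
whose upstream pipeline already produced clustered mutations and clone
trees.

## What it computes

- **Divergence timing** — per metastasis and per case, *early* versus
  *late* relative to the last clonal sweep of the primary: the fraction of
  primary-clonal mutations (clusters clonal in **all** primary regions)
  that are also clonal in the metastasis,

  `shared fraction = (primary-clonal mutations clonal in met) / (primary-clonal mutations)`,

  with early ⇔ fraction < 1. Orthogonal calls from region-based mutation
  presence (after LOH filtering), ubiquitous arm-level LOH (allele-aware,
  ≥75% of the arm) and clonal whole-genome doubling.
- **Sampling bias** — exhaustive downsampling over all C(n, k) subsets of
  primary regions, quantifying how the *illusion of clonality* flips late
  cases to early under sparse sampling.
- **Dissemination patterns** — monoclonal/polyclonal (are all
  primary-shared clusters clonal within the metastasis?) and
  monophyletic/polyphyletic (do shared clusters sit on one tree branch?),
  with consensus over alternative topologies.
- **Seeding clones** — the leaf-up walk that marks the most recent shared
  cluster of each branch and its path ancestors whose metastasis phyloCCF
  exceeds their child's, with CCF summation where branches converge.
- **Clone proportions** (MACHINA-ready) by bottom-up subtraction of direct
  children, and the **clonal dispersion index**
  `D = 1 − (max(p) − 1/n) / (1 − 1/n)` over primary regions.
- **Paired selection analyses** — metastasis-favoured / primary-favoured /
  maintained classification for mutation clusters and gene-level SCNAs,
  exact or Monte-Carlo multinomial tests against a non-driver background
  with BH correction, GISTIC-style G-score differences and dN/dS odds
  ratios from supplied estimates.
- **A deme-based agent model** (Rcpp) of tumour growth under an asymmetric
  Laplace fitness landscape with drivers and large genomic events,
  metastasis seeding at prespecified primary sizes, emulated 400× WES, and
  the early-fraction-versus-size experiment.
- **A synthetic-data generator** producing clone trees with known
  ground-truth timing/dissemination/seeding labels, so every stage is
  testable without controlled-access patient data.

## Worked example

```r
library(metevol)

tree <- metevol_example_tree()   # 4 clusters, 2 primary regions, 1 met
time_divergence(tree)
#> # A tibble: 2 × 6
#>   case_id level  target_id label shared_clonal_fraction method
#>   <chr>   <chr>  <chr>     <chr>                  <dbl> <chr>
#> 1 EX1     sample M1        late                       1 phylogenetic
#> 2 EX1     case   EX1       late                       1 phylogenetic
```

Every mutation cluster that is clonal in both primary regions is also
clonal in the metastasis M1, so no clonal sweep post-dates divergence: the
metastasis diverged **late**, with a shared clonal fraction of exactly 1.

```r
cl <- classify_clonality(tree)
find_seeding_clusters(tree, cl, met_sample = "M1")
#> # A tibble: 1 × 4
#>   case_id met_sample_id cluster_id truncal
#> 1 EX1     M1            4          FALSE
```

Cluster 4 — subclonal in the primary (CCF 0.30/0.45 across regions) but
clonal in M1 — is the seeding cluster: its clone founded the metastasis.

```r
dispersion_index(c(0.6, 0.2, 0.2))
#> [1] 0.6
```

A clone at CCF 0.6 in one of three regions and 0.2 in the others is fairly
dispersed (`D = 0.6`; 0 = region-private, 1 = evenly spread).

Simulated cohorts work the same way end to end:

```r
set.seed(1)
pair <- simulate_met_pair(sim_config(final_size = 1e5, region_cells = 5e3,
                                     n_regions = 4),
                          divergence_size = 1e3, n_cells = 1,
                          met_final_size = 5e4, met_n_regions = 2,
                          met_region_cells = 5e3)
tree_sim <- abm_bridge(pair)     # pseudo-clusters from genotype truth
time_divergence(tree_sim)$label
```

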