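---
title: "Models and methods behind metevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metevol)
```

metevol analyses the evolution of metastasis from multi-region tumour
sequencing that has already been processed into *mutation clusters*: groups
of somatic mutations that co-occur in the same subset of cancer cells,
arranged in a rooted clone tree, with a phylogenetic cancer cell fraction
(phyloCCF) for every cluster in every sequenced sample. This vignette
explains the models implemented, the parameters that matter, and the design
choices made where more than one reasonable definition exists.

## Clonality classification

Everything downstream consumes a three-way status per cluster and sample:
**clonal** (present in essentially every cancer cell of the sample),
**subclonal**, or **absent**. `classify_clonality()` thresholds phyloCCF
point estimates: clonal at `ccf >= clonal_min` (default 0.9), absent at
`ccf < absent_max` (default 0.05). Upstream pipelines differ in how they
make this call (some use CCF confidence intervals rather than point
estimates), so both thresholds are arguments, and every analysis accepts a
precomputed clonality table. Point estimates above 1 — a known artefact of
CCF estimation — are treated as clonal and are only capped (at 1) inside
clone-proportion estimation.

At the tumour level (`group_status()`), a cluster is clonal only if clonal
in *every* sample of the group, absent only if absent in every sample, and
subclonal otherwise. This asymmetry is deliberate: a single region where a
cluster is subclonal proves the cluster did not sweep the tumour.

## Timing metastatic divergence

Timing is relative to the *last clonal sweep* of the primary tumour, not to
chronological time. The mutations of clusters clonal across all primary
regions record every sweep that completed in the primary. For each
metastasis, `time_divergence()` computes the fraction of those mutations
that are also clonal in the metastasis. If the fraction is 1, no sweep
completed after the metastatic lineage branched: **late** divergence. Any
shortfall means a sweep post-dates divergence: **early**. Because the
fraction is a ratio of integer mutation counts, the comparison against 1
uses a tolerance of 1e-9 and is effectively exact on noiseless input. A
case with several metastases is early if any metastasis is early.

Three orthogonal read-outs support the same call where the relevant data
exist: mutation presence across regions after excluding loci under LOH in
any sample (`region_shared_fraction()`); ubiquitous arm-level LOH events,
which are irreversible and therefore ratchet-like (`loh_timing()`, arm loss
defined as at least 75% of the arm); and clonal whole-genome doubling,
where a metastasis lacking the primary's WGD event — or carrying a separate,
parallel one — must have diverged before it (`wgd_timing()`).

`downsample_timing()` quantifies sampling bias: for every k-subset of
primary regions it recomputes the primary-clonal set and the shared
fraction. Dropping regions can only enlarge the apparent primary-clonal set
(the *illusion of clonality*), so the mean shared fraction is non-decreasing
in k, and sparse sampling misclassifies genuinely late cases as early. All
C(n, k) subsets are enumerated exhaustively; multi-region studies rarely
exceed 8-10 regions, so enumeration is cheap and removes a source of noise.

## Dissemination patterns and seeding clones

`classify_dissemination()` asks whether one or several primary clones
founded the metastases. Per metastasis: if every cluster shared between
primary and metastasis is clonal *within the metastasis*, one clone
suffices — monoclonal; any shared cluster left subclonal in the metastasis
requires a second founding clone — polyclonal. At the case level,
metastases that are individually monoclonal but share *different* cluster
sets with the primary still imply polyclonal dissemination; restricting
such a case to a single metastasis hides this, which is itself a sampling
caveat the package's tests assert.

`phyletic_origin()` maps shared clusters onto the tree: monophyletic if one
root-to-leaf path covers them all, polyphyletic otherwise. A monoclonal
metastasis is necessarily monophyletic. Because mutation clustering can
admit several tree topologies, `consensus_origin()` repeats the call on
every topology attached to the tree and reports `uncertain` on
disagreement; timing, by contrast, always uses the default topology.

`find_seeding_clusters()` implements the leaf-up walk. Per branch of the
shared subtree, the deepest shared cluster always seeds (its clone
demonstrably reached the metastasis). If it is subclonal in the metastasis,
ancestors are ascended until the first cluster clonal in the metastasis; a
cluster on the path seeds when its metastasis phyloCCF *strictly* exceeds
its path-child's (equality is not enough — an ancestor whose CCF equals its
child's brought no additional cells; the strict reading was chosen because
the boundary case is unstated in the field's descriptions). Where branches
converge on a shared ancestor, the ancestor's effective CCF is the sum over
its converging branches — generalised to any number of branches — and the
ascent stops at the first metastasis-clonal cluster.

### Clone proportions and the dispersion index

`clone_proportions()` converts cumulative phyloCCFs into per-clone cell
fractions bottom-up: a leaf's proportion is its CCF; an internal cluster's
is its CCF minus the sum of its *direct children* (subtracting all
descendants would double-count — the 0.75-leaf example, whose ancestors must
sum to 0.25, pins this down). Clonal clusters are first corrected to CCF
exactly 1; residual negative differences (point-estimate noise) are clamped
to 0 and the vector renormalised. The output is the clone-labelling input
that migration-history tools such as MACHINA consume.

The clonal dispersion index of a cluster with regional CCFs `x` is
`D = 1 - (max(p) - 1/n) / (1 - 1/n)` with `p = x / sum(x)`: 0 for a
region-private clone, 1 for an evenly spread one, invariant to uniform
scaling. Together with the maximum regional CCF it quantifies subclonal
expansion within the primary.

## Paired selection analyses

`classify_paired_mutation()` reduces to an ordinal comparison: a cluster is
metastasis-favoured when its tumour-level clonality is higher in the
metastasis than in the primary, primary-favoured when lower, maintained
when equal. The metastasis side takes the *maximum* clonality over
metastasis samples, matching the "higher clonality in metastases" reading.
The cluster's label propagates to each of its mutations; per-gene driver
counts (at least 5 driver mutations per tested gene) are compared to the
mutation-weighted background formed from non-driver mutations, stratified
(e.g. by histology) when a stratum column is present.

The goodness-of-fit test is an exact multinomial test: the p-value is the
total probability of outcomes no more probable than the observed one. All
outcomes are enumerated up to 12 events (the spec's exactness regime;
enumeration of `(n+2 choose 2)` outcome vectors is trivial there), with a
seeded Monte-Carlo estimate (default 1e5 draws, add-one corrected) above.
The function also returns the strictly-less tail so calibration can be
checked with randomised p-values, which are exactly Uniform(0,1) for a
correctly implemented discrete test — the package's calibration test uses
this rather than pretending discrete p-values are continuous.

Copy-number events are called per gene relative to sample ploidy at
`|log2 ratio| > 0.5` (the conventional doubling/halving cut-offs, exposed
as arguments); paired favouring then counts group-level presence (called in
at least one sample of the group), with tumours lacking the event entirely
left out. Gene-level G-scores are assigned by overlap with GISTIC-style
segment score tables — the overlap-length-weighted mean over segments, the
mean of the two flanking segments when a gene falls in a gap, and a warning
-and-drop for genes on chromosomes without segments. dN/dS estimates are
consumed from external tables; the odds ratio seeding/non-seeding is
labelled seeding-favoured above 2 and primary-favoured below 0.5.

## The deme-based agent model

`grow_tumor()` simulates tumour growth on a 3D cubic lattice of demes with
capacity 5,000 cells, from one founder cell to `final_size` (1e9 in the
study conditions; see *Problem sizes* below). Time advances in synchronous
sweeps. Per sweep a cell divides with probability
`(fitness / max fitness in deme) x (1 - n / 2K)` and then dies with
probability 0.2. The fitness-ratio gate makes selection purely relative and
local; the density factor makes division less likely as a deme fills. The
factor uses `2K` rather than `K` in the denominator: with the steeper
`(1 - n/K)` form, births balance the fixed 0.2 death rate at about 0.75 K,
demes never exceed capacity, and the tumour stops growing — a fixed point of
the model, not of the biology. With `n/2K`, division at the capacity
threshold (probability 0.5) still outpaces death, demes overflow and split:
half the cells (binomially) move to a uniformly chosen empty neighbour, or
to the nearest empty site along a random direction when enclosed.

Each daughter acquires `Poisson(0.4)` new mutations per division over the
exome (0.6 for the high-rate condition; the per-bp equivalents are
bookkeeping metadata). Fitness effects come from an asymmetric Laplace DFE
centred at 0 and skewed negative: exponential tails with mean `s` on the
negative side and `s/2` on the positive side, with side probabilities
proportional to the side scales (2/3 negative, 1/3 positive) — the standard
asymmetric-Laplace parameterisation; the sources state only the tail means.
At the study's `s = 0.01` effects effectively span -0.07 to +0.02. Drivers
occur at 1e-5 per mutation with a deterministic `+10 s` effect; the first
driver in a lineage also enables large genomic events, which then occur at
0.3 per division with a broader DFE (positive mean `s`, negative mean
`3 s`, 3/4 negative). Events change fitness only — no copy-number
bookkeeping. At `s = 0` every effect is 0 and growth is neutral.

The implementation tracks genotype counts per deme, never cell objects, so
memory and time scale with genotypes rather than cells; the contract is
equivalence with per-cell semantics in distribution. All randomness flows
through R's RNG, so `set.seed()` makes entire simulations reproducible.
The founder carries `founder_mutations` (default 100) truncal mutations —
the pre-expansion burden every cancer cell inherits — which gives the
emulated pipeline the clonal baseline real tumours have.

Metastases (`simulate_met_pair()`) are seeded when the growing primary
first reaches `divergence_size`: founder cells (1-100, from 1 or 3 surface
localities) are *removed* from the primary surface and grown as a new
tumour under their own selection coefficient. Removal matters only at very
small divergence sizes, where it is precisely what generates early
divergence: the remaining lineage's private mutations fix in the primary by
construction.

Bulk sampling (`sample_regions` inside the simulator) takes spatially
contiguous, mutually disjoint groups of demes of ~50,000 cells; WES
emulation draws depth `Poisson(400)` and alt reads
`Binomial(depth, vaf(1-e) + (1-vaf)e/3)` at per-base error `e = 1e-3`,
with detection requiring 2 alt reads and observed VAF 0.02 — standard
short-read characteristics. A mutation is primary-clonal when its VAF
exceeds 0.3 in at least `ceiling(0.9 x regions)` primary regions; a pair is
late when every primary-clonal mutation is detected in some metastasis
region. `abm_bridge()` groups detected mutations by their originating
genotype into pseudo-clusters (CCF = 2 x mean VAF), standing in for the
external mutation-clustering step so simulator output can be pushed through
the same timing/dissemination classifiers as observational data.

### What the scaled experiments can and cannot show

Under the stated parameters, growth to 1e7 cells takes roughly 55
generations; a driver with fitness 1.1 needs several hundred generations to
sweep a tumour, so in desk-scale runs post-divergence sweeps only complete
when divergence precedes the first few cell generations. The package's
experiment (`run_timing_experiment()`, final size 1e7, divergence grid
2-1e6 cells, 10 replicates per size) therefore shows the monotone decline
of early divergence with size concentrated at the small end of the grid.
The full-scale study conditions (1e9 cells, 20 replicates per condition)
put meaningful early fractions at much larger absolute sizes; those runs
are cluster-scale and are not asserted by the test suite.

## The synthetic-data generator

`generate_cohort()` builds cases whose labels follow from their
construction: a clonal trunk (CCF 1 in every sample it swept); early cases
extend the trunk with a cluster clonal in all regions but absent from the
metastases (a post-divergence sweep); late cases attach a seeding branch
subclonal in a proper subset of regions and clonal in the metastases;
polyclonal cases leave one shared cluster subclonal in the metastasis;
polyphyletic cases place two sibling seeding branches; clonal-illusion
clusters are clonal in exactly one region and absent elsewhere. Filler
clusters attach uniformly at random within the per-sample CCF budget of
their parent, so the phylogenetic sum rule holds in every noiseless sample.
Ground truth is recorded from the construction, never from the classifiers.

Defaults (2-8 regions, 1-3 metastases, 6-12 clusters, a quarter early,
roughly a third polyclonal) are a realistic mix for exercising the
classifiers, chosen once; cohort-level frequencies in any real dataset are
data outcomes, not generator targets. Optional Gaussian CCF noise is
truncated to [0, 1], which mildly biases values near the boundaries (a
clonal CCF of 1 can only move down). With noise sd 0.05 a clonal entry
falls below the 0.9 clonal threshold with probability ~2.3%; since a late
case needs *every* trunk cluster to stay clonal in every metastasis, label
recovery under noise is high but structurally below 1 (the seeded benchmark
in the tests asserts at least 0.9 over 200 cases). Early cases are
constructed so that, in this generator, they are always monophyletic: a
post-divergence sweep leaves non-trunk clones no CCF budget in the primary,
so shared clusters are confined to the trunk.

## Problem sizes and numerical choices

The test suite and the acceptance script run: 200 noiseless synthetic cases
for round-trip recovery; 40 illusion-cluster cases for downsampling; 1,000
null genes for multinomial calibration (exact enumeration up to 40 events
there); and 50 primary-metastasis pairs at final size 1e7 for the
early-fraction curve. These sizes keep the whole suite in the tens of
minutes on one CPU while leaving each check statistically meaningful.
Deterministic tie-breaks: cluster ids sort lexicographically wherever sets
are emitted; writers sort rows so outputs are diffable; `ROOT` is the
literal parent token for root clusters in files.

## Known limitations

- Clonality from point estimates: the CI-based calls of upstream pipelines
  can differ near thresholds; both thresholds are exposed.
- The generator does not emulate region-specific copy-number distortion of
  CCFs, multi-sample noise correlation, or mutation-level clustering error;
  passing round-trip tests therefore shows classifier correctness, not
  robustness to every real-data artefact.
- The agent model omits copy-number/WGD genotypes, chemotherapy mutagenesis
  and any fitting to cohort data; genomic events are fitness-only.
- dNdScv and GISTIC are consumed as output tables; their internals, the
  two-dataset likelihood-ratio comparison, and MACHINA's migration-history
  inference are out of scope (the package prepares MACHINA's inputs).
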