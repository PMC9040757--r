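---
title: "Models and methods: root microbiota dynamics, stability and metabolite covariation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizodyn)
```

This vignette explains the statistical procedures the package
implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The experimental design the package assumes

The data model is a factorial field survey: two fields (DEMO, DOK)
holding four soil managements (NK and NPK with one plot each; CONMIN
and BIODYN with three plots each), five host genotypes per plot, three
compartments (bulk soil, rhizosphere, root endosphere) and three
sampling times (unplanted soil before sowing, vegetative stage,
reproductive stage), with about six replicate plants per genotype ×
plot × stage. Samples are profiled per microbial kingdom — bacteria,
fungi, oomycetes — as sample × ASV count tables. Unplanted and bulk
soil carry the genotype sentinel `none`.

## Rarefaction and diversity

Counts are rarefied by drawing, per sample, exactly `depth` reads
without replacement from the sample's count multiset (a multivariate
hypergeometric draw). Defaults are 1,000 (bacteria), 10,000 (fungi)
and 2,000 (oomycetes) reads. Samples below depth are dropped, never
up-sampled, and the drop list is reported — resampling with
replacement would fabricate precision for shallow libraries.

Alpha diversity is the Shannon index with natural logarithm (the
common ecology convention; the base is exposed), averaged over 999
independent rarefactions so that the index does not inherit the
variance of a single subsample. When a sample's total equals the
depth the index is computed once, exactly.

Beta diversity uses Bray-Curtis dissimilarity on rarefied counts
(equivalently on relative abundances — the implementation is invariant
to per-sample rescaling of normalised rows). PCoA is classical metric
scaling: Gower double-centering of −D²/2 and eigendecomposition.
Negative eigenvalues (Bray-Curtis matrices are generally
non-Euclidean) are reported but excluded from proportion-explained
denominators; no Cailliez/Lingoes correction is applied. Axis signs
are fixed by making the largest-magnitude coordinate positive, so
results are reproducible across platforms.

PERMANOVA partitions the Gower-centred matrix sequentially (Type I) in
the user-given term order, with pseudo-F tested by free permutation of
sample labels. Whether the original analysis used sequential or
marginal sums of squares, or permutation strata, is not documented in
the conventions this package follows; sequential with free permutation
(the historical `adonis` default) was chosen and the term order is the
user's responsibility. The permutation p-value carries the +1
correction, `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, and therefore never
returns zero. Interaction terms are factor crosses. The constrained
PCoA regresses all positive-eigenvalue PCoA axes on the constraint
design, eigendecomposes the fitted values, and reports
SS(fitted)/SS(total) with a row-permutation test; on Euclidean
distance matrices it agrees with distance-based RDA.

Group comparisons throughout use two-sided Wilcoxon rank-sum tests on
all group pairs with Benjamini–Hochberg correction across the pairs.
Compact letters come from the insert-and-absorb algorithm: start with
one class holding all groups, split classes on each significant pair,
delete classes contained in others; groups sharing any letter are not
significantly different at the chosen level. Ties in letter order
follow the factor's level order.

## The stable/dynamic partition

A taxon is *stable* in a compartment when its prevalence — the
fraction of samples with a nonzero count — is strictly above θ = 0.8
among that compartment's vegetative samples **and** among its
reproductive samples. The inequality is strict ("more than 80%");
`strict = FALSE` switches to ≥. Prevalence is pooled across
managements, plots and genotypes within a compartment × stage;
per-management stratification can be had by subsetting the metadata.
Detection is evaluated on the rarefied table by default, so
"presence" means presence at standardised sequencing effort; passing
the unrarefied table gives the raw-detection variant. The stable set
definition leaves both choices open, and this package prefers the
depth-standardised one because prevalence otherwise grows with library
size.

The aggregated relative abundance (aRA) of a taxon set is the mean
over samples of the per-sample sum of the set's relative abundances,
in percent — the mean of sums rather than the sum of per-taxon means;
the two agree on complete tables, and the mean-of-sums form keeps the
complementarity identity `aRA(stable) + aRA(dynamic) = 100` exact for
any partition. The stable-to-dynamic ratio is
`aRA_stable / (100 − aRA_stable)`, reported both at full precision and
rounded to two decimals: 39.35% stable gives 0.65, 80.49% gives 4.13,
50% gives 1. The convention's own worked example contains a transposed
fraction in one parenthetical; only the stable/dynamic orientation is
consistent with both of its printed ratio values, and that orientation
is implemented. The complementary symmetry
`ratio(x) · ratio(100 − x) = 1` is property-tested. Venn-region counts
between compartments' stable sets come from exhaustive
inclusion–exclusion membership classification.

## Convergence toward the reproductive-root community

The initial reference community is the arithmetic mean relative
abundance profile of the unplanted-soil samples; the final reference
is the mean profile of reproductive roots (a median variant is
provided; the mean is the default because reference communities here
are composition centroids). Each sample is then represented by the
pair of Bray-Curtis distances to those references,
`(d_init, d_final) ∈ [0, 1]²`.

The phrase "Euclidean distances between the Bray-Curtis
dissimilarities to the initial and final communities" admits several
readings: the Euclidean norm of the 2-vector, the difference
`|d_init − d_final|`, or inter-sample distances in the 2-D plane. The
package makes the 2-D reading primary for inference — group separation
is the Euclidean distance between group centroids in the
`(d_init, d_final)` plane, tested by label permutation — while the
per-sample norm is also emitted for 1-D distance-distribution plots.
The ambiguity is documented rather than resolved; all three quantities
are derivable from the returned coordinates.

`level_contrast()` runs the identical analysis on the same samples at
ASV level and at phylum level. Because compartments share phyla but
largely not ASVs, a community can converge at phylum level while
remaining maximally distant at ASV level — the phenomenon of interest.

## Taxa–metabolite covariation

Metabolite intensities are log10-transformed after adding, to zero
values only, half the compound's smallest positive intensity (a
pseudo-count rule; the base-10 log and the ε rule are this package's
choices where only "log-transformed" is conventional), then
range-normalised per compound to [0, 1]. Constant compounds map to 0
and are flagged. The transform is idempotent via a state flag.

Taxa (prevalence-filtered at 10%) are ranked by fitting, per compound,
a random-forest regression of the compound on all taxon relative
abundances; importance is the permutation increase in out-of-bag MSE,
unscaled. A taxon's score is its **maximum** importance across
compounds and the top K = 25 are retained. How multi-compound
responses were combined is not conventionally fixed; max-combine was
chosen because a taxon tightly linked to a single lipid should not be
diluted by the compounds it ignores, and mean-combine is available.
Forest hyperparameters (500 trees, default mtry) are exposed.

Edges of the covariation network are (taxon, compound) pairs with
Spearman |ρ| > 0.5 and two-sided p < 0.05, deliberately without
multiple-testing correction — the raw-p convention for this network.
Spearman's rank invariance makes the edge set immune to monotone
transforms of the intensities, which is property-tested. Nodes carry
the ratio of mean vegetative to mean reproductive abundance
(undefined 0/0 ratios are flagged and excluded from display).

## OTU clustering

ASVs are clustered at 97% identity by abundance-sorted greedy centroid
clustering: sequences are processed in decreasing total abundance
(ties broken lexicographically by id); each joins the first centroid,
in founding order, whose global pairwise identity reaches the
threshold, else founds a new OTU. Identity is matches divided by
alignment columns under Needleman–Wunsch global alignment with match
+1, mismatch −1, and a linear gap penalty of 2 per position — only the
97% threshold is conventionally fixed; the scoring parameters are
exposed. The ordering rule makes the result invariant to input file
order, which is tested.

## The synthetic-data generator

The generator is the package's ground-truth instrument. Per kingdom it
builds expected compositions and draws counts:

* each taxon is native to each compartment independently with
  probability 0.5, with log-normal baseline weights (sdlog 1.2), so
  compartments overlap partially at ASV level but share phyla;
* each compartment receives a planted **stable core** (default 20
  taxa) whose combined expected relative abundance is `core_mean_ra`
  (default 0.4) at both stages;
* the remaining **dynamic shell** in rhizosphere and root is split
  into vegetative- and reproductive-preferring taxa, down-weighted by
  `off_stage_factor = 0.01` at the other stage. That value makes the
  shell genuinely dynamic at the default depths: off-stage expected
  counts fall near or below one read, so shell taxa fail the 80%
  prevalence rule while core taxa pass it with expected prevalence
  above 0.9. Bulk soil has no stage-specific shell — its stage
  structure comes solely from convergence mixing, so with κ = 0 soil
  composition is stage-invariant in expectation and null calibration
  is exact by construction;
* convergence: at stage s, the phylum-level composition of soil and
  rhizosphere is `(1 − κ_s)·π_compartment + κ_s·π_final`, where
  `π_final` is the expected reproductive-root composition and
  `κ_unplanted = 0 < κ_vegetative = 0.25 < κ_reproductive = 0.5`.
  Mixing is applied to phylum totals and broadcast proportionally to
  member taxa (phyla absent from a compartment inherit the root's
  within-phylum profile — immigration), which plants convergence that
  is detectable at phylum level but largely invisible at ASV level;
* management-, plot- and genotype-level log-normal weight jitters
  (sd 0.3 / 0.2 / 0.1) are constant across stages, so they add
  realistic between-condition variance without contaminating stage
  contrasts;
* counts are Dirichlet-multinomial with concentration
  `α0 · π` (α0 = 500), the standard overdispersed count model for
  amplicon data, at log-normal depths centred on 3× the kingdom's
  rarefaction depth (sdlog 0.3), so rarefaction drops a known small
  fraction of samples;
* metabolites: compound j over root samples is
  `exp(b_j + s_j·1[reproductive] + β·z(RA_t) + ε)`, ε ~ N(0, 0.1),
  where the β term exists only for the planted links and `z(RA_t)` is
  the linked core taxon's relative abundance standardised across the
  root samples used. The standardisation is part of the link's
  definition: it makes β the effect size in noise-sd units regardless
  of the taxon's absolute abundance (a β on raw proportions of order
  10⁻² would be numerically invisible at any plausible noise level).
  The exponential link keeps intensities strictly positive. Realised
  links are recorded in the truth ledger.

What the generator does **not** emulate: phylogenetic correlation
among taxa, chimeras and primer/PCR bias, batch and run effects,
compositional spurious correlation structure beyond what the
Dirichlet-multinomial induces, spatial autocorrelation between plots,
and metabolite-metabolite dependence. Tests passing on this generator
therefore demonstrate correctness of the algorithms under the stated
model, not robustness of the biology to those real-data complications.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately scaled
problems chosen as the smallest sizes at which each property is
statistically decidable: 120–200 taxa per kingdom, 30 samples per
stage for core recovery (20 seeds), 15 soil samples per stage for the
convergence contrast (50 planted + 100 null seeds, 99 permutations
inside the Monte-Carlo loops, 999 elsewhere), 48 root samples and 300
trees for covariation recovery, and 500 null simulations at n = 20 for
PERMANOVA calibration. Tolerances follow the quantity's sampling
error (3 standard errors for permutation-vs-enumeration comparisons,
1e-9 for exact linear-algebra identities, 1e-12 for conservation
laws). Degenerate inputs are contracts, not crashes: all-zero samples,
saturated constraint designs, constant correlation vectors and
undefined ratios raise informative errors or flags.

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. The pipeline's master seed fans out as fixed
offsets (+1 rarefaction, +2 alpha, +3 beta, +4 convergence, +5
covariation), so any stage can be reproduced in isolation; a rerun
under the same master seed is byte-identical, which is asserted in the
test suite.

Configuration is an R-level object (`pipeline_config()`) rather than a
config file: for a package whose users drive it from R, a validated
constructor is the more idiomatic and testable surface, and it
serialises naturally into the run manifest.

## Known limitations

The stable aRA recovered from any single simulated experiment scatters
around the planted core abundance by several percentage points —
occasionally a heavy dynamic taxon crosses the prevalence threshold —
so aRA recovery is assessed as convergence in the mean over seeds, not
per seed. UniFrac and other phylogenetic metrics, variance-stabilising
transforms, mixed-model PERMANOVA with strata, and
compositionality-aware correlation (SparCC-type) are out of scope.
PERMANOVA R² partitions are order-dependent by construction; only the
total is order-invariant. OTU clustering is quadratic in the number of
centroids and intended for ASV sets of a few thousand sequences, not
raw-read scale.
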