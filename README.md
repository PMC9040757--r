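# rhizodyn

Tools for analysing the temporal dynamics of soil- and root-associated
microbial communities in field experiments. The package targets
amplicon surveys in which bulk soil, rhizosphere and root (endosphere)
compartments are sampled at successive host growth stages — unplanted
soil before sowing, the vegetative phase and the reproductive phase —
across multiple soil managements and host genotypes, for several
microbial kingdoms (bacteria, fungi, oomycetes). It is written for
microbial ecologists who want the full analysis chain as tested,
reusable functions rather than one-off scripts.

## What it computes

Given sample × taxon count tables, taxonomy, sample metadata and
(optionally) metabolite intensity matrices, the package provides:

* **Core data handling** — validated community tables, rarefaction to
  even depth (multivariate hypergeometric subsampling), relative
  abundances, taxonomic aggregation, grouping of rare phyla (<0.1%
  mean RA) into "Others", and greedy abundance-sorted centroid
  clustering of ASVs into OTUs at 97% global-alignment identity.
* **Diversity machinery** — Shannon index
  `H = -Σ p_i ln p_i` averaged over 999 independent rarefactions;
  Bray-Curtis dissimilarity
  `BC(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)`; principal-coordinate
  analysis; sequential-SS PERMANOVA with free label permutation;
  distance-based constrained PCoA; pairwise Wilcoxon rank-sum tests
  with Benjamini–Hochberg FDR and compact-letter displays.
* **Stable/dynamic partition** — a taxon is *stable* in a compartment
  when it is detected in more than 80% of that compartment's samples
  at **both** the vegetative and reproductive stages (threshold θ
  configurable). Aggregated relative abundance (aRA) of the stable set
  and the stable-to-dynamic ratio
  `ratio = aRA_stable / (100 − aRA_stable)`,
  e.g. a 39.35% stable aRA gives 60.65% dynamic and ratio 0.65;
  an 80.49% stable aRA gives 4.13. Venn-region counts quantify overlap
  of stable sets between compartments.
* **Convergence analysis** — every sample is located by its pair of
  Bray-Curtis distances `(d_init, d_final)` to an initial reference
  community (mean profile of unplanted soil) and a final reference
  (mean profile of reproductive roots); group separation is the
  Euclidean distance between group centroids in that plane, tested by
  label permutation, and contrasted between ASV-level and phylum-level
  tables on identical samples.
* **Taxa–metabolite covariation** — metabolite intensities are
  log10-transformed and range-normalised per compound; taxa are ranked
  by random-forest permutation importance (increase in out-of-bag MSE)
  against each compound, the top 25 are retained, and edges with
  Spearman |ρ| > 0.5 and raw p < 0.05 form a bipartite network whose
  nodes carry vegetative/reproductive mean-abundance ratios.
* **Synthetic data with ground truth** — a Dirichlet-multinomial
  simulator of the full factorial field design: planted stable cores,
  stage-specific dynamic shells, phylum-level convergence of
  soil/rhizosphere toward the reproductive-root composition, log-normal
  sequencing depths, and metabolites linearly linked to chosen root
  taxa. Every statistical claim in the test suite is validated against
  this generator's known truth.

## Worked example

```r
library(rhizodyn)

cfg <- sim_config(kingdoms = "bacteria", managements = "NK",
                  genotypes = "B73", n_reps = 8, n_soil_reps = 10,
                  n_unplanted = 6, seed = 42)
ex  <- generate_experiment(cfg)
rar <- rarefy(ex$tables$bacteria, depth = 1000, seed = 1)
rar
#> <community_table> 58 samples x 200 taxa [bacteria, level ASV, counts]

stability_partition(rar, ex$metadata, "root")
#> <stability_partition> bacteria root: 20 stable / 82 dynamic taxa (theta = 0.8)
#>   vegetative: stable aRA 32.62%, ratio 0.48
#>   reproductive: stable aRA 36.54%, ratio 0.58
```

All 20 recovered stable taxa are exactly the generator's planted
20-taxon root core. The per-stage lines read: at the reproductive
stage the stable members jointly account for 36.54% of the community,
so the dynamic complement holds 63.46% and the stable-to-dynamic ratio
is 0.58.

```r
md  <- ex$metadata[ex$metadata$sample_id %in% rownames(rar), ]
permanova(bray_curtis(rar), md, c("compartment", "stage"),
          n_perm = 999, seed = 1)
#>          term df sum_sq    r2 pseudo_f p_value
#> 1 compartment  2   9.18 0.631     64.0   0.001
#> 2       stage  2   1.56 0.107     10.9   0.001
#> 3    Residual 53   3.80 0.261       NA      NA
#> 4       Total 57  14.54 1.000       NA      NA
```

Compartment explains 63% of the Bray-Curtis variance and growth stage
a further 11%, both significant at the permutation floor — the
structure the simulator plants.

An end-to-end run (`run_pipeline()`) chains rarefaction, alpha/beta
diversity, the phylum pipeline, stability, convergence and covariation,
writing every intermediate table plus a manifest of stages and seeds;
`make_demo()` writes a ready-made two-kingdom demonstration dataset.

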