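# forestspec

Habitat specialization of woody plants across forest disturbance regimes.

`forestspec` asks a community-ecology question: when several forest stands
share a species pool but differ in disturbance history (e.g. a plantation,
once- and twice-cut stands, and old growth), are woody species distributed
among them at random, or do they specialize? The package implements the
full analysis chain for stem-mapped censuses — four 1-ha plots gridded into
10 m × 10 m quadrats is the canonical design — together with a synthetic
census generator so every stage can be exercised and validated without
field data.

## What it computes

* **Torus-translation habitat association** (`torus_test()`). For species
  *s* and habitat *h*, the relative density
  `RD = (n_sh / A_h) / (n_s / A)` is compared against its null
  distribution over all torus transforms of the habitat map (every
  translation of the identity, 180° rotation, mirror, and mirrored
  rotation — stems stay fixed, the map moves, so spatial aggregation is
  preserved under the null). For four 1-ha plots concatenated into a
  40 × 10 torus this family is 1 real + 1,599 translated maps. Species
  are classified `+` / `−` / none at a two-sided level α with
  `p = (1 + #{null RD ≥ observed}) / 1600`, ties counting toward both
  tails (conservative).
* **Bipartite network specialization** (`build_network()`, `h2prime()`,
  `connectance()`). The species × community abundance matrix is scored by
  the network-level index `H2′ = (H2max − H2) / (H2max − H2min)`, the
  Shannon entropy of interaction proportions rescaled between its bounds
  under fixed marginals (0 = interactions follow marginal totals,
  1 = maximal specialization), plus the fraction of realized links.
* **Indicator species analysis** (`indval()`): group-equalized
  `IndVal = sqrt(A · B)` (specificity × fidelity) with permutation or
  exact p-values.
* **Multivariate dispersion** (`bray_curtis()`, `pcoa()`,
  `betadisper_test()`): distances to group centroids in a principal
  coordinates embedding (negative eigenvalues retained), with ANOVA and
  permutation tests — the PERMDISP approach to beta diversity.
* **Marginal RDA** (`rda_marginal()`): per-covariate explained fractions
  of species variance for quadrat topography (elevation, slope, aspect,
  convexity), with permutation p-values.
* **Composition summaries** (`importance_values()`,
  `species_accumulation()`, `kruskal_wallis()`, `occurrence_overlap()`):
  importance values `IV = (rel. abundance % + rel. frequency % +
  rel. basal area %) / 3`, exact sample-based accumulation curves with
  exact hypergeometric standard deviations, rank tests, and Venn-style
  occurrence counts.
* **Point-pattern statistics** (`pcf()`, `pcf_bivariate()`,
  `mc_envelope()`): pair-correlation functions g(r) with Epanechnikov
  kernel, translation edge correction, and pointwise Monte-Carlo rank
  envelopes (199 simulations → 99% pointwise coverage).
* **Synthetic censuses** (`synthetic_config()`, `generate_census()`,
  `study_config()`): Poisson abundances with controlled plot preferences,
  uniform or Thomas-clustered stem placement, truncated-lognormal DBH,
  reproducible from one seed via per-species × plot streams.

## Worked example

```r
library(forestspec)
cfg <- study_config(seed = 1)        # 4 plots, 89 species, fold-6 preferences
cns <- generate_census(cfg)
cns
#> Stem-mapped census: 10930 stems, 86 species, 4 plot(s)
#>   plantation: 100 x 100 m (quadrat 10 m), 1130 stems
#>   twice_cut: 100 x 100 m (quadrat 10 m), 3011 stems
#>   once_cut: 100 x 100 m (quadrat 10 m), 4264 stems
#>   old_growth: 100 x 100 m (quadrat 10 m), 2525 stems

qm  <- grid_stems(cns)
map <- build_combined_map(cns)
map
#> Habitat map: 40 x 10 cells ( 10 m quadrats ); 4 habitats
#>   null family: 1599 transformed maps

assoc <- torus_test(filter_min_abundance(qm, 5), map, alpha = 0.05)
summarize_associations(assoc)
#> overall: 44/70 species with associations (62.86%); 57 pairs (41 +, 16 -), 13 dual
#> tree: 39/58 species with associations (67.24%); 52 pairs (37 +, 15 -), 13 dual
#> shrub: 5/12 species with associations (41.67%); 5 pairs (4 +, 1 -), 0 dual

build_network(qm)
#> Bipartite network: 86 species x 4 communities, 10930 stems
#>   H2' = 0.2815, connectance = 0.7965 (H2 = 4.5183 in [3.5875, 4.8830])
```

Of the 70 species abundant enough to test (≥ 5 stems), 44 are
significantly associated with at least one disturbance regime — the
generator plants a 6-fold preference in every species, and the torus test
recovers most of them; H2′ ≈ 0.28 says the community is moderately
specialized. `run_pipeline()` executes all stages from one YAML config
and writes CSV/JSON outputs with provenance metadata.

The package also ships `published_associations()`, a transcription of a
published 57-species association table from a four-community temperate
deciduous forest census, used to exercise the reporting layer against
printed results.

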