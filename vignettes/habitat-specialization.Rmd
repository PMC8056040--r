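---
title: "Methods: habitat specialization of woody plants across disturbance regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat specialization across disturbance regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models behind `forestspec`, the choices made
where the design was genuinely open, and what the validation suite does
and does not demonstrate. The setting is a stem-mapped census of woody
plants (every stem with DBH ≥ 1 cm tagged and mapped) across several
plots under contrasting disturbance regimes, with each 100 m × 100 m
plot gridded into 10 m × 10 m quadrats.

## Torus-translation test of habitat association

The question "does species *s* prefer community *h*?" cannot be answered
by a naive chi-square on quadrat counts, because stems aggregate
spatially and quadrats are not independent. The torus-translation test
keeps the stem pattern fixed and instead translates the *habitat map*
around a torus: every shift of the map by whole quadrats, for each of
four variants (identity, 180° rotation, mirror, mirrored rotation),
yields a null map in which habitat patch structure and stem aggregation
are both intact but their alignment is randomized.

The statistic is the relative density
`RD_sh = (n_sh / A_h) / (n_s / A)`, the species' stem density inside the
habitat relative to its overall density (`RD = 1` under no association).
With the four plots concatenated along x into a 40 × 10 torus the family
has `4 × 40 × 10 = 1600` maps: the real one plus 1,599 translations.
Concatenation along x is the only arrangement of four 10 × 10-cell
plots that produces a family of exactly this size on a single torus; the
order of plots is configurable (`layout` argument of
`build_combined_map()`), and per-habitat cell counts are invariant to
it. Translations do wrap across plot boundaries — that is what makes
the family a group and the null exchangeable.

Tail probabilities are empirical:
`p_pos = (1 + #{null maps with RD ≥ observed}) / 1600`, `p_neg`
analogously with `≤`, and a species is called positive (negative) for a
habitat when `p_pos ≤ α/2` (`p_neg ≤ α/2`), with `α = 0.05` by default.
Ties count toward both tails, which makes the test conservative: on
synthetic censuses with no preference (80 stems per species) the
acceptance script measures a positive-call rate of about 0.015 against
the nominal 0.025, approaching the nominal level only as abundances grow
and exact ties in the discrete null thin out. We treat validity (never
exceeding the nominal level) as the requirement and the conservatism as
a documented property, not a defect to be corrected by changing the tie
rule.

Only species with at least five individuals are tested
(`filter_min_abundance()`, "more than four individuals" read literally
as ≥ 5); below that the null distribution of RD is too coarse to be
informative. Tests are per species × habitat, so a species can be
positively associated with one community and negatively with another;
nothing forces a single association.

## Network specialization H2′ and connectance

The species × community abundance matrix is treated as a bipartite
network. With `p_ij = a_ij / m`, the interaction entropy is
`H2 = −Σ p_ij ln p_ij` (natural logarithms throughout, the convention of
the index). Given the observed row and column totals, `H2max` is the
entropy of the independence distribution `r_i c_j / m²`, and `H2min` is
the entropy of the most concentrated integer allocation of the
marginals. The index `H2′ = (H2max − H2) / (H2max − H2min)` is 0 when
interactions follow the marginals and 1 at maximal specialization.

Two numerical choices deserve note:

* **H2min.** For any census-sized network we use a greedy allocation
  (repeatedly place `min(remaining row, remaining column)` into the cell
  with the largest product of remaining totals). The greedy value is an
  upper bound on the true minimum and can exceed it on awkward
  marginals; we verified this by exhaustive search, so for grand totals
  `m ≤ 12` — where enumeration over all integer matrices with the
  observed marginals is trivial — `h2_bounds()` is exact by default, and
  both behaviors remain available via the `exhaustive` argument. The
  `greedy ≥ exact minimum` property is part of the test suite. At census
  scale (thousands of stems) the greedy gap is irrelevant relative to
  `H2max − H2min`.
* **H2max.** The continuous independence bound is the default; an
  integer-constrained alternative exists behind the same `exhaustive`
  flag for sensitivity analysis on toy networks. The continuous bound is
  deterministic, standard, and never smaller than the integer one.

Degenerate networks (a single row or column, where the bounds coincide)
report `H2′ = 0` with a `degenerate` attribute rather than 0/0.
Connectance is simply the fraction of realized species × community
links.

## Indicator species analysis

For species *s* and group *g*, specificity
`A_gs = mean abundance in g / Σ over groups of mean abundances` and
fidelity `B_gs = fraction of sites in g occupied`; the indicator value
is `sqrt(A · B)` and each species is scored by its best group. The
group-equalized form (means, not sums) is the default so that unequal
quadrat counts between communities do not masquerade as specificity; the
site-weighted variant is available (`equalized = FALSE`). Significance
comes from permuting site group labels; the reported p is for the best
group only, uncorrected by default (a `p_adjust` argument provides Holm
and friends). `exact = TRUE` enumerates all distinct label arrangements
instead of sampling, which the oracle tests exploit at six sites.

## Multivariate dispersion (PERMDISP)

Quadrat dissimilarity defaults to Bray–Curtis on untransformed
abundances, the community-ecology default when nothing else is
specified; a pair of entirely empty quadrats is defined to be at
distance 0 with a warning. The dissimilarity matrix is embedded by
classical scaling; Bray–Curtis is non-Euclidean, so negative eigenvalues
appear and are retained, with distances to group centroids combining
real and imaginary axes as `z = sqrt(max(0, d_real² − d_imag²))`.
Group centroids (not spatial medians) are used — a deliberate, simpler
choice, cross-checked exactly against the centroid mode of the
reference implementation in the test suite. Mean distances are compared
by one-way ANOVA, with an optional permutation p obtained by shuffling
the computed distances among groups; both parametric and permutation
p-values are reported since either reading of "ANOVA on the distances"
is defensible.

## Marginal RDA of topography

The per-covariate percentages are computed marginally — each covariate
alone, `100 · SS(fitted) / SS(total)` over all centered species columns
— because per-factor percentages without a stated partitioning scheme
are most naturally read as marginal effects. They do not sum to a full
model fraction unless the covariates are orthogonal (a property the
suite checks on orthogonal designs). Aspect is circular and enters as
its sine and cosine. Constant covariates explain 0% with a warning.
Permutation p-values shuffle the covariate across quadrats.

## Composition summaries

Importance values use
`IV = (rel. abundance % + rel. frequency % + rel. basal area %) / 3`
with relative frequency computed from occupied-quadrat counts and
normalized by the sum of those counts over species — the convention
that makes each component sum to 100% per community, which the `/3`
normalization presupposes. Basal area is `Σ π (dbh/2)²` per species,
reported in both cm² and m²: printed census tables in this field
sometimes label per-species basal areas as cm² while the magnitudes are
only consistent with m², so the package reports both rather than
adjudicating.

Species accumulation uses the exact sample-based estimator
`E[S(n)] = S_obs − Σ_i C(T − T_i, n) / C(T, n)` with binomial
coefficients in log space. Its standard deviation is the exact
hypergeometric one, including all between-species covariances — this
matches brute-force enumeration over site subsets exactly, whereas the
common reference implementation approximates the covariance term via
presence–absence correlations; the suite pins the mean to the reference
exactly and the sd to the enumeration oracle.

Kruskal–Wallis comparisons delegate to the standard rank test with tie
correction, with the fully degenerate case (all pooled values identical)
defined as `H = 0, p = 1` instead of the 0/0 the tie correction would
produce.

## Pair-correlation functions

`g(r)` is estimated with an Epanechnikov kernel (half-width `h`) and
translation edge correction, normalized by `λ̂² = n(n−1)/A²`:

```
ĝ(r) = Σ_{i≠j} k_h(r − d_ij) / ((W − |dx|)(H − |dy|)) / (2 π r λ̂²)
```

Bandwidth defaults to Stoyan's rule `h = 0.15 / sqrt(λ̂)`. `r = 0` is
excluded; estimates at `r < h` carry kernel truncation bias and should
not be over-read. The `n(n−1)` normalization conditions on the realized
point count; for cluster processes with few clusters this induces a
known downward bias of order one over the number of cluster parents, so
closed-form comparisons against the Thomas process
`g(r) = 1 + exp(−r²/(4σ²)) / (4πσ²κ)` are run at 100 parents/ha where
the bias is about 1%; the acceptance script measures a mean relative
error of a few percent over `r ∈ [1.5, 8]` m.

Envelopes are pointwise rank envelopes: with `n_sim` simulations and
coverage `c`, `k = (1 − c)(n_sim + 1)/2` must be a positive integer and
the bounds are the k-th extreme order statistics — 199 simulations and
`k = 1` give the 99% pointwise envelope; incompatible combinations are
rejected with the nearest valid `n_sim` named. The bivariate null
defaults to random labeling (species labels permuted over fixed stem
positions), the standard null for interspecific association in mapped
plots, with independent CSR available as an alternative. Envelopes are
pointwise, not global: reading an exceedance at a preselected distance
is valid, scanning all distances inflates the error rate.

## The synthetic census generator

The generator emulates the study design the analyses expect: four
square 1-ha plots, 10 m quadrats, stems ≥ 1 cm DBH. The baseline
configuration (`study_config()`) fixes per-plot expected totals at
1165, 3065, 4302, and 2490 stems (sparsest in the plantation, densest
in the once-cut stand — magnitudes typical of temperate deciduous
censuses of this design), an 89-species pool (58 trees, 31 shrubs)
with geometric rank-abundance (ratio 0.93), a 6-fold plot preference
rotating through the four plots, Thomas clustering (25 parents/ha,
σ = 5 m) for every second species, and lognormal DBH (trees:
meanlog 1.9, sdlog 0.7; shrubs: 1.0, 0.5; truncated at 1 cm, giving
mean DBHs of roughly 3–25 cm). Abundances are Poisson per
species × plot; positions are uniform or Thomas with offspring re-drawn
until inside the plot (plots are physically bounded; re-drawing
preserves intensity to a good approximation). Each species × plot cell
has its own deterministic random stream hashed from the global seed, so
adding or removing a species never perturbs the others — fixtures stay
stable.

What the generator does *not* emulate: topographic dependence of stem
placement (synthetic topography is generated independently of the
stems, so RDA percentages on synthetic data are near-zero by
construction), interspecific interactions, dispersal limitation beyond
Thomas clustering, size–habitat correlations, and any temporal process
(growth, mortality, succession). Consequently, passing tests demonstrate
that the estimators recover *planted* structure of the kinds above —
intensity contrasts between plots, within-plot clustering, known
dispersion contrasts — at realistic sample sizes; they do not certify
behavior under ecological mechanisms the generator omits.

## Validation design and problem sizes

Every operation with an enumerable small case is tested against an
independent brute-force oracle: torus p-values on a 2 × 2 grid against
explicit enumeration of all 16 transforms; the accumulation curve
against the mean over all 5! site orderings and all site subsets;
H2min against exhaustive integer-matrix search at `m ≤ 12`; IndVal
exact p against enumeration of all label arrangements at 6 sites.
Operating characteristics use moderate Monte-Carlo sizes chosen to keep
the full suite around a minute: 200 null censuses × 20 species for the
torus test's level; 100 replicate species (10-fold preference, ~300
stems) for its power, which is expected to exceed 90% and in practice
saturates; 200 simulations × 199 permutations for the dispersion test's
level; five replicate patterns of ~2000 points for the Thomas
closed-form comparison.

## Known limitations

* The torus test's conservatism at low abundance is inherent to the
  discrete null with two-tailed tie counting; power at small n is
  correspondingly limited.
* Greedy H2min is an upper bound, not the exact minimum, for `m > 12`.
* `pcf()` has no inhomogeneous-intensity variant; K- and L-functions
  are deliberately out of scope.
* The marginal RDA is not a variance partitioning; collinear covariates
  double-count shared variance.
* The pipeline treats whole plots as habitats; within-plot topographic
  habitat subdivision is not implemented.
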