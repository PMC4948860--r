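---
title: "Inferring community assembly from life-stage diversity shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly from life-stage diversity shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageshift)
```

## The inference problem

Woody-plant communities on habitat islands pass through census-able life
stages — seedlings, saplings, trees — and the ecological processes that
filter individuals between stages leave signatures in how diversity changes
across those transitions. A snapshot of one stage confounds the imprint of
assembly with the starting composition; the *change* from one stage to the
next, compared against what random survival would produce, is a far more
direct probe. `stageshift` implements that comparison for two metrics:

* **SD** — species richness;
* **PD** — Faith's phylogenetic diversity, the summed branch length of the
  minimal subtree spanning an island's species.

For each island and each transition (SS: seedling to sapling; ST: sapling
to tree) the package computes the standardized difference

$$Z_D = \frac{(D_{obs,old} - D_{obs,young}) -
  \overline{(D_{ran,old} - D_{ran,young})}}
  {\mathrm{sd}\left(D_{ran,old} - D_{ran,young}\right)},$$

where the `ran` quantities come from randomized communities. Each life
stage is randomized *independently*, which insulates the statistic from the
very different sampling intensities and densities of the stages. A
significantly negative $Z_D$ means diversity fell across the transition
more than random thinning allows (clustering); a significantly positive one
means it rose (overdispersion). This sign convention is used for both SD
and PD.

## The two null models

**Individual-pool resampling (SD).** All individuals of one stage are
pooled, the pooled list is permuted, and individuals are dealt back to
islands so that every island keeps its total abundance and every species
keeps its system-wide total. This is a uniform draw from the fixed-margin
(multivariate hypergeometric) distribution of contingency tables, realized
literally as an individual-label permutation — exact and unbiased, no
burn-in needed.

**Independent swap (PD).** The occurrence structure is randomized by
repeated 2×2 checkerboard swaps; abundance values travel with their
occurrences inside species columns. Per-species occurrence frequency,
per-island richness, and per-species total abundance are all conserved
exactly. Because per-island richness is held fixed, the PD null asks
whether the *identity* of co-occurring species is more phylogenetically
clustered or dispersed than chance, at the observed richness. The swap
chain uses 30,000 attempted swaps per randomization (configurable), a
conventional burn-in for community matrices of this size; the swap kernel
is compiled code driven by R's RNG, so runs are seed-reproducible.

Both nulls default to 1,000 randomizations per ensemble, with
per-replicate seeds derived deterministically from one master seed.

## Significance

Two methods are available for the per-island test of $Z_D$ against its
ensemble:

* `t_test` (default): the one-tailed Student-$t$ tail probability of the
  standardized deviate, $p = P(T_{n-1} \ge |z|)$, in the direction of the
  observed deviation. A literal one-sample $t$-test of the ensemble against
  the observed value would divide by $\mathrm{sd}/\sqrt{n}$ and reject
  essentially always at $n = 1000$; reading the "$t$-test" as the
  $t$-quantile of the standardized effect size is the interpretation that
  calibrates (rejection rate ≈ $\alpha$ under neutral simulation, which the
  test suite verifies).
* `rank`: the randomization p-value
  $(\#\{\text{null values as or more extreme}\} + 1)/(n + 1)$ — the
  distribution-free choice we recommend when in doubt.

Degenerate ensembles (null sd = 0, possible when margins force a unique
table) are flagged and reported as `random`.

## From patterns to mechanisms

The joint (SD, PD) pattern per island and transition maps to candidate
processes:

| SD pattern | PD pattern | inferred mechanisms |
|---|---|---|
| clustering | clustering | environmental filtering, dispersal limitation |
| clustering | overdispersed | interspecific competition |
| overdispersed | overdispersed | density dependence |
| random | random | random process |

Combinations outside the table are flagged `unclassified` and reported as
`random_process`. The mapping rests on phylogenetic niche conservatism
(close relatives share niches), which is why the package ships Blomberg's
K — `blomberg_k()` computes the ratio-of-ratios closed form with the
$n-1$ denominator convention and a tip-permutation test (999 permutations
by default). K is exactly 1 on an equal-branch star phylogeny and averages
1 for Brownian traits, both verified in the tests.

One published description of the PD variant inverts the sign reading
(negative = overdispersion); that contradicts both the SD definition and
the mechanism table above, and we treat it as a typographical inversion:
in this package positive $Z_D$ always means diversity rose across the
transition.

## Faith's PD conventions

`faith_pd()` includes the path to the root by default, so a single-species
community has PD equal to its root-to-tip distance and the full community
recovers the total tree length; `include_root = FALSE` is available.
Missing branch lengths parse as 0 with a warning rather than an error,
because megatree exports often drop them. PD is computed through a
branch–incidence matrix, which makes the per-randomization PD of all
islands a single matrix product; a brute-force path-union oracle checks it
in the tests to $10^{-9}$.

## Attributing shifts to island attributes

`fit_tree()` is a from-scratch CART for a continuous response: greedy
binary partitioning minimizing within-node SSE, candidate thresholds at
midpoints of consecutive sorted unique values, best-first growth, and the
`rpart`-style controls `minsplit = 20`, `minbucket = 7`, `cp = 0.01`,
`maxdepth = 30`. With ~30 islands these defaults allow one or two splits,
which is the right resolution for single-driver questions ("is area or
isolation doing the work?"). Ties in SSE improvement are broken by
predictor column order and then by the smaller threshold, so fits are
deterministic. The "approximate r-square" report is the apparent
$R^2 = 1 - \sum_{\text{leaves}} SSE / SST$ after each split;
cross-validated error is deliberately out of scope. The first split is
checked against an exhaustive search over every (attribute, threshold)
pair, and whole fits against `rpart`, in the test suite. Reference
(mainland) sites are excluded from trees by default, since the attribute
gradients of interest are island properties.

## The synthetic-data generator

`simulate_dataset()` builds a complete testbed: a pure-birth phylogeny, a
niche trait, island attributes, and a three-stage metacommunity with a
known assembly process per transition. Design choices, made once:

* **Cohort sizes.** Seedling cohorts default to 1,000 individuals per
  island, thinned by 12% survival to saplings and 25% to trees. The
  order-of-magnitude excess of seedlings over saplings mirrors natural
  stand thinning, and it also matters statistically: the stage-independent
  null is exactly calibrated for each stage separately, and a large younger
  cohort keeps the nesting covariance between consecutive stages small, so
  neutral $Z_D$ has mean ≈ 0 and sd ≈ 1 across islands (verified at 200
  islands × 1,000 randomizations in the acceptance tests). Census effort
  is equal across islands, so per-island statistical power is comparable
  and the sampling-area attribute carries no signal of its own — matching
  field designs in which sampling area proves non-significant.
* **Regional abundances.** Log-series with $\theta = 0.98$ (lognormal
  available), reproducing the strong rarity skew of real tree communities.
  Neutral colonization is multinomial from one shared regional pool, which
  makes each observed stage conditionally *exactly* a draw from the
  fixed-margin null — the property that underwrites the calibration test.
* **Niche trait.** Brownian motion on an early-burst rescaling of the tree
  (evolutionary rate decaying with depth), i.e. a trait conserved deep in
  the phylogeny. Habitat affinities of woody plants are conserved at this
  depth; a plain-Brownian trait links trait filtering to phylogenetic
  clustering only weakly. `simulate_traits_bm()` itself remains plain
  Brownian motion — the rescaling is applied only to the niche trait
  inside `simulate_dataset()`.
* **Environmental filtering** multiplies survival by a Gaussian kernel in
  the distance between the species trait and the island's best-matching
  habitat optimum. Each island holds one or two habitat patches — patch
  number growing with log area — whose optima are drawn from the
  empirical trait distribution (with jitter), so every optimum
  corresponds to viable niche space. Small islands thus filter the
  community through a single habitat, large islands through several:
  area-driven loss of rare habitats, which makes island area the
  recoverable driver of SS shifts while keeping filtering active
  everywhere.
* **Interspecific competition** is asymmetric exclusion among close
  relatives: each island draws a persistent local competitive hierarchy,
  and a species' survival decays with the abundance of phylogenetically
  similar species that outrank it locally (similarity kernel with decay
  scale 0.12 of the mean pairwise distance; penalty scaled by local
  richness; thinning in 10 rounds so exclusion feeds back). Different
  islands keep different clade winners, which is what makes the signature
  detectable against margin-preserving nulls: richness falls below the
  null (SD clustering) while survivors are phylogenetically spread (PD
  overdispersion).
* **Dispersal limitation** acts at colonization (pool weights down-weighted
  by isolation × a conserved dispersal-limitation score) and at transition
  survival, producing clustering of both metrics that strengthens with
  isolation.
* **Density dependence** penalizes conspecific relative density
  (survival $\propto e^{-s\,f_i S}$), promoting evenness and rare-species
  persistence — overdispersion of both metrics.
* **Reference site.** One mainland-like site (largest area, zero
  isolation) is appended and flagged `is_reference`; it flows through
  shift tables but is excluded from regression trees.
* **Strength 0 is neutral by construction** for every process (the test
  suite asserts bit-identical output), and all processes reduce to uniform
  thinning continuously as strength → 0.

What the generator does **not** emulate: within-island spatial structure,
seed banks, growth and mortality dynamics between censuses, observation
error in species identification, and real floristic composition. Passing
the recovery tests therefore shows the *inference machinery* behaves as
designed under its own assumptions, not that field data meet those
assumptions. An optional `quadrat_sampling` mode emulates seedling
censuses in 1×1 m quadrats whose count scales with log island area (4–48);
the proportionality rule is a stand-in, as published protocols rarely
state the exact mapping, and it is off by default so that all stages are
full censuses.

## Numerical choices and degenerate inputs

* Shape index $SI = P / (2\sqrt{\pi A})$ is computed after converting
  hectares and kilometers to meters, so it is exactly 1 for a circle and
  dimensionless; mixed-unit evaluation would silently scale it by 0.1.
* Polygon area uses the shoelace formula with absolute value (orientation
  free); isolation is the minimum segment-to-segment distance, 0 for
  touching boundaries, an error for overlapping interiors.
* `z_score()` with a zero-sd ensemble returns 0 when the observed
  difference equals the null mean and signed infinity otherwise, flagged
  `degenerate`; classification treats such islands as `random`.
* Swap randomization of a matrix with no 2×2 checkerboard returns the
  input with a message (the chain has a single state).
* All pipeline randomness flows from one master seed through
  deterministically derived per-replicate seeds; two runs with the same
  seed produce byte-identical output files.

## Problem sizes in the test suite

The statistical tests run at deliberately moderate sizes chosen to hold
Monte-Carlo noise well below each tolerance: neutral calibration at 200
islands × 1,000 randomizations; mechanism recovery at 30 islands × 999
randomizations with scenario strength 12 ("high"); Brownian-trait
covariance at 2,000 replicates on 32 tips; K behaviour at 200 Brownian
replicates on 64 tips; null-model uniformity at 5,000 draws over the six
3×3 permutation matrices, where the fixed-margin law is exactly uniform.

## Known limitations

* The per-island tests are not corrected for multiple comparisons across
  islands; the island-level calls are descriptive, as in the field's
  standard workflow, and system-level statements should rest on the sign
  counts and regression trees.
* The `t_test` p-value assumes the null ensemble is approximately
  location-scale regular; for small `n_rand` or heavily discrete metrics
  prefer `rank`.
* The independent swap explores the checkerboard-connected component of
  the matrix; extremely dense or degenerate matrices mix slowly, and the
  fixed 30,000-swap burn-in is a convention, not a convergence guarantee.
* Regression trees with ~30 islands resolve at most one or two splits;
  the reported apparent $R^2$ is optimistic by construction and should not
  be compared across trees with different numbers of splits.
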