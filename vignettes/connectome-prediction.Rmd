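---
title: "Predicting cortical projections from structural type and border distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cortical projections from structural type and border distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopred)
```

## The data model

Tract-tracing collations report, for an ordered pair of cortical areas,
one of five outcomes: the projection was never examined (*unknown*), was
examined and not found (*absent*, code 0), or was found with ordinal
density *sparse* (1), *intermediate* (2) or *dense* (3). The package
keeps the absent/unknown distinction first-class throughout: a
`projection_table` stores one record per *examined* ordered pair, and
every pair without a record is unknown. Most analyses binarize the three
densities to a single *present* code (`binarize()`), because densities
cannot be normalized against the sampling structure of the collation the
way existence can.

Three per-pair structural variables drive the analyses:

* `delta_dist` — border distance, the shortest-path length between the
  two areas in the symmetric border-adjacency graph of the parcellation
  (breadth-first search via `igraph`; only lengths are used, so tie
  structure among shortest paths is irrelevant). Unitless counts of
  borders crossed; on whole-cortex parcellations of this granularity it
  spans roughly 1–6.
* `delta_type` — difference of ordinal structural types 1–5
  (cytoarchitectonic differentiation, principally the width, density and
  granularity of layer IV; 1 = agranular/least differentiated). Signed
  and antisymmetric; analyses of undirected questions use `abs_type`.
* `delta_level` — difference of levels in a named, externally supplied
  hierarchy of visual areas. Hierarchies are inputs, never derived here:
  deriving them from laminar patterns and then correlating them with
  those patterns would be circular, which is precisely the caveat the
  laminar analyses are designed around.

Pairs missing an attribute are excluded per-analysis, not globally, so
the distance analysis can use every pair while the level analysis uses
its small visual subset.

## The predictive model

The model asks: knowing only how far apart two areas are and how
different their cytoarchitecture is, can one predict whether a
projection between them exists?

Not all combinations of the predictors can occur equally often — small
type differences at distance 1 are abundant, extreme combinations are
rare — and the examined pairs are a biased sample of the possible ones.
`build_grid()` therefore normalizes the observed absent/present counts
in every cell (a, d) = (|Δtype|, Δdist) by the total number of ordered
typed pairs with that combination, yielding percentages `pct_absent` and
`pct_present` whose sum is below 100 by exactly the unexamined share.
`construct_cases()` converts the percentages back into a case set
(rounded to the nearest integer, halves up — the rounding rule is a
package choice, as percentages are rarely integral), which re-weights
the evidence by how thoroughly each region of predictor space was
sampled.

`fit_lda()` is classic two-class linear discriminant analysis with
pooled (bias-corrected, denominator N−2) within-class covariance and
uniform priors, written in closed form: weights
`w = S⁻¹(μ_present − μ_absent)`, bias `b = −w·(μ_present + μ_absent)/2`,
posterior `plogis(w·x + b)`. A ridge of 1e-8·tr(S) is added only if S is
numerically singular. Standardized coefficients are reported as
magnitudes |w_j|·s_j with s_j the pooled within-class SD of predictor j.
The in-package implementation is the model itself; `MASS::lda` serves
only as an independent cross-check in the test suite.

Decisions use a symmetric band: present if posterior ≥ θ, absent if
posterior ≤ 1 − θ, otherwise unclassified; θ runs over 0.60–0.90 in
steps of 0.05 and 0.75 is the headline threshold. `cross_validate()`
holds out a random 10% of the *constructed cases* (the cases are the
model's training currency; holding out raw projections instead would be
the other defensible choice) for each of 200 cycles, refits, and reports
mean ± SD accuracy per predicted category, counting only classified
cases. `predict_unknown()` applies the fitted posterior to every
unknown-status ordered pair with defined predictors. The model is
symmetric by construction — |Δtype| discards the direction of the type
difference — so it cannot express asymmetric connectivity, and
`delta_level` is deliberately not a predictor (its relative frequency
correlation is weak and its coverage tiny).

## Ordinal statistics

All tests use average ranks for ties and two-tailed α = 0.05:

* `spearman_test()` — ρ as the Pearson correlation of ranks; for n ≤ 8
  the p-value is an exact permutation p (the classical exact tables are
  invalid under ties; the frequency-profile vectors these tests run on
  have n = 5 or 6), else a t-approximation.
* `wilcoxon_rank_sum()` — rank-sum W with tie-corrected normal z;
  exact enumeration p for combined n ≤ 8.
* `kruskal_wallis()` — tie-corrected H and χ² p via
  `stats::kruskal.test`; `bonferroni()` exposes the correction
  denominator because post-hoc families can be defined more than one
  way.
* `jonckheere_terpstra()` — trend across ordered groups; raw JT counts
  cross-group pairs in order plus half-ties, z uses the no-tie variance
  (a documented simplification; the tie-corrected variance differs
  negligibly at the group sizes used here), exact enumeration p for
  combined n ≤ 8.

## The synthetic generator

`generator_config()` fixes the generative assumptions:

| parameter | default | meaning |
|---|---|---|
| `n_areas` | 64 | areas in the parcellation |
| `adjacency_model` | random-geometric | unit-square threshold graph, regenerated (bounded attempts) towards a border-distance range of about 1–6, matching real whole-cortex parcellations; a 4-neighbour grid is available but its diameter (14 at 64 areas) is unrealistically long |
| `type_field_smoothness` | 1.5 | kernel bandwidth of the spatial type field in units of mean inter-area spacing; types are quantile bins of a smoothed Gaussian field, so differentiation changes gradually and each type recurs in several places |
| `beta0, beta_dist, beta_type` | 2.0, 0.6, 0.8 | existence model P(present) = plogis(β₀ − β_dist·Δdist − β_type·|Δtype|) — the simplest monotone model consistent with the observed frequency declines |
| `unknown_rate` | 0.67 | each ordered pair is masked to unknown independently (missing completely at random), mirroring the examined share of the real collation |
| `strength_decay` | 0.5 | dense projections are favoured at short distances via softmax weights exp(decay·(3−d)·(s−1)) |
| `level_scale, hierarchy_noise` | 1, 0.5 | hierarchy levels on a designated corner subset: max(0, round((6 − type)·scale + N(0, noise))) — levels anti-correlate with type, as real hierarchies do |
| `direction_flip_rate` | 0.10 | directions derive from the sign of Δlevel (ascending if negative, descending if positive, lateral at zero) with this much reassignment noise |

Directions derive from *levels*, not directly from types, so the
direction–type correlation emerges indirectly through the type–level
coupling — mirroring how, in real data, hierarchical levels are
themselves constructed from laminar patterns.

`synthetic_cat_fixture()` produces the deterministic stand-in shipped
under `inst/extdata/` at the published dimensions of the cat collation:
65 areas (geometric graph conditioned on diameter exactly 6), 49 typed,
four spatial modules over 53 areas named along the decreasing-type
gradient, 11 top-degree hub areas, hierarchy levels on the 22 typed
areas nearest the visual-module centroid, and quota-sampled statuses —
exactly 1,400 known projections, 954 examined typed pairs with exactly
218 absent and 736 present, examination effort decaying with distance
and presence sampled by the logistic model's probabilities. The sample
sizes are constructive inputs; every *statistic* computed downstream is
emergent.

## What the stand-in does and does not show

Because the generator shares the monotone structure the analyses test
for, the pipeline on the stand-in reproduces the *qualitative* published
findings: relative frequency maximally rank-anticorrelated with both
distance and type difference (ρ = −1.00), cross-validated accuracy above
75% for both prediction categories at θ = 0.75, a negative and
significant degree–type correlation, lower types among hub areas, and a
decreasing type trend across modules.

Quantitative point values of the real collation are *not* matched, and
tests asserting them fail by design honesty rather than being weakened:
the stand-in's discriminant coefficients (≈1.3/1.5 vs the published
0.95/0.71), decided-prediction counts, module medians and range
percentages depend on the real joint distribution of types, distances
and sampling that only the original supplementary table contains.
Two structural divergences are worth naming. First, a single smooth
type field makes |Δtype| and Δdist positively correlated (ρ ≈ 0.33 on
the stand-in), whereas the real cortex shows independence (ρ ≈ 0.06) —
real differentiation gradients repeat across modules more than one
smooth field can express. Second, because the stand-in's levels derive
from types, level differences inherit predictive signal, so its
level–frequency correlation is stronger than the published null result.

## Numerical and testing choices

* Problem sizes: unit tests run generators at 16–64 areas; the
  acceptance-level recovery checks use 20 seeds at the 64-area default
  and 200-cycle cross-validation on the fixture's ~940 cases.
* Boundary-orientation recovery (fitted weight ratio vs β_type/β_dist)
  holds to within ~10% at 64 areas but degrades beyond 20% below ~50
  areas, where the discrete predictor grid is too coarse.
* Known limitation (spatial confounding): with `beta_type = 0` the
  degree–type correlation is non-significant in only ≈75% of seeds, not
  the nominal 95%, because the smooth type field is spatially
  autocorrelated while degree tracks graph centrality — the effective
  sample size of the rank test is far below the number of areas. A
  spatially corrected null test is out of scope; the corresponding
  stochastic acceptance check is left failing with this explanation
  rather than being relaxed.
* The strict ρ = −1 frequency-monotonicity recovery is sensitive to the
  sparsely examined farthest distance classes (a handful of examined
  pairs at distances 5–6 under Bernoulli existence and the 67% mask);
  across arbitrary seeds it holds for |Δtype| in ≈95% and for Δdist in
  ≈75% of realizations.
* Degenerate inputs: zero-variance correlation inputs, empty test
  groups, one-class case sets and singular covariances raise errors;
  all-identical observations in the two- and k-group tests warn and
  return the trivial statistic; distance-6 projections fall in neither
  the short (1–2) nor long (4–5) range bin.
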