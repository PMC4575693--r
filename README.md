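# connectopred

Predicting the existence of corticocortical projections from
cytoarchitecture and inter-areal distance.

## The problem

Anatomical tract tracing has mapped only a fraction of the mammalian
cortical connectome: in the classic whole-cortex collation for the cat,
about two thirds of all possible directed area pairs have never been
examined, and an unexamined ("unknown") pair is *not* the same thing as a
pair that was examined and found unconnected ("absent"). `connectopred`
implements an analysis pipeline for such collations that

1. computes, for every ordered pair of cortical areas, three structural
   variables —

   * **border distance** Δ<sub>dist</sub>: the minimum number of area
     borders crossed between the two areas, i.e. the unweighted
     shortest-path length in the parcellation adjacency graph,
   * **structural type difference**
     Δ<sub>type</sub> = type(source) − type(target), where the ordinal
     *structural type* 1–5 summarizes an area's cytoarchitectonic
     differentiation (1 = least, 5 = most differentiated), and
   * **hierarchical level difference** Δ<sub>level</sub> in a published
     hierarchy of visual areas;

2. quantifies how the probability of a projection's existence depends on
   these variables (relative projection frequencies, cumulative
   percentages, Spearman rank correlations, Wilcoxon / Kruskal–Wallis /
   Jonckheere–Terpstra tests);

3. fits the core predictive model: a two-class linear discriminant over
   (|Δ<sub>type</sub>|, Δ<sub>dist</sub>) with uniform priors, trained on
   cases constructed from *co-occurrence-normalized* percentages — the
   observed numbers of absent and present projections per predictor
   combination are divided by the maximum possible number of pairs with
   that combination, so that unevenly sampled regions of the predictor
   space are re-weighted. The fitted posterior
   p<sub>present</sub>(|Δ<sub>type</sub>|, Δ<sub>dist</sub>) classifies
   unexamined pairs as present (p ≥ θ), absent (p ≤ 1 − θ) or
   unclassified, with holdout cross-validation across thresholds
   θ = 0.60 … 0.90;

4. relates structural type to connectome topology: node degree and
   weighted degree (ordinal strengths sparse / intermediate / dense
   weighted 10⁰ / 10¹ / 10²), short- versus long-range connection
   profiles, module and rich-club ("hub") comparisons, and a robustness
   scan for the degree–type correlation under hypothetical examination
   of the unknown pairs;

5. correlates laminar projection directions (ascending / lateral /
   descending) with type and level differences.

A seeded synthetic generator (`generator_config()`,
`synthetic_connectome()`) emulates the statistical structure these
analyses assume — a connected planar-like parcellation, spatially smooth
types, logistic existence probability decreasing in both distance and
type difference, and a missing-completely-at-random unknown mask — so
the whole pipeline runs and is tested without any external data.
`synthetic_cat_fixture()` generates the deterministic stand-in dataset
shipped under `inst/extdata/` with the published dimensions of the cat
collation (65 areas, 49 typed, 954 examined typed pairs: 218 absent,
736 present, …). It is synthetic data, not a transcription of the real
collation.

## Worked example

```r
library(connectopred)

fx <- load_fixture()            # shipped synthetic stand-in
pv <- join_status(pair_variables(fx$parcellation, fx$hierarchy), fx$table)

# existence falls off monotonically with distance
relative_frequencies(pv, "delta_dist")[, c("value", "rel_freq")]
#>   value  rel_freq
#> 1     1 0.8447837
#> 2     2 0.6824645
#> 3     3 0.5171340
#> 4     4 0.3841808
#> 5     5 0.2987013
#> 6     6 0.0000000

# discriminant model on co-occurrence-normalized cases
model <- fit_lda(construct_cases(build_grid(pv)))
model
#> two-class linear discriminant model (uniform priors)
#>   weights: abs_type = -1.1264, delta_dist = -1.1419
#>   standardized coefficients: abs_type = 1.325, delta_dist = 1.510
#>   cases: absent = 344, present = 593

# classify the unexamined pairs at the 0.75 / 0.25 thresholds
pred <- predict_unknown(model, pv)
n_decided(pred, 0.75)
#> [1] 859
```

Both discriminant weights are negative: the posterior probability that a
projection exists decreases with border distance and with absolute type
difference, so predictions of "present" concentrate among nearby,
cytoarchitectonically similar area pairs. Of the 1,398 unexamined typed
pairs, 859 fall outside the posterior band (0.25, 0.75) and receive a
decision at θ = 0.75. `run_all(fx, "out/")` executes every stage and
writes the TSV/JSON report bundle; a thin command-line front end lives
at `inst/cli/connectopred.R`.

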