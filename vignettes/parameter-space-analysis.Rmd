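---
title: "Parameter-space analysis with psweep: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter-space analysis with psweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psweep)
```

This vignette documents the methodology behind `psweep`: the sampling and
session model, each derivation method's exact semantics, the statistics
behind the demo apps, what the synthetic generators do and do not emulate,
and the numerical conventions chosen where the design was genuinely open.

## The sampling model

A manifest declares each parameter's kind, default, and legal values.
Sampling is uniform and independent per parameter: integers uniformly on
the closed interval `[lo, hi]` (both endpoints reachable), doubles
uniformly on `[lo, hi]`, booleans and categoricals uniformly over the
enabled subset. Nothing fancier (Latin hypercube, stratification,
adaptive refinement) is offered: independent uniform draws compose
trivially under stop/resume and make every marginal histogram directly
interpretable.

Reproducibility uses a counter-based scheme: draw *i* of a session is
generated under a temporary RNG state seeded with `mix_seed(seed, i)`,
two rounds of a multiplicative congruential map (multiplier 40014,
modulus 2^31 − 85, exact in double arithmetic). Consequences worth
knowing:

* stopping after *m* draws and resuming later replays draws
  *m*, *m*+1, … exactly as an uninterrupted session would have produced
  them — the session's `sampling_spec.json` tracks the draw counter;
* the caller's global RNG stream is never consumed;
* two sessions with equal `(manifest, spec, seed)` have byte-identical
  parameter columns.

`runsInfo.txt` is appended one record at a time and rewritten atomically
during derivation, so a killed process leaves a loadable prefix. A run
whose app raises an error keeps its run id with status `failed` and
missing derived values; downstream analytics drop such records and say
how many were dropped. Two bookkeeping columns beyond the parameter
values are always present: `status` and `duration_seconds` (models with
per-epoch records also get their recorded metric columns).

## Derivation semantics

Each pass reads one output table per run and appends columns whose names
are part of the on-disk contract (external tools may join on them):
`<fn>_<column>` for the five numeric aggregates, `Num(<table>)` for the
distinct-label count, `mode_<column>` for the modal label,
`n(<column> = <label>)` for per-label counts (the label universe is the
union over all runs, zero-filled per run, so the table stays
rectangular), and `n(<pred> = P & <gt> = G)` for the six cells of a
boolean prediction crossed with a ternary `{TRUE, FALSE, NA}` ground
truth. The `NA` truth category is deliberate: in the spike-in benchmark
only the 92 spike-ins have known state, and the two `GT = NA` cells count
candidate calls among the unknown background rather than polluting the
true/false cells.

The dimensionality-reduction pass embeds *runs*, not data rows: each
run's selected columns are flattened to one feature vector and the
runs-by-features matrix is projected to 2-D, giving one coordinate pair
per run to join onto the runs table (row-wise projection of a single
table is the `dimred_app()` demo instead). Re-running a pass replaces the
columns it produced earlier (provenance is kept in
`derived_columns.json`), parameter columns are never overwritten, and
derivation never modifies `runs/` files.

## Exploration conventions

* **Dominance.** `pareto_front()` uses weak dominance with strict
  improvement on at least one axis; exact ties on all axes keep all tied
  runs. Implementation is a lexicographic-sort sweep; the test suite
  checks it against an O(n²) pairwise oracle.
* **Quality aggregation.** `normalized_mean_quality()` min–max normalizes
  each metric over non-missing runs, inverts metrics whose registry entry
  says lower-is-better, and averages. The default registry treats
  Calinski–Harabasz, silhouette and gap as higher-is-better and
  Davies–Bouldin and S_Dbw as lower-is-better; the registry is an
  explicit argument so either orientation can be overridden. A constant
  metric carries no ranking information and is mapped to 0.5 (with a
  warning) rather than to either extreme.
* **Histograms.** Sturges' rule for numeric columns (no principled bin
  count is implied by the data; Sturges is the familiar default), one bar
  per value for categoricals.
* **Jitter.** Scatter plots of categorical axes jitter only at render
  time with a seeded offset; stored data are never perturbed.

## The clustering study

`clustering_run()` wraps four standard algorithms (`stats::kmeans`,
`stats::hclust` + `cutree` with ward/complete/average/single/median/
centroid linkage, `kernlab::specc`, and a plain DBSCAN written in-package
because no DBSCAN implementation is available among the dependencies).
Cluster ids are relabeled to consecutive integers from 0; DBSCAN noise
keeps id 0. Methods may legitimately return fewer distinct ids than the
requested `k`.

The five validity indices are own implementations with these
conventions:

* *Calinski–Harabasz*: `(B/(k−1))/(W/(n−k))` on Euclidean scatter.
* *Silhouette*: mean width via the `cluster` package; points in singleton
  clusters contribute 0 (including the all-singleton `k = n` labeling);
  indices needing within-cluster structure are `NA` when `k < 2` or
  `k ≥ n`.
* *Davies–Bouldin*: mean worst-pair `(S_i + S_j)/d(c_i, c_j)` with
  centroid distances.
* *Gap*: `mean(log W*_b) − log W` with `B` uniform reference draws over
  the per-feature bounding box, each clustered by k-means at the same
  `k`. `B` defaults to 10 and is exposed as the app parameter `gap_B`;
  desk-scale sweeps use `gap_B = 2`, trading reference variance for a
  roughly five-fold speedup of the most expensive index.
* *S_Dbw*: average cluster scatter plus inter-cluster density (density at
  cluster-pair midpoints relative to the denser of the two centers,
  probe radius = mean cluster standard deviation); pairs with an empty
  denominator contribute 0.

`generate_paintings_like()` emulates a catalogue of 403 paintings scored
on 67 binary scene features: five planted theme blocks of co-occurring
features (on-probability 0.7 inside the block, 0.05 outside) plus four
near-universal features. It reproduces the *shape* and the block
structure that makes clustering non-trivial — it does not model feature
marginals, inter-theme correlation or metadata of any real catalogue, so
index values on it say nothing quantitative about real data.

## The differential-expression study

`generate_seqc_like()` draws negative-binomial counts for two conditions
with five replicates each: log-normal baseline means (meanlog 3,
sdlog 1.8 — median ≈ 20 counts with a long tail), gamma dispersions
(shape 2, rate 20, floor 0.01), spike-ins at higher abundance
(meanlog 5), and 10% nuisance DE among the background (log-fold-changes
N(0, 0.8)) so the background is not a pure null. The 92 spike-ins split
23 : 23 : 23 : 23 across ratios 1, 0.5, 0.67 and 2, with `GT_DE` TRUE
exactly when the ratio differs from 1 and `NA` for all background genes.
The count depths and dispersions are plausible for bulk RNA-seq but are
config values, not estimates of any particular benchmark's distribution.

`de_caller_run()` is deliberately transparent rather than
state-of-the-art: size factors by total count or median-of-ratios; genes
below the CPM cutoff in every sample excluded (`DE = 0`); a log-ratio
statistic `log(m2 + ½) − log(m1 + ½)` with variance from the NB relation
`(m + φm²)/n` propagated through the log; a Student-t reference with
`n1 + n2 − 2` degrees of freedom; `stats::p.adjust`; sign of the
log-ratio where the adjusted p-value clears the threshold. Two numerical
choices matter for calibration at five replicates: per-gene moment
dispersions are *not* truncated at zero (truncation systematically
inflates the variance and makes the test conservative; untruncated, the
modeled variance coincides with the sample variance), and the common-
dispersion mode shares the median of the truncated per-gene estimates (a
negative shared dispersion would be meaningless, so that mode is mildly
conservative by construction). Under the generator's global null the
per-gene mode's empirical false-positive rate at p < 0.05 is within
sampling error of nominal; this is verified, not assumed, in the test
suite.

## The neural-network study

`generate_playground_dataset()` reproduces the four classic 2-D
classification shapes on the `[−5, 5]` square with exactly 100 points per
label. Constants are fixed here since the emulated tool does not publish
them: gauss blobs at (±2, ±2) with sd 0.5 → 4 linear in noise; circle
positives on radius ≤ 2.5 against an annulus 3.5–5; xor with 0.3 padding
off the axes; spirals of 1.75 turns half a turn apart. For circle, xor
and spiral, noise `v` perturbs the *labelling* position by a uniform
offset of `v`% of the half-width per coordinate — labels flip near class
boundaries while stored coordinates stay clean, so class overlap grows
with noise; balance is kept exact by quota sampling. The seven standard
feature transforms are exact functions of the stored coordinates.

`mlp_train()` is a plain mini-batch gradient-descent network: squared
error on ±1 targets, hidden activation chosen per run (`linear` is the
identity), a tanh output unit (bounding predictions and loss, so extreme
learning rates saturate instead of overflowing — bad settings leave
interpretable records rather than NaNs), uniform(−0.5, 0.5) seeded
initialization, L1/L2 penalties on weights only. Each sampled
combination trains once and snapshots train/test loss, TPR, FPR and
timing at every checkpoint epoch, emitting one runs-table record per
checkpoint with `epoch` as a column; the predicted-labels table and
optional decision-surface image are stored under the combination's first
record id. A combination whose loss turns non-finite, or that samples an
empty feature set, keeps its per-checkpoint records with missing metrics
and status `failed`, so a sweep's record count is always
`n_combinations × n_checkpoints`. Classification thresholds the output
at 0; with balanced ±1 targets a train loss of 0.2 is the conventional
"converged" bar used throughout.

## Problem sizes and verification scale

The bundled studies are exercised at the scale a single desk session
handles comfortably: the clustering sweep at 1,000 runs over three
methods with `gap_B = 2`; the DE sweep at 500 runs over a 2,000-gene
table (the full 21,716-gene benchmark is generated for census checks,
where only its design invariants matter); the MLP sweep at 2,500
combinations checkpointed at epochs {2, 4, 6, 8} — training dynamics are
validated separately at the standard {50, 100, 200, 400} checkpoints on
single fits. Calibration of the DE caller uses 50 generator seeds at
2,000 genes. The learnability contrast (linear vs tanh networks) runs at
noise 10 rather than the sweep's noise 25, so the 0.2-loss bar measures
model capacity rather than the label-noise floor, and the nonlinear arm
may use all seven input features — separating "this family cannot
represent the boundary" from "this dataset is noisy".

## Known limitations

* Only independent uniform sampling; no surrogate modeling, adaptive
  sampling, or parameter-importance ranking. Declared parameter
  dependencies are parsed and retained but not enforced.
* The ground-truth derivation handles a boolean prediction against a
  ternary truth; multi-class comparison is an extension point.
* The DE caller is a teaching-grade statistic: no shrinkage across
  genes, no GLM offsets, no weighting. Its parameter *roles* mirror
  production callers; its calls should not be used for real inference.
* The MLP trains by plain SGD without momentum or adaptive rates;
  playground-exact numerical parity is out of scope (the emulated tool
  itself reports implementation-dependent differences).
* Synthetic generators reproduce designs (shapes, censuses, ratio
  structure), not the empirical distributions of any real dataset;
  passing tests demonstrate correct mechanics, not real-data behavior.
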