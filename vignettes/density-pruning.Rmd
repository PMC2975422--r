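---
title: "Density-based pruning for DEG identification: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based pruning for DEG identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degprune)
```

## The model

Given a log-scale expression matrix `M` with `N` genes and `P = P1 + P2`
samples split between conditions A and B, each gene is mapped to two
features:

- `AG = (X̄^A + X̄^B) / 2`, the average expression level, in log units;
- `AD = |X̄^A − X̄^B|`, the average difference, which on log data equals the
  absolute log fold change.

`AG` is defined as the mean of the two condition means, not the mean over
all `P` samples; the two differ under unbalanced designs (`P1 ≠ P2`) and the
condition-mean form is implemented as written, so that a heavily replicated
condition does not dominate the expression-level axis.

The working assumption is geometric: equally expressed genes form a dense
cloud hugging `AD = 0`, while true DEGs are sparse boundary points at high
`AD` and, empirically, high `AG`. *DB pruning* removes the dense cloud: gene
`i` is pruned iff it has `n_i ≥ N0` neighbours, where a neighbour is any
other gene at Euclidean distance *strictly* less than `R0` in (AG, AD). What
survives is, by construction, the sparse boundary.

Strictness matters for two edge cases and we adopt the literal reading:
points at distance exactly `R0` are not neighbours, and therefore `R0 = 0`
is a guaranteed no-op (everything survives). Coincident genes are mutual
neighbours at any positive radius and are never de-duplicated — a stack of
`N0 + 1` identical points prunes itself entirely.

## Parameters

- `n0` (dimensionless count, default 4): the density threshold. A gene
  survives with up to `n0 − 1` neighbours. Small integers (3–6) behave
  similarly; 4 is a robust default across heterogeneous datasets.
- `r0` (log2 units): the neighbour radius. Its meaningful range is 0 to
  `max(AD)`: by `max(AD)` the radius spans the whole difference axis and the
  survivor count has essentially bottomed out. Because the survivor count is
  a non-increasing step function of `r0`, the package normally derives `r0`
  from a target candidate-list size instead (`target_k`).
- `target_k`: the desired number of surviving candidate genes. A bisection
  over `[0, max(AD)]` (at most 64 iterations, or earlier if the target is
  hit exactly) tracks the best radius visited. Exact `target_k` may be
  unattainable — the step function jumps — so the closest visited count
  wins, with ties broken toward *more* survivors, which errs on the side of
  retaining true DEGs. After 64 halvings the bracket is far below the
  spacing of distinct neighbour distances, so the two counts adjacent to the
  target have both been visited and the bisection is as close as an
  exhaustive scan over all pairwise-distance midpoints (this is asserted in
  the test suite).
- Features are kept in raw log units; no standardisation precedes the
  distance computation, since the radius bounds are stated in `AD` units. A
  min–max rescaling of both axes to `[0, 1]` is available behind
  `compute_features(..., rescale = TRUE)` (off by default) for users who
  prefer a scale-free radius; published radii for this style of pruning vary
  by more than an order of magnitude between studies, which is consistent
  with differing axis scalings, so neither convention is claimed to
  reproduce any particular external number.

## The four rankers

All four statistics score genes so that higher means more DEG-like, and
`rank_genes()` breaks ties stably by input row order for determinism.

- **Fold change**: `score = AD`.
- **WAD**: `score = AD × w` with `w = (AG − min AG) / (max AG − min AG)`;
  when `AG` is constant the weight is 1 everywhere (pure fold change) rather
  than 0/0.
- **t statistic**: pooled-variance Student form
  `|X̄^A − X̄^B| / sqrt(s_p²(1/P1 + 1/P2) + ε)` with `ε = variance_floor`
  (default 1e-8) added to the squared standard error. The floor gives
  zero-variance genes a finite, dominant score instead of `Inf`; the pooled
  (not Welch) form is the default because the small-sample microarray
  literature this targets predates Welch-by-default, and its
  small-variance pathology is exactly what pruning is meant to fix. Welch is
  available via `welch = TRUE`. Designs with fewer than 2 samples per
  condition are refused with a pointer to FC/RP.
- **Rank product**: over all `P1 × P2` ordered sample pairs, genes are
  ranked by the pairwise difference `value_B − value_A` descending (rank 1 =
  most up) and ascending (rank 1 = most down), average ranks on ties;
  `RP_up`/`RP_down` are geometric means across pairs, accumulated in log
  space to avoid overflow, and `score = −log(min(RP_up, RP_down))`. The
  `min` combines both regulation directions because real truth sets contain
  both. All `P1 × P2` pairings are used (the published default for the
  statistic), not matched pairs. One subtlety: with a single sample pair the
  min-combined ordering agrees with fold change only up to the tent-shaped
  symmetry of `min(r, N+1−r)`; the agreement is exact on sign-balanced
  difference profiles, which is how the property is tested. Permutation
  p-values for RP are out of scope — the statistic is used purely as a
  ranking.

Pruned-gene handling defaults to **append**: survivors sorted by score, then
pruned genes sorted by score. This keeps top-K prefixes defined for any K
and keeps ROC axes identical with and without pruning; it also yields a
clean guarantee, tested as a property: the rank of every surviving gene can
only improve. `exclude` mode restricts the ranking to survivors.

## Evaluation harness

ROC curves are prefix-based — one point per prediction count `k = 0..k_max`
(default 1000), `TPR = TP/|truth|`, `FPR = FP/(N − |truth|)` — rather than
score-threshold-based, because the cutoff of practical interest is how many
genes a lab can verify. The partial AUC is the trapezoidal area under these
points in raw FPR × TPR units, deliberately *unnormalised*: with a truth set
of tens among thousands of genes and `k_max = 1000`, FPR only reaches a few
percent, so magnitudes of a few hundredths are expected and comparisons are
made within a dataset, never across differently sized ones. Enrichment is
the plain truth fraction of a list; top-K counts default to the grid
150–550. When several datasets are compared, top-K counts are summed across
datasets at each K.

## The synthetic generator

`simulate_deg_matrix()` reproduces the geometry the method assumes, on the
log2 scale (i.e. log-normal intensities):

- non-DEG `i`: baseline `μ_i ~ N(baseline_mean, baseline_sd²)`, every sample
  `= μ_i + N(0, noise_sd²)`;
- DEG `i`: baseline shifted up by `deg_level_shift`; condition B offset by
  `δ_i = s_i·U(effect_min, effect_max)` with `s_i = ±1` equiprobable (truth
  sets contain both directions);
- a `hard_fraction` (default 0.1) of DEGs forgo the level shift, emulating
  the minority of true DEGs mixed into the dense cloud at ordinary
  expression levels.

Defaults — 10000 genes, 100 DEGs, 10+10 samples, `baseline_mean = 7`,
`baseline_sd = 1.5`, `noise_sd = 0.3`, `deg_level_shift = 1.5`,
`effect_min = 1`, `effect_max = 3` — were chosen once as a plausible
normalised two-group log2 microarray: baselines spanning roughly 2–12 log2
units, replicate noise well under the biological effect, and effects from
the conventional 2-fold cutoff up to 8-fold. Under these defaults the mean
`AD` of non-DEGs is ≈ `noise_sd·sqrt(2/π)·sqrt(1/n_a + 1/n_b)` ≈ 0.1,
versus ≥ 1 for DEGs.

What the generator does *not* emulate: probe-level effects, array/batch
structure, intensity-dependent variance (no mean–variance trend),
correlated genes, and any normalisation artefacts. Consequently the
separation between DEGs and the core is cleaner than in real data — at the
full 10+10 design all four rankers saturate and pruning can only tie them,
which is why the interesting comparisons (and the stochastic properties in
the test suite) lean on the 2×2 subsampled regime where the t statistic
genuinely struggles. Passing tests demonstrate the mechanism — pruning
enriches boundary-placed truth and never demotes surviving genes — not
performance on any particular real dataset.

## Numerical and degenerate-input policy

- Distances are compared as squared quantities (`dx² + dy² < r0²`), and the
  sweep implementation (sort by `AG`, window of width `r0`) is bit-identical
  to the quadratic definition, which is retained in the tests as the oracle.
- Missing values are rejected at load, never imputed; duplicate gene IDs are
  allowed (probe sets) and treated as independent rows; duplicate sample IDs
  are an error.
- Inputs are required pre-normalised; only a floored log transform is
  offered, since any particular normalisation choice would be invented here.
- Ties everywhere break stably by input row order; reruns with identical
  inputs and seeds are byte-identical (the benchmark report is serialised
  with fixed 6-significant-digit floats for diffability).

## Problem sizes

The shipped tests run the full pipeline at 10000 genes × 20 samples over 10
seeds (pruning, all rankers, partial AUC, 2×2 subsamples), exact
brute-force cross-checks at up to 1000 points × 50 seeds, and exhaustive
radius-scan optimality checks at up to 200 points — sizes at which the
quadratic oracles remain exact and fast while the production path is the
same code that handles 20000-gene arrays.

## Limitations

- Two conditions only; no multi-group extension.
- The pruning is a pre-filter, not an inference procedure: no p-values, no
  FDR control, and the candidate-list size is a user choice.
- `r0`/`n0` have no theoretical optimum; the `target_k` bisection is the
  practical dial. A parameter-free variant (e.g. Pareto-boundary selection)
  is out of scope.
- Truth-set evaluation assumes every truth ID is present in the matrix;
  unknown IDs are an error rather than being silently dropped.
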