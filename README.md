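# degprune

Density-based pre-filtering and ranking of differentially expressed genes
(DEGs) for two-condition expression matrices.

## The problem

Classical DEG rankers — fold change (FC), the two-sample t statistic, rank
product (RP) and weighted average difference (WAD) — each carry a
characteristic bias: FC rewards noisy low-expression genes, the t statistic
is misled by genes with accidentally tiny variances, and both ignore overall
expression level. Yet experimentally verified DEGs (e.g. by RT-PCR) tend to
be highly expressed *and* to sit sparsely at the boundary of the gene cloud
in the plane spanned by

- **AG**, the average expression level: `AG_i = (X̄_i^A + X̄_i^B) / 2`, and
- **AD**, the average difference: `AD_i = |X̄_i^A − X̄_i^B|`,

where `X̄_i^A`, `X̄_i^B` are a gene's mean log expression under the two
conditions (on log data, AD is the absolute log fold change — the MA-plot
geometry).

**DB pruning** exploits this: count, for every gene, its neighbours within a
fixed Euclidean radius `R0` in (AG, AD) space (strictly closer than `R0`,
self excluded), and prune every gene with `n_i ≥ N0` neighbours. The dense
core of equally expressed genes disappears; the sparse boundary — where the
true DEGs live — survives as the candidate list. Because the survivor count
is a non-increasing step function of `R0`, a bisection finds the radius that
yields any desired candidate-list size `K`. Ranking the survivors first
("append" mode) can only improve the rank of every surviving true DEG, which
lifts the partial AUC and top-K hit counts of all four rankers — most
dramatically for the t statistic on 2×2 designs.

This package is intended for anyone benchmarking or applying simple, robust
DEG rankers on small two-group expression studies (bulk microarray or
similar log-scale matrices), and ships a seeded synthetic-data generator so
the whole pipeline is testable without any external downloads.

## Worked example

A 5000-gene simulated study with 60 true DEGs, reduced to a noisy 2-vs-2
design, pruned to a 1000-gene candidate list:

```r
library(degprune)

sim   <- simulate_deg_matrix(n_genes = 5000, n_deg = 60, n_a = 3, n_b = 3, seed = 42)
small <- subsample_columns(sim$matrix, 2, 2, seed = 42)

feats  <- compute_features(small)
pruned <- prune_genes(feats, n0 = 4, target_k = 1000)
glance(pruned)
#>       r0    n0 n_genes n_kept n_pruned prop_pruned
#> 1 0.0454     4    5000   1000     4000         0.8

bm <- run_benchmark(small, sim$truth, n0 = 4, target_k = 1000,
                    k_max = 1000, ks = c(150L, 550L))
tidy(bm)
#>   method pruned partial_auc top_150 top_550
#> 1 fc     FALSE        0.187      59      59
#> 2 fc     TRUE         0.188      59      59
#> 3 rp     FALSE        0.187      59      59
#> 4 rp     TRUE         0.188      59      60
#> 5 ttest  FALSE        0.166      42      58
#> 6 ttest  TRUE         0.178      50      59
#> 7 wad    FALSE        0.189      58      60
#> 8 wad    TRUE         0.189      58      60
```

Reading the numbers: the bisection found `r0 ≈ 0.045` log2 units, pruning
80% of the genes while keeping all 60 true DEGs (`glance(bm)` reports a
5-fold truth enrichment, 0.012 → 0.06). With only 2 samples per condition
the t statistic finds 42 true DEGs in its top 150; pruning lifts that to 50
and raises its partial AUC from 0.166 to 0.178. WAD, which already uses the
same (AG, AD) information, barely moves — the expected pattern.

`autoplot(pruned)` shows the kept/pruned split in the (AG, AD) plane;
`plot_confusion_space()` colours TP/FP/FN/TN at a chosen top-K cutoff.

A thin command-line interface over the same functions ships at
`inst/cli/degprune.R` with `simulate`, `prune`, `rank`, `evaluate` and
`benchmark` subcommands; run any of them with `--help`.

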