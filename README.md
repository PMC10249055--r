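# psweep — parameter-space sampling, derivation and exploration for computer models

Most computational models — clustering algorithms, differential-expression
callers, neural networks — expose a handful of control parameters, and
finding "right" values by manual trial and error is tedious and gives no
global picture of how the model behaves. `psweep` is a headless framework
for *parameter-space analysis*: it runs a model many times over randomly
sampled parameter combinations, condenses each run's raw output into
scalar summaries, and provides the analytics to explore the collection of
runs as a whole.

The workflow has three stages:

1. **Sampling.** A model is wrapped as an *app*: a manifest declaring its
   parameters (kind, default, bounds or items) plus a run function. A
   *sampling spec* assigns each parameter either a constant or a uniform
   sampling directive (closed interval `[lo, hi]` for numeric parameters,
   an enabled subset for boolean/categorical ones). `run_session()` draws
   `n` combinations and persists everything in a plain-text session layout
   — `input.txt`, `paramInfo.txt`, `runsInfo.txt`, `runs/<Table>_<id>.txt`,
   `images/<id>.png` — that external tools can also produce or consume.
   Draw *i* is a pure function of `(seed, i)`, so sessions can be stopped
   at any time and resumed without corrupting or changing the stream.
2. **Derivation.** Derivation passes append per-run summary columns to the
   runs table: numeric aggregates (`mean_A1`), class-label statistics
   (`Num(cluster_ids)`, `n(A2 = x)`), confusion counts against a
   ground-truth column (`n(isDE = TRUE & GT_DE = TRUE)` and the other five
   cells of a boolean prediction crossed with a `{TRUE, FALSE, NA}` truth),
   2-D embeddings of run outputs (PCA/MDS/t-SNE), or the first row of a
   table the model itself uses to self-report custom metrics.
3. **Exploration.** Composable interval/subset filters, histogram
   summaries, min–max-normalized mean quality aggregation, Pareto-frontier
   extraction (a run is kept iff no other run is at least as good on every
   axis and strictly better on one — for an ROC analysis, minimize false
   positives while maximizing true positives), and a static report
   (plots + tables + HTML index) in place of an interactive GUI.

Three fully seeded demo studies ship with the package, each with its own
synthetic data generator so nothing is downloaded:

* **Clustering** (`clustering_demo_app()`): k-means, spectral,
  hierarchical and DBSCAN over a 403 × 67 binary feature table
  (`generate_paintings_like()`), each run self-reporting five internal
  validity indices (Calinski–Harabasz, silhouette, Davies–Bouldin, gap
  statistic, S_Dbw).
* **Differential expression** (`de_demo_app()`): a transparent NB
  log-ratio caller (normalization, dispersion mode, CPM cutoff, p-value
  adjustment, FDR threshold) benchmarked on a SEQC-style spike-in count
  table (`generate_seqc_like()`): 21,716 genes × 10 samples with 92
  spike-ins of known ratio — 23 null (ratio 1) and 69 differentially
  expressed (ratios 0.5, 0.67, 2).
* **Neural network** (`mlp_demo_app()`): a small fully connected
  classifier over the four classic 2-D playground datasets
  (`generate_playground_dataset()`: gauss, circle, xor, spiral; 200
  points, balanced labels), sweeping depth, width, feature toggles,
  learning rate, activation and regularization, with one runs-table
  record per checkpoint epoch.

## Worked example: ROC analysis of the DE caller

```r
library(psweep)

counts <- generate_seqc_like(seed = 1, config = list(n_genes = 2000))
app  <- de_demo_app()
spec <- full_sampling_spec(app$manifest, n_runs = 100, seed = 1,
                           out_dir = "de_sweep", except = character())
rd <- run_session(app, counts, spec)
rd <- apply_passes(rd, derivation_pass("gt_comparison", "de_calls",
                                       columns = "isDE",
                                       gt_column = "GT_DE"))

front <- pareto_front(rd$runs_info,
  c("n(isDE = TRUE & GT_DE = FALSE)" = "minimize",
    "n(isDE = TRUE & GT_DE = TRUE)"  = "maximize"))
```

The derivation pass appends six count columns; with 69 true-DE and 23
null spike-ins, the true-positive / false-positive counts of the 12
Pareto-optimal runs trace the achievable sensitivity–specificity
trade-off:

```
 run_id p_adjust fdr_thr TP FP
     74       BH   0.198 28  0
     80       BH   0.292 35  1
     39     none   0.037 41  2
     79     none   0.173 55  3
     21     none   0.191 61  4
     88       BH   0.769 62  5
      5     none   0.347 65  6
      3       BH   0.903 66 11
     11       BH   0.911 66 11
     54     none   0.757 67 15
     65     none   0.920 68 18
     87     none   0.994 69 22
```

Run 80, for instance, calls 35 of the 69 true-DE spike-ins with a single
false positive; `roc_rates(tp = 35, fp = 1, 69, 23)` converts that to a
TPR of 51% at an FPR of 4%. Moving down the front, higher FDR thresholds
buy sensitivity at the cost of specificity. `export_report()` renders the
corresponding ROC scatter, histograms and Pareto table to a report
directory.

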