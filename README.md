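# spreadsel

Identifying **influential epidemic spreaders** in complex networks by
combining Monte-Carlo SIR simulation with supervised selection over
structural centralities.

## What problem does this solve, and for whom?

For epidemiologists and network scientists who need to know *which
nodes of a contact network would seed the largest outbreaks*. The
influence of node $i$ is its mean final outbreak fraction
$\langle\rho_i^\lambda\rangle$ under discrete-time SIR dynamics
(infection probability $\beta$ per contact per step, recovery
probability $\mu$, effective rate $\lambda = \beta/\mu$); the top
fraction $f$ of nodes by that score are the influential spreaders
($Y_i = +1$), the rest are not ($Y_i = -1$). Predicting these labels
from structural centralities turns spreader identification into an
imbalanced classification problem — and the interesting question
becomes *which minimal combination of centralities suffices*, since
many centralities are collinear and the path-based ones are expensive
on large graphs.

`spreadsel` provides the full pipeline:

* **Networks** — Barabási–Albert, Erdős–Rényi and Watts–Strogatz
  generators with exact edge-count identities, plus a plain-text
  edge-list reader/writer (`generate_ba()`, `generate_er()`,
  `generate_ws()`, `read_edgelist()`).
* **Features** — nine per-node centralities: degree $K$, one-hop and
  two-hop neighbourhood degree sums $K_{sum}$ / $K_{2sum}$, k-shell
  $KS$, clustering coefficient $C$, betweenness $B$, closeness $CC$,
  eigenvector centrality $EC$, PageRank $PR$
  (`compute_feature_table()`).
* **Dynamics** — synchronous SIR simulation, epidemic-threshold
  estimation via the variability measure
  $\Delta = \sqrt{\langle\rho^2\rangle - \langle\rho\rangle^2}\,/\,\langle\rho\rangle$
  (which peaks at $\lambda_c$), per-node influence scores and top-$f$
  labelling (`simulate_sir_once()`, `estimate_threshold()`,
  `influence_labels()`).
* **Two-phase feature selection** — phase 1 balances the data by
  undersampling and votes features across $k$ SVM-RFE-CV replicates
  into $F^*$; phase 2 clusters $F^*$ by absolute Pearson correlation
  into two groups and picks per cluster a ReliefF-best main feature
  (plus a minimally correlated supplementary feature for clusters
  larger than $\gamma = \lfloor|F^*|/2\rfloor$), yielding $F^{**}$
  (`two_phase_select()`).
* **Evaluation** — stratified 70/30 splits, class-weighted linear-SVM
  evaluation reporting Precision, Recall and F1, panels of 13 contrast
  methods and 2 phase ablations, and modal-subset aggregation across
  repeats and networks (`run_contrast()`, `run_ablation()`,
  `run_experiment()`).

The methods vignette (`vignettes/influential-spreaders.Rmd`) documents
the model, the defaults and every numerical tie-break.

## Worked example

Score a 300-node scale-free network at its estimated epidemic
threshold, label the top 15% of spreaders, and select centralities:

```r
library(spreadsel)

g <- generate_ba(300, 3, seed = 11)
scan <- estimate_threshold(g, master_seed = 11)
scan$lambda_c
#> [1] 0.10625

ds <- build_spreading_dataset(g, scan$lambda_c, f = 0.15,
                              runs = 500, master_seed = 11)
ds$features
#> [1] "K"     "Ksum"  "K2sum" "C"     "B"     "CC"    "EC"    "PR"

set.seed(11)
sp <- split_dataset(ds$x, ds$y, 0.7)
sel <- two_phase_select(sp$train$x, sp$train$y)
sel$f_double_star
#> [1] "Ksum"  "K2sum"

evaluate_subset(sp$train, sp$test, sel$f_double_star)[, 1:3]
#>   precision recall        f1
#> 1     0.875      1 0.9333333
```

The threshold scan finds $\lambda_c \approx 0.106$ for this instance
(the k-shell column is constant on this graph and is dropped, leaving
eight features). The two-phase selection reduces eight centralities to
the neighbourhood pair $\{K_{sum}, K_{2sum}\}$, which recovers every
held-out influential spreader (recall 1) with precision 0.875 —
two cheap local centralities in place of the full set.

A command-line front end over the same functions lives at
`inst/cli/spreadsel.R` (subcommands `generate`, `features`,
`threshold`, `label`, `select`, `evaluate`, `experiment`).

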