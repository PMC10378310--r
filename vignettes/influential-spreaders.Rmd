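---
title: "Identifying influential epidemic spreaders by two-phase centrality selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying influential epidemic spreaders by two-phase centrality selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In network epidemiology the influence of a node is the expected size of
the outbreak it seeds. Ranking nodes by a single structural centrality
(degree, betweenness, closeness, ...) captures only one facet of that
influence, while feeding *all* common centralities into a classifier is
wasteful: several of them are strongly collinear, and the path-based ones
cost $O(|V|^3)$ on large graphs. `spreadsel` implements a supervised
pipeline that (i) labels nodes as influential or not from Monte-Carlo
SIR simulations and (ii) selects a minimal, well-performing combination
of centralities with a two-phase feature-selection method designed for
the strongly imbalanced labels that a top-$f$ definition of "influential"
produces.

## Labels from SIR dynamics

The epidemic model is discrete-time SIR on a static undirected graph.
At each step every infectious node independently infects each
susceptible neighbour with probability $\beta$, then recovers with
probability $\mu$ (default $\mu = 1$, i.e. exactly one infectious step);
the effective infection rate is $\lambda = \beta/\mu$. A run started
from seed node $i$ ends in finite time with an outbreak fraction
$\rho \in [1/N, 1]$, and the influence score of $i$ is the mean
$\langle\rho_i^\lambda\rangle$ over `runs` repetitions
(`influence_scores()`). Updates are synchronous with
infect-before-recover ordering within a step. Each node draws from its
own RNG substream derived from the master seed and the node index, so
scores are reproducible and independent of evaluation order.

Interesting dynamics happen near the epidemic threshold $\lambda_c$.
`estimate_threshold()` estimates it as the maximiser over a $\lambda$
grid of the variability
$$\Delta = \frac{\sqrt{\langle\rho^2\rangle - \langle\rho\rangle^2}}{\langle\rho\rangle},$$
the relative standard deviation of outbreak sizes from uniformly random
seeds, which peaks at criticality. The default grid is 40 evenly spaced
points in $(0, 0.25]$ with 300 runs per point; both are configurable,
and grid ties resolve to the smaller rate. On a 1000-node
preferential-attachment graph with mean degree 6 the estimate lands
within a factor of two of the degree-based mean-field value
$\langle k\rangle / (\langle k^2\rangle - \langle k\rangle)$ (asserted
in the test suite).

Nodes are then sorted by score and the top fraction $f$ labelled
$Y_i = +1$ ("influential"), the rest $-1$ (`label_top_f()`; half-up
rounding of $fN$, ties broken by degree then node index so the labels
are deterministic). Small $f$ makes the classification problem strongly
imbalanced, which is the regime the selection method targets.

## The feature table

`compute_feature_table()` returns nine per-node centralities: degree
$K$; the one-hop neighbourhood sum
$K_{sum}(i) = \sum_{j \in \Omega_1(i)} K(j)$; the two-hop neighbourhood
sum $K_{2sum}(i) = \sum_{j \in \Omega_2(i)} K(j)$ where $\Omega_2(i)$
is read as *all nodes within two hops* (a switch selects the
exactly-distance-2 variant); the k-shell index $KS$; the local
clustering coefficient $C$; unnormalised betweenness $B$ (endpoints
excluded); closeness $CC = (N-1)/\sum_j d_{ij}$; eigenvector centrality
$EC$ scaled to unit Euclidean norm; and PageRank $PR$ with damping
$\alpha = 0.85$ and teleport constant $(1-\alpha)/N$. Betweenness is
left unnormalised deliberately — the selection pipeline standardises
features per training split, so only relative order matters. Columns
whose variance falls below `constancy_tol` ($10^{-12}$) are dropped and
recorded: on preferential-attachment graphs built from $m$ isolated
seeds the k-shell index degenerates to the constant $m$, which is why
the working feature set there typically has eight columns. Standard
centralities are computed through `igraph`; the neighbourhood sums and
the table assembly are the package's own.

## Phase 1 — ensemble vote on balanced replicates (initial selection)

Undersampling deals with imbalance: `balance_by_undersampling()` keeps
every minority (influential) row and samples majority rows without
replacement down to the minority count. Sampling *with* replacement is
available behind a flag, but duplicated support vectors distort
maximum-margin fits, so it is off by default.

On each of $k = 10$ balanced replicates, `svm_rfe_cv()` runs recursive
feature elimination with a linear SVM ($C = 1$) under stratified
10-fold cross-validation: per fold the features are standardised on the
training folds only (weight-magnitude rankings are meaningless across
scales, and fitting the scaler on all data would leak), a linear SVM is
fitted, and each feature's importance accumulates the absolute primal
weight $|w_j|$; the mean validation F1 of the positive class scores the
current subset size; the least-important feature is removed (ties drop
the higher column index) and the loop repeats to exhaustion. The best
subset is the surviving set at the size with maximal cross-validated
F1, preferring the smaller size on ties. Exact duplicates of a column
receive *exactly* equal weights (their dual expansions coincide), so
the tie rule removes the duplicate before the original — a property the
tests exploit.

`ensemble_vote()` counts, for each feature, the fraction of the $k$
best subsets containing it and keeps features with frequency strictly
above $\varepsilon = 0.5$ as $F^*$; if nothing clears the threshold the
maximum-frequency features are kept. Neither $k$, $\varepsilon$, $C$
nor the CV metric is canonical; all are exposed as arguments with these
defaults.

## Phase 2 — representative features per correlation cluster (secondary selection)

Phase 1 cannot remove redundancy: strongly collinear survivors (degree
and PageRank, the two neighbourhood sums) carry the same information.
Phase 2 clusters $F^*$ by the absolute Pearson correlation $|r_{ij}|$ —
agglomerative merging of the most-correlated clusters, i.e. single
linkage on the distance $1 - |r|$, cut at two clusters (the working
assumption that features split into a local and a global group).
Exactly tied dissimilarities follow `stats::hclust`'s deterministic
merge order.

Within each cluster the *main* feature is the one with the largest
ReliefF weight, computed on the raw (unbalanced) training split —
phase 2 is a filter and does no resampling; ReliefF is implemented
in-package (deterministic full pass, $k = 10$ nearest hits and misses
per class on standardised features, prior-weighted miss term,
range-normalised differences). With $\gamma = \lfloor |F^*|/2 \rfloor$,
a cluster larger than $\gamma$ (strictly) also contributes a
*supplementary* feature: the member with minimal $|r|$ to the main
feature. The union is the final subset $F^{**}$; ties fall back to the
phase-1 vote frequency and then to the canonical column order `K, Ksum,
K2sum, KS, C, B, CC, EC, PR`. When $|F^*| \le 2$ the phase is vacuous
(two clusters of at most one feature each) and $F^{**} = F^*$. The
floor in $\gamma$ makes a $\{2,2\}$ clustering of four survivors yield
two main features only, so the pipeline can terminate in subsets as
small as one or two features.

## Evaluation harness

`split_dataset()` splits 70/30 *stratified by class* — plain random
splitting can lose every positive from the test set at $f = 5\%$,
leaving precision and recall undefined. The final classifier
(`evaluate_subset()`) is a linear SVM with class weights inversely
proportional to the training class frequencies (switchable to
unweighted); it reports Precision, Recall and
$F1 = 2/(\mathrm{P}^{-1} + \mathrm{R}^{-1})$, with zero-denominator
ratios reported as 0.

`run_contrast()` evaluates, on one split: each single centrality, the
full set (`All`), SVM-RFE-CV on the raw imbalanced training split
(`Imbalanced`), `FFS-ReliefF` and `FFS-Weight` (top-$|F^{**}|$ members
of $F^*$ by ReliefF weight resp. vote frequency — both capped at the
two-phase subset size so the comparison is at equal dimensionality),
and the two-phase method itself. `run_ablation()` evaluates each phase
alone; the secondary phase on the full feature set uses
$\gamma = \lfloor d/2 \rfloor$ and therefore always returns two to
four features. `aggregate_mode()` picks the most frequent subset over
repeats (ties: smaller subset, then canonical order), and the same vote
across networks gives a per-model subset.

`run_experiment()` orchestrates all of this. Its default configuration
is the reduced-scale profile — 300-node networks, 5 networks per model,
10 split repeats, 200 SIR runs per node, mean degree 6, Watts–Strogatz
rewiring probability 0.2, $\lambda \in \{0.5, 1, 1.5\}\,\lambda_c$ and
$f \in \{5, 10, 15, 20\}\%$ — chosen so a full run is tractable on a
single CPU; `experiment_config_full()` switches to the full-scale
profile (1000 nodes, 10 networks, 30 repeats, 1000 runs per node).

## Synthetic generators: what they emulate and what they do not

`generate_ba()` grows a preferential-attachment graph from $m$ isolated
seed vertices, each arrival attaching $m$ degree-proportional edges, so
the edge count is exactly $m(n-m)$ — 2991 edges and density 0.005988 at
$n = 1000$, $m = 3$ — and the graph is connected by construction.
`generate_er()` joins pairs with $p = \langle k\rangle/(n-1)$ and
returns the largest connected component re-indexed (at
$\langle k\rangle = 6$ it covers essentially all vertices; SIR scores
and closeness need connectedness), recording the realised size in the
graph name. `generate_ws()` rewires a ring lattice edge-by-edge,
conserving the edge count $nk/2$ exactly and resampling with an
incremented seed in the rare event of disconnection. These three models
span heterogeneous (scale-free) and homogeneous degree structure, which
is what drives the method's behaviour; they do not emulate degree
assortativity, community structure, weights, directionality or temporal
evolution of real contact networks, so conclusions from passing tests
transfer to real data only to the extent that degree structure is the
dominant factor. Real networks enter through `read_edgelist()`
(whitespace-separated pairs, `#` comments, duplicate and self-loop rows
dropped with a warning, original labels retained).

## Numerical choices and degenerate inputs

* Variability written as the relative standard deviation (population
  moments); constant samples give $\Delta = 0$, zero-mean samples are
  an error.
* Threshold-scan ties resolve to the smaller $\lambda$; labelling ties
  resolve by degree then node index; RFE importance ties drop the
  higher column index; subset-vote ties prefer smaller subsets then
  canonical order.
* Features constant inside a CV fold standardise to zero columns and
  simply receive zero weight; a class smaller than the fold count
  reduces the fold count; a minority class below two instances is a
  hard error (the undersampling ensemble cannot work there — the same
  failure mode occurs on small real networks at $f = 5\%$).
* `round(fN)` uses half-up rounding so the positive count matches the
  printed $f$ percentages exactly.

## Scale of the shipped checks

The test suite and the acceptance script run the pipeline at reduced
scale — 300-node networks, 200–1000 SIR runs per node, 20-seed property
checks — which the package treats as its default study profile; the
full-scale profile is one configuration call away. The property checks
(planted-feature recovery with duplicate exclusion, combinations
beating the best single centrality at the epidemic threshold,
exact-enumeration agreement of the SIR core on tiny graphs) are
statements about these synthetic conditions, not about any particular
real network.

## Known limitations

Only topological features are considered; non-topological attributes
(age, behaviour) are out of scope. The SIR model is the only dynamic
implemented — no exposed compartment, no continuous-time dynamics.
Betweenness and closeness are computed exactly, which becomes expensive
beyond $10^4$–$10^5$ edges. The two-cluster assumption in phase 2 is a
fixed design choice; more clusters would require revisiting the
$\gamma$ rule.
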