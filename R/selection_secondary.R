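# Phase 2 of the two-phase selection (SFS): correlation clustering of F*,
# ReliefF main features, minimum-correlation supplementary features.

#' Pearson correlation matrix of a feature set
#'
#' @param x Feature matrix (rows = instances); at least two rows, no
#'   constant column (constant features must be dropped upstream).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows")
  sds <- apply(x, 2L, sd)
  if (any(sds < 1e-12)) {
    stop("constant feature(s): ",
         paste(colnames(x)[sds < 1e-12], collapse = ", "))
  }
  r <- cor(x)
  diag(r) <- 1
  r
}

#' Cluster features by absolute correlation
#'
#' Agglomerative merging where cluster similarity is the largest absolute
#' correlation across the two clusters (single linkage on the distance
#' `1 - |r|`), cut at `n_clusters` groups.  With fewer features than
#' clusters the identity clustering is returned with `degenerate = TRUE`.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @param n_clusters Number of final clusters (2 by default: a local and a
#'   global structural group is the working assumption).
#' @return A list of class `feature_clustering`: named integer
#'   `assignments`, the `merges` and `heights` of the dendrogram, and
#'   `degenerate`.
#' @export
cluster_features <- function(corr, n_clusters = 2) {
  feats <- colnames(corr)
  d <- length(feats)
  if (d < n_clusters) {
    return(structure(
      list(assignments = stats::setNames(seq_len(d), feats),
           merges = NULL, heights = NULL, degenerate = TRUE),
      class = "feature_clustering"
    ))
  }
  h <- hclust(as.dist(1 - abs(corr)), method = "single")
  structure(
    list(assignments = cutree(h, k = n_clusters),
         merges = h$merge, heights = h$height, degenerate = FALSE),
    class = "feature_clustering"
  )
}

#' ReliefF feature weights
#'
#' Deterministic full-pass ReliefF on standardised features: for every
#' instance, finds its `k` nearest same-class hits and `k` nearest
#' other-class misses (Euclidean distance over all supplied features) and
#' accumulates, per feature, the mean range-normalised miss difference
#' (weighted by class priors) minus the mean hit difference.  Features
#' that separate the classes receive large positive weights; noise
#' features concentrate near zero.
#'
#' @param x Feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param features Columns to weight (default all).
#' @param k_neighbors Neighbours per class; reduced (with a warning) for
#'   classes with too few members.
#' @return Named numeric vector of weights.
#' @export
relieff_weights <- function(x, y, features = colnames(x),
                            k_neighbors = 10) {
  x <- as.matrix(x)[, features, drop = FALSE]
  y <- as.integer(as.character(as_pm1_factor(y)))
  if (k_neighbors < 1) stop("`k_neighbors` must be >= 1")
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(x, ctr, scl)
  rng <- apply(xs, 2L, function(col) diff(range(col)))
  rng[rng < 1e-12] <- 1

  classes <- sort(unique(y))
  prior <- table(factor(y, levels = classes)) / n
  counts <- table(factor(y, levels = classes))
  if (any(counts - 1 < k_neighbors)) {
    warning("k_neighbors reduced for class(es) with too few members")
  }
  dd <- as.matrix(dist(xs))
  diag(dd) <- Inf

  w <- stats::setNames(numeric(ncol(xs)), colnames(xs))
  for (i in seq_len(n)) {
    ci <- y[i]
    for (cl in classes) {
      members <- which(y == cl & seq_len(n) != i)
      k_use <- min(k_neighbors, length(members))
      if (k_use < 1L) next
      nb <- members[order(dd[i, members])[seq_len(k_use)]]
      diffs <- abs(sweep(xs[nb, , drop = FALSE], 2L, xs[i, ])) # |x_i - x_nb|
      mean_diff <- colMeans(sweep(diffs, 2L, rng, "/"))
      if (cl == ci) {
        w <- w - mean_diff
      } else {
        coef <- as.numeric(prior[as.character(cl)]) /
          (1 - as.numeric(prior[as.character(ci)]))
        w <- w + coef * mean_diff
      }
    }
  }
  w / n
}

#' Pick main and supplementary features per cluster
#'
#' For each cluster the main feature is the ReliefF-weight maximiser
#' (ties broken by larger phase-1 vote frequency, then canonical
#' centrality order).  If the cluster has more than `gamma` members, a
#' supplementary feature is added: the remaining member with minimal
#' absolute correlation to the main feature (same tie rules).  `gamma`
#' defaults to `floor(|F*| / 2)`.
#'
#' @param clusters A `feature_clustering` over `f_star`.
#' @param weights Named ReliefF weights covering `f_star`.
#' @param corr Correlation matrix over `f_star`.
#' @param f_star Phase-1 feature subset.
#' @param frequency Optional named phase-1 vote frequencies (tie-break).
#' @param gamma Optional integer cluster-size cutoff.
#' @return A list of class `final_subset`: `main`, `supplementary`,
#'   `gamma`, `f_double_star` (canonically ordered union).
#' @export
select_final <- function(clusters, weights, corr, f_star,
                         frequency = NULL, gamma = NULL) {
  if (is.null(gamma)) gamma <- floor(length(f_star) / 2)
  assignments <- clusters$assignments
  if (!setequal(names(assignments), f_star)) {
    stop("clusters must partition `f_star`")
  }
  pick_tie <- function(cand) {
    if (length(cand) > 1L && !is.null(frequency)) {
      fr <- frequency[cand]
      cand <- cand[fr == max(fr)]
    }
    first_by_canonical(cand)
  }
  main <- character(0L)
  supplementary <- character(0L)
  for (cl in sort(unique(assignments))) {
    members <- names(assignments)[assignments == cl]
    if (!length(members)) stop("internal error: empty cluster")
    wm <- weights[members]
    m <- pick_tie(members[wm == max(wm)])
    main <- c(main, m)
    if (length(members) > gamma) {
      rest <- setdiff(members, m)
      if (length(rest)) {
        rr <- abs(corr[m, rest])
        supplementary <- c(supplementary,
                           pick_tie(rest[rr == min(rr)]))
      }
    }
  }
  structure(
    list(main = main, supplementary = supplementary, gamma = gamma,
         f_double_star = canonical_feature_order(
           unique(c(main, supplementary)))),
    class = "final_subset"
  )
}

#' Secondary (representative) feature selection
#'
#' Runs the clustering + ReliefF phase on a feature subset: Pearson
#' correlations, two-cluster agglomeration, ReliefF weighting on the raw
#' (unbalanced) data, then [select_final()].  With two or fewer input
#' features the phase is vacuous (two singleton clusters under the gamma
#' rule) and the input subset is returned unchanged.
#'
#' @param x Full feature matrix (the raw training split).
#' @param y Labels in `{-1, +1}`.
#' @param f_star Feature subset to refine.
#' @param k_neighbors ReliefF neighbours.
#' @param frequency Optional phase-1 vote frequencies for tie-breaking.
#' @param gamma Optional cluster-size cutoff (default
#'   `floor(|f_star| / 2)`).
#' @param n_clusters Number of feature clusters.
#' @return A list of class `secondary_selection`: `f_double_star`,
#'   `skipped`, and (when run) `corr`, `clustering`, `weights`, `final`.
#' @export
secondary_selection <- function(x, y, f_star, k_neighbors = 10,
                                frequency = NULL, gamma = NULL,
                                n_clusters = 2) {
  if (length(f_star) <= 2L) {
    return(structure(
      list(f_double_star = canonical_feature_order(f_star),
           skipped = TRUE),
      class = "secondary_selection"
    ))
  }
  xs <- as.matrix(x)[, f_star, drop = FALSE]
  corr <- pearson_matrix(xs)
  clustering <- cluster_features(corr, n_clusters = n_clusters)
  weights <- relieff_weights(xs, y, k_neighbors = k_neighbors)
  final <- select_final(clustering, weights, corr, f_star,
                        frequency = frequency, gamma = gamma)
  structure(
    list(f_double_star = final$f_double_star, skipped = FALSE,
         corr = corr, clustering = clustering, weights = weights,
         final = final),
    class = "secondary_selection"
  )
}

#' Two-phase feature selection (initial vote + representative refinement)
#'
#' Full composition: `k` undersampled balanced replicates, SVM-RFE-CV per
#' replicate, ensemble vote into `F*`, then correlation clustering with
#' ReliefF into the final subset `F**`.  All intermediate objects are
#' retained in the returned trace.
#'
#' @inheritParams initial_selection
#' @param k_neighbors ReliefF neighbours for the secondary phase.
#' @param seed Optional RNG seed for the whole procedure.
#' @return A list of class `selection_result`: `f_star`, `f_double_star`,
#'   `vote`, `initial`, `secondary`.
#' @export
two_phase_select <- function(x, y, k = 10, epsilon = 0.5, folds = 10,
                             cost = 1, k_neighbors = 10,
                             with_replacement = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  init <- initial_selection(x, y, k = k, epsilon = epsilon, folds = folds,
                            cost = cost,
                            with_replacement = with_replacement)
  sec <- secondary_selection(x, y, init$vote$f_star,
                             k_neighbors = k_neighbors,
                             frequency = init$vote$frequency)
  structure(
    list(f_star = init$vote$f_star, f_double_star = sec$f_double_star,
         vote = init$vote, initial = init, secondary = sec),
    class = "selection_result"
  )
}
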