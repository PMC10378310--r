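# Phase 1 of the two-phase selection (FFS): undersampled balanced
# replicates, SVM-RFE with cross-validated subset scoring, ensemble vote.

#' Balance a labelled dataset by undersampling the majority class
#'
#' Keeps every minority-class row and samples majority-class rows (without
#' replacement by default) down to the minority count; the output rows are
#' shuffled.  Repeated draws differ only in the majority rows.
#'
#' @param x Feature matrix or data frame, one row per instance.
#' @param y Labels in `{-1, +1}`.
#' @param with_replacement Sample the majority class with replacement
#'   (default `FALSE`; duplicated rows distort maximum-margin fits).
#' @return A list with balanced `x` and `y`.
#' @export
balance_by_undersampling <- function(x, y, with_replacement = FALSE) {
  x <- as.matrix(x)
  y <- as.integer(as.character(as_pm1_factor(y)))
  counts <- table(factor(y, levels = c(-1L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  minority <- if (counts[["-1"]] <= counts[["1"]]) -1L else 1L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  take <- sample(maj_idx, length(min_idx), replace = with_replacement)
  keep <- sample(c(min_idx, take))
  list(x = x[keep, , drop = FALSE], y = y[keep])
}

# Stratified fold assignment: shuffle within class, deal out fold ids.
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

# F1 of the positive class ("1"); 0 when precision or recall is undefined.
.f1_pos <- function(truth, pred) {
  tp <- sum(pred == "1" & truth == "1")
  fp <- sum(pred == "1" & truth == "-1")
  fn <- sum(pred == "-1" & truth == "1")
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 / (1 / p + 1 / r)
}

# Fit a linear SVM and return the primal weight vector (one per feature).
.linear_svm_weights <- function(fit) {
  as.numeric(crossprod(fit$coefs, fit$SV))
}

#' Recursive feature elimination with a cross-validated linear SVM
#'
#' Repeats until all features are eliminated: standardise features on the
#' training folds, fit a linear maximum-margin classifier per fold,
#' accumulate each feature's importance as the sum over folds of its
#' absolute weight, record the mean validation F1 of the current subset,
#' then remove the single least-important feature (ties remove the
#' higher-indexed column).  The best subset is the surviving set at the
#' size with maximal cross-validated F1; score ties prefer the smaller
#' subset.
#'
#' @param x Feature matrix with column names.
#' @param y Labels in `{-1, +1}`.
#' @param folds Cross-validation folds (reduced to the smaller class size
#'   when necessary; at least 2).
#' @param cost Regularisation constant of the linear SVM.
#' @return A list of class `rfe_trace`: `elimination_order` (first-removed
#'   first), `cv_scores` (mean validation F1 indexed by subset size), and
#'   `best_subset`.
#' @export
svm_rfe_cv <- function(x, y, folds = 10, cost = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  yf <- as_pm1_factor(y)
  min_class <- min(table(yf))
  if (min_class < 2L) {
    stop("insufficient sampling quantity: smallest class has < 2 instances")
  }
  folds <- min(folds, min_class)
  if (folds < 2L) stop("need at least 2 cross-validation folds")
  fold_id <- stratified_folds(as.integer(as.character(yf)), folds)

  surviving <- colnames(x)
  elimination <- character(0L)
  cv_scores <- rep(NA_real_, ncol(x))
  subsets_at_size <- vector("list", ncol(x))

  while (length(surviving) >= 1L) {
    d <- length(surviving)
    subsets_at_size[[d]] <- surviving
    importance <- stats::setNames(numeric(d), surviving)
    fold_f1 <- numeric(folds)
    for (fd in seq_len(folds)) {
      tr <- fold_id != fd
      xs <- x[tr, surviving, drop = FALSE]
      ctr <- colMeans(xs)
      scl <- apply(xs, 2L, sd)
      scl[scl < 1e-12] <- 1
      xtr <- scale(xs, ctr, scl)
      xva <- scale(x[!tr, surviving, drop = FALSE], ctr, scl)
      fit <- e1071::svm(xtr, yf[tr], kernel = "linear", cost = cost,
                        scale = FALSE)
      importance <- importance + abs(.linear_svm_weights(fit))
      fold_f1[fd] <- .f1_pos(yf[!tr], predict(fit, xva))
    }
    cv_scores[d] <- mean(fold_f1)
    if (d == 1L) {
      elimination <- c(elimination, surviving)
      break
    }
    worst <- which(importance == min(importance))
    drop <- surviving[max(worst)]
    elimination <- c(elimination, drop)
    surviving <- setdiff(surviving, drop)
  }

  best_size <- min(which(cv_scores == max(cv_scores, na.rm = TRUE)))
  structure(
    list(elimination_order = elimination,
         cv_scores = stats::setNames(cv_scores, seq_along(cv_scores)),
         best_subset = subsets_at_size[[best_size]]),
    class = "rfe_trace"
  )
}

#' Vote features across replicate RFE subsets
#'
#' Each feature's frequency is the fraction of the `k` best subsets
#' containing it; the initial selection `F*` keeps features whose
#' frequency strictly exceeds `epsilon`.  If no feature clears the
#' threshold, `F*` falls back to the maximum-frequency features (reported
#' in canonical centrality order).
#'
#' @param subsets List of `k` character vectors (the per-replicate best
#'   subsets).
#' @param epsilon Vote threshold in `[0, 1)`.
#' @param all_features Full feature name set (defines frequency-0 entries
#'   and ordering); defaults to the union of the subsets.
#' @return A list of class `vote_result`: `k`, `frequency`, `epsilon`,
#'   `f_star`.
#' @export
ensemble_vote <- function(subsets, epsilon = 0.5, all_features = NULL) {
  k <- length(subsets)
  if (k < 1L) stop("need at least one subset")
  if (epsilon < 0 || epsilon >= 1) stop("`epsilon` must be in [0, 1)")
  if (is.null(all_features)) {
    all_features <- canonical_feature_order(unique(unlist(subsets)))
  }
  frequency <- vapply(all_features, function(f) {
    mean(vapply(subsets, function(s) f %in% s, logical(1L)))
  }, numeric(1L))
  f_star <- all_features[frequency > epsilon]
  if (!length(f_star)) {
    f_star <- canonical_feature_order(
      all_features[frequency == max(frequency)]
    )
  }
  structure(
    list(k = k, frequency = frequency, epsilon = epsilon, f_star = f_star),
    class = "vote_result"
  )
}

#' Initial (ensemble) feature selection on imbalanced data
#'
#' Draws `k` balanced replicates by undersampling, runs [svm_rfe_cv()] on
#' each, and votes the per-replicate best subsets into `F*` via
#' [ensemble_vote()].  Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @inheritParams balance_by_undersampling
#' @param k Number of balanced replicates.
#' @param epsilon Vote threshold.
#' @param folds,cost Passed to [svm_rfe_cv()].
#' @return A list of class `initial_selection`: `vote` (a `vote_result`)
#'   and `traces` (the `k` `rfe_trace` objects).
#' @export
initial_selection <- function(x, y, k = 10, epsilon = 0.5, folds = 10,
                              cost = 1, with_replacement = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  traces <- vector("list", k)
  for (i in seq_len(k)) {
    bal <- balance_by_undersampling(x, y, with_replacement)
    traces[[i]] <- svm_rfe_cv(bal$x, bal$y, folds = folds, cost = cost)
  }
  vote <- ensemble_vote(lapply(traces, `[[`, "best_subset"),
                        epsilon = epsilon, all_features = colnames(x))
  structure(list(vote = vote, traces = traces),
            class = "initial_selection")
}
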