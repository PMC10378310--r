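# Evaluation harness: dataset assembly, splits, metrics, the contrast and
# ablation method panels, and modal-subset aggregation.

#' Assemble the spreading dataset for one network
#'
#' Computes the centrality feature table and the SIR-based labels for a
#' given effective infection rate and influential fraction.
#'
#' @param net A connected `igraph` graph.
#' @param lambda Effective infection rate used for labelling.
#' @param f Influential fraction.
#' @param runs SIR repetitions per seed vertex.
#' @param mu Recovery probability.
#' @param master_seed Integer seed for the SIR substreams.
#' @param cfg A [centrality_config()].
#' @return A list of class `labeled_dataset`: feature matrix `x`, labels
#'   `y` in `{-1, +1}`, `features`, `node_id`, `mean_rho`, and
#'   `provenance` (network name, `lambda`, `f`).
#' @export
build_spreading_dataset <- function(net, lambda, f, runs = 1000, mu = 1,
                                    master_seed = 1L,
                                    cfg = centrality_config()) {
  ft <- compute_feature_table(net, cfg)
  lab <- influence_labels(net, lambda, f, runs = runs, mu = mu,
                          master_seed = master_seed)
  structure(
    list(x = feature_matrix(ft), y = lab$scores$label,
         features = setdiff(names(ft), "node_id"),
         node_id = ft$node_id, mean_rho = lab$scores$mean_rho,
         dropped = attr(ft, "dropped"),
         provenance = list(network = igraph::graph_attr(net, "name"),
                           lambda = lambda, f = f)),
    class = "labeled_dataset"
  )
}

#' Stratified train/test split
#'
#' Splits instances into train and test parts preserving the class
#' proportions (each class sampled independently), so that even at a 5%
#' positive rate both parts retain positives.  Uses the current RNG
#' state.
#'
#' @param x Feature matrix.
#' @param y Labels in `{-1, +1}`; each class needs at least 2 members.
#' @param train_fraction Fraction assigned to the training part.
#' @return A list with `train` and `test`, each a list of `x` and `y`.
#' @export
split_dataset <- function(x, y, train_fraction = 0.7) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  x <- as.matrix(x)
  y <- as.integer(as.character(as_pm1_factor(y)))
  tr_idx <- integer(0L)
  for (cl in c(-1L, 1L)) {
    idx <- which(y == cl)
    if (length(idx) < 2L) stop("class ", cl, " has fewer than 2 members")
    n_tr <- floor(train_fraction * length(idx) + 0.5)
    if (n_tr < 1L || n_tr >= length(idx)) {
      stop("class ", cl, " too small to appear in both parts")
    }
    tr_idx <- c(tr_idx, sample(idx, n_tr))
  }
  te_idx <- setdiff(seq_along(y), tr_idx)
  list(
    train = list(x = x[tr_idx, , drop = FALSE], y = y[tr_idx]),
    test = list(x = x[te_idx, , drop = FALSE], y = y[te_idx])
  )
}

#' Precision, Recall and F1 from confusion counts
#'
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`,
#' `F1 = 2 / (Precision^-1 + Recall^-1)`; an undefined ratio (zero
#' denominator) is reported as 0 with a warning, and F1 is 0 whenever
#' either component is 0.
#'
#' @param tp,fp,fn,tn Non-negative integer confusion counts.
#' @return Named list with `precision`, `recall`, `f1`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn = 0) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  if (tp + fp == 0) {
    warning("no positive predictions; precision reported as 0")
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  if (tp + fn == 0) {
    warning("no positive instances; recall reported as 0")
    recall <- 0
  } else {
    recall <- tp / (tp + fn)
  }
  f1 <- if (precision == 0 || recall == 0) 0 else {
    2 / (1 / precision + 1 / recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Train on a feature subset and score the test split
#'
#' Standardises the subset columns on the training split, fits a linear
#' maximum-margin classifier (by default with class weights inversely
#' proportional to the class frequencies of the raw training split, so the
#' minority influential class is not swamped), predicts the test split and
#' returns confusion counts and metrics.
#'
#' @param train,test Lists with `x` and `y` as produced by
#'   [split_dataset()].
#' @param subset Non-empty character vector of feature names.
#' @param cost Regularisation constant.
#' @param class_weight Balance classes by inverse-frequency weights.
#' @return One-row `data.frame`: `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
evaluate_subset <- function(train, test, subset, cost = 1,
                            class_weight = TRUE) {
  if (!length(subset)) stop("`subset` must be non-empty")
  if (!all(subset %in% colnames(train$x))) {
    stop("unknown feature(s): ",
         paste(setdiff(subset, colnames(train$x)), collapse = ", "))
  }
  ytr <- as_pm1_factor(train$y)
  yte <- as_pm1_factor(test$y)
  if (length(unique(ytr)) < 2L) stop("single-class training split")
  xs <- train$x[, subset, drop = FALSE]
  ctr <- colMeans(xs)
  scl <- apply(xs, 2L, sd)
  scl[scl < 1e-12] <- 1
  xtr <- scale(xs, ctr, scl)
  xte <- scale(test$x[, subset, drop = FALSE], ctr, scl)
  cw <- NULL
  if (class_weight) {
    tab <- table(ytr)
    cw <- as.numeric(length(ytr) / (2 * tab))
    names(cw) <- names(tab)
  }
  fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                    scale = FALSE, class.weights = cw)
  pred <- predict(fit, xte)
  tp <- sum(pred == "1" & yte == "1")
  fp <- sum(pred == "1" & yte == "-1")
  fn <- sum(pred == "-1" & yte == "1")
  tn <- sum(pred == "-1" & yte == "-1")
  m <- suppressWarnings(confusion_metrics(tp, fp, fn, tn))
  data.frame(precision = m$precision, recall = m$recall, f1 = m$f1,
             tp = tp, fp = fp, fn = fn, tn = tn)
}

.method_row <- function(method, subset, train, test, cost, class_weight) {
  res <- evaluate_subset(train, test, subset, cost = cost,
                         class_weight = class_weight)
  cbind(data.frame(method = method,
                   subset = paste(subset, collapse = "+"),
                   size = length(subset),
                   stringsAsFactors = FALSE),
        res)
}

# Top-m features of f_star by a named score, ties resolved canonically.
.top_m <- function(score, f_star, m) {
  s <- score[f_star]
  ord <- canonical_feature_order(f_star)
  ord[order(-s[ord])][seq_len(min(m, length(ord)))]
}

#' Contrast panel: single centralities and selection baselines
#'
#' For one stratified split, evaluates every single centrality, the full
#' feature set (`All`), SVM-RFE-CV on the raw imbalanced training split
#' (`Imbalanced`), the two single-criterion phase-2 alternatives
#' `FFS-ReliefF` (top features of `F*` by ReliefF weight) and
#' `FFS-Weight` (top features of `F*` by vote frequency) -- both capped at
#' the size of the `FFS-SFS` subset -- and `FFS-SFS` itself.
#'
#' @param x Feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param train_fraction Training fraction for the stratified split.
#' @param seed RNG seed for this repeat (split, balancing, folds).
#' @param k,epsilon,folds,cost,k_neighbors Selection parameters; see
#'   [two_phase_select()].
#' @param class_weight Class-weight the evaluation classifier.
#' @return A `data.frame` with one row per method (`method`, `subset`,
#'   `size`, `precision`, `recall`, `f1`, confusion counts); the
#'   underlying `selection_result` is attached as attribute `selection`.
#' @export
run_contrast <- function(x, y, train_fraction = 0.7, seed = 1L, k = 10,
                         epsilon = 0.5, folds = 10, cost = 1,
                         k_neighbors = 10, class_weight = TRUE) {
  set.seed(seed)
  x <- as.matrix(x)
  sp <- split_dataset(x, y, train_fraction)
  sel <- two_phase_select(sp$train$x, sp$train$y, k = k,
                          epsilon = epsilon, folds = folds, cost = cost,
                          k_neighbors = k_neighbors)
  m <- length(sel$f_double_star)

  rows <- list()
  for (feat in colnames(x)) {
    rows[[length(rows) + 1L]] <-
      .method_row(feat, feat, sp$train, sp$test, cost, class_weight)
  }
  rows[[length(rows) + 1L]] <-
    .method_row("All", colnames(x), sp$train, sp$test, cost, class_weight)

  imb <- svm_rfe_cv(sp$train$x, sp$train$y, folds = folds, cost = cost)
  rows[[length(rows) + 1L]] <-
    .method_row("Imbalanced", imb$best_subset, sp$train, sp$test, cost,
                class_weight)

  rw <- relieff_weights(sp$train$x, sp$train$y, features = sel$f_star,
                        k_neighbors = k_neighbors)
  rows[[length(rows) + 1L]] <-
    .method_row("FFS-ReliefF", .top_m(rw, sel$f_star, m), sp$train,
                sp$test, cost, class_weight)
  rows[[length(rows) + 1L]] <-
    .method_row("FFS-Weight", .top_m(sel$vote$frequency, sel$f_star, m),
                sp$train, sp$test, cost, class_weight)
  rows[[length(rows) + 1L]] <-
    .method_row("FFS-SFS", sel$f_double_star, sp$train, sp$test, cost,
                class_weight)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selection") <- sel
  out
}

#' Ablation panel: each selection phase alone
#'
#' For one stratified split, evaluates `w/o SFS` (the phase-1 subset `F*`
#' as-is), `w/o FFS` (the clustering + ReliefF phase applied directly to
#' the full feature set with `gamma = floor(d / 2)`), and the full
#' `FFS-SFS`.
#'
#' @inheritParams run_contrast
#' @return A `data.frame` as in [run_contrast()] with attribute
#'   `selection`.
#' @export
run_ablation <- function(x, y, train_fraction = 0.7, seed = 1L, k = 10,
                         epsilon = 0.5, folds = 10, cost = 1,
                         k_neighbors = 10, class_weight = TRUE) {
  set.seed(seed)
  x <- as.matrix(x)
  sp <- split_dataset(x, y, train_fraction)
  sel <- two_phase_select(sp$train$x, sp$train$y, k = k,
                          epsilon = epsilon, folds = folds, cost = cost,
                          k_neighbors = k_neighbors)
  wo_ffs <- secondary_selection(sp$train$x, sp$train$y,
                                f_star = colnames(x),
                                k_neighbors = k_neighbors,
                                gamma = floor(ncol(x) / 2))
  rows <- list(
    .method_row("w/o SFS", sel$f_star, sp$train, sp$test, cost,
                class_weight),
    .method_row("w/o FFS", wo_ffs$f_double_star, sp$train, sp$test, cost,
                class_weight),
    .method_row("FFS-SFS", sel$f_double_star, sp$train, sp$test, cost,
                class_weight)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selection") <- sel
  out
}

.subset_key <- function(s) {
  paste(canonical_feature_order(s), collapse = "+")
}

# Lexicographic sort key in canonical centrality order.
.canonical_sort_key <- function(key) {
  vapply(strsplit(key, "\\+"), function(fs) {
    idx <- match(fs, CENTRALITY_ORDER)
    idx[is.na(idx)] <- length(CENTRALITY_ORDER) + 1L
    paste(sprintf("%02d%s", idx, fs), collapse = "|")
  }, character(1L))
}

#' Modal feature subset across repeats (and across networks)
#'
#' Returns the most frequent subset in a list of subsets; ties prefer the
#' smaller subset, then the lexicographically first in canonical
#' centrality order.  Applied once per network over its repeats, and
#' again over the per-network modal subsets to vote the subset of a
#' network model.
#'
#' @param subsets List of character vectors.
#' @return Character vector: the modal subset, canonically ordered.
#' @export
aggregate_mode <- function(subsets) {
  if (!length(subsets)) stop("need at least one subset")
  keys <- vapply(subsets, .subset_key, character(1L))
  tab <- table(keys)
  cand <- names(tab)[tab == max(tab)]
  sizes <- lengths(strsplit(cand, "\\+"))
  cand <- cand[sizes == min(sizes)]
  pick <- cand[order(.canonical_sort_key(cand))][1L]
  strsplit(pick, "\\+")[[1L]]
}

#' Experiment configuration
#'
#' Defaults follow the reduced-scale study profile (300-vertex networks,
#' 5 networks per model, 10 split repeats, 200 SIR runs per vertex) that
#' keeps a full run tractable on one CPU; [experiment_config_full()]
#' gives the full-scale profile (1000 vertices, 10 networks, 30 repeats,
#' 1000 runs).
#'
#' @param model Network model: `"BA"`, `"ER"` or `"WS"`.
#' @param n Vertices per network.
#' @param avg_degree Target mean degree (BA attaches
#'   `round(avg_degree / 2)` edges per arrival).
#' @param rewire_p WS rewiring probability.
#' @param n_networks Networks sampled per model.
#' @param lambda_multipliers Multiples of the estimated threshold
#'   `lambda_c` at which to label.
#' @param f_values Influential fractions.
#' @param repeats Stratified-split repeats per dataset.
#' @param sir_runs SIR repetitions per seed vertex.
#' @param threshold_grid,threshold_runs Grid and runs for
#'   [estimate_threshold()].
#' @param train_fraction Training fraction.
#' @param k,epsilon,folds,cost,k_neighbors Selection parameters.
#' @param master_seed Master RNG seed for the whole experiment.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(model = "BA", n = 300, avg_degree = 6,
                              rewire_p = 0.2, n_networks = 5,
                              lambda_multipliers = c(0.5, 1, 1.5),
                              f_values = c(0.05, 0.10, 0.15, 0.20),
                              repeats = 10, sir_runs = 200,
                              threshold_grid = seq(0.00625, 0.25,
                                                   length.out = 40),
                              threshold_runs = 300,
                              train_fraction = 0.7, k = 10,
                              epsilon = 0.5, folds = 10, cost = 1,
                              k_neighbors = 10, master_seed = 1L) {
  model <- match.arg(model, c("BA", "ER", "WS"))
  stopifnot(n > 10, avg_degree > 0, repeats >= 1, n_networks >= 1)
  structure(
    list(model = model, n = n, avg_degree = avg_degree,
         rewire_p = rewire_p, n_networks = n_networks,
         lambda_multipliers = lambda_multipliers, f_values = f_values,
         repeats = repeats, sir_runs = sir_runs,
         threshold_grid = threshold_grid, threshold_runs = threshold_runs,
         train_fraction = train_fraction, k = k, epsilon = epsilon,
         folds = folds, cost = cost, k_neighbors = k_neighbors,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @param ... Overrides passed to [experiment_config()].
#' @export
experiment_config_full <- function(...) {
  args <- list(n = 1000, n_networks = 10, repeats = 30, sir_runs = 1000)
  override <- list(...)
  args[names(override)] <- override
  do.call(experiment_config, args)
}

.generate_model_network <- function(cfg, seed) {
  switch(cfg$model,
         BA = generate_ba(cfg$n, max(1L, round(cfg$avg_degree / 2)), seed),
         ER = generate_er(cfg$n, cfg$avg_degree, seed),
         WS = generate_ws(cfg$n, 2L * round(cfg$avg_degree / 2),
                          cfg$rewire_p, seed))
}

#' Run the full selection experiment for one network model
#'
#' For each sampled network: estimates the epidemic threshold, labels
#' vertices at every `(lambda multiplier, f)` combination, repeats the
#' stratified split + two-phase selection + evaluation `repeats` times,
#' takes the per-network modal subset, and finally votes the modal
#' subsets across networks into a per-model subset for each
#' configuration.  Deterministic for a fixed `master_seed`.
#'
#' @param cfg An [experiment_config()].
#' @param panel `"selection"` evaluates FFS-SFS only (fastest);
#'   `"contrast"` and `"ablation"` run the corresponding full panels via
#'   [run_contrast()] / [run_ablation()].
#' @param verbose Emit per-stage progress on stderr.
#' @return A list of class `experiment_report`: `metrics` (per network,
#'   configuration, repeat and method), `modal` (per-network modal
#'   subsets), `voted` (per-model subsets), `lambda_c` per network, and
#'   the `config`.
#' @export
run_experiment <- function(cfg = experiment_config(),
                           panel = c("selection", "contrast", "ablation"),
                           verbose = TRUE) {
  panel <- match.arg(panel)
  say <- function(...) if (verbose) message(sprintf(...))
  metrics <- list()
  modal <- list()
  lambda_c <- numeric(cfg$n_networks)
  rep_counter <- 0L

  for (net_i in seq_len(cfg$n_networks)) {
    t0 <- Sys.time()
    g <- .generate_model_network(cfg, derive_seed(cfg$master_seed, net_i))
    scan <- estimate_threshold(g, cfg$threshold_grid, cfg$threshold_runs,
                               master_seed = derive_seed(cfg$master_seed,
                                                         net_i, 1L))
    lambda_c[net_i] <- scan$lambda_c
    say("network %d/%d: %s, lambda_c = %.4f (%.1fs)", net_i,
        cfg$n_networks, igraph::graph_attr(g, "name"), scan$lambda_c,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))

    for (lm in cfg$lambda_multipliers) {
      lambda <- min(lm * scan$lambda_c, 1)
      sc <- influence_scores(g, lambda, runs = cfg$sir_runs,
                             master_seed = derive_seed(cfg$master_seed,
                                                       net_i, 2L))
      ft <- compute_feature_table(g)
      x <- feature_matrix(ft)
      for (f in cfg$f_values) {
        y <- label_top_f(sc$mean_rho, f, degrees = igraph::degree(g))
        subsets <- list()
        for (r in seq_len(cfg$repeats)) {
          rep_counter <- rep_counter + 1L
          seed_r <- derive_seed(cfg$master_seed, rep_counter, 3L)
          res <- switch(panel,
            selection = {
              set.seed(seed_r)
              sp <- split_dataset(x, y, cfg$train_fraction)
              sel <- two_phase_select(sp$train$x, sp$train$y, k = cfg$k,
                                      epsilon = cfg$epsilon,
                                      folds = cfg$folds, cost = cfg$cost,
                                      k_neighbors = cfg$k_neighbors)
              out <- .method_row("FFS-SFS", sel$f_double_star, sp$train,
                                 sp$test, cfg$cost, TRUE)
              attr(out, "selection") <- sel
              out
            },
            contrast = run_contrast(x, y, cfg$train_fraction, seed_r,
                                    k = cfg$k, epsilon = cfg$epsilon,
                                    folds = cfg$folds, cost = cfg$cost,
                                    k_neighbors = cfg$k_neighbors),
            ablation = run_ablation(x, y, cfg$train_fraction, seed_r,
                                    k = cfg$k, epsilon = cfg$epsilon,
                                    folds = cfg$folds, cost = cfg$cost,
                                    k_neighbors = cfg$k_neighbors)
          )
          sel <- attr(res, "selection")
          subsets[[r]] <- sel$f_double_star
          res$network <- net_i
          res$lambda_mult <- lm
          res$lambda <- lambda
          res$f <- f
          res$repeat_id <- r
          metrics[[length(metrics) + 1L]] <- res
        }
        modal[[length(modal) + 1L]] <- data.frame(
          network = net_i, lambda_mult = lm, f = f,
          subset = .subset_key(aggregate_mode(subsets)),
          stringsAsFactors = FALSE
        )
        say("  lm=%.1f f=%.2f modal subset: %s", lm, f,
            modal[[length(modal)]]$subset)
      }
    }
  }

  metrics <- do.call(rbind, metrics)
  modal <- do.call(rbind, modal)
  voted <- do.call(rbind, lapply(
    split(modal, list(modal$lambda_mult, modal$f), drop = TRUE),
    function(d) {
      data.frame(
        lambda_mult = d$lambda_mult[1L], f = d$f[1L],
        subset = .subset_key(
          aggregate_mode(lapply(d$subset,
                                function(s) strsplit(s, "\\+")[[1L]]))),
        stringsAsFactors = FALSE
      )
    }
  ))
  rownames(voted) <- NULL
  structure(
    list(metrics = metrics, modal = modal, voted = voted,
         lambda_c = lambda_c, config = cfg),
    class = "experiment_report"
  )
}
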