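test_that("stratified splits preserve class proportions exactly", {
  set.seed(1)
  y <- c(rep(1L, 100), rep(-1L, 900))
  x <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  sp <- split_dataset(x, y, 0.7)
  expect_equal(sum(sp$train$y == 1), 70)
  expect_equal(sum(sp$train$y == -1), 630)
  expect_equal(sum(sp$test$y == 1), 30)
  expect_equal(sum(sp$test$y == -1), 270)
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x), 1000)

  y2 <- rep(c(1L, -1L), each = 10)
  x2 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  sp2 <- split_dataset(x2, y2, 0.5)
  expect_equal(as.vector(table(sp2$train$y)), c(5, 5))

  # different seeds: different partitions, identical class ratios
  set.seed(2); a <- split_dataset(x, y)
  set.seed(3); b <- split_dataset(x, y)
  expect_false(identical(a$train$x, b$train$x))
  expect_equal(table(a$train$y), table(b$train$y))
  expect_error(split_dataset(x2, rep(c(1L, -1L), c(1, 19)), 0.5), "class")
})

test_that("precision, recall and F1 follow their definitions", {
  m <- confusion_metrics(2, 0, 0, 5)
  expect_equal(unlist(m), c(precision = 1, recall = 1, f1 = 1))
  m2 <- confusion_metrics(1, 1, 3, 10)
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 0.25)
  expect_equal(m2$f1, 1 / 3)
  expect_warning(m3 <- confusion_metrics(0, 0, 3), "positive predictions")
  expect_equal(m3$f1, 0)
  expect_error(confusion_metrics(-1, 0, 0), "non-negative")

  # harmonic-mean identity on random counts
  set.seed(4)
  for (i in 1:20) {
    cnt <- sample(0:30, 4, replace = TRUE)
    cnt[1] <- cnt[1] + 1 # keep ratios defined
    m <- suppressWarnings(confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4]))
    expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall))
  }
})

test_that("subset evaluation scores a held-out split", {
  d <- make_planted(200, f = 0.2, n_noise = 2, with_duplicate = FALSE,
                    seed = 31)
  set.seed(32)
  sp <- split_dataset(d$x, d$y)
  # perfectly separable single feature classifies the test set exactly
  res <- evaluate_subset(sp$train, sp$test, "inf")
  expect_equal(res$f1, 1)
  expect_equal(res$tp + res$fp + res$fn + res$tn, length(sp$test$y))
  # the full-column subset defines the "All" baseline
  res_all <- evaluate_subset(sp$train, sp$test, colnames(d$x))
  expect_equal(res_all$tp + res_all$tn + res_all$fp + res_all$fn,
               length(sp$test$y))
  expect_error(evaluate_subset(sp$train, sp$test, "nope"), "unknown")
  expect_error(evaluate_subset(sp$train, sp$test, character(0)),
               "non-empty")
})

test_that("the contrast panel reports every method at the right sizes", {
  d <- make_planted(150, f = 0.3, n_noise = 3, with_duplicate = FALSE,
                    seed = 41)
  rc <- run_contrast(d$x, d$y, seed = 42, k = 5, folds = 5)
  singles <- colnames(d$x)
  expect_setequal(rc$method, c(singles, "All", "Imbalanced",
                               "FFS-ReliefF", "FFS-Weight", "FFS-SFS"))
  expect_true(all(rc$size[rc$method %in% singles] == 1))
  expect_equal(rc$size[rc$method == "All"], ncol(d$x))
  m_sfs <- rc$size[rc$method == "FFS-SFS"]
  expect_equal(rc$size[rc$method == "FFS-ReliefF"], m_sfs)
  expect_equal(rc$size[rc$method == "FFS-Weight"], m_sfs)
  expect_true(all(rc$f1 >= 0 & rc$f1 <= 1))
})

test_that("RFE without balancing keeps most features when all carry signal", {
  sizes <- vapply(1:5, function(s) {
    d <- make_sum_dataset(200, d = 6, f = 0.3, seed = s)
    set.seed(s)
    length(svm_rfe_cv(d$x, d$y)$best_subset)
  }, numeric(1))
  expect_true(all(sizes >= 5))
})

test_that("ablation panel honours the phase definitions", {
  d <- make_planted(150, f = 0.3, n_noise = 4, with_duplicate = FALSE,
                    seed = 51)
  ra <- run_ablation(d$x, d$y, seed = 52, k = 5, folds = 5)
  sel <- attr(ra, "selection")
  expect_equal(ra$subset[ra$method == "w/o SFS"],
               paste(canonical_feature_order(sel$f_star), collapse = "+"))
  # secondary selection alone always returns 2-4 features (2 clusters)
  wo_ffs_size <- ra$size[ra$method == "w/o FFS"]
  expect_gte(wo_ffs_size, 2)
  expect_lte(wo_ffs_size, 4)
  expect_lte(ra$size[ra$method == "FFS-SFS"],
             ra$size[ra$method == "w/o SFS"])
})

test_that("modal-subset aggregation follows frequency then parsimony", {
  s <- c(rep(list(c("K", "Ksum")), 18), rep(list("K"), 12))
  expect_equal(aggregate_mode(s), c("K", "Ksum"))

  # all distinct: smallest size, then canonical order
  s2 <- list(c("K2sum", "PR"), "PR", "K2sum", c("B", "CC", "EC"))
  expect_equal(aggregate_mode(s2), "K2sum")

  # unanimous networks vote their shared subset
  s3 <- rep(list(c("K", "K2sum")), 10)
  expect_equal(aggregate_mode(s3), c("K", "K2sum"))
  expect_error(aggregate_mode(list()), "at least one")
})

test_that("a full reduced-scale experiment run is deterministic", {
  cfg <- experiment_config(model = "BA", n = 100, n_networks = 1,
                           lambda_multipliers = 1, f_values = 0.2,
                           repeats = 2, sir_runs = 30,
                           threshold_grid = seq(0.02, 0.3, by = 0.04),
                           threshold_runs = 60, k = 3, folds = 3,
                           master_seed = 77)
  r1 <- run_experiment(cfg, verbose = FALSE)
  r2 <- run_experiment(cfg, verbose = FALSE)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$modal, r2$modal)
  expect_identical(r1$voted, r2$voted)
  expect_equal(nrow(r1$metrics), 2)
  expect_true(all(r1$metrics$f1 >= 0 & r1$metrics$f1 <= 1))
  expect_equal(nrow(r1$voted), 1)
})

test_that("the full-scale preset merges overrides over study defaults", {
  cfg <- experiment_config_full(repeats = 5, model = "ER")
  expect_equal(cfg$n, 1000)
  expect_equal(cfg$n_networks, 10)
  expect_equal(cfg$repeats, 5)
  expect_equal(cfg$model, "ER")
  expect_equal(cfg$sir_runs, 1000)
})
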