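# Programmatic fixtures shared across tests.

# Planted single-feature design: the label is a noiseless threshold rule
# on the first feature (positives shifted by a margin so the classes are
# separable on it); an exact duplicate column and pure-noise columns are
# appended.
make_planted <- function(n, f = 0.2, n_noise = 3, with_duplicate = TRUE,
                         seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  npos <- round(f * n)
  ord <- order(-x1)
  x1[ord[seq_len(npos)]] <- x1[ord[seq_len(npos)]] + 1
  y <- rep(-1L, n)
  y[ord[seq_len(npos)]] <- 1L
  cols <- list(inf = x1)
  if (with_duplicate) cols$dup <- x1
  for (j in seq_len(n_noise)) cols[[paste0("noise", j)]] <- rnorm(n)
  list(x = do.call(cbind, cols), y = y)
}

# Every feature mildly informative: the label thresholds the row sum plus
# noise, so no feature is redundant and full-set classifiers do best.
make_sum_dataset <- function(n = 200, d = 6, f = 0.3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  score <- rowSums(x) + rnorm(n, sd = 0.5)
  y <- ifelse(rank(-score) <= f * n, 1L, -1L)
  list(x = x, y = y)
}

path3 <- function() igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
star5 <- function() igraph::make_star(5, mode = "undirected") # centre = 1
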