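test_that("outbreak size hits its deterministic limits", {
  graphs <- list(path3(), star5(), generate_ba(50, 2, seed = 1))
  for (g in graphs) {
    n <- igraph::vcount(g)
    set.seed(1)
    # beta = 0: only the seed is ever infected
    expect_equal(simulate_sir_once(g, 1, beta = 0), 1 / n)
    # beta = 1, mu = 1: deterministic BFS sweep reaches everyone
    expect_equal(simulate_sir_once(g, 1, beta = 1), 1)
  }
  expect_error(simulate_sir_once(path3(), 9, 0.5), "seed")
})

test_that("star-centre outbreak mean matches the one-step expectation", {
  # centre infects each of 4 leaves once w.p. 1/2: E[rho] = (1 + 4/2)/5
  set.seed(42)
  rho <- replicate(1e4, simulate_sir_once(star5(), 1, beta = 0.5))
  se <- sd(rho) / sqrt(length(rho))
  expect_lt(abs(mean(rho) - 0.6), 3 * se)
})

test_that("variability is the relative standard deviation", {
  expect_equal(variability(rep(0.3, 50)), 0)
  expect_equal(variability(c(0.1, 0.3)), 0.5) # sd/mean with population sd
  x <- c(0.05, 0.2, 0.4, 0.9)
  expect_equal(variability(3 * x), variability(x)) # scale invariance
  expect_error(variability(numeric(0)), "sample")
  expect_error(variability(c(0, 0)), "positive")
})

test_that("Monte-Carlo means agree with exhaustive enumeration on tiny graphs", {
  cases <- list(
    list(g = path3(), seed = 1, beta = 0.6),
    list(g = star5(), seed = 2, beta = 0.4), # leaf seed
    list(g = igraph::make_graph(c(1, 2, 2, 3, 3, 1, 3, 4, 4, 5, 5, 6),
                                directed = FALSE), seed = 1, beta = 0.5)
  )
  for (cs in cases) {
    exact <- oracle_sir_mean(cs$g, cs$seed, cs$beta)
    set.seed(7)
    rho <- replicate(4000, simulate_sir_once(cs$g, cs$seed, cs$beta))
    se <- sd(rho) / sqrt(length(rho))
    expect_lt(abs(mean(rho) - exact), 4 * se)
  }
  # the enumeration oracle itself reproduces the analytic star value
  expect_equal(oracle_sir_mean(star5(), 1, 0.5), 0.6, tolerance = 1e-12)
})

test_that("outbreaks grow stochastically with the infection rate", {
  g <- generate_ba(100, 3, seed = 3)
  mean_rho <- function(beta, seed) {
    set.seed(seed)
    mean(replicate(400, simulate_sir_once(g, 1, beta)))
  }
  lo <- mean_rho(0.1, 11)
  hi <- mean_rho(0.3, 11)
  expect_gt(hi, lo)
})

test_that("threshold estimation picks the variability peak", {
  # grid of length 1 is returned as-is
  g <- generate_ba(60, 2, seed = 5)
  scan1 <- estimate_threshold(g, lambda_grid = 0.1, runs_per_lambda = 50)
  expect_equal(scan1$lambda_c, 0.1)

  # complete graph: interior maximum well below 1
  k10 <- igraph::make_full_graph(10)
  scan <- estimate_threshold(k10, lambda_grid = seq(0.05, 1, by = 0.05),
                             runs_per_lambda = 500, master_seed = 2)
  expect_true(all(scan$deltas >= 0))
  peak <- which.max(scan$deltas)
  expect_gt(peak, 1)
  expect_lt(peak, length(scan$lambdas))
  expect_lt(scan$lambda_c, 0.6)

  expect_error(estimate_threshold(k10, lambda_grid = c(0.2, 0.1)),
               "increasing")
})

test_that("threshold estimate is near the degree-based mean-field value", {
  g <- generate_ba(1000, 3, seed = 8)
  k <- igraph::degree(g)
  hmf <- mean(k) / (mean(k^2) - mean(k))
  scan <- estimate_threshold(g, lambda_grid = seq(0.01, 0.25, by = 0.008),
                             runs_per_lambda = 150, master_seed = 8)
  expect_gt(scan$lambda_c, hmf / 2)
  expect_lt(scan$lambda_c, hmf * 2)
})

test_that("per-node influence scores respect seeds and limits", {
  g <- star5()
  # beta = 0: every score is exactly 1/N
  sc0 <- influence_scores(g, 0, runs = 5)
  expect_equal(sc0$mean_rho, rep(1 / 5, 5))

  # centre strictly exceeds leaves at beta = 0.5
  sc <- influence_scores(g, 0.5, runs = 4000, master_seed = 1)
  expect_gt(sc$mean_rho[1], max(sc$mean_rho[-1]))

  # identical substreams give identical scores regardless of call order
  a <- influence_scores(g, 0.5, runs = 50, master_seed = 9)
  b <- influence_scores(g, 0.5, runs = 50, master_seed = 9)
  expect_identical(a, b)
  expect_error(influence_scores(g, 1.5), "lambda")
})

test_that("top-f labelling is exact and deterministic", {
  set.seed(1)
  rho <- runif(10)
  y <- label_top_f(rho, 0.2)
  expect_equal(sum(y == 1), 2)
  expect_equal(sum(y == -1), 8)
  expect_setequal(which(y == 1), order(-rho)[1:2])

  # round-half-up at N = 1000, f = 0.15
  y2 <- label_top_f(runif(1000), 0.15)
  expect_equal(sum(y2 == 1), 150)

  # all-equal scores: ties resolved by degree then index
  deg <- c(5, 1, 9, 9, 2)
  y3 <- label_top_f(rep(0.4, 5), 0.4, degrees = deg)
  expect_equal(which(y3 == 1), c(3, 4))

  expect_error(label_top_f(runif(10), 0.01), "degenerate")
  expect_error(label_top_f(runif(10), 0.99), "degenerate")
})

test_that("scoring plus labelling composes into the labelled scores object", {
  g <- generate_ba(60, 2, seed = 2)
  lab <- influence_labels(g, 0.15, f = 0.2, runs = 50, master_seed = 3)
  expect_equal(sum(lab$scores$label == 1), round(0.2 * 60))
  expect_equal(nrow(lab$scores), 60)
  # positives all score at least as high as negatives (up to tie rules)
  expect_gte(min(lab$scores$mean_rho[lab$scores$label == 1]),
             max(lab$scores$mean_rho[lab$scores$label == -1]) - 1e-12)
})
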