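# Discrete-time SIR dynamics, threshold estimation, influence labelling.

#' SIR simulation settings
#'
#' @param beta Per-contact infection probability per step, in `[0, 1]`.
#' @param mu Per-step recovery probability in `(0, 1]`; the default 1
#'   gives every vertex exactly one infectious step, so the effective
#'   infection rate `lambda = beta / mu` equals `beta`.
#' @param runs Monte-Carlo repetitions per seed vertex.
#' @param master_seed Integer master seed; per-node substreams are derived
#'   from it so results are independent of execution order.
#' @return A list of class `epidemic_config`.
#' @export
epidemic_config <- function(beta = 0.1, mu = 1, runs = 1000,
                            master_seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, mu > 0, mu <= 1, runs >= 1)
  structure(list(beta = beta, mu = mu, runs = as.integer(runs),
                 master_seed = as.integer(master_seed)),
            class = "epidemic_config")
}

# Core synchronous SIR sweep on an integer adjacency list.  Within a step,
# every infected vertex first attempts to infect each susceptible
# neighbour independently with probability beta (multiple infected
# neighbours give a vertex multiple chances), then recovers with
# probability mu.  Returns the final recovered fraction in [1/N, 1].
.sir_run <- function(adj, seed_node, beta, mu) {
  n <- length(adj)
  state <- integer(n) # 0 = S, 1 = I, 2 = R
  state[seed_node] <- 1L
  infected <- seed_node
  while (length(infected)) {
    targets <- unlist(adj[infected], use.names = FALSE)
    targets <- targets[state[targets] == 0L]
    if (length(targets) && beta > 0) {
      hit <- unique(targets[runif(length(targets)) < beta])
    } else {
      hit <- integer(0L)
    }
    if (mu >= 1) {
      state[infected] <- 2L
      state[hit] <- 1L
      infected <- hit
    } else {
      rec <- infected[runif(length(infected)) < mu]
      state[rec] <- 2L
      state[hit] <- 1L
      infected <- which(state == 1L)
    }
  }
  sum(state == 2L) / n
}

.as_adjlist <- function(net) {
  lapply(igraph::as_adj_list(net), as.integer)
}

#' Run one SIR outbreak from a given seed vertex
#'
#' Synchronous discrete-time dynamics; the run stops once no infectious
#' vertex remains, which is guaranteed in finite time.
#'
#' @param net A connected `igraph` graph.
#' @param seed_node Seed vertex index (1-based).
#' @param beta Infection probability per infected-susceptible contact.
#' @param mu Recovery probability per step.
#' @return The outbreak size as a fraction of the network,
#'   `rho` in `[1/N, 1]`.
#' @export
simulate_sir_once <- function(net, seed_node, beta, mu = 1) {
  n <- igraph::vcount(net)
  if (seed_node < 1 || seed_node > n) stop("invalid seed node")
  stopifnot(beta >= 0, beta <= 1, mu > 0, mu <= 1)
  .sir_run(.as_adjlist(net), as.integer(seed_node), beta, mu)
}

#' Variability of a sample of outbreak sizes
#'
#' Relative standard deviation `sqrt(<rho^2> - <rho>^2) / <rho>` using
#' population moments; as a function of the effective infection rate it
#' peaks at the epidemic threshold.  Scale-invariant and zero for
#' constant samples.
#'
#' @param rho_samples Numeric vector of outbreak fractions, mean > 0.
#' @return Non-negative scalar `Delta`.
#' @export
variability <- function(rho_samples) {
  if (!length(rho_samples)) stop("need at least one sample")
  m <- mean(rho_samples)
  if (m <= 0) stop("mean outbreak size must be positive")
  v <- mean(rho_samples^2) - m^2
  sqrt(max(v, 0)) / m
}

#' Estimate the epidemic threshold by the variability maximum
#'
#' For each effective infection rate on the grid, runs SIR outbreaks from
#' uniformly random seed vertices and computes the variability `Delta` of
#' the outbreak sizes; the threshold estimate `lambda_c` is the grid point
#' maximising `Delta` (ties resolved towards the smaller rate).
#'
#' @param net A connected `igraph` graph.
#' @param lambda_grid Strictly increasing grid of effective rates.
#' @param runs_per_lambda Outbreaks simulated per grid point.
#' @param mu Recovery probability.
#' @param master_seed Integer seed; each grid point gets its own derived
#'   substream.
#' @return A list of class `threshold_scan` with elements `lambdas`,
#'   `deltas`, `lambda_c`, `runs_per_lambda`.
#' @export
estimate_threshold <- function(net,
                               lambda_grid = seq(0.00625, 0.25,
                                                 length.out = 40),
                               runs_per_lambda = 300,
                               mu = 1,
                               master_seed = 1L) {
  if (!length(lambda_grid)) stop("lambda grid must be non-empty")
  if (is.unsorted(lambda_grid, strictly = TRUE)) {
    stop("lambda grid must be strictly increasing")
  }
  validate_network(net)
  adj <- .as_adjlist(net)
  n <- length(adj)
  deltas <- vapply(seq_along(lambda_grid), function(j) {
    set.seed(derive_seed(master_seed, j, 7L))
    seeds <- sample.int(n, runs_per_lambda, replace = TRUE)
    rho <- vapply(seeds, function(s) {
      .sir_run(adj, s, lambda_grid[j] * mu, mu)
    }, numeric(1L))
    variability(rho)
  }, numeric(1L))
  structure(
    list(lambdas = lambda_grid, deltas = deltas,
         lambda_c = lambda_grid[which.max(deltas)],
         runs_per_lambda = runs_per_lambda),
    class = "threshold_scan"
  )
}

#' Mean outbreak size seeded from every vertex
#'
#' For each vertex `i`, averages `runs` independent SIR outcomes with `i`
#' as the sole initial infectious vertex at effective rate `lambda`.
#' Each vertex uses its own RNG substream derived from `master_seed` and
#' the vertex index, so scores do not depend on evaluation order.
#'
#' @param net A connected `igraph` graph.
#' @param lambda Effective infection rate; `beta = lambda * mu` must lie
#'   in `[0, 1]`.
#' @param runs Monte-Carlo repetitions per vertex.
#' @param mu Recovery probability.
#' @param master_seed Integer master seed.
#' @param node_seeds Optional integer vector of per-vertex substream
#'   seeds overriding the derived ones (used e.g. to verify relabelling
#'   equivariance).
#' @return `data.frame` with columns `node_id` (0-based) and `mean_rho`.
#' @export
influence_scores <- function(net, lambda, runs = 1000, mu = 1,
                             master_seed = 1L, node_seeds = NULL) {
  beta <- lambda * mu
  if (beta < 0 || beta > 1) stop("lambda * mu must lie in [0, 1]")
  validate_network(net)
  adj <- .as_adjlist(net)
  n <- length(adj)
  if (is.null(node_seeds)) {
    node_seeds <- vapply(seq_len(n), function(i) {
      derive_seed(master_seed, i, 13L)
    }, integer(1L))
  }
  stopifnot(length(node_seeds) == n)
  mean_rho <- vapply(seq_len(n), function(i) {
    set.seed(node_seeds[i])
    tot <- 0
    for (r in seq_len(runs)) tot <- tot + .sir_run(adj, i, beta, mu)
    tot / runs
  }, numeric(1L))
  data.frame(node_id = seq_len(n) - 1L, mean_rho = mean_rho)
}

#' Label the top-f fraction of vertices as influential spreaders
#'
#' Sorts vertices by decreasing mean outbreak size (ties broken by
#' decreasing degree, then increasing vertex index, so labels are
#' deterministic) and labels the first `round(f * N)` (half-up) vertices
#' `+1`, the rest `-1`.
#'
#' @param mean_rho Per-vertex mean outbreak fractions.
#' @param f Influential fraction, `0 < f < 1`; must yield a non-degenerate
#'   split (neither 0 nor N positives).
#' @param degrees Optional per-vertex degrees for tie-breaking.
#' @return Integer vector of labels in `{-1, +1}`.
#' @export
label_top_f <- function(mean_rho, f, degrees = NULL) {
  n <- length(mean_rho)
  if (f <= 0 || f >= 1) stop("`f` must be in (0, 1)")
  npos <- floor(f * n + 0.5)
  if (npos <= 0L || npos >= n) {
    stop("degenerate labelling: round(f * N) must be in 1..N-1")
  }
  if (is.null(degrees)) degrees <- numeric(n)
  ord <- order(-mean_rho, -degrees, seq_len(n))
  labels <- rep(-1L, n)
  labels[ord[seq_len(npos)]] <- 1L
  labels
}

#' Score and label every vertex of a network
#'
#' Convenience composition of [influence_scores()] and [label_top_f()].
#'
#' @inheritParams influence_scores
#' @param f Influential fraction passed to [label_top_f()].
#' @return A list of class `influence_labels`: `scores` (data frame with
#'   `node_id`, `mean_rho`, `label`), `f`, `lambda`.
#' @export
influence_labels <- function(net, lambda, f, runs = 1000, mu = 1,
                             master_seed = 1L) {
  sc <- influence_scores(net, lambda, runs = runs, mu = mu,
                         master_seed = master_seed)
  sc$label <- label_top_f(sc$mean_rho, f, degrees = igraph::degree(net))
  structure(list(scores = sc, f = f, lambda = lambda),
            class = "influence_labels")
}
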