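# Network generation and edge-list I/O.
#
# All generators return simple, connected, undirected igraph graphs whose
# vertices are indexed 1..N internally; files on disk use dense 0-based ids.

#' Generate a Barabasi-Albert scale-free network
#'
#' Preferential attachment starting from `m` isolated seed vertices: each of
#' the `n - m` arriving vertices attaches `m` edges to distinct existing
#' vertices with probability proportional to their current degree (uniform
#' while all degrees are zero, i.e. the first arrival links to every seed).
#' The edge count is therefore exactly `m * (n - m)` and the graph is
#' connected by construction; at `n = 1000`, `m = 3` this yields 2991 edges
#' and density 0.005988.
#'
#' @param n Number of vertices.
#' @param m Edges attached by every arriving vertex; `1 <= m < n`.
#' @param seed Optional integer RNG seed; the same seed reproduces the same
#'   edge set bit-for-bit.
#' @return An undirected simple connected `igraph` graph with graph
#'   attributes `name` and `model`.
#' @examples
#' g <- generate_ba(100, 3, seed = 1)
#' igraph::ecount(g) # 3 * 97 = 291
#' @export
generate_ba <- function(n, m, seed = NULL) {
  if (length(m) != 1L || m < 1 || m >= n) {
    stop("`m` must satisfy 1 <= m < n")
  }
  n <- as.integer(n)
  m <- as.integer(m)
  if (!is.null(seed)) set.seed(seed)
  n_new <- n - m
  from <- integer(m * n_new)
  to <- integer(m * n_new)
  deg <- numeric(n)
  ptr <- 0L
  for (v in (m + 1L):n) {
    w <- deg[seq_len(v - 1L)]
    if (sum(w) == 0) w <- rep(1, v - 1L)
    targets <- sample.int(v - 1L, m, prob = w)
    idx <- ptr + seq_len(m)
    from[idx] <- v
    to[idx] <- targets
    deg[targets] <- deg[targets] + 1
    deg[v] <- m
    ptr <- ptr + m
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- set_net_attrs(g, sprintf("BA(n=%d,m=%d)", n, m), "BA")
  g
}

#' Generate an Erdos-Renyi random graph (largest connected component)
#'
#' Each unordered vertex pair is joined independently with probability
#' `p = avg_degree / (n - 1)`.  Because SIR dynamics and the path-based
#' centralities require connectedness, the largest connected component is
#' returned, re-indexed to dense ids; at average degree 6 the component
#' covers essentially all vertices.  The realised size is recorded in the
#' graph `name`.
#'
#' @param n Number of vertices before component extraction.
#' @param avg_degree Target mean degree, `0 < avg_degree < n`.
#' @inheritParams generate_ba
#' @return An undirected simple connected `igraph` graph.
#' @export
generate_er <- function(n, avg_degree, seed = NULL) {
  if (length(avg_degree) != 1L || avg_degree <= 0 || avg_degree >= n) {
    stop("`avg_degree` must satisfy 0 < avg_degree < n")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- avg_degree / (n - 1)
  g <- igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
  comp <- igraph::components(g)
  if (max(comp$csize) < 2L) {
    stop("generated graph is (almost) empty; increase `avg_degree`")
  }
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  g <- set_net_attrs(
    g, sprintf("ER(n=%d,k=%g,lcc=%d)", n, avg_degree, length(keep)), "ER"
  )
  g
}

#' Generate a Watts-Strogatz small-world network
#'
#' Ring lattice of `n` vertices each linked to its `k` nearest neighbours
#' (`k/2` on each side), followed by independent rewiring of each edge with
#' probability `rewire_p`: the far endpoint is replaced by a uniformly
#' chosen vertex, avoiding self-loops and duplicate edges, so the edge
#' count `n * k / 2` is conserved exactly.  If rewiring disconnects the
#' graph, generation is retried with the seed incremented until connected.
#'
#' @param n Number of vertices.
#' @param k Even ring degree, `k < n`.
#' @param rewire_p Rewiring probability in `[0, 1]`.
#' @inheritParams generate_ba
#' @return An undirected simple connected `igraph` graph.
#' @export
generate_ws <- function(n, k, rewire_p, seed = NULL) {
  if (length(k) != 1L || k %% 2 != 0 || k <= 0 || k >= n) {
    stop("`k` must be even and satisfy 0 < k < n")
  }
  if (rewire_p < 0 || rewire_p > 1) stop("`rewire_p` must be in [0, 1]")
  n <- as.integer(n)
  k <- as.integer(k)
  attempt <- 0L
  repeat {
    if (!is.null(seed)) set.seed(seed + attempt)
    u <- rep(seq_len(n), k %/% 2L)
    v <- unlist(lapply(seq_len(k %/% 2L), function(j) {
      ((seq_len(n) - 1L + j) %% n) + 1L
    }))
    adj <- matrix(FALSE, n, n)
    adj[cbind(u, v)] <- TRUE
    adj[cbind(v, u)] <- TRUE
    rewire <- which(runif(length(u)) < rewire_p)
    for (e in rewire) {
      a <- u[e]
      b <- v[e]
      cand <- which(!adj[a, ] & seq_len(n) != a)
      if (!length(cand)) next
      w <- cand[sample.int(length(cand), 1L)]
      adj[a, b] <- adj[b, a] <- FALSE
      adj[a, w] <- adj[w, a] <- TRUE
      v[e] <- w
    }
    g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
    if (igraph::is_connected(g)) break
    attempt <- attempt + 1L
    if (is.null(seed) && attempt > 1000L) {
      stop("failed to generate a connected WS network")
    }
  }
  set_net_attrs(g, sprintf("WS(n=%d,k=%d,p=%g)", n, k, rewire_p), "WS")
}

#' Read an undirected network from a whitespace-separated edge list
#'
#' Lines hold two whitespace-separated node tokens; `#` starts a comment.
#' Tokens are mapped to dense vertex ids (numeric labels sorted
#' numerically, other labels lexically); the original labels are kept in
#' the vertex attribute `label`.  Self-loops and duplicate edges are
#' dropped with a warning giving the counts.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` graph.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("edge list contains no data lines: ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop("malformed edge list line (fewer than 2 tokens): line ", bad[1L])
  }
  a <- vapply(toks, `[`, character(1L), 1L)
  b <- vapply(toks, `[`, character(1L), 2L)
  labels <- unique(c(a, b))
  num <- suppressWarnings(as.numeric(labels))
  labels <- if (!anyNA(num)) labels[order(num)] else sort(labels)
  ai <- match(a, labels)
  bi <- match(b, labels)
  self <- ai == bi
  lo <- pmin(ai, bi)
  hi <- pmax(ai, bi)
  dup <- duplicated(cbind(lo, hi)) & !self
  n_self <- sum(self)
  n_dup <- sum(dup)
  if (n_self || n_dup) {
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  }
  keep <- !self & !dup
  if (!any(keep)) stop("edge list has no valid edges: ", path)
  g <- igraph::graph_from_edgelist(cbind(lo[keep], hi[keep]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(labels)) {
    g <- igraph::add_vertices(g, length(labels) - igraph::vcount(g))
  }
  igraph::V(g)$label <- labels
  set_net_attrs(g, basename(path), "file")
}

#' Write a network as a 0-based whitespace-separated edge list
#'
#' One edge per line, two space-separated dense 0-based vertex ids, sorted
#' by `(u, v)` with `u < v`; a round-trip through [read_edgelist()]
#' preserves the edge set.
#'
#' @param net An `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net, names = FALSE)
  lo <- pmin(el[, 1L], el[, 2L]) - 1L
  hi <- pmax(el[, 1L], el[, 2L]) - 1L
  ord <- order(lo, hi)
  writeLines(paste(lo[ord], hi[ord]), path)
  invisible(path)
}

#' Validate the structural invariants of a network
#'
#' Checks that a graph is undirected, simple (no self-loops or duplicate
#' edges), non-empty, and -- unless `connected = FALSE` -- connected.
#'
#' @param net An `igraph` graph.
#' @param connected Require connectedness (default `TRUE`).
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_network <- function(net, connected = TRUE) {
  if (!igraph::is_igraph(net)) stop("not an igraph graph")
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (igraph::vcount(net) < 1L) stop("network has no vertices")
  if (any(igraph::which_loop(net))) stop("network contains self-loops")
  if (any(igraph::which_multiple(net))) {
    stop("network contains duplicate edges")
  }
  if (connected && !igraph::is_connected(net)) {
    stop("network is not connected")
  }
  invisible(TRUE)
}

set_net_attrs <- function(g, name, model) {
  g <- igraph::set_graph_attr(g, "name", name)
  igraph::set_graph_attr(g, "model", model)
}
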