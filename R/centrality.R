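# Structural centralities and the node feature table.

#' Centrality computation settings
#'
#' @param pr_damping PageRank damping factor alpha in (0, 1); the per-node
#'   teleport constant is `(1 - alpha) / N` so the scores sum to one.
#' @param constancy_tol Variance threshold below which a feature column is
#'   treated as constant and dropped from the table (e.g. the k-shell
#'   column on a preferential-attachment graph, where every vertex ends in
#'   the same shell).
#' @param two_hop_exact If `TRUE`, the two-hop neighbourhood sum uses only
#'   vertices at shortest-path distance exactly 2; the default (`FALSE`)
#'   sums degrees over all vertices within two hops (distance 1 or 2),
#'   the standard reading of a two-hop neighbourhood.
#' @return A list of class `centrality_config`.
#' @export
centrality_config <- function(pr_damping = 0.85,
                              constancy_tol = 1e-12,
                              two_hop_exact = FALSE) {
  stopifnot(pr_damping > 0, pr_damping < 1, constancy_tol > 0)
  structure(
    list(pr_damping = pr_damping, constancy_tol = constancy_tol,
         two_hop_exact = two_hop_exact),
    class = "centrality_config"
  )
}

#' K-shell (coreness) decomposition index
#'
#' Iteratively prunes vertices of degree at most `s`, assigning shell `s`,
#' for increasing `s`; every vertex receives an index bounded by the
#' maximum degree.
#'
#' @param net An `igraph` graph.
#' @return Integer vector of shell indices, one per vertex.
#' @export
kshell <- function(net) {
  validate_network(net, connected = FALSE)
  as.integer(igraph::coreness(net))
}

#' Sum of degrees over the two-hop neighbourhood of a vertex
#'
#' Degrees summed over all vertices at shortest-path distance 1 or 2 from
#' `node` (the vertex itself excluded); with `exact = TRUE` only distance-2
#' vertices count.
#'
#' @param net An `igraph` graph.
#' @param node Vertex index (1-based).
#' @param exact Use distance exactly 2 instead of within-two-hops.
#' @return A single number.
#' @export
two_hop_sum <- function(net, node, exact = FALSE) {
  n <- igraph::vcount(net)
  if (node < 1 || node > n) stop("unknown node: ", node)
  deg <- igraph::degree(net)
  nb <- igraph::ego(net, order = 2, nodes = node,
                    mindist = if (exact) 2L else 1L)[[1L]]
  sum(deg[as.integer(nb)])
}

#' Compute the node-by-centrality feature table
#'
#' Returns nine structural centralities per vertex: degree `K`; one-hop
#' neighbourhood sum `Ksum` (sum of neighbours' degrees); two-hop
#' neighbourhood sum `K2sum`; k-shell index `KS`; local clustering
#' coefficient `C` (0 for degree < 2); unnormalised shortest-path
#' betweenness `B` (endpoints excluded); closeness `CC = (N-1) / sum_j
#' d_ij`; eigenvector centrality `EC` scaled to unit Euclidean norm; and
#' PageRank `PR` (sums to one).  Columns with variance below
#' `cfg$constancy_tol` carry no information for classification and are
#' removed; their names are recorded in the `dropped` attribute.
#'
#' @param net A connected `igraph` graph.
#' @param cfg A [centrality_config()].
#' @param drop_constant Remove constant columns (default `TRUE`); disable
#'   to inspect raw values, e.g. on vertex-transitive graphs where every
#'   centrality is constant.
#' @return A `data.frame` of class `feature_table` with a 0-based
#'   `node_id` column followed by the surviving centrality columns;
#'   attribute `dropped` lists removed constant columns.
#' @examples
#' g <- generate_ba(100, 3, seed = 1)
#' ft <- compute_feature_table(g)
#' attr(ft, "dropped") # "KS": every vertex sits in shell 3
#' @export
compute_feature_table <- function(net, cfg = centrality_config(),
                                  drop_constant = TRUE) {
  validate_network(net, connected = TRUE)
  n <- igraph::vcount(net)
  deg <- igraph::degree(net)

  adj <- igraph::as_adj_list(net)
  ksum <- vapply(adj, function(v) sum(deg[as.integer(v)]), numeric(1L))
  nb2 <- igraph::ego(net, order = 2,
                     mindist = if (cfg$two_hop_exact) 2L else 1L)
  k2sum <- vapply(nb2, function(v) sum(deg[as.integer(v)]), numeric(1L))

  cc_local <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc_local[is.na(cc_local)] <- 0

  ec <- igraph::eigen_centrality(net)$vector
  ec <- abs(ec)
  ec <- ec / sqrt(sum(ec^2))

  pr <- igraph::page_rank(net, damping = cfg$pr_damping)$vector

  tab <- data.frame(
    node_id = seq_len(n) - 1L,
    K = as.numeric(deg),
    Ksum = ksum,
    K2sum = k2sum,
    KS = as.numeric(kshell(net)),
    C = cc_local,
    B = as.numeric(igraph::betweenness(net, directed = FALSE)),
    CC = as.numeric(igraph::closeness(net, normalized = TRUE)),
    EC = as.numeric(ec),
    PR = as.numeric(pr)
  )

  feat_cols <- setdiff(names(tab), "node_id")
  vars <- vapply(tab[feat_cols], var, numeric(1L))
  dropped <- feat_cols[vars < cfg$constancy_tol]
  if (!drop_constant) dropped <- character(0L)
  if (length(dropped)) tab[dropped] <- NULL

  if (any(!is.finite(as.matrix(tab[setdiff(names(tab), "node_id")])))) {
    stop("non-finite centrality values computed")
  }
  structure(tab, dropped = dropped,
            class = c("feature_table", "data.frame"))
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param ft A `feature_table` from [compute_feature_table()] (or any
#'   data frame with a `node_id` column).
#' @return Numeric matrix, rows = nodes, named columns = centralities.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[setdiff(names(ft), "node_id")])
}
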