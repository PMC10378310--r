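# Independent oracles used to cross-check the package implementations.

# All-pairs BFS betweenness by explicit shortest-path counting:
# B(i) = sum over pairs s < t of sigma_st(i) / sigma_st, with
# sigma_st(i) = sigma_s(i) * sigma_i(t) when i lies on a shortest path.
oracle_betweenness <- function(g) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  n <- length(adj)
  dmat <- matrix(Inf, n, n)
  smat <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    cnt <- numeric(n)
    d[s] <- 0
    cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0L)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) cnt[w] <- cnt[w] + cnt[v]
        }
      }
      frontier <- unique(nxt)
    }
    dmat[s, ] <- d
    smat[s, ] <- cnt
  }
  b <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      if (is.infinite(dmat[s, t])) next
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (dmat[s, i] + dmat[i, t] == dmat[s, t]) {
          b[i] <- b[i] + smat[s, i] * smat[i, t] / smat[s, t]
        }
      }
    }
  }
  b
}

# Exact expected outbreak fraction for synchronous SIR with mu = 1 on a
# tiny graph, by exhaustive branching over per-step infection outcomes.
# Each susceptible vertex with c infected neighbours is infected this step
# with probability 1 - (1 - beta)^c, independently.
oracle_sir_mean <- function(g, seed_node, beta) {
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  n <- length(adj)
  recurse <- function(S, I) {
    if (!length(I)) return(0)
    cnt <- vapply(S, function(v) sum(adj[[v]] %in% I), numeric(1L))
    risk <- S[cnt > 0]
    cnt <- cnt[cnt > 0]
    recovered_now <- length(I)
    m <- length(risk)
    if (!m) return(recovered_now)
    p <- 1 - (1 - beta)^cnt
    acc <- 0
    for (mask in 0:(2^m - 1)) {
      sel <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
      prob <- prod(ifelse(sel, p, 1 - p))
      if (prob == 0) next
      acc <- acc + prob * recurse(setdiff(S, risk[sel]), risk[sel])
    }
    recovered_now + acc
  }
  recurse(setdiff(seq_len(n), seed_node), seed_node) / n
}
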