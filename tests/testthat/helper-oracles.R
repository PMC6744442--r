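# Independent oracles used to validate the package implementations.

# Reference MCL: straight-line dense implementation (no pruning), same
# self-loop policy, components read from the limit matrix.
ref_mcl <- function(A, inflation = 2, iterations = 100) {
  loops <- apply(A, 2, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iterations)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  S <- (M + t(M)) > 1e-9
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected")
  igraph::components(g)$membership
}

# Reference two-sided Fisher p: dhyper-based enumeration with the same
# "at most as probable as observed" convention.
ref_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
  x <- max(0, k - m2):min(k, m1)
  pm <- stats::dhyper(x, m1, m2, k)
  sum(pm[pm <= pm[x == a] * (1 + 1e-12)])
}

# All set partitions of 1..n as integer label vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (lab in seq_len(k + 1L)) recurse(c(labels, lab), max(k, lab))
  }
  recurse(integer(0), 0L)
  out
}

# Newman weighted modularity from the adjacency matrix (no self-loops).
ref_modularity <- function(A, comm) {
  k <- rowSums(A)
  m2 <- sum(k)
  same <- outer(comm, comm, "==")
  sum((A - outer(k, k) / m2)[same]) / m2
}

# adjacency matrix for an unweighted edge list on n nodes
adj_from_edges <- function(n, edges, w = 1) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    wt <- if (length(w) == 1) w else w[r]
    A[edges[r, 1], edges[r, 2]] <- A[edges[r, 2], edges[r, 1]] <- wt
  }
  A
}

# small planted-structure truth for fast end-to-end tests
small_truth <- function(seed = 42, ...) {
  default_truth(n_cpr = 30, n_bac = 30, n_phyla = 3, n_universal = 12,
                n_enriched = 12, n_lineage_blocks = 2, lineage_block_size = 4,
                n_background = 6, seed = seed, ...)
}

# edge list data.frame helper for louvain/mcl inputs
net <- function(nodes, a, b, weight = 1) {
  list(nodes = nodes,
       edges = data.frame(a = a, b = b,
                          weight = rep_len(weight, length(a)),
                          stringsAsFactors = FALSE))
}
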