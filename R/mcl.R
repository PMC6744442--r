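# Markov clustering (MCL) on a weighted undirected graph, implemented on
# sparse matrices: add self-loops, column-normalize, then iterate expansion
# (matrix squaring) and inflation (elementwise power + renormalization) with
# pruning until the matrix stops changing.

#' Markov clustering of a weighted undirected graph
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with columns `a`, `b`, `weight` (non-negative);
#'   undirected, no self-loops required.
#' @param inflation inflation parameter, must be > 1 (default 2.0).
#' @param max_iter iteration cap; non-convergence raises a warning and the
#'   current matrix is interpreted as-is.
#' @param tol convergence tolerance on the max absolute entry change.
#' @param prune entries below this value are dropped after each inflation.
#' @param self_loop self-loop weight policy: `"max"` (the node's maximum
#'   incident weight; isolated nodes get 1) or a single numeric value.
#' @return integer cluster assignment named by node; every node is in
#'   exactly one cluster, disconnected components are never merged, and
#'   isolated nodes form singleton clusters.  Attributes `iterations` and
#'   `converged` record the run.
#' @export
mcl <- function(nodes, edges, inflation = 2.0, max_iter = 200L,
                tol = 1e-8, prune = 1e-5, self_loop = "max") {
  if (!is.numeric(inflation) || length(inflation) != 1L || inflation <= 1)
    stop("inflation must be a single number > 1")
  n <- length(nodes)
  if (n == 0L) return(setNames(integer(0), character(0)))
  if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  i <- match(edges$a, nodes); j <- match(edges$b, nodes)
  if (anyNA(i) || anyNA(j)) stop("edges reference unknown nodes")
  keep <- i != j
  i <- i[keep]; j <- j[keep]; w <- edges$weight[keep]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  loops <- if (identical(self_loop, "max")) {
    mx <- apply_max_incident(A)
    ifelse(mx > 0, mx, 1)
  } else rep(as.numeric(self_loop), n)
  M <- A + Matrix::Diagonal(n, loops)
  M <- col_normalize(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M                      # expansion
    M2 <- as(M2, "CsparseMatrix")
    M2@x <- M2@x^inflation             # inflation
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- col_normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; interpreting the current matrix", max_iter))
  cl <- components_from_matrix(M)
  attr(cl, "iterations") <- it
  attr(cl, "converged") <- converged
  setNames(cl, nodes)
}

apply_max_incident <- function(A) {
  A <- as(A, "CsparseMatrix")
  out <- numeric(ncol(A))
  dp <- diff(A@p)
  if (length(A@x)) {
    col <- rep.int(seq_len(ncol(A)), dp)
    tap <- tapply(A@x, col, max)
    out[as.integer(names(tap))] <- tap
  }
  out
}

col_normalize <- function(M) {
  s <- Matrix::colSums(M)
  s[s == 0] <- 1
  M %*% Matrix::Diagonal(ncol(M), 1 / s)
}

# undirected connected components of the nonzero pattern of M (plus its
# transpose); the limit matrix of MCL is block-structured, so its
# components are the clusters.
components_from_matrix <- function(M) {
  n <- ncol(M)
  S <- as(M + Matrix::t(M), "CsparseMatrix")
  ptr <- S@p; idx <- S@i + 1L
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      nb <- idx[seq.int(ptr[v] + 1L, length.out = ptr[v + 1L] - ptr[v])]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      stack <- c(stack, new)
    }
  }
  comp
}
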