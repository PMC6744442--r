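# Content-based genome dendrograms over Jaccard distances, cophenetic
# comparison between trees (dendrograms or phylogenies), branch collapsing
# with per-group wedge counts, and within-group similarity testing.

#' Jaccard distances between presence/absence profiles
#'
#' `d(a, b) = 1 - |a intersect b| / |a union b|` over matrix rows (genomes)
#' or columns (families).  A pair of all-zero profiles has an undefined
#' Jaccard index; its distance is defined as 0 with a warning.
#'
#' @param mat 0/1 presence matrix.
#' @param between `"rows"` (genomes) or `"columns"` (families).
#' @return a `dist` object.
#' @export
jaccard_distance <- function(mat, between = c("rows", "columns")) {
  between <- match.arg(between)
  if (between == "columns") mat <- t(mat)
  storage.mode(mat) <- "numeric"
  inter <- tcrossprod(mat)
  s <- diag(inter)
  union <- outer(s, s, "+") - inter
  if (any(union[upper.tri(union)] == 0))
    warning("profile pairs with empty union: distance defined as 0")
  d <- ifelse(union > 0, 1 - inter / union, 0)
  diag(d) <- 0
  as.dist(d)
}

#' Agglomerative hierarchical clustering
#'
#' Bottom-up merging under single, complete or average linkage (the three
#' linkage definitions: shortest, longest and mean pairwise distance
#' between clusters).
#'
#' @param distances a `dist` object (e.g. from [jaccard_distance()]).
#' @param linkage `"single"`, `"complete"` or `"average"`.
#' @return an `hclust` tree; leaf labels are taken from the distance
#'   object, merge heights are the linkage distances.
#' @export
agglomerative <- function(distances,
                          linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  if (attr(distances, "Size") < 2L) stop("need at least 2 items to cluster")
  hclust(distances, method = linkage)
}

cophenetic_of <- function(tree) {
  if (inherits(tree, "hclust")) {
    d <- cophenetic(tree)
    m <- as.matrix(d)
  } else if (inherits(tree, "phylo")) {
    m <- ape::cophenetic.phylo(tree)  # patristic path lengths
  } else if (inherits(tree, "dist")) {
    m <- as.matrix(tree)
  } else stop("tree must be an hclust, phylo or dist object")
  m[order(rownames(m)), order(colnames(m))]
}

#' Cophenetic correlation between two trees
#'
#' Pearson correlation between the vectors of pairwise cophenetic distances
#' of the two trees over their (identical) leaf sets.  For a dendrogram the
#' cophenetic distance of two leaves is the merge height of their lowest
#' common ancestor; for a phylogeny it is the patristic path length.  The
#' raw distance vectors are used (no normalization), so the comparison may
#' mix ultrametric and additive scales.
#'
#' @param tree_a,tree_b `hclust` or `phylo` objects with identical leaf
#'   label sets (at least 3 leaves).
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning if either
#'   distance vector has zero variance (e.g. a star tree).
#' @export
cophenetic_correlation <- function(tree_a, tree_b) {
  ma <- cophenetic_of(tree_a)
  mb <- cophenetic_of(tree_b)
  if (nrow(ma) < 3L) stop("need at least 3 leaves")
  if (!identical(rownames(ma), rownames(mb)))
    stop("trees must share an identical leaf set")
  va <- ma[upper.tri(ma)]
  vb <- mb[upper.tri(mb)]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero variance in cophenetic distances: correlation undefined")
    return(NA_real_)
  }
  cor(va, vb)
}

# per-node heights and parent pointers of an hclust tree.
# nodes 1..n are leaves (height 0); node n+k is the k-th merge.
hclust_edges <- function(tree) {
  n <- length(tree$order)
  parent <- integer(2L * n - 1L)
  height <- c(rep(0, n), tree$height)
  for (k in seq_len(n - 1L)) {
    for (child in tree$merge[k, ]) {
      id <- if (child < 0) -child else n + child
      parent[id] <- n + k
    }
  }
  list(n = n, parent = parent, height = height)
}

#' Collapse short branches and count wedges per group
#'
#' Edge lengths are parent height minus child height.  Every edge shorter
#' than `fraction` times the maximum edge length is contracted; the leaf
#' groups connected through contracted edges are the wedges (a maximal
#' subtree whose internal branches are all short collapses into one wedge).
#' Wedges partition the leaves.  A wedge counts toward every group with at
#' least one member genome in it; per-wedge purity (largest group share) is
#' reported so stricter majority rules can be recovered.
#'
#' @param tree an `hclust` over genomes.
#' @param fraction collapse threshold as a fraction of the maximum branch
#'   length (default 0.25, strict: an edge is contracted iff
#'   `length < fraction * max`).
#' @param groups named character vector, genome id -> group label; every
#'   leaf must be labelled.
#' @return object of class `wedge_summary`: list with `wedges` (data.frame
#'   wedge_id, size, purity, and one count column per group), `group_counts`
#'   (group -> number of wedges containing it) and `n_wedges`.
#' @export
collapse_and_count <- function(tree, fraction = 0.25, groups) {
  stopifnot(inherits(tree, "hclust"))
  info <- hclust_edges(tree)
  n <- info$n
  labels <- tree$labels
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (anyNA(groups[labels]))
    stop("every leaf needs a group label")
  n_nodes <- 2L * n - 1L
  par <- info$parent
  par[n_nodes] <- n_nodes  # root: no parent edge (zero length, masked below)
  elen <- info$height[par] - info$height
  elen[n_nodes] <- NA
  lmax <- max(elen[-n_nodes])
  contract <- which(elen[-n_nodes] < fraction * lmax)
  # union-find over contracted edges
  comp <- seq_len(n_nodes)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (v in contract) {
    a <- find(v); b <- find(info$parent[v])
    if (a != b) comp[a] <- b
  }
  leaf_comp <- vapply(seq_len(n), find, 1L)
  wedge <- match(leaf_comp, unique(leaf_comp))
  glab <- groups[labels]
  tab <- table(wedge, glab)
  sizes <- as.integer(rowSums(tab))
  purity <- apply(tab, 1L, max) / sizes
  wedges <- data.frame(wedge_id = sprintf("w%03d", seq_len(nrow(tab))),
                       size = sizes, purity = as.numeric(purity),
                       stringsAsFactors = FALSE)
  counts <- as.data.frame.matrix(tab)
  names(counts) <- colnames(tab)
  wedges <- cbind(wedges, counts)
  group_counts <- setNames(as.integer(colSums(tab > 0)), colnames(tab))
  structure(list(wedges = wedges, group_counts = group_counts,
                 n_wedges = nrow(tab), fraction = fraction),
            class = "wedge_summary")
}

#' @export
print.wedge_summary <- function(x, ...) {
  cat(sprintf("Collapsed tree: %d wedges (branches < %.2f of max length contracted)\n",
              x$n_wedges, x$fraction))
  cat("  wedges containing each group:\n")
  for (g in names(x$group_counts))
    cat(sprintf("    %s: %d\n", g, x$group_counts[[g]]))
  invisible(x)
}

#' Compare within-group content similarity between two groups
#'
#' Computes `1 - Jaccard distance` for every within-group genome pair in
#' each of the two groups and compares the two similarity samples with a
#' two-sided Mann-Whitney U test (exact when the combined sample size is at
#' most 20 and there are no ties, normal approximation with tie/continuity
#' correction otherwise).
#'
#' @param mat 0/1 presence matrix (genomes x families).
#' @param groups named character vector, genome id -> group.
#' @param group_a,group_b the two group labels to compare.
#' @return list with `summary` (per-group n, median, mean), `statistic`
#'   (the U statistic of the first sample) and `p_value`.
#' @export
within_group_similarity_test <- function(mat, groups, group_a, group_b) {
  sims <- function(g) {
    ids <- intersect(rownames(mat), names(groups)[groups == g])
    if (length(ids) < 2L)
      stop(sprintf("group %s has fewer than 2 genomes", g))
    d <- jaccard_distance(mat[ids, , drop = FALSE], "rows")
    1 - as.numeric(d)
  }
  sa <- sims(group_a)
  sb <- sims(group_b)
  exact <- (length(sa) + length(sb)) <= 20L && !anyDuplicated(c(sa, sb))
  wt <- suppressWarnings(wilcox.test(sa, sb, exact = exact,
                                     correct = !exact))
  list(summary = data.frame(group = c(group_a, group_b),
                            n_pairs = c(length(sa), length(sb)),
                            median = c(median(sa), median(sb)),
                            mean = c(mean(sa), mean(sb))),
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Export a dendrogram or tree to Newick
#'
#' Dendrogram merge heights are preserved: the patristic distance between
#' two leaves of the exported tree equals their cophenetic distance in the
#' dendrogram.
#'
#' @param tree an `hclust` or `phylo` object.
#' @return a Newick string (terminated by `;`).
#' @export
to_newick <- function(tree) {
  phy <- if (inherits(tree, "hclust")) ape::as.phylo(tree) else tree
  stopifnot(inherits(phy, "phylo"))
  ape::write.tree(phy)
}

#' Parse a Newick string
#'
#' @param text a Newick string.
#' @return a `phylo` tree.
#' @export
read_newick <- function(text) {
  opens <- cumsum((strsplit(text, "")[[1]] == "(") -
                    (strsplit(text, "")[[1]] == ")"))
  if (length(opens) && (any(opens < 0) || opens[length(opens)] != 0)) {
    pos <- if (any(opens < 0)) which(opens < 0)[1] else length(opens)
    stop(sprintf("unbalanced parentheses in Newick string at position %d",
                 pos))
  }
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy)) stop("malformed Newick string")
  phy
}
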