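# Co-occurring family modules: Jaccard co-occurrence network over family
# presence/absence profiles, Louvain community detection, module-size
# filtering, median-m taxonomic assignment and widespread-module selection.

#' Family co-occurrence network from a presence matrix
#'
#' For each family pair, the Jaccard index of their presence profiles
#' across genomes: `J = |both| / |either|`.  An edge is stored iff
#' `J > threshold` (strict).  Families present nowhere have undefined J and
#' stay isolated.
#'
#' @param mat 0/1 presence matrix (genomes x families).
#' @param threshold Jaccard threshold, strict (default 0.4).
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (family ids) and `edges` (data.frame `a`, `b`, `weight` = J).
#' @export
family_jaccard_network <- function(mat, threshold = 0.4) {
  if (!is.matrix(mat) || ncol(mat) == 0L) stop("empty presence matrix")
  storage.mode(mat) <- "numeric"
  inter <- crossprod(mat)                      # families x families
  s <- diag(inter)
  union <- outer(s, s, "+") - inter
  J <- ifelse(union > 0, inter / union, 0)
  diag(J) <- 0
  idx <- which(upper.tri(J) & J > threshold, arr.ind = TRUE)
  fams <- colnames(mat)
  structure(list(nodes = fams,
                 edges = data.frame(a = fams[idx[, 1L]],
                                    b = fams[idx[, 2L]],
                                    weight = J[idx],
                                    stringsAsFactors = FALSE)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Family co-occurrence network: %d families, %d edges (J > threshold)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Louvain community detection
#'
#' Standard two-phase Louvain on a weighted undirected network: repeated
#' local moving of nodes to the neighboring community with the largest
#' modularity gain, then aggregation of communities into super-nodes, until
#' no further gain.  Node visitation order is shuffled by a seeded RNG each
#' pass, so the result is deterministic given the seed.  Modularity is
#' non-decreasing across levels (recorded in the result).
#'
#' @param network a [family_jaccard_network()] result, or any list with
#'   `nodes` and `edges` (`a`, `b`, `weight`).
#' @param seed integer seed for the node visitation order.
#' @param resolution resolution parameter gamma (default 1.0, the classic
#'   modularity).
#' @return object of class `module_partition`: list with `membership`
#'   (data.frame `family_id`, `module_id`), `modularity` (final weighted Q),
#'   `q_levels` (Q after each aggregation level) and `seed`.  Isolated nodes
#'   form singleton modules; an empty network yields an empty partition.
#' @export
louvain <- function(network, seed = 1L, resolution = 1.0) {
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0L)
    return(structure(list(membership = data.frame(family_id = character(),
                                                  module_id = character()),
                          modularity = NA_real_, q_levels = numeric(0),
                          seed = seed),
                     class = "module_partition"))
  ei <- match(network$edges$a, nodes)
  ej <- match(network$edges$b, nodes)
  w <- network$edges$weight
  keep <- ei != ej
  ei <- ei[keep]; ej <- ej[keep]; w <- w[keep]
  if (any(w < 0)) stop("edge weights must be non-negative")
  # community of each original node, updated level by level
  node_comm <- seq_len(n)
  q_levels <- numeric(0)
  lv_ei <- ei; lv_ej <- ej; lv_w <- w
  lv_self <- numeric(n)      # self-loop weights (appear on aggregation)
  lv_map <- seq_len(n)       # original node -> current level node
  level_seed <- seed
  repeat {
    nn <- max(c(lv_map, 1L))
    res <- louvain_one_level(nn, lv_ei, lv_ej, lv_w, lv_self,
                             resolution, level_seed)
    comm <- res$comm
    q_levels <- c(q_levels, res$q)
    node_comm <- comm[lv_map]
    if (res$n_comm == nn) break  # no aggregation possible -> done
    # aggregate
    lv_map <- node_comm
    agg <- aggregate_graph(comm, lv_ei, lv_ej, lv_w, lv_self, res$n_comm)
    lv_ei <- agg$ei; lv_ej <- agg$ej; lv_w <- agg$w; lv_self <- agg$self
    if (!res$moved) break  # converged: last level made no move
    level_seed <- level_seed + 1L
  }
  # stable module ids ordered by first member
  first <- vapply(split(seq_len(n), node_comm), min, 1L)
  ranks <- rank(first, ties.method = "first")
  module <- sprintf("mod%04d", ranks[match(as.character(node_comm),
                                           names(first))])
  q <- if (length(q_levels)) q_levels[length(q_levels)] else 0
  structure(list(membership = data.frame(family_id = nodes,
                                         module_id = module,
                                         stringsAsFactors = FALSE),
                 modularity = q, q_levels = q_levels, seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- table(x$membership$module_id)
  cat(sprintf("Louvain partition: %d families in %d modules (Q = %.4f, seed %d)\n",
              nrow(x$membership), length(sizes), x$modularity, x$seed))
  cat(sprintf("  module sizes: largest %s\n",
              paste(head(sort(as.integer(sizes), decreasing = TRUE), 6L),
                    collapse = ", ")))
  invisible(x)
}

# one local-moving phase; returns renumbered communities, final Q, count,
# and whether any node moved
louvain_one_level <- function(n, ei, ej, w, selfw, resolution, seed) {
  adj_n <- split(c(ej, ei), factor(c(ei, ej), levels = seq_len(n)))
  adj_w <- split(c(w, w), factor(c(ei, ej), levels = seq_len(n)))
  k <- vapply(adj_w, sum, 0) + 2 * selfw   # weighted degree incl. self-loop
  m2 <- sum(k)                             # = 2m
  comm <- seq_len(n)
  tot <- k
  moved_any <- FALSE
  if (m2 > 0) {
    repeat {
      moved <- FALSE
      order_pass <- with_seed(seed, sample.int(n))
      for (i in order_pass) {
        ci <- comm[i]
        nb <- adj_n[[i]]; nw <- adj_w[[i]]
        if (!length(nb)) next
        tot[ci] <- tot[ci] - k[i]
        wc <- tapply(nw, comm[nb], sum)     # weight to each neighbor comm
        cand <- as.integer(names(wc))
        wc <- as.numeric(wc)
        if (!(ci %in% cand)) { cand <- c(cand, ci); wc <- c(wc, 0) }
        gain <- wc - resolution * k[i] * tot[cand] / m2
        att <- cand[gain >= max(gain) - 1e-12]
        target <- if (ci %in% att) ci else min(att)  # ties: stay, else lowest id
        if (target != ci) { moved <- TRUE; moved_any <- TRUE }
        comm[i] <- target
        tot[target] <- tot[target] + k[i]
      }
      seed <- seed + 1000L
      if (!moved) break
    }
  }
  # renumber communities consecutively
  uc <- sort(unique(comm))
  comm <- match(comm, uc)
  q <- modularity_of(comm, ei, ej, w, selfw, resolution)
  list(comm = comm, q = q, n_comm = length(uc), moved = moved_any)
}

aggregate_graph <- function(comm, ei, ej, w, selfw, n_comm) {
  ci <- comm[ei]; cj <- comm[ej]
  internal <- ci == cj
  new_self <- numeric(n_comm)
  if (any(internal)) {
    t1 <- tapply(w[internal], ci[internal], sum)
    new_self[as.integer(names(t1))] <- t1
  }
  t2 <- tapply(selfw, comm, sum)
  new_self[as.integer(names(t2))] <- new_self[as.integer(names(t2))] + t2
  a <- pmin(ci[!internal], cj[!internal])
  b <- pmax(ci[!internal], cj[!internal])
  ww <- w[!internal]
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    agg <- tapply(ww, key, sum)
    ab <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    list(ei = as.integer(ab[, 1L]), ej = as.integer(ab[, 2L]),
         w = as.numeric(agg), self = new_self)
  } else {
    list(ei = integer(0), ej = integer(0), w = numeric(0), self = new_self)
  }
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c (in_c / 2m - gamma * (tot_c / 2m)^2)` with each undirected
#' edge counted in both directions.
#'
#' @param comm integer community per node.
#' @param ei,ej,w edge endpoints (indices) and weights.
#' @param selfw per-node self-loop weights.
#' @param resolution gamma.
#' @keywords internal
modularity_of <- function(comm, ei, ej, w, selfw = numeric(length(comm)),
                          resolution = 1.0) {
  n <- length(comm)
  deg <- numeric(n)
  if (length(ei)) {
    t1 <- tapply(c(w, w), c(ei, ej), sum)
    deg[as.integer(names(t1))] <- t1
  }
  deg <- deg + 2 * selfw
  m2 <- sum(deg)
  if (m2 == 0) return(0)
  internal <- comm[ei] == comm[ej]
  in_c <- numeric(max(comm))
  if (any(internal)) {
    t2 <- tapply(2 * w[internal], comm[ei][internal], sum)
    in_c[as.integer(names(t2))] <- t2
  }
  t3 <- tapply(2 * selfw, comm, sum)
  in_c[as.integer(names(t3))] <- in_c[as.integer(names(t3))] + t3
  tot <- numeric(max(comm))
  t4 <- tapply(deg, comm, sum)
  tot[as.integer(names(t4))] <- t4
  sum(in_c / m2 - resolution * (tot / m2)^2)
}

#' Filter modules by size
#'
#' Modules with at least `min_size` families are kept (boundary inclusive);
#' families in smaller modules are flagged unassigned.
#'
#' @param partition a [louvain()] result.
#' @param min_size minimum family count (default 10).
#' @return data.frame `family_id`, `module_id`, `assigned` (logical);
#'   attribute `modules` lists the retained module ids and sizes.
#' @export
filter_modules <- function(partition, min_size = 10L) {
  mem <- partition$membership
  sizes <- table(mem$module_id)
  keep <- names(sizes)[sizes >= min_size]
  mem$assigned <- mem$module_id %in% keep
  attr(mem, "modules") <- data.frame(module_id = keep,
                                     size = as.integer(sizes[keep]),
                                     stringsAsFactors = FALSE)
  mem
}

#' Taxonomic assignment of a module by the median-m rule
#'
#' For the module's families, m is the median number of genomes per family
#' (lower median for even counts: m indexes a number of genomes).  Genomes
#' are ranked by the number of module families they carry (descending, ties
#' by genome id) and the top m are retained; their phylum distribution is
#' the module's taxonomic assignment.
#'
#' @param families character vector of the module's family ids.
#' @param mat 0/1 presence matrix containing those families as columns.
#' @param taxonomy data.frame `genome_id`, `group`, `phylum`.
#' @return list with `m`, `genomes` (the retained genome ids), `phyla`
#'   (phylum -> genome count) and `groups` (group -> genome count).
#' @export
assign_module_taxonomy <- function(families, mat, taxonomy) {
  if (!length(families)) stop("empty module")
  if (!all(families %in% colnames(mat)))
    stop("module families missing from the matrix")
  sub <- mat[, families, drop = FALSE]
  counts <- colSums(sub)
  m <- as.integer(sort(counts)[floor((length(counts) + 1) / 2)])
  per_genome <- rowSums(sub)
  o <- order(-per_genome, rownames(sub))
  top <- rownames(sub)[o][seq_len(min(m, nrow(sub)))]
  tx <- taxonomy[match(top, taxonomy$genome_id), ]
  list(m = m, genomes = top,
       phyla = table(tx$phylum), groups = table(tx$group))
}

#' Select widespread modules
#'
#' A module is widespread iff its taxonomic assignment spans at least
#' `phylum_min` distinct CPR phyla or at least `phylum_min` distinct
#' non-CPR bacterial phyla.
#'
#' @param module_taxa named list of [assign_module_taxonomy()] results (one
#'   per module).
#' @param taxonomy data.frame `genome_id`, `group`, `phylum`.
#' @param phylum_min phylum count threshold (default 10, inclusive).
#' @return data.frame `module_id`, `m`, `n_cpr_phyla`, `n_bac_phyla`,
#'   `widespread`.
#' @export
select_widespread_modules <- function(module_taxa, taxonomy,
                                      phylum_min = 10L) {
  rows <- lapply(names(module_taxa), function(id) {
    mt <- module_taxa[[id]]
    tx <- taxonomy[match(mt$genomes, taxonomy$genome_id), ]
    n_cpr <- length(unique(tx$phylum[tx$group == "CPR"]))
    n_bac <- length(unique(tx$phylum[tx$group == "BAC"]))
    data.frame(module_id = id, m = mt$m, n_cpr_phyla = n_cpr,
               n_bac_phyla = n_bac,
               widespread = n_cpr >= phylum_min || n_bac >= phylum_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full module-detection stage
#'
#' Convenience wrapper: Jaccard network, Louvain, size filter, per-module
#' taxonomy and widespread selection.
#'
#' @param mat 0/1 presence matrix.
#' @param taxonomy data.frame `genome_id`, `group`, `phylum`.
#' @param jaccard_threshold strict Jaccard edge threshold (default 0.4).
#' @param min_module_size minimum families per retained module (default 10).
#' @param phylum_min widespread phylum threshold (default 10).
#' @param seed Louvain seed.
#' @return list with `network`, `partition`, `membership` (with `assigned`),
#'   `summary` (module table with m, phylum spans, widespread flag) and
#'   `widespread_families`.
#' @export
detect_modules <- function(mat, taxonomy, jaccard_threshold = 0.4,
                           min_module_size = 10L, phylum_min = 10L,
                           seed = 1L) {
  net <- family_jaccard_network(mat, threshold = jaccard_threshold)
  part <- louvain(net, seed = seed)
  mem <- filter_modules(part, min_size = min_module_size)
  mods <- attr(mem, "modules")
  taxa <- lapply(setNames(mods$module_id, mods$module_id), function(id)
    assign_module_taxonomy(mem$family_id[mem$module_id == id], mat,
                           taxonomy))
  summ <- if (length(taxa)) {
    s <- select_widespread_modules(taxa, taxonomy, phylum_min)
    s$size <- mods$size[match(s$module_id, mods$module_id)]
    s[, c("module_id", "size", "m", "n_cpr_phyla", "n_bac_phyla",
          "widespread")]
  } else {
    data.frame(module_id = character(), size = integer(), m = integer(),
               n_cpr_phyla = integer(), n_bac_phyla = integer(),
               widespread = logical())
  }
  wide <- mem$family_id[mem$module_id %in%
                          summ$module_id[summ$widespread] & mem$assigned]
  list(network = net, partition = part, membership = mem, summary = summ,
       module_taxa = taxa, widespread_families = wide)
}
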