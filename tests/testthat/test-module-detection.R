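# Jaccard co-occurrence network, Louvain community detection, module-size
# filter, median-m taxonomy and widespread-module selection.

test_that("Jaccard network edges follow the strict threshold", {
  mat <- cbind(f1 = c(1, 1, 0, 1), f2 = c(1, 0, 0, 1), f3 = c(0, 0, 1, 0),
               f4 = c(1, 1, 0, 1), f5 = c(0, 0, 0, 0))
  rownames(mat) <- sprintf("g%d", 1:4)
  netw <- family_jaccard_network(mat, threshold = 0.4)
  key <- paste(netw$edges$a, netw$edges$b)
  # identical profiles: J = 1
  expect_equal(netw$edges$weight[key == "f1 f4"], 1)
  # (1,1,0,1) vs (1,0,0,1): J = 2/3 > 0.4
  expect_equal(netw$edges$weight[key == "f1 f2"], 2 / 3)
  # disjoint profiles: no edge; empty profiles: isolated
  expect_false(any(grepl("f3", key)))
  expect_false(any(grepl("f5", key)))
  expect_true("f5" %in% netw$nodes)
  # raising the threshold never increases the edge count
  counts <- vapply(seq(0, 1, 0.1), function(th)
    nrow(family_jaccard_network(mat, th)$edges), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("Louvain separates cliques and maximizes modularity on small graphs", {
  # no edges: every family its own module, Q = 0
  empty <- net(c("f1", "f2", "f3"), character(0), character(0), numeric(0))
  p0 <- louvain(empty, seed = 1)
  expect_identical(length(unique(p0$membership$module_id)), 3L)
  expect_equal(p0$modularity, 0)
  # single clique: one module
  cmb <- combn(4, 2)
  clique <- net(sprintf("f%d", 1:4), sprintf("f%d", cmb[1, ]),
                sprintf("f%d", cmb[2, ]))
  expect_identical(length(unique(louvain(clique, 1)$membership$module_id)), 1L)
  # two 5-cliques joined by one edge: the clique split
  c5 <- combn(5, 2)
  nodes <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  edges <- data.frame(a = c(sprintf("a%d", c5[1, ]), sprintf("b%d", c5[1, ]), "a1"),
                      b = c(sprintf("a%d", c5[2, ]), sprintf("b%d", c5[2, ]), "b1"),
                      weight = 1)
  p2 <- louvain(list(nodes = nodes, edges = edges), seed = 1)
  expect_identical(adjusted_rand(p2$membership$module_id,
                                 rep(c("A", "B"), each = 5)), 1)
  # exhaustive oracle at n = 8 (two 4-cliques joined by one edge):
  # the Louvain partition attains the global modularity maximum
  c4 <- combn(4, 2)
  nodes8 <- sprintf("n%d", 1:8)
  e8 <- data.frame(a = nodes8[c(c4[1, ], c4[1, ] + 4, 1)],
                   b = nodes8[c(c4[2, ], c4[2, ] + 4, 5)], weight = 1)
  A8 <- matrix(0, 8, 8)
  for (r in seq_len(nrow(e8))) {
    i <- match(e8$a[r], nodes8); j <- match(e8$b[r], nodes8)
    A8[i, j] <- A8[j, i] <- 1
  }
  best_q <- max(vapply(all_partitions(8), function(p)
    ref_modularity(A8, p), 0))
  p8 <- louvain(list(nodes = nodes8, edges = e8), seed = 1)
  expect_equal(p8$modularity, best_q, tolerance = 1e-12)
  expect_equal(ref_modularity(A8, as.integer(factor(p8$membership$module_id))),
               p8$modularity, tolerance = 1e-12)
})

test_that("Louvain is deterministic given the seed and Q never decreases", {
  tr <- small_truth()
  mat <- generate_presence_matrix(tr)$matrix
  netw <- family_jaccard_network(mat)
  p1 <- louvain(netw, seed = 7)
  p2 <- louvain(netw, seed = 7)
  expect_identical(p1$membership, p2$membership)
  expect_true(all(diff(p1$q_levels) >= -1e-12))
  # partition is an exact cover of the network nodes
  expect_setequal(p1$membership$family_id, netw$nodes)
  expect_false(anyDuplicated(p1$membership$family_id) > 0)
})

test_that("Louvain agrees with an independent implementation on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (rep in 1:5) {
    n <- 30
    e <- t(combn(n, 2))
    keep <- runif(nrow(e)) < 0.12
    e <- e[keep, , drop = FALSE]
    w <- runif(nrow(e), 0.5, 1)
    nodes <- sprintf("v%02d", 1:n)
    ours <- louvain(list(nodes = nodes,
                         edges = data.frame(a = nodes[e[, 1]],
                                            b = nodes[e[, 2]], weight = w)),
                    seed = rep)
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[e[, 1]], to = nodes[e[, 2]], weight = w),
      directed = FALSE, vertices = nodes)
    ig <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    # same modularity scale: our reported Q matches igraph's for our partition
    q_ours_ig <- igraph::modularity(
      g, as.integer(factor(ours$membership$module_id)),
      weights = igraph::E(g)$weight)
    expect_equal(ours$modularity, q_ours_ig, tolerance = 1e-9)
    # and our optimum is at least as good as igraph's up to small slack
    expect_gte(ours$modularity, igraph::modularity(ig) - 0.02)
  }
})

test_that("module size filter is inclusive at the threshold", {
  mem <- data.frame(family_id = sprintf("f%02d", 1:22),
                    module_id = rep(c("m1", "m2", "m3"), c(10, 9, 3)))
  part <- structure(list(membership = mem), class = "module_partition")
  out <- filter_modules(part, min_size = 10)
  expect_true(all(out$assigned[out$module_id == "m1"]))
  expect_false(any(out$assigned[out$module_id %in% c("m2", "m3")]))
  expect_identical(attr(out, "modules")$module_id, "m1")
  out1 <- filter_modules(part, min_size = 1)
  expect_true(all(out1$assigned))
})

test_that("median-m taxonomy follows the hand-worked example", {
  # f1 in {g1,g2}, f2 in {g1,g2,g3}, f3 in {g1,g2,g3,g4}
  mat <- cbind(f1 = c(1, 1, 0, 0, 0), f2 = c(1, 1, 1, 0, 0),
               f3 = c(1, 1, 1, 1, 0))
  rownames(mat) <- sprintf("g%d", 1:5)
  tax <- data.frame(genome_id = sprintf("g%d", 1:5), group = "BAC",
                    phylum = c("pA", "pA", "pB", "pC", "pD"))
  mt <- assign_module_taxonomy(c("f1", "f2", "f3"), mat, tax)
  expect_identical(mt$m, 3L)  # median of (2, 3, 4)
  expect_setequal(mt$genomes, c("g1", "g2", "g3"))
  expect_identical(as.integer(mt$phyla[c("pA", "pB")]), c(2L, 1L))
  # lower median for even counts
  mt2 <- assign_module_taxonomy(c("f1", "f3"), mat, tax)
  expect_identical(mt2$m, 2L)  # lower median of (2, 4)
  # all families in one genome
  mat1 <- cbind(fx = c(1, 0, 0, 0, 0), fy = c(1, 0, 0, 0, 0))
  rownames(mat1) <- sprintf("g%d", 1:5)
  mt3 <- assign_module_taxonomy(c("fx", "fy"), mat1, tax)
  expect_identical(mt3$m, 1L)
  expect_identical(mt3$genomes, "g1")
  expect_error(assign_module_taxonomy(character(0), mat, tax), "empty")
})

test_that("widespread selection needs 10 phyla in one superclade", {
  tax <- data.frame(genome_id = sprintf("g%02d", 1:24),
                    group = rep(c("CPR", "BAC"), each = 12),
                    phylum = c(sprintf("cp%02d", 1:12), sprintf("bp%02d", 1:12)))
  taxa <- list(
    wide_bac = list(m = 12L, genomes = sprintf("g%02d", 13:24)),
    narrow = list(m = 3L, genomes = sprintf("g%02d", c(1, 2, 13))),
    wide_cpr = list(m = 11L, genomes = sprintf("g%02d", 1:11)))
  out <- select_widespread_modules(taxa, tax)
  expect_identical(out$widespread[match(c("wide_bac", "narrow", "wide_cpr"),
                                        out$module_id)],
                   c(TRUE, FALSE, TRUE))
  expect_identical(out$n_bac_phyla[out$module_id == "wide_bac"], 12L)
})

test_that("planted universal/CPR/BAC modules are recovered as the widespread set", {
  tr <- default_truth(seed = 3)
  pm <- generate_presence_matrix(tr)
  mod <- detect_modules(pm$matrix, pm$taxonomy, seed = 3)
  expect_identical(sum(mod$summary$widespread), 3L)
  wide_classes <- unique(tr$families$class[
    match(mod$widespread_families, tr$families$family_id)])
  expect_setequal(wide_classes, c("universal", "cpr_enriched", "bac_enriched"))
  # lineage blocks are modules but not widespread; background is unassigned
  expect_identical(nrow(mod$summary), 9L)  # 3 widespread + 6 lineage blocks
  bg <- tr$families$family_id[tr$families$class == "background"]
  expect_false(any(mod$membership$assigned[
    mod$membership$family_id %in% bg]))
})
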