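# Jaccard distances, agglomerative dendrograms, cophenetic comparison,
# branch collapsing with wedge counts, within-group similarity testing and
# Newick round trips.

make_hclust <- function(merge, height, labels) {
  structure(list(merge = merge, height = height,
                 order = seq_along(labels), labels = labels,
                 method = "complete"), class = "hclust")
}

test_that("Jaccard distances follow the set formula", {
  mat <- rbind(g1 = c(1, 1, 0, 1), g2 = c(1, 0, 0, 1), g3 = c(0, 0, 1, 0),
               g4 = c(1, 1, 0, 1))
  d <- as.matrix(jaccard_distance(mat, "rows"))
  expect_equal(d["g1", "g4"], 0)            # identical rows
  expect_equal(d["g1", "g3"], 1)            # disjoint non-empty rows
  expect_equal(d["g1", "g2"], 1 - 2 / 3)    # (1,1,0,1) vs (1,0,0,1)
  expect_true(isSymmetric(d))
  # both profiles empty: distance 0 with a warning
  m0 <- rbind(a = c(0, 0), b = c(0, 0))
  expect_warning(d0 <- jaccard_distance(m0, "rows"), "empty union")
  expect_equal(as.numeric(d0), 0)
})

test_that("linkage definitions give the forced three-point merge heights", {
  d <- as.dist(matrix(c(0, .1, .9, .1, 0, .8, .9, .8, 0), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  expect_equal(agglomerative(d, "complete")$height, c(0.1, 0.9))
  expect_equal(agglomerative(d, "single")$height, c(0.1, 0.8))
  expect_equal(agglomerative(d, "average")$height, c(0.1, 0.85))
  expect_error(agglomerative(stats::as.dist(matrix(0, 1, 1))), "at least 2")
})

test_that("cophenetic correlation: identity, scale invariance, symmetry", {
  tr <- small_truth()
  mat <- generate_presence_matrix(tr)$matrix
  tree <- agglomerative(jaccard_distance(mat, "rows"), "complete")
  expect_equal(cophenetic_correlation(tree, tree), 1.0)
  scaled <- tree
  scaled$height <- tree$height * 2
  expect_equal(cophenetic_correlation(tree, scaled), 1.0)
  tree2 <- agglomerative(jaccard_distance(mat, "rows"), "single")
  expect_equal(cophenetic_correlation(tree, tree2),
               cophenetic_correlation(tree2, tree))
  # star tree: zero variance is undefined, not a number
  star <- make_hclust(rbind(c(-1, -2), c(1, -3)), c(0.5, 0.5),
                      c("A", "B", "C"))
  expect_warning(r <- cophenetic_correlation(star, star), "zero variance")
  expect_true(is.na(r))
})

test_that("cophenetic correlation matches the 6-pair hand calculation", {
  # caterpillar (A,B)@0.2, (+C)@0.5, (+D)@0.9 vs the same shape with the
  # deep pair swapped against the shallow leaf: (D,B)@0.2, (+C)@0.5, (+A)@0.9
  t1 <- make_hclust(rbind(c(-1, -2), c(1, -3), c(2, -4)), c(.2, .5, .9),
                    c("A", "B", "C", "D"))
  t2 <- make_hclust(rbind(c(-1, -2), c(1, -3), c(2, -4)), c(.2, .5, .9),
                    c("D", "B", "C", "A"))
  # pairs in order AB, AC, AD, BC, BD, CD, enumerated by hand
  v1 <- c(.2, .5, .9, .5, .9, .9)
  v2 <- c(.9, .9, .9, .5, .2, .5)
  expect_equal(cophenetic_correlation(t1, t2), cor(v1, v2))
  expect_equal(cophenetic_correlation(t1, t2), -0.494253, tolerance = 1e-6)
})

test_that("hclust and phylo routes give the same cophenetic distances", {
  tr <- small_truth()
  mat <- generate_presence_matrix(tr)$matrix[1:20, ]
  tree <- agglomerative(jaccard_distance(mat, "rows"), "average")
  phy <- read_newick(to_newick(tree))
  expect_equal(cophenetic_correlation(tree, phy), 1.0, tolerance = 1e-9)
})

test_that("branch collapsing contracts short edges into wedges", {
  # A,B merge at 0.1, then C at 1.0: edge lengths A/B 0.1, (AB) 0.9, C 1.0
  tree <- make_hclust(rbind(c(-1, -2), c(1, -3)), c(0.1, 1.0),
                      c("A", "B", "C"))
  groups <- c(A = "CPR", B = "CPR", C = "BAC")
  ws <- collapse_and_count(tree, 0.25, groups)
  expect_identical(ws$n_wedges, 2L)
  expect_identical(unname(ws$group_counts[c("CPR", "BAC")]), c(1L, 1L))
  sizes <- sort(ws$wedges$size)
  expect_identical(sizes, c(1L, 2L))
  # fraction 0: no contraction, every leaf its own wedge
  expect_identical(collapse_and_count(tree, 0, groups)$n_wedges, 3L)
  # fraction above 1 contracts every edge into a single wedge
  expect_identical(collapse_and_count(tree, 1.5, groups)$n_wedges, 1L)
  # mixed wedges count toward every group present, with purity reported
  tree2 <- make_hclust(rbind(c(-1, -2), c(1, -3), c(2, -4)),
                       c(0.01, 0.02, 1.0), c("A", "B", "C", "D"))
  groups2 <- c(A = "CPR", B = "BAC", C = "CPR", D = "ARC")
  ws2 <- collapse_and_count(tree2, 0.25, groups2)
  expect_identical(ws2$n_wedges, 2L)
  expect_identical(unname(ws2$group_counts[c("CPR", "BAC", "ARC")]),
                   c(1L, 1L, 1L))
  mixed <- ws2$wedges[ws2$wedges$size == 3, ]
  expect_equal(mixed$purity, 2 / 3)
})

test_that("collapsing a planted two-superclade tree and 2-cut recovery", {
  tr <- small_truth()
  pm <- generate_presence_matrix(tr)
  wide <- tr$families$family_id[tr$families$class != "background"]
  tree <- agglomerative(jaccard_distance(pm$matrix[, wide], "rows"),
                        "complete")
  cut2 <- cutree(tree, k = 2)
  expect_gte(adjusted_rand(cut2, pm$taxonomy$group), 0.95)
  ws <- collapse_and_count(tree, 0.25,
                           setNames(pm$taxonomy$group,
                                    pm$taxonomy$genome_id))
  expect_identical(sum(ws$wedges$size), nrow(pm$matrix))  # wedges partition
})

test_that("within-group similarity comparison uses an exact two-sided U test", {
  fams <- sprintf("f%02d", 1:13)
  rows <- list(
    c1 = 1:4, c2 = 4:7, c3 = 7:11,        # sims 1/7, 0, 1/8 (all distinct)
    b1 = 1:10, b2 = 1:9, b3 = 1:8)        # sims 9/10, 8/10, 8/9
  mat <- t(vapply(rows, function(ix) as.integer(seq_along(fams) %in% ix),
                  integer(13)))
  colnames(mat) <- fams
  groups <- c(c1 = "CPR", c2 = "CPR", c3 = "CPR",
              b1 = "BAC", b2 = "BAC", b3 = "BAC")
  res <- within_group_similarity_test(mat, groups, "CPR", "BAC")
  expect_identical(unname(res$statistic), 0)   # every CPR sim below every BAC sim
  expect_equal(res$p_value, 0.1)               # exact: 2 / choose(6, 3)
  expect_error(within_group_similarity_test(mat[-(1:2), ], groups,
                                            "CPR", "BAC"), "fewer than 2")
  # identical samples: p = 1 (up to tie handling)
  mat2 <- mat[c(4:6, 4:6), ]
  rownames(mat2) <- names(groups)
  expect_equal(within_group_similarity_test(mat2, groups, "CPR",
                                            "BAC")$p_value, 1)
})

test_that("higher CPR dropout yields detectably lower within-CPR similarity", {
  base <- default_truth(seed = 17)
  drop <- ifelse(base$genomes$group == "CPR", 0.25, 0.05)
  tr <- pangenome_truth(base$genomes, base$families, base$presence_prob,
                        dropout = drop, seed = 17)
  pm <- generate_presence_matrix(tr)
  groups <- setNames(pm$taxonomy$group, pm$taxonomy$genome_id)
  res <- within_group_similarity_test(pm$matrix, groups, "CPR", "BAC")
  expect_lt(res$p_value, 0.01)
  expect_lt(res$summary$median[1], res$summary$median[2])
})

test_that("Newick export and parsing round-trip topology and lengths", {
  phy <- read_newick("(A:1,B:1):0;")
  expect_identical(sort(phy$tip.label), c("A", "B"))
  expect_identical(read_newick(to_newick(phy))$edge.length, phy$edge.length)
  # 50-leaf random dendrogram: identical cophenetic matrix after round trip
  set.seed(8)
  m <- matrix(rbinom(50 * 40, 1, 0.4), 50,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("f%02d", 1:40)))
  tree <- agglomerative(jaccard_distance(m, "rows"), "complete")
  phy2 <- read_newick(to_newick(tree))
  c1 <- as.matrix(cophenetic(tree))
  c2 <- ape::cophenetic.phylo(phy2)
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-9)
  expect_error(read_newick("((A:1,B:1:0;"), "position")
})
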