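# Two-step homology clustering: similarity-graph filtering, greedy set
# cover, profile-match filtering, Markov clustering, and annotation QC.

m8_row <- function(q, t, evalue = 1e-20, qcov = 0.95, tcov = 0.95) {
  data.frame(query = q, target = t, identity = 95, alnlen = 100,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 100, tstart = 1,
             tend = 100, evalue = evalue, bits = 300, qcov = qcov,
             tcov = tcov, stringsAsFactors = FALSE)
}

test_that("similarity edges are filtered on e-value and min coverage", {
  hits <- rbind(m8_row("p1", "p2", evalue = 1e-5, qcov = 0.6, tcov = 0.9),
                m8_row("p1", "p3", evalue = 0.01, qcov = 0.9, tcov = 0.9),
                m8_row("p2", "p3", evalue = 1e-9, qcov = 0.9, tcov = 0.4),
                m8_row("p1", "p1"))
  g <- build_similarity_graph(hits)
  expect_identical(g$edges,
                   data.frame(from = "p1", to = "p2",
                              stringsAsFactors = FALSE))
  expect_setequal(g$nodes, c("p1", "p2", "p3"))
  # proteins with no passing edges become singleton subfamilies
  g2 <- build_similarity_graph(hits[2:3, ], proteins = c("p1", "p2", "p3"))
  subs <- greedy_set_cover(g2)
  expect_identical(length(unique(subs$subfamily_id)), 3L)
  expect_identical(subs$representative, subs$protein_id)
})

test_that("greedy set cover picks maximal closed neighborhoods deterministically", {
  # star c-l1, c-l2, c-l3 plus isolated x
  hits <- rbind(m8_row("c", "l1"), m8_row("c", "l2"), m8_row("c", "l3"))
  g <- build_similarity_graph(hits, proteins = c("c", "l1", "l2", "l3", "x"))
  subs <- greedy_set_cover(g)
  by_sub <- split(subs$protein_id, subs$subfamily_id)
  expect_setequal(vapply(by_sub, paste, "", collapse = " "),
                  c("c l1 l2 l3", "x"))
  expect_identical(unique(subs$representative[subs$protein_id != "x"]), "c")
  # path a-b-c: the degree-2 middle node covers all three
  # (verified by exhaustive set cover: {N[b]} is the only single-set cover)
  gp <- build_similarity_graph(rbind(m8_row("a", "b"), m8_row("b", "c")))
  sp <- greedy_set_cover(gp)
  expect_identical(length(unique(sp$subfamily_id)), 1L)
  expect_identical(unique(sp$representative), "b")
  # two disjoint triangles -> exactly two subfamilies
  tri <- rbind(m8_row("t1", "t2"), m8_row("t2", "t3"), m8_row("t1", "t3"),
               m8_row("u1", "u2"), m8_row("u2", "u3"), m8_row("u1", "u3"))
  st <- greedy_set_cover(build_similarity_graph(tri))
  expect_identical(length(unique(st$subfamily_id)), 2L)
  # invariance under edge order
  st2 <- greedy_set_cover(build_similarity_graph(tri[sample(6), ]))
  expect_identical(st, st2)
})

test_that("profile matches are thresholded and weighted as probability x coverage", {
  pm <- data.frame(subfamily_a = c("s1", "s2", "s3"),
                   subfamily_b = c("s2", "s3", "s1"),
                   probability = c(95, 94.9, 100),
                   coverage = c(0.50, 0.9, 1.0))
  netw <- filter_profile_matches(pm)
  expect_equal(netw$edges$weight[netw$edges$a == "s1" & netw$edges$b == "s2"],
               0.475)
  expect_equal(netw$edges$weight[netw$edges$a == "s1" & netw$edges$b == "s3"],
               1.0)
  expect_identical(nrow(netw$edges), 2L)  # the 94.9 match is dropped
  expect_error(filter_profile_matches(transform(pm, probability = c(101, 50, 50))),
               "probability")
  expect_error(filter_profile_matches(transform(pm, coverage = c(2, .5, .5))),
               "coverage")
})

test_that("MCL splits a barbell at the weak bridge and never merges components", {
  # two disconnected equal-weight triangles
  n1 <- net(c("a1", "a2", "a3", "b1", "b2", "b3"),
            c("a1", "a2", "a1", "b1", "b2", "b1"),
            c("a2", "a3", "a3", "b2", "b3", "b3"))
  cl <- mcl(n1$nodes, n1$edges)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(length(unique(cl[1:3])), 1L)
  expect_identical(length(unique(cl[4:6])), 1L)
  # barbell: two 4-cliques joined by one weight-0.1 edge
  nodes <- c(sprintf("x%d", 1:4), sprintf("y%d", 1:4))
  cmb <- combn(4, 2)
  edges <- data.frame(
    a = c(sprintf("x%d", cmb[1, ]), sprintf("y%d", cmb[1, ]), "x1"),
    b = c(sprintf("x%d", cmb[2, ]), sprintf("y%d", cmb[2, ]), "y1"),
    weight = c(rep(1, 12), 0.1), stringsAsFactors = FALSE)
  cl2 <- mcl(nodes, edges, inflation = 2.0)
  expect_identical(unname(split(nodes, cl2)[order(sapply(split(nodes, cl2), min))]),
                   list(sprintf("x%d", 1:4), sprintf("y%d", 1:4)))
  # independent dense reference implementation agrees
  A <- matrix(0, 8, 8)
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$a[r], nodes); j <- match(edges$b[r], nodes)
    A[i, j] <- A[j, i] <- edges$weight[r]
  }
  ref <- ref_mcl(A, inflation = 2.0)
  expect_identical(adjusted_rand(unname(cl2), ref), 1)
  # single isolated node -> singleton family
  cl3 <- mcl("solo", data.frame(a = character(), b = character(),
                                weight = numeric()))
  expect_identical(as.integer(cl3), 1L)
})

test_that("MCL validates inputs and reports convergence", {
  expect_error(mcl(c("a", "b"),
                   data.frame(a = "a", b = "b", weight = 1),
                   inflation = 1), "> 1")
  expect_error(mcl(c("a", "b"),
                   data.frame(a = "a", b = "b", weight = -1)),
               "non-negative")
  cl <- mcl(c("a", "b"), data.frame(a = "a", b = "b", weight = 1))
  expect_true(attr(cl, "converged"))
  # a path graph needs several expansion/inflation rounds to settle
  path4 <- data.frame(a = c("a", "b", "c"), b = c("b", "c", "d"), weight = 1)
  expect_warning(mcl(c("a", "b", "c", "d"), path4, max_iter = 1L),
                 "did not converge")
})

test_that("end-to-end clustering recovers planted families exactly at noise 0", {
  tr <- small_truth()
  pm <- generate_presence_matrix(tr)
  pr <- proteins_from_matrix(pm$matrix, seed = 21)
  st <- sequence_truth(pr, seed = 22)
  ht <- generate_hit_tables(st, noise = 0)
  cl <- cluster_proteins(ht$m8, ht$profiles, proteins = pr$protein_id,
                         profile_units = data.frame(
                           protein_id = pr$protein_id,
                           unit_id = pr$subfamily_id))
  mm <- match_families(cl$membership, pr)
  expect_identical(mm$subfamily_ari, 1)
  expect_identical(mm$family_ari, 1)
  expect_true(mm$exact)
  # exact partitions: every protein in exactly one subfamily and family
  expect_identical(sort(cl$membership$protein_id), sort(pr$protein_id))
  expect_false(anyNA(cl$membership$subfamily_id))
  sub_fam <- unique(cl$membership[, c("subfamily_id", "family_id")])
  expect_false(anyDuplicated(sub_fam$subfamily_id) > 0)
})

test_that("annotation admixture is the minority share of annotated members", {
  ann <- setNames(rep("K00001", 5), sprintf("p%d", 1:5))
  expect_equal(annotation_admixture(sprintf("p%d", 1:5), ann)$admixture, 0)
  # 11 of 20 K01889, 9 K01890 -> 45%
  ann2 <- setNames(rep(c("K01889", "K01890"), c(11, 9)), sprintf("p%d", 1:20))
  r2 <- annotation_admixture(sprintf("p%d", 1:20), ann2)
  expect_equal(r2$admixture, 45)
  expect_identical(r2$dominant, "K01889")
  # denominator is annotated members only: 4 of 20 annotated (3 A, 1 B)
  ann3 <- setNames(c("A", "A", "A", "B"), sprintf("p%d", 1:4))
  r3 <- annotation_admixture(sprintf("p%d", 1:20), ann3)
  expect_equal(r3$admixture, 25)
  expect_identical(r3$n_annotated, 4L)
  # no annotated member: undefined, not 0
  expect_true(is.na(annotation_admixture("p99", ann)$admixture))
  # modal ties break lexicographically
  ann4 <- setNames(c("Kb", "Ka"), c("p1", "p2"))
  expect_identical(annotation_admixture(c("p1", "p2"), ann4)$dominant, "Ka")
})

test_that("best family per annotation reports the largest share, ties to lower id", {
  mem <- data.frame(protein_id = sprintf("p%d", 1:12),
                    family_id = rep(c("famA", "famB"), c(9, 3)))
  ann <- setNames(c(rep("K1", 10), "K2", NA), sprintf("p%d", 1:12))
  out <- best_family_per_annotation(mem, ann)
  expect_equal(out$percent[out$annotation == "K1"], 90)
  expect_identical(out$family_id[out$annotation == "K1"], "famA")
  expect_equal(out$percent[out$annotation == "K2"], 100)
  # 5/5 split -> lower family id
  mem2 <- data.frame(protein_id = sprintf("p%d", 1:10),
                     family_id = rep(c("famB", "famA"), each = 5))
  ann2 <- setNames(rep("K9", 10), sprintf("p%d", 1:10))
  out2 <- best_family_per_annotation(mem2, ann2)
  expect_identical(out2$family_id, "famA")
  expect_equal(out2$percent, 50)
})

test_that("m8 round trip and malformed-row handling", {
  hits <- rbind(m8_row("p1", "p2"), m8_row("p2", "p3"))
  f <- tempfile(fileext = ".m8")
  write_m8(hits, f)
  back <- read_m8(f)
  expect_equal(back$evalue, hits$evalue)
  expect_identical(back$query, hits$query)
  # corrupt a numeric field
  lines <- readLines(f)
  lines[2] <- sub("1e-20", "not_a_number", lines[2])
  writeLines(lines, f)
  expect_warning(ok <- read_m8(f), "line")
  expect_identical(nrow(ok), 1L)
  expect_error(read_m8(f, on_error = "fail"), "malformed")
})
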