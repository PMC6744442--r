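# Two-step homology clustering: subfamilies by greedy set cover on the
# filtered similarity graph, families by Markov clustering of the
# profile-match network.  The all-vs-all search and the profile-profile
# alignment themselves are consumed as tabular inputs; the clustering logic
# starts at graph construction.

#' Build the protein similarity graph from filtered m8 hits
#'
#' An undirected edge is retained iff `evalue <= evalue_max` and
#' `min(qcov, tcov) >= cover_min`.  Self-hits are dropped; duplicate pairs
#' collapse to one edge.  Proteins named in `proteins` but in no passing hit
#' are kept as isolated nodes (they become singleton subfamilies).
#'
#' @param hits m8-dialect data.frame (see [read_m8()]).
#' @param evalue_max e-value cutoff (default 0.001).
#' @param cover_min coverage cutoff applied to `min(qcov, tcov)`
#'   (default 0.5).
#' @param proteins optional character vector of all protein ids.
#' @return object of class `similarity_graph`: list with `nodes` (sorted
#'   ids) and `edges` (data.frame `from`, `to`).
#' @export
build_similarity_graph <- function(hits, evalue_max = 0.001,
                                   cover_min = 0.5, proteins = NULL) {
  stopifnot(all(c("query", "target", "evalue", "qcov", "tcov") %in%
                  names(hits)))
  if (any(hits$evalue < 0)) stop("negative e-values in hit table")
  cov <- pmin(hits$qcov, hits$tcov)
  stopifnot_prob(cov, "coverage")
  keep <- hits$evalue <= evalue_max & cov >= cover_min &
    hits$query != hits$target
  from <- pmin(hits$query[keep], hits$target[keep])
  to <- pmax(hits$query[keep], hits$target[keep])
  dup <- duplicated(paste(from, to, sep = "\r"))
  edges <- data.frame(from = from[!dup], to = to[!dup],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(proteins, edges$from, edges$to,
                         hits$query, hits$target)))
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("Protein similarity graph: %d proteins, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Greedy set cover of the similarity graph into subfamilies
#'
#' Iteratively selects the uncovered node whose closed neighborhood covers
#' the most still-uncovered nodes; that node becomes the representative and
#' its uncovered neighbors plus itself form one subfamily.  Ties on coverage
#' gain are broken by lexicographic node id, so the result does not depend
#' on input edge order.  The subfamilies partition the protein set.
#'
#' Uses lazy greedy evaluation (coverage gains are monotone non-increasing),
#' which is exact for this objective.
#'
#' @param graph a [build_similarity_graph()] result.
#' @return data.frame `protein_id`, `subfamily_id`, `representative`; the
#'   subfamily id is `sf` plus the selection rank.
#' @export
greedy_set_cover <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(data.frame(protein_id = character(),
                                 subfamily_id = character(),
                                 representative = character()))
  fi <- match(graph$edges$from, nodes)
  ti <- match(graph$edges$to, nodes)
  adj <- split(c(ti, fi), factor(c(fi, ti), levels = seq_len(n)))
  covered <- logical(n)
  assign_sub <- integer(n)
  rep_of <- integer(0)
  gain <- lengths(adj) + 1L  # stale upper bounds (closed neighborhood size)
  k <- 0L
  while (any(!covered)) {
    gain[covered] <- 0L
    repeat {
      i <- which.max(gain)  # first index wins ties -> lexicographic ids
      g_true <- sum(!covered[adj[[i]]]) + (!covered[i])
      if (g_true == gain[i]) break
      gain[i] <- g_true
    }
    k <- k + 1L
    members <- c(i, adj[[i]][!covered[adj[[i]]]])
    covered[members] <- TRUE
    assign_sub[members] <- k
    rep_of[k] <- i
    gain[i] <- 0L
  }
  data.frame(protein_id = nodes,
             subfamily_id = sprintf("sf%05d", assign_sub),
             representative = nodes[rep_of[assign_sub]],
             stringsAsFactors = FALSE)[order(nodes), ]
}

#' Filter profile matches into a weighted subfamily network
#'
#' An edge is kept iff `probability >= prob_min` (percent) and
#' `coverage >= cov_min`; its weight is `(probability / 100) * coverage`.
#' Subfamilies with no retained match remain isolated nodes and later become
#' singleton families.
#'
#' @param matches data.frame subfamily_a, subfamily_b, probability, coverage.
#' @param prob_min probability cutoff in percent (default 95).
#' @param cov_min coverage cutoff (default 0.50).
#' @param subfamilies optional character vector of all subfamily ids.
#' @return object of class `subfamily_network`: list with `nodes` and
#'   `edges` (data.frame `a`, `b`, `weight`).
#' @export
filter_profile_matches <- function(matches, prob_min = 95, cov_min = 0.50,
                                   subfamilies = NULL) {
  need <- c("subfamily_a", "subfamily_b", "probability", "coverage")
  stopifnot(all(need %in% names(matches)))
  if (any(matches$probability < 0 | matches$probability > 100, na.rm = TRUE))
    stop("probability outside [0, 100]")
  if (any(matches$coverage < 0 | matches$coverage > 1, na.rm = TRUE))
    stop("coverage outside [0, 1]")
  if (anyNA(matches$probability) || anyNA(matches$coverage))
    stop("missing probability/coverage values")
  keep <- matches$probability >= prob_min & matches$coverage >= cov_min &
    matches$subfamily_a != matches$subfamily_b
  a <- pmin(matches$subfamily_a[keep], matches$subfamily_b[keep])
  b <- pmax(matches$subfamily_a[keep], matches$subfamily_b[keep])
  w <- (matches$probability[keep] / 100) * matches$coverage[keep]
  # duplicate pairs: keep the best-scoring record
  o <- order(a, b, -w)
  a <- a[o]; b <- b[o]; w <- w[o]
  dup <- duplicated(paste(a, b, sep = "\r"))
  nodes <- sort(unique(c(subfamilies, matches$subfamily_a,
                         matches$subfamily_b)))
  structure(list(nodes = nodes,
                 edges = data.frame(a = a[!dup], b = b[!dup],
                                    weight = w[!dup],
                                    stringsAsFactors = FALSE)),
            class = "subfamily_network")
}

#' @export
print.subfamily_network <- function(x, ...) {
  cat(sprintf("Subfamily profile-match network: %d subfamilies, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Group subfamilies into families by Markov clustering
#'
#' Runs MCL (see [mcl()]) on the weighted profile-match network with the
#' study default inflation 2.0.  Every subfamily is assigned to exactly one
#' family; isolated subfamilies become singleton families.
#'
#' @param network a [filter_profile_matches()] result.
#' @param inflation inflation parameter (> 1, default 2.0).
#' @param ... further arguments passed to [mcl()].
#' @return data.frame `subfamily_id`, `family_id` (ids `fam` + cluster rank,
#'   ordered by first subfamily id in the cluster).
#' @export
markov_cluster <- function(network, inflation = 2.0, ...) {
  stopifnot(inherits(network, "subfamily_network"))
  cl <- mcl(network$nodes, network$edges, inflation = inflation, ...)
  # stable family ids: number clusters by their lexicographically first member
  first <- vapply(split(network$nodes, cl), min, "")
  ranks <- rank(first, ties.method = "first")
  fam <- sprintf("fam%05d", ranks[match(as.character(cl), names(first))])
  data.frame(subfamily_id = network$nodes, family_id = fam,
             stringsAsFactors = FALSE)
}

#' Two-step protein clustering
#'
#' Convenience wrapper running [build_similarity_graph()],
#' [greedy_set_cover()], [filter_profile_matches()] and [markov_cluster()]
#' with the study's default thresholds (e-value 0.001, cover 0.5,
#' probability 95, coverage 0.5, inflation 2.0).
#'
#' @param hits m8-dialect similarity data.frame.
#' @param profiles profile-match data.frame.
#' @param evalue_max,cover_min similarity-graph thresholds.
#' @param prob_min,profile_cov_min profile-match thresholds.
#' @param inflation MCL inflation.
#' @param proteins optional vector of all protein ids (isolated proteins).
#' @param profile_units optional data.frame `protein_id`, `unit_id` giving
#'   the proteins each profile was built from, when the profile table's ids
#'   are not the ids assigned by the set-cover step (e.g. profiles built on
#'   an earlier clustering of the same proteins).  Each profile unit is
#'   translated to the recovered subfamily holding most of its members.
#' @return object of class `protein_families`: list with `membership`
#'   (protein_id, subfamily_id, family_id), `subfamilies` (subfamily_id,
#'   representative, size) and `families` (family_id, n_subfamilies,
#'   n_proteins).
#' @export
cluster_proteins <- function(hits, profiles, evalue_max = 0.001,
                             cover_min = 0.5, prob_min = 95,
                             profile_cov_min = 0.5, inflation = 2.0,
                             proteins = NULL, profile_units = NULL) {
  graph <- build_similarity_graph(hits, evalue_max, cover_min, proteins)
  subs <- greedy_set_cover(graph)
  if (!is.null(profile_units)) {
    stopifnot(all(c("protein_id", "unit_id") %in% names(profile_units)))
    mu <- merge(profile_units, subs[, c("protein_id", "subfamily_id")],
                by = "protein_id")
    tab <- table(mu$unit_id, mu$subfamily_id)
    unit_map <- setNames(colnames(tab)[apply(tab, 1L, which.max)],
                         rownames(tab))
    profiles$subfamily_a <- unname(unit_map[profiles$subfamily_a])
    profiles$subfamily_b <- unname(unit_map[profiles$subfamily_b])
    profiles <- profiles[!is.na(profiles$subfamily_a) &
                           !is.na(profiles$subfamily_b), , drop = FALSE]
  }
  net <- filter_profile_matches(profiles, prob_min, profile_cov_min,
                                subfamilies = unique(subs$subfamily_id))
  fams <- markov_cluster(net, inflation = inflation)
  membership <- merge(subs[, c("protein_id", "subfamily_id")], fams,
                      by = "subfamily_id", sort = FALSE)
  membership <- membership[order(membership$protein_id),
                           c("protein_id", "subfamily_id", "family_id")]
  rownames(membership) <- NULL
  sub_tab <- unique(subs[, c("subfamily_id", "representative")])
  sub_tab$size <- as.integer(table(subs$subfamily_id)[sub_tab$subfamily_id])
  fam_sizes <- table(fams$family_id)
  prot_sizes <- table(membership$family_id)
  fam_tab <- data.frame(family_id = names(fam_sizes),
                        n_subfamilies = as.integer(fam_sizes),
                        n_proteins = as.integer(prot_sizes[names(fam_sizes)]),
                        stringsAsFactors = FALSE)
  res <- list(membership = membership,
              subfamilies = sub_tab[order(sub_tab$subfamily_id), ],
              families = fam_tab)
  # partition sanity: every protein in exactly one subfamily and one family
  stopifnot(!anyDuplicated(res$membership$protein_id),
            !anyNA(res$membership$family_id))
  class(res) <- "protein_families"
  res
}

#' @export
print.protein_families <- function(x, ...) {
  cat(sprintf("Protein clustering: %d proteins -> %d subfamilies -> %d families\n",
              nrow(x$membership), nrow(x$subfamilies), nrow(x$families)))
  cat(sprintf("  singleton families: %d\n",
              sum(x$families$n_proteins == 1L)))
  invisible(x)
}

#' Annotation admixture of a protein family
#'
#' Over the annotated members only: `100 * (1 - n(modal label) /
#' n(annotated))`.  Ties on the modal label are broken by lexicographic
#' label order (the reported dominant label; the percentage is unaffected).
#' A family with no annotated member has an undefined admixture (`NA`), not
#' 0.
#'
#' @param members character vector of the family's protein ids.
#' @param annotations named character vector, protein id -> label (partial).
#' @return list with `admixture` (percent or `NA`), `dominant` label and
#'   `n_annotated`.
#' @export
annotation_admixture <- function(members, annotations) {
  lab <- annotations[members]
  lab <- lab[!is.na(lab)]
  if (!length(lab))
    return(list(admixture = NA_real_, dominant = NA_character_,
                n_annotated = 0L))
  tab <- table(lab)
  top <- max(tab)
  dominant <- sort(names(tab)[tab == top])[1L]
  list(admixture = 100 * (1 - top / length(lab)), dominant = dominant,
       n_annotated = length(lab))
}

#' Best family per annotation label
#'
#' For each label, reports the family containing the highest percentage of
#' the proteins carrying that label; ties are broken by lexicographically
#' smaller family id.
#'
#' @param membership data.frame with `protein_id` and `family_id`.
#' @param annotations named character vector, protein id -> label.
#' @return data.frame `annotation`, `family_id`, `percent`.
#' @export
best_family_per_annotation <- function(membership, annotations) {
  lab <- annotations[membership$protein_id]
  keep <- !is.na(lab)
  if (!any(keep))
    return(data.frame(annotation = character(), family_id = character(),
                      percent = numeric()))
  d <- data.frame(label = unname(lab[keep]),
                  family_id = membership$family_id[keep],
                  stringsAsFactors = FALSE)
  tab <- table(d$label, d$family_id)
  totals <- rowSums(tab)
  out <- lapply(rownames(tab), function(l) {
    counts <- tab[l, ]
    best <- sort(colnames(tab)[counts == max(counts)])[1L]
    data.frame(annotation = l, family_id = best,
               percent = 100 * max(counts) / totals[[l]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
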