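# Genome quality control from single-copy gene (SCG) inventories,
# de-replication, presence/absence matrix construction, prevalence
# filtering, and family detection in a second genome dataset.

#' Single-copy-gene marker sets
#'
#' Group-specific marker sets used for completeness/contamination
#' estimation: 43 universal SCGs for CPR, 51 for non-CPR bacteria, 38 for
#' archaea.  Marker ids are placeholders; real analyses supply their own.
#'
#' @param cpr,bac,arc character vectors of marker ids.
#' @return named list of marker sets, class `scg_config`.
#' @export
scg_config <- function(cpr = sprintf("cpr_scg%02d", 1:43),
                       bac = sprintf("bac_scg%02d", 1:51),
                       arc = sprintf("arc_scg%02d", 1:38)) {
  out <- list(CPR = unique(cpr), BAC = unique(bac), ARC = unique(arc))
  if (any(lengths(out) == 0L)) stop("SCG sets must be non-empty")
  structure(out, class = "scg_config")
}

#' Estimate genome completeness and contamination from SCG hits
#'
#' Completeness is the percentage of the group's marker set found at least
#' once; contamination is the percentage of the set found in more than one
#' copy.  Hits to ids outside the marker set are ignored with a warning.
#'
#' @param scg_hits data.frame `genome_id`, `scg_id`; one row per detected
#'   copy.
#' @param genomes data.frame with `genome_id` and `group`.
#' @param cfg an [scg_config()].
#' @return data.frame `genome_id`, `group`, `completeness`, `contamination`
#'   (percent).
#' @export
assess_genomes <- function(scg_hits, genomes, cfg = scg_config()) {
  stopifnot(all(c("genome_id", "scg_id") %in% names(scg_hits)),
            all(c("genome_id", "group") %in% names(genomes)))
  if (!all(genomes$group %in% names(cfg)))
    stop("genome group without an SCG set")
  hits_by_genome <- split(scg_hits$scg_id, scg_hits$genome_id)
  res <- genomes[, c("genome_id", "group")]
  comp <- cont <- numeric(nrow(res))
  unknown <- character(0)
  for (k in seq_len(nrow(res))) {
    set <- cfg[[res$group[k]]]
    ids <- hits_by_genome[[res$genome_id[k]]]
    if (is.null(ids)) ids <- character(0)
    out_of_set <- setdiff(unique(ids), set)
    if (length(out_of_set)) unknown <- c(unknown, out_of_set)
    ids <- ids[ids %in% set]
    tab <- table(ids)
    comp[k] <- 100 * length(tab) / length(set)
    cont[k] <- 100 * sum(tab > 1L) / length(set)
  }
  if (length(unknown))
    warning("ignoring hits to ids outside the SCG set: ",
            paste(head(unique(unknown), 5L), collapse = ", "),
            if (length(unique(unknown)) > 5L) ", ...")
  res$completeness <- comp
  res$contamination <- cont
  res
}

#' Filter genomes to draft quality
#'
#' Keeps genomes with completeness strictly above `completeness_min` and
#' contamination strictly below `contamination_max` (defaults 70 and 10; a
#' high-quality variant uses `completeness_min = 90`).
#'
#' @param genomes data.frame with `completeness` and `contamination`
#'   (percent).
#' @param completeness_min,contamination_max thresholds in percent.
#' @return the rows of `genomes` that pass.
#' @export
filter_draft_quality <- function(genomes, completeness_min = 70,
                                 contamination_max = 10) {
  stopifnot(all(c("completeness", "contamination") %in% names(genomes)))
  keep <- genomes$completeness > completeness_min &
    genomes$contamination < contamination_max
  out <- genomes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' De-replicate genomes by replicate cluster
#'
#' Keeps one genome per replicate cluster (near-identical genomes, e.g. ANI
#' > 95% clusters computed upstream): the most complete; ties broken by
#' lower contamination, then lexicographic genome id.  Genomes without a
#' cluster id are treated as their own cluster.
#'
#' @param genomes data.frame with `genome_id`, `completeness`,
#'   `contamination` and optionally `replicate_cluster`.
#' @return the retained rows of `genomes`.
#' @export
dereplicate <- function(genomes) {
  stopifnot(all(c("genome_id", "completeness") %in% names(genomes)))
  cl <- genomes$replicate_cluster
  if (is.null(cl)) cl <- rep(NA_character_, nrow(genomes))
  cl <- ifelse(is.na(cl), paste0("self:", genomes$genome_id), cl)
  cont <- if (is.null(genomes$contamination)) rep(0, nrow(genomes))
          else genomes$contamination
  o <- order(cl, -genomes$completeness, cont, genomes$genome_id)
  first <- !duplicated(cl[o])
  out <- genomes[o[first], , drop = FALSE]
  out <- out[order(match(out$genome_id, genomes$genome_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the genome x family presence/absence matrix
#'
#' A cell is 1 iff the genome encodes at least one member of the family
#' (presence, not count).  Every listed genome gets a row even if it has no
#' proteins in any family; a protein mapped to an unknown genome is fatal.
#'
#' @param membership data.frame `protein_id`, `family_id`.
#' @param proteins data.frame `protein_id`, `genome_id`.
#' @param genomes character vector of genome ids (the matrix rows, in this
#'   order).
#' @return integer 0/1 matrix, genomes x families (families sorted).
#' @export
build_matrix <- function(membership, proteins, genomes) {
  stopifnot(all(c("protein_id", "family_id") %in% names(membership)),
            all(c("protein_id", "genome_id") %in% names(proteins)))
  gid <- proteins$genome_id[match(membership$protein_id,
                                  proteins$protein_id)]
  if (anyNA(gid))
    stop("proteins with unknown genome: ",
         paste(head(membership$protein_id[is.na(gid)], 5L), collapse = ", "))
  keep <- gid %in% genomes
  fams <- sort(unique(membership$family_id))
  mat <- matrix(0L, nrow = length(genomes), ncol = length(fams),
                dimnames = list(genomes, fams))
  if (any(keep))
    mat[cbind(match(gid[keep], genomes),
              match(membership$family_id[keep], fams))] <- 1L
  mat
}

#' Filter families by genome prevalence
#'
#' Keeps families present in at least `min_genomes` distinct genomes
#' (boundary inclusive: a family in exactly `min_genomes` genomes is kept).
#'
#' @param mat 0/1 presence matrix (genomes x families).
#' @param min_genomes minimum number of genomes (default 5).
#' @return the matrix restricted to passing columns.
#' @export
filter_families_by_prevalence <- function(mat, min_genomes = 5L) {
  keep <- colSums(mat) >= min_genomes
  mat[, keep, drop = FALSE]
}

#' Detect known families in a second genome dataset
#'
#' Assigns each protein to the subfamily of its best-scoring passing hit
#' (e-value <= `evalue_max`, profile coverage strictly > `cov_min`; score
#' ties broken by lexicographically smaller subfamily id), maps subfamilies
#' to families, and builds the presence matrix for the new genomes.
#' Proteins without a passing hit contribute no presence.
#'
#' @param hits data.frame `protein_id`, `genome_id`, `subfamily_id`,
#'   `score`, `evalue`, `coverage`.
#' @param subfam_map data.frame `subfamily_id`, `family_id`.
#' @param genomes character vector of the second dataset's genome ids.
#' @param evalue_max e-value cutoff (default 0.001).
#' @param cov_min profile coverage cutoff, strict (default 0.5).
#' @return list with `matrix` (0/1, genomes x families) and `assignments`
#'   (protein_id, genome_id, subfamily_id, family_id).
#' @export
detect_in_second_dataset <- function(hits, subfam_map, genomes,
                                     evalue_max = 0.001, cov_min = 0.5) {
  need <- c("protein_id", "genome_id", "subfamily_id", "score", "evalue",
            "coverage")
  stopifnot(all(need %in% names(hits)),
            all(c("subfamily_id", "family_id") %in% names(subfam_map)))
  pass <- hits$evalue <= evalue_max & hits$coverage > cov_min
  h <- hits[pass, , drop = FALSE]
  o <- order(h$protein_id, -h$score, h$subfamily_id)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$protein_id), , drop = FALSE]
  h$family_id <- subfam_map$family_id[match(h$subfamily_id,
                                            subfam_map$subfamily_id)]
  if (anyNA(h$family_id))
    stop("hits reference unknown subfamilies: ",
         paste(head(unique(h$subfamily_id[is.na(h$family_id)]), 5L),
               collapse = ", "))
  assignments <- h[, c("protein_id", "genome_id", "subfamily_id",
                       "family_id")]
  rownames(assignments) <- NULL
  mat <- build_matrix(assignments[, c("protein_id", "family_id")],
                      assignments[, c("protein_id", "genome_id")], genomes)
  list(matrix = mat, assignments = assignments)
}
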