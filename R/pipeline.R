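# End-to-end orchestration: cluster -> matrix -> modules -> tree -> enrich,
# with a single validated config, fixed seeds, stage outputs written to a
# run directory and a manifest recording parameters and input hashes.

#' Pipeline configuration
#'
#' All stage thresholds with the study defaults: similarity e-value 0.001
#' and coverage 0.5; profile probability 95 (percent) and coverage 0.5; MCL
#' inflation 2.0; family prevalence >= 5 genomes; Jaccard module threshold
#' 0.4 (strict); minimum module size 10; completeness > 70 and
#' contamination < 10 (percent); widespread threshold 10 phyla; branch
#' collapse fraction 0.25; enrichment alpha 1e-5 on the adjusted p.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(evalue = 0.001, cover = 0.5, prob = 95, profile_cov = 0.5,
              inflation = 2.0, prevalence = 5L, jaccard = 0.4,
              min_module_size = 10L, completeness = 70, contamination = 10,
              phylum_min = 10L, collapse_fraction = 0.25, alpha = 1e-5,
              linkage = "complete", seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, dots)
  with(cfg, {
    if (inflation <= 1) stop("inflation must be > 1")
    stopifnot_prob(c(cover, profile_cov, jaccard, collapse_fraction),
                   "coverage/jaccard/collapse fractions")
    if (prob < 0 || prob > 100) stop("prob must be in [0, 100] percent")
    if (evalue < 0) stop("evalue must be >= 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    if (!linkage %in% c("single", "complete", "average"))
      stop("linkage must be single, complete or average")
  })
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("famcontent pipeline configuration:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Match recovered clusters to planted truth
#'
#' Maps each recovered family (and subfamily) to the planted family
#' (subfamily) contributing most of its proteins, ties broken by
#' lexicographic id, and reports the protein-level adjusted Rand index of
#' the two partitions.
#'
#' @param membership clustering membership (`protein_id`, `subfamily_id`,
#'   `family_id`).
#' @param proteins planted truth (`protein_id`, `family_id`,
#'   `subfamily_id`).
#' @return list with `family_map` (recovered -> planted),
#'   `planted_to_recovered` (majority map the other way), `subfamily_map`,
#'   `family_ari`, `subfamily_ari`, `exact` (TRUE iff the two family
#'   partitions are identical).
#' @export
match_families <- function(membership, proteins) {
  m <- merge(membership, proteins, by = "protein_id",
             suffixes = c("_rec", "_true"))
  stopifnot(nrow(m) == nrow(membership))
  majority <- function(rec, true) {
    tab <- table(rec, true)
    planted <- colnames(tab)[apply(tab, 1L, which.max)]
    setNames(planted, rownames(tab))
  }
  fam_map <- majority(m$family_id_rec, m$family_id_true)
  fam_rev <- majority(m$family_id_true, m$family_id_rec)
  sub_map <- majority(m$subfamily_id_rec, m$subfamily_id_true)
  fam_ari <- adjusted_rand(m$family_id_rec, m$family_id_true)
  sub_ari <- adjusted_rand(m$subfamily_id_rec, m$subfamily_id_true)
  exact <- isTRUE(all.equal(fam_ari, 1))
  list(family_map = fam_map, planted_to_recovered = fam_rev,
       subfamily_map = sub_map, family_ari = fam_ari,
       subfamily_ari = sub_ari, exact = exact)
}

#' Run the full pipeline on a (synthetic) study
#'
#' Executes cluster -> matrix -> modules -> tree -> enrich.  When `study`
#' is NULL, a synthetic study pair is generated from the config seed with
#' the package's default planted-structure scenario, and planted-truth
#' recovery metrics are included.  Stage outputs and a manifest are written
#' to `out_dir` when given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); NULL to skip writing.
#' @param study,study2 [simulate_study()]-style input bundles for the two
#'   genome datasets; generated synthetically when NULL.
#' @return list of class `famcontent_run` with per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         study = NULL, study2 = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  check_study <- function(st, who) {
    need <- c("proteins", "hits", "scg", "genome_meta", "taxonomy", "matrix")
    miss <- setdiff(need, names(st))
    if (length(miss))
      stop(sprintf("%s is missing inputs: %s", who,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(study))
    study <- simulate_study(default_truth(seed = config$seed))
  if (is.null(study2))
    study2 <- simulate_study(default_truth(seed = config$seed + 1000L),
                             n_low_completeness = 0L, n_replicates = 0L,
                             n_contaminated = 0L)
  check_study(study, "study")
  check_study(study2, "study2")
  ## stage 1: protein clustering
  clust <- cluster_proteins(study$hits$m8, study$hits$profiles,
                            evalue_max = config$evalue,
                            cover_min = config$cover,
                            prob_min = config$prob,
                            profile_cov_min = config$profile_cov,
                            inflation = config$inflation,
                            proteins = study$proteins$protein_id,
                            profile_units = data.frame(
                              protein_id = study$proteins$protein_id,
                              unit_id = study$proteins$subfamily_id,
                              stringsAsFactors = FALSE))
  ## stage 2: genome QC + presence matrix
  qc <- assess_genomes(study$scg, study$genome_meta)
  qc$replicate_cluster <-
    study$genome_meta$replicate_cluster[match(qc$genome_id,
                                              study$genome_meta$genome_id)]
  qc_pass <- filter_draft_quality(qc, config$completeness,
                                  config$contamination)
  qc_kept <- dereplicate(qc_pass)
  genomes <- qc_kept$genome_id
  mat <- build_matrix(clust$membership[, c("protein_id", "family_id")],
                      study$proteins[, c("protein_id", "genome_id")],
                      genomes)
  mat <- filter_families_by_prevalence(mat, config$prevalence)
  taxonomy <- study$genome_meta[match(genomes,
                                      study$genome_meta$genome_id),
                                c("genome_id", "group", "phylum")]
  ## stage 3: co-occurrence modules
  modules <- detect_modules(mat, taxonomy,
                            jaccard_threshold = config$jaccard,
                            min_module_size = config$min_module_size,
                            phylum_min = config$phylum_min,
                            seed = config$seed)
  wide <- intersect(colnames(mat), modules$widespread_families)
  mat_wide <- mat[, wide, drop = FALSE]
  ## stage 4: content dendrograms
  d_full <- jaccard_distance(mat, "rows")
  d_wide <- jaccard_distance(mat_wide, "rows")
  tree_full <- agglomerative(d_full, config$linkage)
  tree_wide <- agglomerative(d_wide, config$linkage)
  coph <- cophenetic_correlation(tree_full, tree_wide)
  group_of <- setNames(taxonomy$group, taxonomy$genome_id)
  wedges <- collapse_and_count(tree_wide, config$collapse_fraction,
                               group_of)
  sim_test <- within_group_similarity_test(mat_wide, group_of, "CPR", "BAC")
  ## stage 5: detection in dataset 2 + enrichment over widespread families
  truth_match <- match_families(clust$membership, study$proteins)
  sub_planted <- data.frame(
    subfamily_id = names(truth_match$subfamily_map),
    family_id = study$proteins$family_id[
      match(truth_match$subfamily_map, study$proteins$subfamily_id)],
    stringsAsFactors = FALSE)
  hits2 <- generate_search_hits(study2$matrix, sub_planted,
                                seed = config$seed + 2000L)
  sub_map <- unique(clust$membership[, c("subfamily_id", "family_id")])
  det2 <- detect_in_second_dataset(hits2, sub_map,
                                   rownames(study2$matrix),
                                   evalue_max = config$evalue,
                                   cov_min = config$profile_cov)
  mat2 <- filter_families_by_prevalence(det2$matrix, config$prevalence)
  tax2 <- study2$taxonomy
  enr <- categorize_families(
    mat[, wide, drop = FALSE], taxonomy,
    mat2[, intersect(colnames(mat2), wide), drop = FALSE], tax2,
    alpha = config$alpha)
  res <- list(config = config, clustering = clust, qc = qc,
              genomes = genomes, matrix = mat, taxonomy = taxonomy,
              modules = modules, matrix_widespread = mat_wide,
              tree_full = tree_full, tree_widespread = tree_wide,
              cophenetic_full_vs_widespread = coph, wedges = wedges,
              similarity_test = sim_test, matrix_2 = mat2,
              enrichment = enr, truth_match = truth_match)
  res$recovery <- recovery_report(res, study, study2)
  class(res) <- "famcontent_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' Planted-truth recovery metrics for a pipeline run
#'
#' @param res a partial `famcontent_run` list.
#' @param study,study2 the synthetic inputs with ground truth.
#' @return list of recovery metrics.
#' @keywords internal
recovery_report <- function(res, study, study2) {
  truth <- study$truth
  fam_map <- res$truth_match$family_map
  ## module recovery: planted block labels vs Louvain modules, per matrix
  ## column (background families are planted singleton blocks)
  planted_block <- truth$families$block[
    match(fam_map[colnames(res$matrix)], truth$families$family_id)]
  mem <- res$modules$membership
  module_of <- setNames(mem$module_id, mem$family_id)
  module_ari <- adjusted_rand(planted_block, module_of[colnames(res$matrix)])
  ## superclade recovery: 2-cut of the widespread-content tree
  two_cut <- cutree(res$tree_widespread, k = 2L)
  superclade <- ifelse(res$taxonomy$group == "CPR", "CPR", "nonCPR")
  superclade_ari <- adjusted_rand(two_cut[res$taxonomy$genome_id],
                                  superclade)
  ## enrichment recovery on planted labels
  planted_of <- function(ids) unname(fam_map[ids])
  enriched_pred <- planted_of(res$enrichment$family_id[
    res$enrichment$category == "enriched"])
  depleted_pred <- planted_of(res$enrichment$family_id[
    res$enrichment$category == "depleted"])
  enriched_true <- truth$families$family_id[
    truth$families$class == "cpr_enriched"]
  depleted_true <- truth$families$family_id[
    truth$families$class == "bac_enriched"]
  list(family_ari = res$truth_match$family_ari,
       subfamily_ari = res$truth_match$subfamily_ari,
       families_exact = res$truth_match$exact,
       module_ari = module_ari,
       superclade_ari = superclade_ari,
       enriched = set_recovery(enriched_pred, enriched_true),
       depleted = set_recovery(depleted_pred, depleted_true))
}

#' @export
print.famcontent_run <- function(x, ...) {
  cat("famcontent pipeline run\n")
  cat(sprintf("  genomes analyzed: %d; families in matrix: %d\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  modules (>= %d families): %d, of which widespread: %d (%d families)\n",
              x$config$min_module_size, nrow(x$modules$summary),
              sum(x$modules$summary$widespread),
              ncol(x$matrix_widespread)))
  cat(sprintf("  cophenetic correlation, all vs widespread families (%s linkage): %.3f\n",
              x$config$linkage, x$cophenetic_full_vs_widespread))
  gc_ <- x$wedges$group_counts
  cat(sprintf("  wedges: %d total (%s)\n", x$wedges$n_wedges,
              paste(sprintf("%s %d", names(gc_), gc_), collapse = ", ")))
  tab <- table(factor(x$enrichment$category,
                      c("enriched", "depleted", "equal")))
  cat(sprintf("  widespread families: %d CPR-enriched / %d depleted / %d equal\n",
              tab[["enriched"]], tab[["depleted"]], tab[["equal"]]))
  if (!is.null(x$recovery))
    cat(sprintf("  planted-structure recovery: family ARI %.3f, module ARI %.3f, superclade ARI %.3f\n",
                x$recovery$family_ari, x$recovery$module_ari,
                x$recovery$superclade_ari))
  invisible(x)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write.table(res$clustering$membership, p("membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$qc, p("genome_qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_presence_matrix(res$matrix, p("presence_matrix.tsv"))
  write_presence_matrix(res$matrix_2, p("presence_matrix_dataset2.tsv"))
  write_taxonomy(res$taxonomy, p("taxonomy.tsv"))
  mem <- res$modules$membership
  mem$status <- ifelse(mem$assigned, "assigned", "unassigned")
  write.table(mem[, c("family_id", "module_id", "status")],
              p("module_membership.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summ <- res$modules$summary
  summ$phyla <- vapply(summ$module_id, function(id) {
    tx <- res$modules$module_taxa[[id]]$phyla
    jsonlite::toJSON(as.list(tx), auto_unbox = TRUE)
  }, "")
  write.table(summ, p("module_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(to_newick(res$tree_full), p("tree_full.nwk"))
  writeLines(to_newick(res$tree_widespread), p("tree_widespread.nwk"))
  write.table(res$wedges$wedges, p("wedges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(res$enrichment), p("enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "famcontent",
    version = as.character(utils::packageVersion("famcontent")),
    seed = res$config$seed,
    parameters = unclass(res$config),
    n_genomes = nrow(res$matrix),
    n_families = ncol(res$matrix),
    files = list.files(out_dir))
  cfg_file <- p("config.yml")
  yaml::write_yaml(unclass(res$config), cfg_file)
  manifest$parameter_hash <- unname(tools::md5sum(cfg_file))
  if (!is.null(res$recovery)) {
    manifest$recovery <- res$recovery
    jsonlite::write_json(res$recovery, p("recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
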