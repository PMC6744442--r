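#' Ground truth for a synthetic pangenome
#'
#' Bundles the genome table, family catalog, per (class, group) presence
#' probabilities and per-genome dropout into a validated truth object from
#' which every synthetic artifact (matrices, sequences, hit tables, SCG
#' tables) is generated deterministically.
#'
#' Family classes mirror the structure seen in real presence/absence arrays
#' of CPR vs. non-CPR genomes: a near-universal core block, blocks widespread
#' in only one superclade, lineage-specific blocks confined to one phylum,
#' and uncorrelated background families.  Lineage-specific families use the
#' class probability inside their `home_phylum` and 0 elsewhere.
#'
#' @param genomes data.frame with columns `genome_id`, `group` (one of
#'   `"CPR"`, `"BAC"`, `"ARC"`), `phylum`.
#' @param families data.frame with columns `family_id`, `class` (one of
#'   `"universal"`, `"bac_enriched"`, `"cpr_enriched"`, `"lineage_specific"`,
#'   `"background"`), `block` (planted-module label) and optionally
#'   `home_phylum` (required for lineage-specific families).
#' @param presence_prob numeric matrix, rows = classes, columns = groups,
#'   entries in `[0, 1]`.
#' @param dropout per-genome missingness fraction in `[0, 1]`; scalar or one
#'   value per genome.  Emulates incomplete draft assemblies: every family's
#'   presence probability in genome g is multiplied by `1 - dropout[g]`.
#' @param seed integer seed; all generators derive their streams from it.
#' @return An object of class `pangenome_truth`.
#' @export
pangenome_truth <- function(genomes, families, presence_prob, dropout = 0,
                            seed = 1L) {
  stopifnot(is.data.frame(genomes), is.data.frame(families))
  need_g <- c("genome_id", "group", "phylum")
  if (!all(need_g %in% names(genomes)))
    stop("genomes needs columns: ", paste(need_g, collapse = ", "))
  if (anyDuplicated(genomes$genome_id))
    stop("genome ids must be unique")
  if (!all(genomes$group %in% c("CPR", "BAC", "ARC")))
    stop("group must be CPR, BAC or ARC")
  need_f <- c("family_id", "class")
  if (!all(need_f %in% names(families)))
    stop("families needs columns: ", paste(need_f, collapse = ", "))
  if (anyDuplicated(families$family_id))
    stop("family ids must be unique")
  classes <- c("universal", "bac_enriched", "cpr_enriched",
               "lineage_specific", "background")
  if (!all(families$class %in% classes))
    stop("unknown family class")
  if (is.null(families$block)) families$block <- families$family_id
  if (is.null(families$home_phylum))
    families$home_phylum <- rep(NA_character_, nrow(families))
  lin <- families$class == "lineage_specific"
  if (any(lin & is.na(families$home_phylum)))
    stop("lineage_specific families need a home_phylum")
  presence_prob <- as.matrix(presence_prob)
  stopifnot_prob(presence_prob, "presence_prob")
  if (!all(unique(families$class) %in% rownames(presence_prob)))
    stop("presence_prob must have a row for every family class used")
  if (!all(unique(genomes$group) %in% colnames(presence_prob)))
    stop("presence_prob must have a column for every genome group used")
  stopifnot_prob(dropout, "dropout")
  if (length(dropout) == 1L) dropout <- rep(dropout, nrow(genomes))
  if (length(dropout) != nrow(genomes))
    stop("dropout must be scalar or one value per genome")
  stopifnot_scalar_count(seed, "seed")
  structure(
    list(genomes = genomes, families = families,
         presence_prob = presence_prob,
         dropout = setNames(dropout, genomes$genome_id),
         seed = as.integer(seed)),
    class = "pangenome_truth")
}

#' @export
print.pangenome_truth <- function(x, ...) {
  cat("Synthetic pangenome truth\n")
  cat(sprintf("  genomes:  %d (%s)\n", nrow(x$genomes),
              paste(sprintf("%s=%d", names(table(x$genomes$group)),
                            table(x$genomes$group)), collapse = ", ")))
  cat(sprintf("  families: %d in %d classes, %d planted blocks\n",
              nrow(x$families), length(unique(x$families$class)),
              length(unique(x$families$block))))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Default two-superclade study truth
#'
#' The package's reference scenario: two superclades (CPR-like and other
#' bacteria) with phylum substructure, a shared core-family module, one
#' module widespread only in each superclade, lineage-specific blocks and
#' uncorrelated background families.  Defaults are the conditions used
#' throughout the package's validation: 100 + 100 genomes in 10 phyla per
#' superclade, superclade-specific presence 0.9 at home / 0.05 away,
#' core-family presence 0.8, dropout 0.1.
#'
#' @param n_cpr,n_bac,n_arc genomes per group.
#' @param n_phyla phyla per superclade (archaea get a single phylum per 20
#'   genomes).
#' @param n_universal,n_enriched,n_background family counts (n_enriched is
#'   used for each of the two superclade-specific blocks).
#' @param n_lineage_blocks,lineage_block_size lineage-specific blocks
#'   (alternating between superclade phyla) and families per block.
#' @param p_universal,p_enriched_home,p_enriched_away,p_lineage,p_background
#'   presence probabilities before dropout.
#' @param dropout per-genome missingness fraction.
#' @param seed integer seed.
#' @return A [pangenome_truth()] object.
#' @export
default_truth <- function(n_cpr = 100, n_bac = 100, n_arc = 0, n_phyla = 10,
                          n_universal = 40, n_enriched = 40,
                          n_lineage_blocks = 6, lineage_block_size = 12,
                          n_background = 40,
                          p_universal = 0.8, p_enriched_home = 0.9,
                          p_enriched_away = 0.05, p_lineage = 0.9,
                          p_background = 0.1, dropout = 0.1, seed = 1L) {
  grp_tab <- function(n, group, prefix) {
    if (n == 0) return(NULL)
    phyla <- if (group == "ARC") {
      sprintf("%s_p%02d", prefix, ((seq_len(n) - 1L) %/% 20L) + 1L)
    } else {
      sprintf("%s_p%02d", prefix, ((seq_len(n) - 1L) %% n_phyla) + 1L)
    }
    data.frame(genome_id = sprintf("%s_g%03d", tolower(prefix), seq_len(n)),
               group = group, phylum = phyla, stringsAsFactors = FALSE)
  }
  genomes <- rbind(grp_tab(n_cpr, "CPR", "cpr"), grp_tab(n_bac, "BAC", "bac"),
                   grp_tab(n_arc, "ARC", "arc"))
  fam <- function(n, class, block, home = NA_character_) {
    if (n == 0) return(NULL)
    data.frame(family_id = sprintf("%s%03d", block, seq_len(n)),
               class = class, block = block, home_phylum = home,
               stringsAsFactors = FALSE)
  }
  lineage <- NULL
  if (n_lineage_blocks > 0) {
    cpr_ph <- unique(genomes$phylum[genomes$group == "CPR"])
    bac_ph <- unique(genomes$phylum[genomes$group == "BAC"])
    homes <- character(n_lineage_blocks)
    for (i in seq_len(n_lineage_blocks)) {
      pool <- if (i %% 2 == 1) cpr_ph else bac_ph
      if (is.null(pool) || !length(pool)) pool <- unique(genomes$phylum)
      homes[i] <- pool[((i - 1L) %/% 2L) %% length(pool) + 1L]
    }
    lineage <- do.call(rbind, lapply(seq_len(n_lineage_blocks), function(i)
      fam(lineage_block_size, "lineage_specific", sprintf("lin%02d", i),
          homes[i])))
  }
  families <- rbind(fam(n_universal, "universal", "uni"),
                    fam(n_enriched, "bac_enriched", "bace"),
                    fam(n_enriched, "cpr_enriched", "cpre"),
                    lineage,
                    fam(n_background, "background", "bg"))
  # background block labels are per-family: uncorrelated singletons
  bg <- families$class == "background"
  families$block[bg] <- families$family_id[bg]
  pp <- rbind(universal = c(p_universal, p_universal, p_universal),
              bac_enriched = c(p_enriched_away, p_enriched_home,
                               p_enriched_away),
              cpr_enriched = c(p_enriched_home, p_enriched_away,
                               p_enriched_away),
              lineage_specific = c(p_lineage, p_lineage, p_lineage),
              background = c(p_background, p_background, p_background))
  colnames(pp) <- c("CPR", "BAC", "ARC")
  pangenome_truth(genomes, families, pp, dropout = dropout, seed = seed)
}

#' Generate a presence/absence matrix from a truth object
#'
#' Each cell (g, f) is an independent Bernoulli draw with probability
#' `presence_prob[class(f), group(g)] * (1 - dropout(g))` (0 outside the
#' home phylum for lineage-specific families).  Reproducible given
#' `truth$seed`.
#'
#' @param truth a [pangenome_truth()] object.
#' @return list with `matrix` (integer 0/1, genomes x families, dimnames
#'   set) and `taxonomy` (data.frame genome_id, group, phylum).
#' @export
generate_presence_matrix <- function(truth) {
  stopifnot(inherits(truth, "pangenome_truth"))
  g <- truth$genomes; f <- truth$families
  if (nrow(g) == 0L) stop("no genomes in truth")
  if (nrow(f) == 0L) stop("no families in truth")
  p <- truth$presence_prob[f$class, g$group, drop = FALSE]  # fams x genomes
  lin <- which(f$class == "lineage_specific")
  if (length(lin)) {
    away <- outer(f$home_phylum[lin], g$phylum, FUN = "!=")
    p[lin, ][away] <- 0
  }
  p <- t(p) * (1 - truth$dropout)  # genomes x families
  mat <- with_seed(truth$seed, {
    matrix(rbinom(length(p), 1L, as.vector(p)), nrow = nrow(g),
           dimnames = list(g$genome_id, f$family_id))
  })
  list(matrix = mat,
       taxonomy = g[, c("genome_id", "group", "phylum")])
}

#' Draw protein occurrences consistent with a presence matrix
#'
#' For every present (genome, family) cell, emits one protein assigned to
#' one of the family's planted subfamilies (uniformly at random).  The
#' resulting table is the ground-truth protein catalog consumed by the
#' sequence and hit-table generators, and the reference against which
#' clustering recovery is measured.
#'
#' @param mat 0/1 presence matrix (genomes x families).
#' @param n_subfamilies subfamilies planted per family.
#' @param seed integer seed.
#' @return data.frame protein_id, genome_id, family_id, subfamily_id.
#' @export
proteins_from_matrix <- function(mat, n_subfamilies = 2L, seed = 1L) {
  idx <- which(mat == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("presence matrix has no present cells")
  gid <- rownames(mat)[idx[, 1L]]
  fid <- colnames(mat)[idx[, 2L]]
  sub <- with_seed(seed, sample.int(n_subfamilies, nrow(idx), replace = TRUE))
  data.frame(protein_id = sprintf("%s|%s", gid, fid),
             genome_id = gid, family_id = fid,
             subfamily_id = sprintf("%s.s%d", fid, sub),
             stringsAsFactors = FALSE)
}

#' Ground truth for synthetic protein sequences
#'
#' Families descend from a random ancestor; each planted subfamily seed is
#' the ancestor mutated at `divergence` of its sites, and each member is its
#' subfamily seed mutated independently at `member_rate`, so within-subfamily
#' identity exceeds between-subfamily identity whenever
#' `member_rate < divergence / 2`.
#'
#' @param proteins data.frame as returned by [proteins_from_matrix()].
#' @param divergence between-subfamily substitution fraction in `[0, 1]`.
#' @param member_rate within-subfamily per-member substitution rate.
#' @param seed integer seed.
#' @return object of class `sequence_truth`.
#' @export
sequence_truth <- function(proteins, divergence = 0.4, member_rate = 0.05,
                           seed = 1L) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "genome_id", "family_id", "subfamily_id")
                %in% names(proteins)))
  if (nrow(proteins) == 0L) stop("empty protein table")
  if (anyDuplicated(proteins$protein_id)) stop("protein ids must be unique")
  stopifnot_prob(divergence, "divergence")
  stopifnot_prob(member_rate, "member_rate")
  if (member_rate >= divergence)
    warning("member_rate >= divergence: subfamily structure will be weak")
  structure(list(proteins = proteins, divergence = divergence,
                 member_rate = member_rate, seed = as.integer(seed)),
            class = "sequence_truth")
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_seq <- function(x, rate, alphabet) {
  hit <- runif(length(x)) < rate
  if (any(hit)) {
    # draw a replacement different from the current letter
    repl <- alphabet[sample.int(length(alphabet) - 1L, sum(hit),
                                replace = TRUE)]
    cur <- x[hit]
    bump <- repl >= cur  # shift past the current letter to avoid identity
    ord <- match(repl, alphabet) + as.integer(bump)
    ord[ord > length(alphabet)] <- 1L
    x[hit] <- alphabet[ord]
  }
  x
}

#' Generate protein sequences for a sequence truth
#'
#' @param truth a [sequence_truth()] object.
#' @param length sequence length in residues (>= 30).
#' @param alphabet amino-acid letters.
#' @return a [Biostrings::AAStringSet] named by protein id, in the order of
#'   `truth$proteins`.
#' @export
generate_sequence_families <- function(truth, length = 120L,
                                       alphabet = aa_alphabet()) {
  stopifnot(inherits(truth, "sequence_truth"))
  if (length < 30L) stop("sequence length must be >= 30 residues")
  pr <- truth$proteins
  with_seed(truth$seed, {
    fams <- unique(pr$family_id)
    subs <- unique(pr[, c("family_id", "subfamily_id")])
    anc <- lapply(setNames(fams, fams), function(f)
      alphabet[sample.int(length(alphabet), length, replace = TRUE)])
    seed_seqs <- setNames(vector("list", nrow(subs)), subs$subfamily_id)
    for (i in seq_len(nrow(subs)))
      seed_seqs[[i]] <- mutate_seq(anc[[subs$family_id[i]]],
                                   truth$divergence, alphabet)
    out <- character(nrow(pr))
    for (i in seq_len(nrow(pr)))
      out[i] <- paste(mutate_seq(seed_seqs[[pr$subfamily_id[i]]],
                                 truth$member_rate, alphabet),
                      collapse = "")
    Biostrings::AAStringSet(setNames(out, pr$protein_id))
  })
}

#' Generate similarity and profile-match hit tables from planted clusters
#'
#' Emulates the tabular outputs of an all-vs-all sequence search and of
#' profile-profile comparison, directly from the planted subfamily/family
#' structure: within-subfamily pairs appear in the m8-style similarity table
#' with e-value <= 1e-10 and coverage >= 0.9; between-subfamily pairs of the
#' same family appear in the profile-match table with probability >= 95 and
#' coverage >= 0.5.  `noise` removes that fraction of true rows and adds the
#' same number of random cross-family rows with passing scores.
#'
#' @param truth a [sequence_truth()] object (sequences themselves are not
#'   needed; hits are generated from the planted structure).
#' @param noise fraction in `[0, 1]` of edges perturbed.
#' @param length nominal alignment length used for the m8 columns.
#' @return list with `m8` (14-column similarity table: the 12 standard
#'   columns plus query and target coverage) and `profiles` (subfamily_a,
#'   subfamily_b, probability, coverage).
#' @export
generate_hit_tables <- function(truth, noise = 0, length = 120L) {
  stopifnot(inherits(truth, "sequence_truth"))
  stopifnot_prob(noise, "noise")
  pr <- truth$proteins
  with_seed(truth$seed + 1L, {
    # all unordered within-subfamily pairs
    by_sub <- split(pr$protein_id, pr$subfamily_id)
    pairs <- lapply(by_sub, function(ids) {
      if (length(ids) < 2L) return(NULL)
      ids <- sort(ids)
      t(utils::combn(ids, 2L))
    })
    pairs <- do.call(rbind, pairs)
    m8 <- if (is.null(pairs)) empty_m8() else {
      n <- nrow(pairs)
      data.frame(query = pairs[, 1L], target = pairs[, 2L],
                 identity = round(runif(n, 90, 100), 1),
                 alnlen = length, mismatch = 0L, gapopen = 0L,
                 qstart = 1L, qend = length, tstart = 1L, tend = length,
                 evalue = 10^-runif(n, 10, 50),
                 bits = round(runif(n, 200, 400)),
                 qcov = round(runif(n, 0.9, 1), 3),
                 tcov = round(runif(n, 0.9, 1), 3),
                 stringsAsFactors = FALSE)
    }
    # between-subfamily, same-family pairs -> profile matches
    subs <- unique(pr[, c("family_id", "subfamily_id")])
    by_fam <- split(sort(subs$subfamily_id), subs$family_id[order(subs$subfamily_id)])
    sp <- do.call(rbind, lapply(by_fam, function(s) {
      if (length(s) < 2L) return(NULL)
      t(utils::combn(s, 2L))
    }))
    profiles <- if (is.null(sp)) {
      data.frame(subfamily_a = character(), subfamily_b = character(),
                 probability = numeric(), coverage = numeric())
    } else {
      n <- nrow(sp)
      data.frame(subfamily_a = sp[, 1L], subfamily_b = sp[, 2L],
                 probability = round(runif(n, 95, 100), 2),
                 coverage = round(runif(n, 0.55, 1), 3),
                 stringsAsFactors = FALSE)
    }
    if (noise > 0) {
      drop_m8 <- runif(nrow(m8)) < noise
      m8 <- m8[!drop_m8, , drop = FALSE]
      drop_pr <- runif(nrow(profiles)) < noise
      profiles <- profiles[!drop_pr, , drop = FALSE]
      n_add <- sum(drop_m8)
      if (n_add > 0 && nrow(pr) >= 2L) {
        i <- sample.int(nrow(pr), n_add, replace = TRUE)
        j <- sample.int(nrow(pr), n_add, replace = TRUE)
        keep <- pr$family_id[i] != pr$family_id[j]
        if (any(keep)) {
          n2 <- sum(keep)
          m8 <- rbind(m8, data.frame(
            query = pr$protein_id[i[keep]], target = pr$protein_id[j[keep]],
            identity = round(runif(n2, 30, 60), 1), alnlen = length,
            mismatch = 0L, gapopen = 0L, qstart = 1L, qend = length,
            tstart = 1L, tend = length, evalue = 10^-runif(n2, 4, 12),
            bits = round(runif(n2, 50, 120)),
            qcov = round(runif(n2, 0.5, 1), 3),
            tcov = round(runif(n2, 0.5, 1), 3), stringsAsFactors = FALSE))
        }
      }
    }
    rownames(m8) <- NULL; rownames(profiles) <- NULL
    list(m8 = m8, profiles = profiles)
  })
}

empty_m8 <- function() {
  data.frame(query = character(), target = character(), identity = numeric(),
             alnlen = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), tstart = integer(),
             tend = integer(), evalue = numeric(), bits = numeric(),
             qcov = numeric(), tcov = numeric(), stringsAsFactors = FALSE)
}

#' Generate a single-copy-gene hit table with known completeness
#'
#' Per genome, `floor(completeness * |set|)` SCGs of its group's marker set
#' are present once, and `floor(duplication * |set|)` of those are present in
#' two copies, so downstream completeness/contamination estimates are known
#' exactly.
#'
#' @param genomes data.frame with `genome_id` and `group`.
#' @param cfg an [scg_config()].
#' @param completeness,duplication targets in `[0, 1]`, scalar or per genome.
#' @param seed integer seed (which SCGs are present/duplicated is shuffled).
#' @return data.frame genome_id, scg_id; duplicated copies appear as
#'   repeated rows.
#' @export
generate_scg_table <- function(genomes, cfg = scg_config(),
                               completeness = 1, duplication = 0,
                               seed = 1L) {
  stopifnot_prob(completeness, "completeness")
  stopifnot_prob(duplication, "duplication")
  n <- nrow(genomes)
  if (length(completeness) == 1L) completeness <- rep(completeness, n)
  if (length(duplication) == 1L) duplication <- rep(duplication, n)
  stopifnot(length(completeness) == n, length(duplication) == n)
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      set <- cfg[[genomes$group[i]]]
      k <- floor(completeness[i] * length(set))
      d <- floor(duplication[i] * length(set))
      if (d > k)
        stop(sprintf("genome %s: duplicated SCG count (%d) exceeds present count (%d)",
                     genomes$genome_id[i], d, k))
      present <- sample(set, k)
      rows[[i]] <- data.frame(
        genome_id = genomes$genome_id[i],
        scg_id = c(present, present[seq_len(d)]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Emulate profile-search hits of new proteins against known subfamilies
#'
#' For detection of the families in a second genome dataset: every present
#' (genome, family) cell of the second dataset's truth matrix yields one
#' protein with a passing hit (e-value <= 1e-6, coverage > 0.5) to one
#' subfamily of that family, plus, with probability `decoy_rate`, a
#' lower-scoring decoy hit to a random other subfamily that fails the
#' coverage filter.
#'
#' @param mat 0/1 presence matrix of the second dataset (genomes x families).
#' @param subfam_map data.frame subfamily_id, family_id (the first dataset's
#'   clustering result or the planted truth).
#' @param decoy_rate fraction of proteins that also get a failing decoy hit.
#' @param seed integer seed.
#' @return data.frame protein_id, genome_id, subfamily_id, score, evalue,
#'   coverage.
#' @export
generate_search_hits <- function(mat, subfam_map, decoy_rate = 0.1,
                                 seed = 1L) {
  stopifnot(all(c("subfamily_id", "family_id") %in% names(subfam_map)))
  idx <- which(mat == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("presence matrix has no present cells")
  by_fam <- split(subfam_map$subfamily_id, subfam_map$family_id)
  gid <- rownames(mat)[idx[, 1L]]
  fid <- colnames(mat)[idx[, 2L]]
  keep <- fid %in% names(by_fam)
  gid <- gid[keep]; fid <- fid[keep]
  with_seed(seed, {
    n <- length(gid)
    sub <- vapply(by_fam[fid], function(s) s[sample.int(length(s), 1L)], "")
    hits <- data.frame(
      protein_id = sprintf("%s|%s", gid, fid), genome_id = gid,
      subfamily_id = unname(sub),
      score = round(runif(n, 150, 400), 1),
      evalue = 10^-runif(n, 6, 40),
      coverage = round(runif(n, 0.6, 1), 3), stringsAsFactors = FALSE)
    dec <- which(runif(n) < decoy_rate)
    if (length(dec)) {
      decoys <- hits[dec, ]
      decoys$subfamily_id <- sample(subfam_map$subfamily_id, length(dec),
                                    replace = TRUE)
      decoys$score <- decoys$score * runif(length(dec), 0.3, 0.8)
      decoys$coverage <- round(runif(length(dec), 0.05, 0.5), 3)
      hits <- rbind(hits, decoys)
    }
    rownames(hits) <- NULL
    hits
  })
}

#' Generate a complete synthetic study
#'
#' Produces everything the pipeline consumes for one genome dataset:
#' presence-matrix truth, protein catalog, similarity/profile hit tables and
#' an SCG table.  Optionally appends quality-control "fodder": genomes that
#' fail the completeness or contamination filters and replicate copies that
#' de-replication must remove, so the QC stage is exercised without touching
#' the analyzed set.
#'
#' @param truth a [pangenome_truth()] object.
#' @param noise hit-table noise fraction.
#' @param n_low_completeness,n_replicates,n_contaminated QC-fodder genomes.
#' @param sequences if TRUE, also generate the protein sequences (FASTA
#'   content); the hit tables never require them.
#' @return list with `truth`, `matrix`, `taxonomy`, `genome_meta` (including
#'   fodder, with `replicate_cluster`), `proteins`, `hits` (`m8`,
#'   `profiles`), `scg`, and optionally `sequences`.
#' @export
simulate_study <- function(truth = default_truth(), noise = 0,
                           n_low_completeness = 2L, n_replicates = 2L,
                           n_contaminated = 1L, sequences = FALSE) {
  pm <- generate_presence_matrix(truth)
  proteins <- proteins_from_matrix(pm$matrix, seed = truth$seed + 2L)
  struth <- sequence_truth(proteins, seed = truth$seed + 3L)
  hits <- generate_hit_tables(struth, noise = noise)
  tax <- pm$taxonomy
  meta <- tax
  meta$replicate_cluster <- meta$genome_id
  comp <- rep(1 - unname(truth$dropout), length.out = nrow(meta))
  dup <- rep(0, nrow(meta))
  extra <- NULL
  mk_extra <- function(src_rows, suffix, completeness, duplication) {
    if (nrow(src_rows) == 0L) return(NULL)
    out <- src_rows
    out$genome_id <- paste0(src_rows$genome_id, suffix)
    out$completeness_target <- completeness
    out$duplication_target <- duplication
    out
  }
  with_seed(truth$seed + 4L, {
    if (n_low_completeness > 0L) {
      src <- tax[sample.int(nrow(tax), n_low_completeness), ]
      src$replicate_cluster <- paste0(src$genome_id, "_low")
      extra <- rbind(extra, mk_extra(src, "_low", 0.5, 0))
    }
    if (n_replicates > 0L) {
      src <- tax[sample.int(nrow(tax), n_replicates), ]
      src$replicate_cluster <- src$genome_id  # same cluster as the source
      extra <- rbind(extra, mk_extra(src, "_rep", 0.75, 0))
    }
    if (n_contaminated > 0L) {
      src <- tax[sample.int(nrow(tax), n_contaminated), ]
      src$replicate_cluster <- paste0(src$genome_id, "_dup")
      extra <- rbind(extra, mk_extra(src, "_dup", 0.95, 0.15))
    }
  })
  if (!is.null(extra)) {
    meta <- rbind(meta,
                  extra[, c("genome_id", "group", "phylum",
                            "replicate_cluster")])
    comp <- c(comp, extra$completeness_target)
    dup <- c(dup, extra$duplication_target)
  }
  scg <- generate_scg_table(meta, scg_config(), completeness = comp,
                            duplication = dup, seed = truth$seed + 5L)
  out <- list(truth = truth, matrix = pm$matrix, taxonomy = tax,
              genome_meta = meta, proteins = proteins, hits = hits,
              scg = scg)
  if (sequences)
    out$sequences <- generate_sequence_families(struth)
  out
}
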