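# Per-family two-sided Fisher's exact test of CPR vs non-CPR presence,
# Benjamini-Hochberg correction, and three-way categorization requiring
# significance (and a consistent direction) in both genome datasets.

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' For the 2x2 table `(a, b; c, d)` (rows: CPR with/without, non-CPR
#' with/without), sums the hypergeometric probabilities, computed in log
#' space, of all tables with the same margins whose point probability does
#' not exceed that of the observed table (within 1e-12 relative tolerance).
#' A table with a zero margin carries no information; its p-value is 1 by
#' convention, with a warning.
#'
#' Vectorized over tables; tables sharing margins reuse one enumeration.
#'
#' @param a,b,c,d non-negative integer counts (recycled to equal length).
#' @return p-values in `[0, 1]`.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), len); b <- rep_len(as.integer(b), len)
  c <- rep_len(as.integer(c), len); d <- rep_len(as.integer(d), len)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("counts must be non-negative")
  m1 <- a + b; m2 <- c + d; k <- a + c
  p <- numeric(len)
  degenerate <- m1 == 0L | m2 == 0L | k == 0L | k == m1 + m2
  if (any(degenerate)) {
    warning("tables with a zero margin: p = 1 by convention")
    p[degenerate] <- 1
  }
  todo <- which(!degenerate)
  if (length(todo)) {
    key <- paste(m1[todo], m2[todo], k[todo], sep = ":")
    for (grp in split(todo, key)) {
      i1 <- grp[1L]
      M1 <- m1[i1]; M2 <- m2[i1]; K <- k[i1]
      lo <- max(0L, K - M2); hi <- min(K, M1)
      x <- lo:hi
      logp <- lchoose(M1, x) + lchoose(M2, K - x) - lchoose(M1 + M2, K)
      pm <- exp(logp)
      obs <- logp[match(a[grp], x)]
      # p = sum of pmf over tables at most as probable as the observed one
      p[grp] <- vapply(obs, function(lo_obs)
        sum(pm[logp <= lo_obs + log1p(1e-12)]), 0)
    }
  }
  pmin(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at
#' 1, with input order restored.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot_prob(pvalues, "pvalues")
  p.adjust(pvalues, method = "BH")
}

#' Categorize families as CPR-enriched, depleted or equally distributed
#'
#' Per dataset and family, builds the presence contingency table over CPR
#' vs. non-CPR bacterial genomes (archaea are excluded), computes the
#' two-sided Fisher p-value and BH-adjusts it across all families tested in
#' that dataset.  A family is `enriched` iff its q-value is below `alpha`
#' in both datasets and its CPR presence frequency exceeds the non-CPR
#' frequency in both; `depleted` iff significant in both with the CPR
#' frequency lower in both; everything else is `equal`.  Families
#' significant in both datasets but with conflicting directions are
#' categorized `equal` and flagged.
#'
#' @param matrix_1,matrix_2 0/1 presence matrices (genomes x families) of
#'   the two datasets.  Families absent from one matrix get presence counts
#'   of 0 there.
#' @param taxonomy_1,taxonomy_2 data.frames `genome_id`, `group`.
#' @param alpha significance threshold on the adjusted p-value (strict;
#'   default 1e-5).
#' @return data.frame of class `enrichment_results`: one row per family in
#'   the union, with counts `a`/`b`/`c`/`d`, `p` and `q` per dataset,
#'   per-dataset frequencies, `category` and `direction_conflict`.
#' @export
categorize_families <- function(matrix_1, taxonomy_1, matrix_2, taxonomy_2,
                                alpha = 1e-5) {
  fams <- sort(union(colnames(matrix_1), colnames(matrix_2)))
  one_dataset <- function(mat, tax) {
    tax <- tax[tax$group %in% c("CPR", "BAC"), , drop = FALSE]
    cpr_ids <- intersect(rownames(mat), tax$genome_id[tax$group == "CPR"])
    bac_ids <- intersect(rownames(mat), tax$genome_id[tax$group == "BAC"])
    n_cpr <- length(cpr_ids); n_bac <- length(bac_ids)
    a <- b <- c_ <- d <- integer(length(fams))
    present <- fams %in% colnames(mat)
    a[present] <- as.integer(colSums(mat[cpr_ids, fams[present],
                                         drop = FALSE]))
    c_[present] <- as.integer(colSums(mat[bac_ids, fams[present],
                                          drop = FALSE]))
    b <- n_cpr - a; d <- n_bac - c_
    p <- fisher_exact_two_sided(a, b, c_, d)
    q <- bh_adjust(p)
    list(a = a, b = b, c = c_, d = d, p = p, q = q,
         f_cpr = if (n_cpr > 0) a / n_cpr else rep(NA_real_, length(a)),
         f_bac = if (n_bac > 0) c_ / n_bac else rep(NA_real_, length(a)))
  }
  d1 <- suppressWarnings(one_dataset(matrix_1, taxonomy_1))
  d2 <- suppressWarnings(one_dataset(matrix_2, taxonomy_2))
  sig <- d1$q < alpha & d2$q < alpha
  up <- d1$f_cpr > d1$f_bac & d2$f_cpr > d2$f_bac
  down <- d1$f_cpr < d1$f_bac & d2$f_cpr < d2$f_bac
  category <- rep("equal", length(fams))
  category[sig & up] <- "enriched"
  category[sig & down] <- "depleted"
  conflict <- sig & !up & !down
  out <- data.frame(family_id = fams,
                    a1 = d1$a, b1 = d1$b, c1 = d1$c, d1 = d1$d,
                    a2 = d2$a, b2 = d2$b, c2 = d2$c, d2 = d2$d,
                    p1 = d1$p, q1 = d1$q, p2 = d2$p, q2 = d2$q,
                    freq_cpr_1 = d1$f_cpr, freq_bac_1 = d1$f_bac,
                    freq_cpr_2 = d2$f_cpr, freq_bac_2 = d2$f_bac,
                    category = category, direction_conflict = conflict,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' @export
print.enrichment_results <- function(x, ...) {
  tab <- table(factor(x$category, c("enriched", "depleted", "equal")))
  cat(sprintf("Enrichment categorization of %d families (CPR vs non-CPR, both datasets):\n",
              nrow(x)))
  cat(sprintf("  enriched in CPR: %d\n  depleted in CPR: %d\n  equally distributed: %d\n",
              tab[["enriched"]], tab[["depleted"]], tab[["equal"]]))
  if (any(x$direction_conflict))
    cat(sprintf("  (%d significant with conflicting directions, kept equal)\n",
                sum(x$direction_conflict)))
  invisible(x)
}
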