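# Tabular readers/writers for the formats the pipeline consumes and emits.
# Similarity hits use the 12-column m8 dialect plus two appended columns
# (query coverage, target coverage), because the downstream cover filter
# needs explicit coverage which plain m8 lacks.

m8_columns <- function() {
  c("query", "target", "identity", "alnlen", "mismatch", "gapopen",
    "qstart", "qend", "tstart", "tend", "evalue", "bits", "qcov", "tcov")
}

#' Read an m8-dialect similarity table
#'
#' Tab-separated, no header: the 12 standard tabular-alignment columns plus
#' query coverage and target coverage.  Malformed rows (wrong field count or
#' non-numeric scores) are reported with their line numbers and either
#' skipped or fatal.
#'
#' @param path file path.
#' @param on_error `"skip"` (drop bad rows with a warning) or `"fail"`.
#' @return data.frame with columns `r paste(m8_columns(), collapse = ", ")`.
#' @export
read_m8 <- function(path, on_error = c("skip", "fail")) {
  on_error <- match.arg(on_error)
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) != 14L)
    stop(sprintf("%s: expected 14 tab-separated columns, found %d",
                 path, ncol(raw)))
  names(raw) <- m8_columns()
  num_cols <- setdiff(m8_columns(), c("query", "target"))
  suppress <- function(x) suppressWarnings(as.numeric(x))
  nums <- lapply(raw[num_cols], suppress)
  bad <- Reduce(`|`, lapply(nums, is.na))
  if (any(bad)) {
    msg <- sprintf("%s: malformed rows at lines %s", path,
                   paste(head(which(bad), 10L), collapse = ", "))
    if (on_error == "fail") stop(msg)
    warning(msg, "; skipped")
  }
  out <- data.frame(query = raw$query, target = raw$target, nums,
                    stringsAsFactors = FALSE)
  out[!bad, , drop = FALSE]
}

#' @rdname read_m8
#' @param hits m8 data.frame to write.
#' @export
write_m8 <- function(hits, path) {
  write.table(hits[, m8_columns()], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a profile-match table
#'
#' Tab-separated with header: subfamily_a, subfamily_b, probability (percent
#' in `[0, 100]`), coverage (`[0, 1]`).
#' @param path file path.
#' @export
read_profile_matches <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subfamily_a", "subfamily_b", "probability", "coverage")
  if (!all(need %in% names(d)))
    stop(sprintf("%s: need columns %s", path, paste(need, collapse = ", ")))
  d
}

#' @rdname read_profile_matches
#' @param matches profile-match data.frame.
#' @export
write_profile_matches <- function(matches, path) {
  write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a presence/absence matrix as TSV
#'
#' Genomes as rows, families as columns, 0/1 cells, with a header row and a
#' leading `genome_id` column.
#' @param mat integer 0/1 matrix with dimnames.
#' @param path file path.
#' @export
write_presence_matrix <- function(mat, path) {
  df <- data.frame(genome_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "integer"
  if (any(mat != 0L & mat != 1L)) stop(path, ": cells must be 0/1")
  mat
}

#' Read/write genome metadata (taxonomy) TSV
#'
#' Columns: genome_id, group, phylum, and optionally replicate_cluster,
#' completeness, contamination.
#' @param path file path.
#' @export
read_taxonomy <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "group", "phylum") %in% names(d)))
    stop(path, ": need columns genome_id, group, phylum")
  d
}

#' @rdname read_taxonomy
#' @param taxonomy data.frame to write.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write protein sequences to FASTA
#' @param seqs an `AAStringSet`.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
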