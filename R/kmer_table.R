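#' Construct a k-mer table
#'
#' The sole input of the crawl aligner: a set of distinct fixed-length DNA
#' k-mers, each with one numeric binding metric (relative enrichment, log
#' enrichment, or any quantity whose rank tracks binding affinity; larger =
#' stronger binding).
#'
#' @param sequences character vector of k-mers over A/C/G/T (lower case is
#'   uppercased), all of identical length.
#' @param metrics numeric vector, one finite value per sequence.
#' @return An object of class `kmer_table`: a list with elements `sequences`,
#'   `metrics` and `k`.
#' @examples
#' kmer_table(c("GTAAACA", "AGTAAAC"), c(9, 5))
#' @export
kmer_table <- function(sequences, metrics) {
  sequences <- toupper(as.character(sequences))
  metrics <- as.numeric(metrics)
  if (length(sequences) != length(metrics)) {
    stop_tdc("sequences and metrics must have the same length")
  }
  if (length(sequences) < 1L) stop_tdc("k-mer table is empty")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop_tdc(sprintf("mixed k-mer lengths: row %d ('%s', length %d) differs from length %d",
                     bad, sequences[bad], lens[bad], lens[1L]))
  }
  bad_alpha <- grepl("[^ACGT]", sequences)
  if (any(bad_alpha)) {
    bad <- which(bad_alpha)[1L]
    stop_tdc(sprintf("non-ACGT character in row %d: '%s'", bad, sequences[bad]))
  }
  dup <- duplicated(sequences)
  if (any(dup)) {
    stop_tdc(sprintf("duplicate k-mer '%s'; aggregate metrics upstream before alignment",
                     sequences[which(dup)[1L]]))
  }
  if (any(!is.finite(metrics))) {
    stop_tdc(sprintf("non-finite metric in row %d", which(!is.finite(metrics))[1L]))
  }
  structure(list(sequences = sequences, metrics = metrics, k = lens[1L]),
            class = "kmer_table")
}

#' Read a k-mer table from a tab-delimited file
#'
#' Expects one k-mer per row with at least one numeric metric column. A single
#' header row is auto-detected (first row whose metric field is non-numeric)
#' unless `header` is given explicitly.
#'
#' @param path path to a tab-delimited file.
#' @param metric_column column name or index holding the binding metric
#'   (default: second column).
#' @param header `NA` (auto-detect, default), `TRUE` or `FALSE`.
#' @param skip_invalid if `TRUE`, rows containing non-ACGT characters are
#'   dropped with a warning instead of raising an error.
#' @return A [kmer_table].
#' @export
read_kmer_table <- function(path, metric_column = 2L, header = NA,
                            skip_invalid = FALSE) {
  if (!file.exists(path)) stop_tdc(sprintf("input file not found: %s", path))
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE, blank.lines.skip = TRUE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    stop_tdc("k-mer table must contain at least 2 rows; file is empty")
  }
  col_names <- NULL
  if (is.character(metric_column)) {
    # a named metric column implies the first row is a header
    hdr <- as.character(raw[1L, ])
    idx <- match(metric_column, hdr)
    if (is.na(idx)) stop_tdc(sprintf("metric column '%s' not found in header", metric_column))
    metric_column <- idx
    header <- TRUE
  }
  if (metric_column > ncol(raw)) {
    stop_tdc(sprintf("metric column %d requested but file has %d columns",
                     metric_column, ncol(raw)))
  }
  if (is.na(header)) {
    header <- suppressWarnings(is.na(as.numeric(raw[1L, metric_column])))
  }
  if (header) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) < 2L) stop_tdc("k-mer table must contain at least 2 rows")
  seqs <- toupper(as.character(raw[[1L]]))
  metrics <- suppressWarnings(as.numeric(raw[[metric_column]]))
  if (any(is.na(metrics))) {
    bad <- which(is.na(metrics))[1L]
    stop_tdc(sprintf("non-numeric metric in row %d: '%s'", bad, raw[bad, metric_column]))
  }
  if (skip_invalid) {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      warning(sprintf("skipping %d row(s) with non-ACGT characters (e.g. '%s')",
                      sum(bad), seqs[which(bad)[1L]]), call. = FALSE)
      seqs <- seqs[!bad]
      metrics <- metrics[!bad]
    }
    if (length(seqs) < 2L) stop_tdc("fewer than 2 valid rows after skipping invalid k-mers")
  }
  kmer_table(seqs, metrics)
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("k-mer table: %d sequences of length k = %d\n",
              length(x$sequences), x$k))
  cat(sprintf("  metric range: [%.4g, %.4g]\n", min(x$metrics), max(x$metrics)))
  invisible(x)
}

#' Merge reverse-complement k-mer pairs
#'
#' Optional preprocessing for double-stranded assays: each k-mer is replaced by
#' the lexicographically smaller of itself and its reverse complement. When both
#' orientations are present their metrics must be equal (a mismatch indicates
#' an upstream aggregation problem and is an error).
#'
#' @param table a [kmer_table].
#' @return A [kmer_table] of canonical k-mers.
#' @export
merge_revcomp <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  rc <- revcomp(table$sequences)
  canon <- ifelse(table$sequences <= rc, table$sequences, rc)
  split_metric <- split(table$metrics, canon)
  metrics <- vapply(split_metric, function(m) {
    if (length(m) > 1L && diff(range(m)) > 0) {
      stop_tdc("reverse-complement pair present with unequal metrics; merge or drop one orientation upstream")
    }
    m[1L]
  }, numeric(1))
  kmer_table(names(split_metric), unname(metrics))
}
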