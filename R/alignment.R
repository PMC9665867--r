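#' Construct an alignment of fixed-length k-mers
#'
#' An alignment maps each k-mer to an integer shift in base pairs relative to
#' the first reference (shift 0); negative shifts lie toward the 5' end. The
#' gap-padded representation places each k-mer inside a window of width
#' `(max shift - min shift) + k`, padding with the `_` character.
#'
#' @param sequences character vector of ungapped k-mers (A/C/G/T, equal length).
#' @param shifts integer vector of shifts, one per sequence.
#' @param metrics numeric vector of binding metrics, one per sequence.
#' @return An object of class `tdc_alignment` with elements `sequences`,
#'   `shifts`, `metrics` and `k`.
#' @export
tdc_alignment <- function(sequences, shifts, metrics) {
  tab <- kmer_table(sequences, metrics)
  shifts <- as.integer(shifts)
  if (length(shifts) != length(tab$sequences) || any(is.na(shifts))) {
    stop_tdc("shifts must be one finite integer per sequence")
  }
  structure(list(sequences = tab$sequences, shifts = shifts,
                 metrics = tab$metrics, k = tab$k),
            class = "tdc_alignment")
}

#' Gap-padded sequences of an alignment
#'
#' @param alignment a [tdc_alignment].
#' @return character vector of padded strings of common width
#'   `(max shift - min shift) + k`, with `_` for gaps.
#' @export
padded_sequences <- function(alignment) {
  stopifnot(inherits(alignment, "tdc_alignment"))
  lead <- alignment$shifts - min(alignment$shifts)
  width <- max(lead) + alignment$k
  trail <- width - alignment$k - lead
  paste0(strrep("_", lead), alignment$sequences, strrep("_", trail))
}

#' @export
print.tdc_alignment <- function(x, ...) {
  cat(sprintf("alignment: %d k-mers (k = %d), shifts %d..%d\n",
              length(x$sequences), x$k, min(x$shifts), max(x$shifts)))
  n <- min(6L, length(x$sequences))
  ord <- order(-x$metrics, x$sequences)[seq_len(n)]
  pad <- padded_sequences(x)
  for (i in ord) {
    cat(sprintf("  %s  %+d  %.4g\n", pad[i], x$shifts[i], x$metrics[i]))
  }
  if (length(x$sequences) > n) cat(sprintf("  ... %d more\n", length(x$sequences) - n))
  invisible(x)
}

#' Write an alignment as a gap-padded tab-delimited file
#'
#' Columns are the padded sequence (gaps as `_`), the shift, and the metric;
#' rows are ordered by descending metric. Metrics are written with 12
#' significant digits so that [read_alignment()] round-trips exactly at that
#' precision.
#'
#' @param alignment a [tdc_alignment].
#' @param path output path.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "tdc_alignment"))
  pad <- padded_sequences(alignment)
  ord <- order(-alignment$metrics, alignment$sequences)
  lines <- c("seq\tshift\tmetric",
             paste(pad[ord], alignment$shifts[ord],
                   format_metric(alignment$metrics[ord]), sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_tdc(sprintf("cannot write alignment to '%s'", path))
  invisible(path)
}

#' Read a gap-padded alignment file
#'
#' Shifts are recovered from the leading gap counts and cross-checked against
#' the shift column written by [write_alignment()].
#'
#' @param path path to a file written by [write_alignment()].
#' @return A [tdc_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_tdc(sprintf("alignment file not found: %s", path))
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (identical(tolower(raw[1L, 1L]), "seq")) raw <- raw[-1L, , drop = FALSE]
  if (ncol(raw) < 3L || nrow(raw) < 1L) stop_tdc("malformed alignment file")
  padded <- toupper(raw[[1L]])
  shifts <- suppressWarnings(as.integer(raw[[2L]]))
  metrics <- suppressWarnings(as.numeric(raw[[3L]]))
  if (any(is.na(shifts)) || any(is.na(metrics))) stop_tdc("malformed alignment file")
  if (!all(grepl("^_*[ACGT]+_*$", padded))) {
    stop_tdc("alignment file contains a malformed or non-contiguous padded k-mer")
  }
  seqs <- gsub("_", "", padded, fixed = TRUE)
  lead <- nchar(sub("[ACGT].*$", "", padded))
  # leading-gap counts determine shifts up to the (constant) minimum shift
  origin <- shifts - lead
  if (length(unique(origin)) != 1L) {
    stop_tdc("alignment file is inconsistent: shift column does not match gap padding")
  }
  tdc_alignment(seqs, shifts, metrics)
}
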