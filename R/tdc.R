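#' Single base-pair mutation neighbours of a k-mer
#'
#' All `3k` strings at Hamming distance exactly 1 from `seq`. During the crawl
#' these inherit the reference's shift: a point mutation does not move the
#' binding-site register.
#'
#' @param seq a single k-mer string over A/C/G/T.
#' @return character vector of `3k` distinct k-mers, excluding `seq` itself.
#' @examples
#' single_bp_neighbors("AC")
#' @export
single_bp_neighbors <- function(seq) {
  seq <- toupper(seq)
  if (length(seq) != 1L || grepl("[^ACGT]", seq)) {
    stop_tdc("seq must be a single A/C/G/T string")
  }
  k <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- character(3L * k)
  idx <- 0L
  for (i in seq_len(k)) {
    for (b in BASES) {
      if (b == chars[i]) next
      idx <- idx + 1L
      mutated <- chars
      mutated[i] <- b
      out[idx] <- paste(mutated, collapse = "")
    }
  }
  out
}

#' Overlap candidates of a reference k-mer
#'
#' Finds members of `universe` that overlap `reference` by `k-1` or `k-2` bp.
#' A k-mer whose last `k-d` characters equal the reference's first `k-d`
#' characters extends the 5' end and carries relative shift `-d`; the mirror
#' case on the 3' end carries `+d` (d in 1, 2). A k-mer satisfying several
#' overlap offsets is reported once, at the smallest `|shift|`, 5' before 3'.
#'
#' @param reference a single k-mer string (k >= 3).
#' @param universe character vector of candidate k-mers of the same length.
#' @return data frame with columns `kmer` and `shift` (values in -2,-1,1,2).
#'   The reference itself is never a candidate.
#' @examples
#' overlap_candidates("GTAAACA", c("AGTAAAC", "TAAACAG"))
#' @export
overlap_candidates <- function(reference, universe) {
  reference <- toupper(reference)
  k <- nchar(reference)
  if (k < 3L) stop_tdc("overlap rule requires k >= 3")
  universe <- setdiff(toupper(universe), reference)
  found <- character(0)
  shifts <- integer(0)
  # precedence: |shift| 1 before 2, 5' (-d) before 3' (+d)
  for (d in 1:2) {
    for (side in c(-1L, 1L)) {
      if (side < 0L) {
        hits <- universe[substr(universe, d + 1L, k) == substr(reference, 1L, k - d)]
      } else {
        hits <- universe[substr(universe, 1L, k - d) == substr(reference, d + 1L, k)]
      }
      hits <- setdiff(hits, found)
      found <- c(found, hits)
      shifts <- c(shifts, rep(side * d, length(hits)))
    }
  }
  data.frame(kmer = found, shift = shifts, stringsAsFactors = FALSE)
}

#' Align a k-mer table with the Top-Down Crawl algorithm
#'
#' The crawl assigns the k-mer with the largest binding metric a shift of
#' 0 bp and marks it as the first reference. Each round recruits, from the
#' unaligned pool, (1) all single-bp mutation neighbours of the reference,
#' which inherit the reference's shift, then (2) all k-mers overlapping the
#' reference by `k-1` or `k-2` bp, which receive the reference's shift +/- 1
#' or 2 bp according to the overlapping end. The reference is then marked
#' complete, and the next reference is the highest-metric aligned-but-not-
#' complete k-mer. The crawl terminates when every aligned k-mer is complete;
#' shifts are never reassigned. K-mers unreachable from the seed remain
#' unaligned and are returned separately.
#'
#' Equal metrics are broken lexicographically by sequence so runs are
#' reproducible. For k < 3 only the mutation rule applies.
#'
#' @param table a [kmer_table].
#' @param revcomp_merge if `TRUE`, k-mers are first canonicalised with
#'   [merge_revcomp()].
#' @return A list of class `tdc_result`: `alignment` (a [tdc_alignment]),
#'   `unaligned` (data frame of unreached k-mers and metrics) and `trace`
#'   (data frame: reference k-mer and number of newly aligned k-mers per
#'   round, seed round first).
#' @examples
#' res <- top_down_crawl(kmer_table(c("GTAAACA", "AGTAAAC"), c(9, 5)))
#' res$alignment$shifts
#' @export
top_down_crawl <- function(table, revcomp_merge = FALSE) {
  stopifnot(inherits(table, "kmer_table"))
  if (revcomp_merge) table <- merge_revcomp(table)
  seqs <- table$sequences
  metrics <- table$metrics
  k <- table$k
  n <- length(seqs)

  index_of <- new.env(parent = emptyenv(), size = n)
  for (i in seq_len(n)) assign(seqs[i], i, envir = index_of)

  # prefix/suffix indexes for O(1) overlap candidate lookup
  overlap_index <- NULL
  if (k >= 3L) {
    overlap_index <- list()
    for (d in 1:2) {
      pre <- substr(seqs, 1L, k - d)
      suf <- substr(seqs, d + 1L, k)
      overlap_index[[paste0("pre", d)]] <- split(seq_len(n), pre)
      overlap_index[[paste0("suf", d)]] <- split(seq_len(n), suf)
    }
  }

  shift <- rep(NA_integer_, n)
  complete <- rep(FALSE, n)
  frontier <- integer(0)   # aligned but not complete

  seed <- order(-metrics, seqs)[1L]
  shift[seed] <- 0L
  frontier <- seed
  trace_ref <- character(0)
  trace_new <- integer(0)

  while (length(frontier) > 0L) {
    ref <- frontier[order(-metrics[frontier], seqs[frontier])[1L]]
    rseq <- seqs[ref]
    newly <- 0L

    # mutation neighbours first: same register, strongest evidence
    for (m in single_bp_neighbors(rseq)) {
      j <- get0(m, envir = index_of, ifnotfound = NULL)
      if (!is.null(j) && is.na(shift[j])) {
        shift[j] <- shift[ref]
        frontier <- c(frontier, j)
        newly <- newly + 1L
      }
    }

    if (k >= 3L) {
      for (d in 1:2) {
        for (side in c(-1L, 1L)) {
          key <- if (side < 0L) substr(rseq, 1L, k - d) else substr(rseq, d + 1L, k)
          bucket <- if (side < 0L) overlap_index[[paste0("suf", d)]][[key]] else
                                   overlap_index[[paste0("pre", d)]][[key]]
          for (j in bucket) {
            if (j != ref && is.na(shift[j])) {
              shift[j] <- shift[ref] + side * d
              frontier <- c(frontier, j)
              newly <- newly + 1L
            }
          }
        }
      }
    }

    complete[ref] <- TRUE
    frontier <- frontier[frontier != ref]
    trace_ref <- c(trace_ref, rseq)
    trace_new <- c(trace_new, if (length(trace_ref) == 1L) newly + 1L else newly)
  }

  aligned <- !is.na(shift)
  structure(list(
    alignment = tdc_alignment(seqs[aligned], shift[aligned], metrics[aligned]),
    unaligned = data.frame(kmer = seqs[!aligned], metric = metrics[!aligned],
                           stringsAsFactors = FALSE),
    trace = data.frame(reference = trace_ref, n_new = trace_new,
                       stringsAsFactors = FALSE)
  ), class = "tdc_result")
}

#' @export
print.tdc_result <- function(x, ...) {
  cat(sprintf("Top-Down Crawl result: %d aligned, %d unaligned, %d rounds\n",
              length(x$alignment$sequences), nrow(x$unaligned), nrow(x$trace)))
  print(x$alignment)
  invisible(x)
}
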