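#' Construct a position weight matrix
#'
#' @param matrix numeric matrix, positions in rows and the four bases
#'   (A, C, G, T) in columns; each row must sum to 1 within 1e-6 and is
#'   renormalised exactly.
#' @param background length-4 base background distribution (default uniform).
#' @return An object of class `pwm` with elements `matrix`, `width` and
#'   `background`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L || nrow(matrix) < 1L) {
    stop_tdc("PWM matrix must have >= 1 position row and 4 base columns")
  }
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop_tdc("PWM entries must be finite and non-negative")
  }
  sums <- rowSums(matrix)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_tdc(sprintf("PWM position %d probabilities sum to %.8f, not 1",
                     which(abs(sums - 1) > 1e-6)[1L], sums[abs(sums - 1) > 1e-6][1L]))
  }
  matrix <- matrix / sums
  colnames(matrix) <- BASES
  background <- background / sum(background)
  structure(list(matrix = matrix, width = nrow(matrix), background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, digits = 3, ...) {
  cat(sprintf("PWM: %d positions\n", x$width))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Build an enrichment-weighted PWM from an alignment
#'
#' Rows with `|shift| > max_abs_shift` are excluded; the remaining k-mers are
#' stacked in a window of width `2 * max_abs_shift + k` and each base count is
#' weighted by the k-mer's binding metric. Each window column is normalised
#' over the total weight of the sequences covering it, so gap positions
#' contribute nothing. Metrics must be non-negative: exponentiate log
#' enrichments before calling.
#'
#' @param alignment a [tdc_alignment] with non-negative metrics.
#' @param max_abs_shift window half-width in bp (default 5, matching a
#'   +/-5 bp window around 10-mer alignments).
#' @param pseudoweight value added to every base weight at every column
#'   (default 0; metrics are weights, not counts).
#' @return A [pwm] of width `2 * max_abs_shift + k`.
#' @export
pwm_from_alignment <- function(alignment, max_abs_shift = 5L, pseudoweight = 0) {
  stopifnot(inherits(alignment, "tdc_alignment"))
  if (max_abs_shift < 0L) stop_tdc("max_abs_shift must be >= 0")
  if (pseudoweight < 0) stop_tdc("pseudoweight must be >= 0")
  if (any(alignment$metrics < 0)) {
    stop_tdc("negative metric: PWM weights must be non-negative; exponentiate log enrichments first")
  }
  k <- alignment$k
  keep <- abs(alignment$shifts) <= max_abs_shift
  if (!any(keep)) stop_tdc("no k-mers within +/- max_abs_shift of the origin")
  width <- 2L * max_abs_shift + k
  counts <- matrix(pseudoweight, nrow = width, ncol = 4L,
                   dimnames = list(NULL, BASES))
  seqs <- alignment$sequences[keep]
  shifts <- alignment$shifts[keep]
  w <- alignment$metrics[keep]
  for (i in seq_along(seqs)) {
    pos <- shifts[i] + max_abs_shift + seq_len(k)   # window rows covered
    base <- match(strsplit(seqs[i], "", fixed = TRUE)[[1L]], BASES)
    for (j in seq_len(k)) counts[pos[j], base[j]] <- counts[pos[j], base[j]] + w[i]
  }
  tot <- rowSums(counts)
  uncovered <- tot == 0
  if (any(uncovered)) {
    warning(sprintf("%d window column(s) covered by no sequence; set to background",
                    sum(uncovered)), call. = FALSE)
    counts[uncovered, ] <- rep(0.25, 4)
    tot[uncovered] <- 1
  }
  pwm(counts / tot)
}

#' Pad a PWM with neutral positions
#'
#' Adds `pad` background-distribution columns to the 5' and 3' ends. Neutral
#' positions score zero log-odds against the same background, so padding never
#' changes which window of the PWM a k-mer prefers.
#'
#' @param pwm a [pwm].
#' @param pad number of neutral positions per side (>= 0).
#' @return A [pwm] of width `width + 2 * pad`.
#' @export
pad_pwm <- function(pwm, pad) {
  stopifnot(inherits(pwm, "pwm"))
  pad <- as.integer(pad)
  if (pad < 0L) stop_tdc("pad must be >= 0")
  if (pad == 0L) return(pwm)
  neutral <- matrix(pwm$background, nrow = pad, ncol = 4L, byrow = TRUE)
  pwm(rbind(neutral, pwm$matrix, neutral), background = pwm$background)
}

#' Assign shifts to k-mers by sliding them along a PWM
#'
#' Pads the PWM with `k-1` neutral positions per side, scores every placement
#' of each k-mer by summed log2 odds against the background (with a floor
#' probability of `floor_prob` per cell to avoid minus infinity), and reports
#' the best-scoring placement as a shift. Shift 0 places the k-mer start at
#' the PWM's anchor column, `floor((width - k) / 2)` positions into the
#' matrix, which makes shifts directly comparable to crawl shifts when the
#' PWM was built by [pwm_from_alignment()] with the same k. Score ties are
#' broken toward the smaller `|shift|`, then toward the 5' end. Neutral
#' (background-equal) flank columns of the input PWM are stripped before
#' scoring, so the result does not depend on pre-existing padding.
#'
#' @param pwm a [pwm].
#' @param table a [kmer_table].
#' @param floor_prob per-cell probability floor used in log-odds scoring.
#' @return Named integer vector mapping each k-mer to its best shift.
#' @export
pwm_align_kmers <- function(pwm, table, floor_prob = 1e-4) {
  stopifnot(inherits(pwm, "pwm"), inherits(table, "kmer_table"))
  k <- table$k
  # neutral flank columns carry no information; strip them so that results do
  # not depend on how much padding the PWM arrived with
  is_neutral <- apply(abs(pwm$matrix - matrix(pwm$background, nrow = pwm$width,
                                              ncol = 4L, byrow = TRUE)) < 1e-9,
                      1L, all)
  lo <- 1L
  hi <- pwm$width
  while (lo < hi && is_neutral[lo]) lo <- lo + 1L
  while (hi > lo && is_neutral[hi]) hi <- hi - 1L
  if (lo > 1L || hi < pwm$width) {
    pwm <- pwm(pwm$matrix[lo:hi, , drop = FALSE], background = pwm$background)
  }
  padded <- pad_pwm(pwm, k - 1L)
  if (k > padded$width) stop_tdc("k-mer longer than padded PWM")
  score_mat <- log2(pmax(padded$matrix, floor_prob) /
                    matrix(padded$background, nrow = padded$width, ncol = 4L, byrow = TRUE))
  anchor <- (pwm$width - k) %/% 2L
  offsets <- 0:(padded$width - k)            # 0-based start within padded PWM
  shifts_for <- offsets - (k - 1L) - anchor
  # tie preference: smaller |shift| first, 5' before 3'
  pref <- order(abs(shifts_for), shifts_for)
  out <- integer(length(table$sequences))
  names(out) <- table$sequences
  for (i in seq_along(table$sequences)) {
    base <- match(strsplit(table$sequences[i], "", fixed = TRUE)[[1L]], BASES)
    scores <- vapply(offsets, function(o) {
      sum(score_mat[cbind(o + seq_len(k), base)])
    }, numeric(1))
    best <- max(scores)
    pick <- pref[which(scores[pref] >= best - 1e-9)[1L]]
    out[i] <- shifts_for[pick]
  }
  out
}

#' Fraction of k-mers two aligners place at the same shift
#'
#' Different aligners anchor their shift origins differently, so raw shifts
#' are compared after reconciling origins: agreement is computed at the single
#' constant offset (searched over all observed shift differences) that
#' maximises it.
#'
#' @param reference_shifts named integer vector (k-mer -> shift).
#' @param other_shifts named integer vector from the other aligner.
#' @param eligible k-mers to compare (default: those present in both maps);
#'   must be non-empty and a subset of both.
#' @return Fraction in `[0, 1]` of eligible k-mers assigned the same shift
#'   after origin reconciliation.
#' @export
shift_agreement <- function(reference_shifts, other_shifts,
                            eligible = intersect(names(reference_shifts),
                                                 names(other_shifts))) {
  eligible <- as.character(eligible)
  if (length(eligible) == 0L) stop_tdc("no eligible k-mers shared by both alignments")
  if (!all(eligible %in% names(reference_shifts)) ||
      !all(eligible %in% names(other_shifts))) {
    stop_tdc("eligible k-mers must be aligned by both methods")
  }
  d <- reference_shifts[eligible] - other_shifts[eligible]
  max(table(d)) / length(eligible)
}

#' Write a PWM as a minimal MEME motif file
#'
#' @param pwm a [pwm].
#' @param path output path.
#' @param name motif name recorded in the file.
#' @export
write_pwm <- function(pwm, path, name = "motif") {
  stopifnot(inherits(pwm, "pwm"))
  rows <- apply(pwm$matrix, 1L, function(p) paste(sprintf("%.10g", p), collapse = " "))
  lines <- c("MEME version 4", "",
             "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             paste(sprintf("%s %.6g", BASES, pwm$background), collapse = " "), "",
             sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0", pwm$width),
             paste0(" ", rows))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_tdc(sprintf("cannot write PWM to '%s'", path))
  invisible(path)
}

#' Read a minimal MEME motif file
#'
#' Parses the first letter-probability matrix in the file; positions whose
#' probabilities deviate from sum 1 by more than 1e-3 are an error, smaller
#' deviations are renormalised.
#'
#' @param path path to a MEME-format motif file.
#' @return A [pwm].
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop_tdc(sprintf("PWM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L && bg_at[1L] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    if (length(toks) >= 8L) {
      vals <- suppressWarnings(as.numeric(toks[c(2L, 4L, 6L, 8L)]))
      names(vals) <- toks[c(1L, 3L, 5L, 7L)]
      if (!any(is.na(vals)) && all(BASES %in% names(vals))) bg <- unname(vals[BASES])
    }
  }
  at <- grep("^letter-probability matrix", lines)
  if (length(at) == 0L) stop_tdc("no letter-probability matrix found")
  at <- at[1L]
  w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[at])))
  body <- lines[-seq_len(at)]
  body <- body[nzchar(trimws(body))]
  rows <- list()
  for (ln in body) {
    toks <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
    if (length(toks) != 4L || any(is.na(toks))) break
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0L) stop_tdc("malformed letter-probability matrix")
  if (!is.na(w) && length(rows) < w) stop_tdc("letter-probability matrix shorter than declared width")
  if (!is.na(w)) rows <- rows[seq_len(w)]
  mat <- do.call(rbind, rows)
  sums <- rowSums(mat)
  if (any(abs(sums - 1) > 1e-3)) {
    stop_tdc(sprintf("PWM position %d sums to %.6f; deviation exceeds 1e-3",
                     which(abs(sums - 1) > 1e-3)[1L], sums[abs(sums - 1) > 1e-3][1L]))
  }
  pwm(mat / sums, background = bg)
}
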