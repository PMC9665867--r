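all_pentamers <- function() {
  g <- expand.grid(BASES, BASES, BASES, BASES, BASES, stringsAsFactors = FALSE)
  sort(apply(g[, 5:1], 1L, paste, collapse = ""))
}

validate_shape_table <- function(features) {
  pents <- all_pentamers()
  for (nm in names(features)) {
    vals <- features[[nm]]
    missing <- setdiff(pents, names(vals))
    if (length(missing) > 0L) {
      stop_tdc(sprintf("shape table is missing %d pentamer(s) for %s, e.g. %s",
                       length(missing), nm, paste(utils::head(missing, 5L), collapse = ", ")))
    }
    vals <- vals[pents]
    if (any(!is.finite(vals))) {
      stop_tdc(sprintf("non-finite %s value for pentamer %s",
                       nm, pents[which(!is.finite(vals))[1L]]))
    }
    asym <- abs(vals - vals[revcomp(pents)]) > 0.01
    if (any(asym)) {
      bad <- pents[which(asym)]
      stop_tdc(sprintf(
        "%s violates reverse-complement symmetry for %d pentamer(s), e.g. %s vs %s",
        nm, length(bad), bad[1L], revcomp(bad[1L])))
    }
    features[[nm]] <- vals
  }
  structure(features, class = "shape_table")
}

#' Load a pentamer DNA shape lookup table
#'
#' Reads a tab-delimited table with a header row and columns `pentamer`,
#' `MGW` (minor groove width, Angstrom) and `EP` (electrostatic potential,
#' kT/e): one value per pentamer, indexed by the centre base pair. All 1024
#' pentamers must be present, values finite, and each feature symmetric under
#' reverse complement within 0.01 (both features describe the double helix,
#' which has no preferred strand).
#'
#' @param path path to the TSV file.
#' @return An object of class `shape_table`: per-feature named numeric
#'   vectors over the 1024 pentamers.
#' @seealso [synthetic_shape_table()] for a download-free stand-in.
#' @export
load_shape_table <- function(path) {
  if (!file.exists(path)) stop_tdc(sprintf("shape table not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("pentamer", "MGW", "EP")
  if (!all(need %in% names(df))) {
    stop_tdc("shape table must have header columns: pentamer, MGW, EP")
  }
  pent <- toupper(df$pentamer)
  if (anyDuplicated(pent)) {
    stop_tdc(sprintf("duplicate pentamer '%s' in shape table", pent[duplicated(pent)][1L]))
  }
  feats <- list(MGW = stats::setNames(as.numeric(df$MGW), pent),
                EP = stats::setNames(as.numeric(df$EP), pent))
  validate_shape_table(feats)
}

#' Write a shape table to TSV
#'
#' @param table a `shape_table`.
#' @param path output path.
#' @export
write_shape_table <- function(table, path) {
  stopifnot(inherits(table, "shape_table"))
  pents <- all_pentamers()
  df <- data.frame(pentamer = pents, MGW = table$MGW[pents], EP = table$EP[pents])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministic synthetic pentamer shape table
#'
#' Generates a reverse-complement-symmetric stand-in for a pentamer shape
#' lookup: each canonical pentamer (the lexicographic minimum of the pentamer
#' and its reverse complement) is hashed to a value in a physically plausible
#' range (MGW in roughly 3.8-6.3 Angstrom, EP in roughly -12 to -2 kT/e). The
#' values are arbitrary but fixed, sufficient for testing feature plumbing;
#' real pentamer tables in the same TSV format plug in unchanged via
#' [load_shape_table()].
#'
#' @return A `shape_table`.
#' @export
synthetic_shape_table <- function() {
  pents <- all_pentamers()
  canon <- pmin(pents, revcomp(pents))
  # base-4 integer code of the canonical pentamer
  code <- vapply(strsplit(canon, "", fixed = TRUE), function(ch) {
    sum((match(ch, BASES) - 1L) * 4L^(4:0))
  }, numeric(1))
  scramble <- function(code, a, c) ((a * code + c) %% 2147483647) / 2147483647
  mgw <- 3.8 + 2.5 * scramble(code, 1103515245, 12345)
  ep <- -12 + 10 * scramble(code, 22695477, 1)
  validate_shape_table(list(MGW = stats::setNames(mgw, pents),
                            EP = stats::setNames(ep, pents)))
}

#' Per-position shape profile of a k-mer
#'
#' Slides a pentamer window along the k-mer and looks up each feature at the
#' centre position. The two outermost positions on each end lack full
#' pentamer context and are dropped, so the profile covers positions
#' `3..k-2` (length `k-4`).
#'
#' @param seq a single k-mer string, k >= 5.
#' @param table a `shape_table`.
#' @return Numeric matrix with `k-4` rows (positions) and one column per
#'   feature (MGW, EP).
#' @export
shape_profile <- function(seq, table) {
  stopifnot(inherits(table, "shape_table"))
  seq <- toupper(seq)
  k <- nchar(seq)
  if (k < 5L) stop_tdc("shape profile requires k >= 5")
  centers <- 3:(k - 2L)
  pents <- substring(seq, centers - 2L, centers + 2L)
  out <- vapply(table, function(vals) unname(vals[pents]), numeric(length(centers)))
  out <- matrix(out, nrow = length(centers),
                dimnames = list(NULL, names(table)))
  out
}
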