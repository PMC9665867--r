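#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the A/C/G/T alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "GTAAACA"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

BASES <- c("A", "C", "G", "T")

# Run code under a temporary RNG state so package functions taking a `seed`
# argument do not disturb the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shortest decimal representation preserving 12 significant digits, used for
# metric columns so write/read round-trips are exact at that precision.
format_metric <- function(x) {
  sprintf("%.12g", x)
}

stop_tdc <- function(...) stop(..., call. = FALSE)

random_kmers <- function(n, k) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(BASES, n * k, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}
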