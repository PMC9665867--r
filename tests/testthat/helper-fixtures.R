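# shared fixtures: everything is built in code at test time

worked_example_table <- function() {
  kmer_table(c("GTAAACA", "AGTAAAC"), c(9, 5))
}

random_table <- function(seed, k, n) {
  set.seed(seed)
  pool <- unique(replicate(n * 2, paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                                        collapse = "")))
  pool <- pool[seq_len(min(n, length(pool)))]
  kmer_table(pool, stats::runif(length(pool), 0, 10))
}

random_alignment <- function(seed, k = 6L, n = 12L, max_shift = 3L) {
  tab <- random_table(seed, k, n)
  set.seed(seed + 1000L)
  tdc_alignment(tab$sequences,
                sample(seq(-max_shift, max_shift), length(tab$sequences), replace = TRUE),
                tab$metrics)
}

random_pwm <- function(seed, width = 8L) {
  set.seed(seed)
  m <- matrix(stats::rexp(width * 4), ncol = 4)
  pwm(m / rowSums(m))
}

# naive reference crawl: rescans the full table every round with no priority
# structure or prefix/suffix indexes; deliberately independent of the package
# implementation
naive_crawl <- function(table) {
  seqs <- table$sequences
  metrics <- table$metrics
  k <- table$k
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  shift <- rep(NA_integer_, n)
  complete <- rep(FALSE, n)
  seed_i <- order(-metrics, seqs)[1L]
  shift[seed_i] <- 0L
  repeat {
    frontier <- which(!is.na(shift) & !complete)
    if (length(frontier) == 0L) break
    ref <- frontier[order(-metrics[frontier], seqs[frontier])[1L]]
    ham <- rowSums(chars != matrix(chars[ref, ], n, k, byrow = TRUE))
    shift[is.na(shift) & ham == 1L] <- shift[ref]       # mutations first
    if (k >= 3L) {
      for (d in 1:2) for (side in c(-1L, 1L)) {
        ok <- if (side < 0L) substr(seqs, d + 1L, k) == substr(seqs[ref], 1L, k - d)
              else substr(seqs, 1L, k - d) == substr(seqs[ref], d + 1L, k)
        hit <- is.na(shift) & ok & seq_len(n) != ref
        shift[hit] <- shift[ref] + side * d
      }
    }
    complete[ref] <- TRUE
  }
  stats::setNames(shift, seqs)
}

shift_map <- function(result) {
  stats::setNames(result$alignment$shifts, result$alignment$sequences)
}
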