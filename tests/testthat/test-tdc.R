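test_that("single-bp neighbours are exactly the Hamming-1 shell", {
  expect_setequal(single_bp_neighbors("AC"),
                  c("CC", "GC", "TC", "AA", "AG", "AT"))
  expect_setequal(single_bp_neighbors("A"), c("C", "G", "T"))
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(2:8, 1)
    s <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    nb <- single_bp_neighbors(s)
    expect_length(nb, 3L * k)
    expect_false(s %in% nb)
    expect_false(anyDuplicated(nb) > 0)
    hd <- vapply(nb, function(x) {
      sum(strsplit(x, "")[[1]] != strsplit(s, "")[[1]])
    }, integer(1))
    expect_true(all(hd == 1L))
  }
})

test_that("overlap candidates follow the 5'/3' shift rule with smallest-|shift| precedence", {
  # 5' extension: AGTAAAC's last 6 bases equal GTAAACA's first 6
  expect_equal(overlap_candidates("GTAAACA", "AGTAAAC"),
               data.frame(kmer = "AGTAAAC", shift = -1L))
  # 3' mirror
  expect_equal(overlap_candidates("GTAAACA", "TAAACAG"),
               data.frame(kmer = "TAAACAG", shift = 1L))
  # the reference is never its own candidate
  expect_equal(nrow(overlap_candidates("AAAAAAA", "AAAAAAA")), 0L)
  # AAAC matches both the k-1 (+1) and k-2 (+2) overlap of AAAA; +1 wins
  expect_equal(overlap_candidates("AAAA", "AAAC"),
               data.frame(kmer = "AAAC", shift = 1L))
  # 5' beats 3' at equal |shift| (palindromic-ish candidate)
  both <- overlap_candidates("ACACA", c("CACAC"))
  expect_equal(both$shift, -1L)
  expect_error(overlap_candidates("AC", "CA"), "k >= 3")
})

test_that("the crawl reproduces the reference worked example and edge cases", {
  res <- top_down_crawl(worked_example_table())
  sh <- shift_map(res)
  expect_equal(sh[["GTAAACA"]], 0L)
  expect_equal(sh[["AGTAAAC"]], -1L)
  expect_equal(res$trace$reference[1L], "GTAAACA")

  # single k-mer: aligned alone at shift 0, one trace round
  one <- top_down_crawl(kmer_table("ACGTACG", 1))
  expect_equal(shift_map(one), c(ACGTACG = 0L))
  expect_equal(nrow(one$trace), 1L)

  # disconnected k-mer stays unaligned and is reported
  disc <- top_down_crawl(kmer_table(c("AAAA", "CCCC"), c(3, 2)))
  expect_equal(shift_map(disc), c(AAAA = 0L))
  expect_equal(disc$unaligned$kmer, "CCCC")
})

test_that("crawl bookkeeping: seed rule, trace accounting, immutability via replay", {
  for (seed in 1:25) {
    tab <- random_table(seed, k = 4L, n = 60L)
    res <- top_down_crawl(tab)
    sh <- shift_map(res)
    top <- tab$sequences[order(-tab$metrics, tab$sequences)[1L]]
    expect_equal(sh[[top]], 0L)
    # every aligned k-mer served as reference exactly once
    expect_setequal(res$trace$reference, names(sh))
    expect_false(anyDuplicated(res$trace$reference) > 0)
    # per-round counts account for every aligned k-mer (seed counted in round 1)
    expect_equal(sum(res$trace$n_new), length(sh))
    expect_true(all(res$trace$n_new >= 0L))
    # conservation of input
    expect_equal(length(sh) + nrow(res$unaligned), length(tab$sequences))
  }
})

test_that("every aligned k-mer is reachable from the seed via mutation/overlap edges", {
  for (seed in 1:10) {
    tab <- random_table(seed, k = 4L, n = 80L)
    res <- top_down_crawl(tab)
    sh <- shift_map(res)
    aligned <- names(sh)
    reached <- tab$sequences[order(-tab$metrics, tab$sequences)[1L]]
    frontier <- reached
    while (length(frontier) > 0L) {
      nxt <- character(0)
      for (r in frontier) {
        nb <- intersect(single_bp_neighbors(r), aligned)
        ov <- overlap_candidates(r, aligned)$kmer
        nxt <- c(nxt, setdiff(c(nb, ov), reached))
      }
      nxt <- unique(nxt)
      reached <- c(reached, nxt)
      frontier <- nxt
    }
    expect_setequal(reached, aligned)
  }
})

test_that("crawl matches the naive rescan-every-round reference on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    tab <- random_table(seed, k = sample(3:5, 1), n = sample(20:120, 1))
    fast <- shift_map(top_down_crawl(tab))
    slow <- naive_crawl(tab)
    full <- stats::setNames(rep(NA_integer_, length(tab$sequences)), tab$sequences)
    full[names(fast)] <- fast
    expect_identical(full, slow[names(full)])
  }
})

test_that("crawl with k < 3 applies the mutation rule only", {
  tab <- kmer_table(c("AA", "AC", "CC", "GG"), c(4, 3, 2, 1))
  res <- top_down_crawl(tab)
  sh <- shift_map(res)
  # AA -> AC -> CC chains through Hamming-1; GG is unreachable without overlaps
  expect_equal(sort(names(sh)), c("AA", "AC", "CC"))
  expect_true(all(sh == 0L))
  expect_equal(res$unaligned$kmer, "GG")
})

test_that("reverse-complement mode canonicalises before crawling", {
  tab <- kmer_table(c("GTAAACA", "TGTTTAC"), c(9, 9))  # RC pair, equal metrics
  res <- top_down_crawl(tab, revcomp_merge = TRUE)
  expect_equal(length(res$alignment$sequences), 1L)
  expect_equal(res$alignment$sequences, "GTAAACA")
})
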