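test_that("Z-score filtering pins the sample-sd convention", {
  # metrics {0,0,0,10}: mean 2.5, sample sd (n-1) = 5, so Z(10) = 1.5;
  # the population-sd convention would give Z(10) = 10/sqrt(75/4) - wrong here
  tab <- kmer_table(c("AAAA", "AAAC", "AAAG", "AAAT"), c(0, 0, 0, 10))
  expect_error(zscore_filter(tab, threshold = 2), "no k-mers pass")
  kept <- zscore_filter(tab, threshold = 1.4)
  expect_equal(kept$sequences, "AAAT")
  expect_error(zscore_filter(tab, threshold = 1.5), "no k-mers pass")  # strict >

  # threshold -Inf is the identity
  all_kept <- zscore_filter(tab, threshold = -Inf)
  expect_setequal(all_kept$sequences, tab$sequences)

  expect_error(zscore_filter(kmer_table(c("AAAA", "AAAC"), c(1, 1))), "zero")
})

test_that("feature encoding lays out one-hot and shape blocks over the window", {
  shp <- synthetic_shape_table()
  al <- random_alignment(7, k = 10L, n = 15L, max_shift = 0L)
  fm <- encode_features(al, shp, window = c(0L, 0L))
  expect_equal(length(fm$onehot_cols), 40L)       # 4 * 10
  expect_equal(length(fm$shape_cols), 12L)        # 2 * (10 - 4)
  expect_equal(nrow(fm$x), 15L)
  # one-hot block sums to 1 per covered position
  oh <- fm$x[, fm$onehot_cols]
  pos_sums <- sapply(seq_len(10L), function(p) rowSums(oh[, 4L * (p - 1L) + 1:4]))
  expect_true(all(pos_sums == 1))
  expect_false(anyNA(fm$x[, fm$shape_cols]))      # full window coverage at shift 0

  # mixed shifts: uncovered positions are all-zero one-hot / NA shape
  al2 <- tdc_alignment(c("ACGTACGTAC", "CGTACGTACG"), c(0L, 1L), c(2, 1))
  fm2 <- encode_features(al2, shp, window = c(0L, 1L))
  W <- 1L + 10L
  expect_equal(length(fm2$onehot_cols), 4L * W)
  expect_equal(length(fm2$shape_cols), 2L * (W - 4L))
  oh2 <- fm2$x[, fm2$onehot_cols]
  expect_equal(sum(oh2[1L, (4L * (W - 1L) + 1L):(4L * W)]), 0)  # shift-0 row, last pos
  expect_equal(sum(oh2[2L, 1:4]), 0)                            # shift-1 row, first pos
  expect_true(anyNA(fm2$x[, fm2$shape_cols]))

  # a single row encodes to a single-row matrix
  fm1 <- encode_features(tdc_alignment("ACGTACGTAC", 0L, 1), shp, window = c(0L, 0L))
  expect_equal(nrow(fm1$x), 1L)

  # row order permutations permute the matrix rows identically
  al3 <- tdc_alignment(al2$sequences[c(2, 1)], al2$shifts[c(2, 1)], al2$metrics[c(2, 1)])
  fm3 <- encode_features(al3, shp, window = c(0L, 1L))
  expect_equal(fm3$x[match(fm2$sequences, fm3$sequences), ], fm2$x, ignore_attr = TRUE)

  expect_error(encode_features(al2, shp, window = c(5L, 9L)), "inside the window")
})

test_that("cross-validated elastic net separates signal from noise and is seeded", {
  shp <- synthetic_shape_table()
  set.seed(11)
  n <- 200L
  seqs <- unique(replicate(n * 2, paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                                        collapse = "")))[seq_len(n)]
  al <- tdc_alignment(seqs, rep(0L, n), rep(0, n))
  fm <- encode_features(al, shp, window = c(0L, 0L))

  # response exactly linear in the one-hot features -> near-perfect fit
  beta <- stats::rnorm(length(fm$onehot_cols))
  fm$y <- as.numeric(fm$x[, fm$onehot_cols] %*% beta)
  fit <- fit_mlr_cv(fm, folds = 5L, seed = 3L)
  expect_gte(fit$median_r2, 0.999)

  # pure-noise response -> no skill
  fm$y <- stats::rnorm(n)
  null_fit <- fit_mlr_cv(fm, folds = 5L, seed = 3L)
  expect_lte(null_fit$median_r2, 0.05)

  # identical seed, identical result; different seed may differ
  expect_identical(fit_mlr_cv(fm, folds = 5L, seed = 3L)$r2, null_fit$r2)

  expect_error(fit_mlr_cv(fm, folds = 300L), "fewer rows than folds")
})

test_that("duplicating every row leaves the cross-validated fit stable", {
  # stability holds where the model is well identified (n >> p); with n close
  # to p the held-out optimism itself exceeds the band being tested
  shp <- synthetic_shape_table()
  set.seed(11)
  n <- 2000L
  seqs <- unique(replicate(n * 3, paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                                        collapse = "")))[seq_len(n)]
  al <- tdc_alignment(seqs, rep(0L, n), rep(0, n))
  fm <- encode_features(al, shp, window = c(0L, 0L))
  beta <- stats::rnorm(length(fm$onehot_cols))
  sig <- as.numeric(fm$x[, fm$onehot_cols] %*% beta)
  fm$y <- sig + stats::rnorm(n, sd = 0.6 * stats::sd(sig))
  fit1 <- fit_mlr_cv(fm, folds = 5L, seed = 9L)
  fm2 <- fm
  fm2$x <- rbind(fm$x, fm$x)
  fm2$y <- c(fm$y, fm$y)
  fm2$sequences <- c(fm$sequences, fm$sequences)
  fit2 <- fit_mlr_cv(fm2, folds = 5L, seed = 9L)
  expect_lt(abs(fit1$median_r2 - fit2$median_r2), 0.02)
})
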