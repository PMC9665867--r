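#' Filter k-mers by metric Z-score
#'
#' Retains k-mers whose metric exceeds the mean by more than `threshold`
#' standard deviations, where mean and sd are computed over all input rows.
#' The sample standard deviation (n-1 denominator) is used. Intended for log
#' enrichment values; no transformation is applied here.
#'
#' @param table a [kmer_table].
#' @param threshold Z-score cutoff (default 2; strict inequality).
#' @return A [kmer_table] of the retained rows.
#' @export
zscore_filter <- function(table, threshold = 2) {
  stopifnot(inherits(table, "kmer_table"))
  s <- stats::sd(table$metrics)
  if (!is.finite(s) || s == 0) stop_tdc("metric standard deviation is zero; Z-score filter is undefined")
  z <- (table$metrics - mean(table$metrics)) / s
  keep <- z > threshold
  if (!any(keep)) stop_tdc("no k-mers pass the Z-score threshold")
  kmer_table(table$sequences[keep], table$metrics[keep])
}

#' Encode aligned k-mers as a regression feature matrix
#'
#' Lays out a window of alignment positions from `window[1]` to `window[2]`
#' (inclusive shift range; window width `diff(window) + k`). Each row encodes
#' one k-mer: 4 one-hot base indicator columns per window position, plus one
#' minor-groove-width and one electrostatic-potential column per window
#' position with full pentamer context (window width minus 4). Positions
#' outside a k-mer's span are all-zero in the one-hot block; the
#' corresponding shape entries are `NA` and are mean-imputed after
#' standardisation inside [fit_mlr_cv()], so rows with different shifts stay
#' comparable. The response is the k-mer's metric (log enrichment).
#'
#' @param alignment a [tdc_alignment]; rows with shifts outside `window` are
#'   excluded.
#' @param shapes a `shape_table`.
#' @param window integer length-2 inclusive shift range, e.g. `c(-5, 5)`.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `y` (response), `sequences`, `onehot_cols`, `shape_cols`,
#'   `window` and `k`.
#' @export
encode_features <- function(alignment, shapes, window = c(-5L, 5L)) {
  stopifnot(inherits(alignment, "tdc_alignment"), inherits(shapes, "shape_table"))
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L]) stop_tdc("window must be an inclusive shift range c(lo, hi)")
  k <- alignment$k
  if (k < 5L) stop_tdc("shape features require k >= 5")
  keep <- alignment$shifts >= window[1L] & alignment$shifts <= window[2L]
  if (!any(keep)) stop_tdc("no aligned k-mers fall inside the window")
  seqs <- alignment$sequences[keep]
  shifts <- alignment$shifts[keep]
  y <- alignment$metrics[keep]
  W <- window[2L] - window[1L] + k          # window width in bp
  n <- length(seqs)

  onehot <- matrix(0, nrow = n, ncol = 4L * W,
                   dimnames = list(NULL, paste0("pos", rep(seq_len(W), each = 4L), "_",
                                                rep(BASES, W))))
  n_shape_pos <- W - 4L
  shape <- matrix(NA_real_, nrow = n, ncol = 2L * n_shape_pos,
                  dimnames = list(NULL, paste0(rep(c("MGW", "EP"), each = n_shape_pos),
                                               "_pos", rep(3:(W - 2L), 2L))))
  for (i in seq_len(n)) {
    start <- shifts[i] - window[1L] + 1L    # 1-based window position of k-mer start
    base <- match(strsplit(seqs[i], "", fixed = TRUE)[[1L]], BASES)
    onehot[i, 4L * (start + seq_len(k) - 2L) + base] <- 1
    prof <- shape_profile(seqs[i], shapes)
    pos <- (start + 2L):(start + k - 3L)    # window positions with pentamer context
    col0 <- match(paste0("MGW_pos", pos), colnames(shape))
    shape[i, col0] <- prof[, "MGW"]
    shape[i, col0 + n_shape_pos] <- prof[, "EP"]
  }
  structure(list(x = cbind(onehot, shape), y = y, sequences = seqs,
                 onehot_cols = seq_len(4L * W),
                 shape_cols = 4L * W + seq_len(2L * n_shape_pos),
                 window = window, k = k),
            class = "feature_matrix")
}

#' Elastic-net regression with k-fold cross-validation
#'
#' Rows are shuffled with a seeded RNG and split into `folds` contiguous
#' folds. For each fold, predictors are standardised on the training split
#' (missing shape entries then imputed at the training mean, i.e. zero),
#' an elastic-net linear model is fitted with hyperparameters chosen by an
#' inner 3-fold grid search on the training split (`l1_ratio` over `alphas`,
#' a 20-value regularisation path), and R-squared is computed on the held-out
#' fold as `1 - SS_res / SS_tot` with `SS_tot` centred on the held-out fold's
#' own mean. Identical seeds give identical fold assignments and results.
#'
#' @param features a `feature_matrix` from [encode_features()].
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed controlling the row shuffle and inner folds.
#' @param alphas elastic-net mixing grid searched on the training split.
#' @param nlambda length of the regularisation path.
#' @return An object of class `mlr_cv`: list with `r2` (per-fold R-squared),
#'   `median_r2`, `folds`, `n` and `seed`.
#' @export
fit_mlr_cv <- function(features, folds = 5L, seed = 1L,
                       alphas = c(0.1, 0.5, 0.9), nlambda = 20L) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$x
  y <- features$y
  n <- nrow(x)
  if (n < folds) stop_tdc("fewer rows than folds")
  if (n < 2L * folds) stop_tdc("need at least 2 rows per fold")
  with_seed(seed, {
    perm <- sample.int(n)
    # contiguous blocks of the shuffled order
    fold_id <- integer(n)
    fold_id[perm] <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
    r2 <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      xtr <- x[!test, , drop = FALSE]
      xte <- x[test, , drop = FALSE]
      ytr <- y[!test]
      yte <- y[test]
      mu <- colMeans(xtr, na.rm = TRUE)
      sdv <- apply(xtr, 2L, stats::sd, na.rm = TRUE)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      mu[!is.finite(mu)] <- 0
      std <- function(m) {
        m <- sweep(sweep(m, 2L, mu), 2L, sdv, "/")
        m[is.na(m)] <- 0                     # mean imputation after standardisation
        m
      }
      xtr <- std(xtr)
      xte <- std(xte)
      inner_id <- rep_len(1:3, nrow(xtr))
      fits <- lapply(alphas, function(a) {
        glmnet::cv.glmnet(xtr, ytr, alpha = a, nlambda = nlambda,
                          foldid = inner_id, standardize = FALSE)
      })
      best <- which.min(vapply(fits, function(f) min(f$cvm), numeric(1)))
      pred <- as.numeric(stats::predict(fits[[best]], newx = xte, s = "lambda.min"))
      r2[f] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    }
    structure(list(r2 = r2, median_r2 = stats::median(r2),
                   folds = folds, n = n, seed = seed),
              class = "mlr_cv")
  })
}

#' @export
print.mlr_cv <- function(x, ...) {
  cat(sprintf("elastic-net CV (%d folds, n = %d): median R2 = %.4f\n",
              x$folds, x$n, x$median_r2))
  cat("  per-fold R2:", paste(sprintf("%.4f", x$r2), collapse = " "), "\n")
  invisible(x)
}

#' Score an alignment by cross-validated regression performance
#'
#' Convenience pipeline: optionally filter the aligned k-mers by metric
#' Z-score, encode one-hot and shape features over the given window, and fit
#' the cross-validated elastic net. A well-aligned table lets position-specific
#' base and shape changes predict log enrichment, yielding a higher median
#' R-squared than a poorly aligned one.
#'
#' @param alignment a [tdc_alignment] whose metrics are log enrichments.
#' @param shapes a `shape_table` (default: [synthetic_shape_table()]).
#' @param window inclusive shift range to encode (default `c(-5, 5)`).
#' @param zscore optional Z-score threshold applied to the aligned metrics
#'   before encoding (`NULL` = no filter).
#' @param folds,seed passed to [fit_mlr_cv()].
#' @return An `mlr_cv` object.
#' @export
evaluate_alignment <- function(alignment, shapes = synthetic_shape_table(),
                               window = c(-5L, 5L), zscore = NULL,
                               folds = 5L, seed = 1L) {
  stopifnot(inherits(alignment, "tdc_alignment"))
  if (!is.null(zscore)) {
    s <- stats::sd(alignment$metrics)
    if (!is.finite(s) || s == 0) stop_tdc("metric standard deviation is zero; Z-score filter is undefined")
    keep <- (alignment$metrics - mean(alignment$metrics)) / s > zscore
    if (!any(keep)) stop_tdc("no k-mers pass the Z-score threshold")
    alignment <- tdc_alignment(alignment$sequences[keep], alignment$shifts[keep],
                               alignment$metrics[keep])
  }
  fit_mlr_cv(encode_features(alignment, shapes, window), folds = folds, seed = seed)
}
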