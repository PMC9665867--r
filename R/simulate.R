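#' Ground-truth additive binding-energy model
#'
#' Draws a core binding site of `core_width` positions. At each position one
#' base (the consensus) contributes `consensus_energy` to the log enrichment
#' of any k-mer covering it; the other three bases contribute independent
#' draws from Uniform(0, `max_offtarget`). Contributions are additive across
#' positions, so the ground-truth offset of every k-mer is unambiguous.
#'
#' @param core_width number of core positions (>= 4).
#' @param seed integer seed.
#' @param consensus_energy per-position contribution of the consensus base.
#' @param max_offtarget upper bound of non-consensus contributions; must be
#'   strictly below `consensus_energy` so each column has a unique argmax.
#' @return An object of class `binding_energy_model`: list with `energy`
#'   (core_width x 4 matrix), `consensus`, `width` and `consensus_score`
#'   (the log enrichment of a perfectly placed consensus k-mer).
#' @export
binding_energy_model <- function(core_width = 7L, seed = 1L,
                                 consensus_energy = 1, max_offtarget = 0.5) {
  core_width <- as.integer(core_width)
  if (core_width < 4L) stop_tdc("core_width must be >= 4")
  if (max_offtarget >= consensus_energy) {
    stop_tdc("max_offtarget must be below consensus_energy")
  }
  with_seed(seed, {
    energy <- matrix(stats::runif(4L * core_width, 0, max_offtarget),
                     nrow = core_width, ncol = 4L, dimnames = list(NULL, BASES))
    cons_base <- sample.int(4L, core_width, replace = TRUE)
    energy[cbind(seq_len(core_width), cons_base)] <- consensus_energy
    structure(list(energy = energy,
                   consensus = paste(BASES[cons_base], collapse = ""),
                   width = core_width,
                   consensus_score = sum(apply(energy, 1L, max))),
              class = "binding_energy_model")
  })
}

# score of string s (as base indices) when its window starts at core offset o
# (0-based relative to core start); flank positions contribute 0
placement_score <- function(base_idx, o, energy) {
  w <- nrow(energy)
  k <- length(base_idx)
  core_pos <- (o + seq_len(k)) - 1L            # 0-based core coordinates covered
  in_core <- core_pos >= 0L & core_pos < w
  if (!any(in_core)) return(0)
  sum(energy[cbind(core_pos[in_core] + 1L, base_idx[in_core])])
}

#' Simulate a SELEX-like k-mer enrichment table with known offsets
#'
#' Emulates the k-mer level summary of a SELEX-seq experiment. A binding site
#' (the model's consensus core flanked by `k-1` random background bases on
#' each side) is windowed at every placement overlapping the core; the window
#' k-mers and all their single-base variants at core-covered positions form
#' the signal set. Each distinct k-mer's log enrichment is its best additive
#' placement score plus Gaussian noise; `n_background` random k-mers score 0
#' plus noise. The generator records a true offset (the best-scoring
#' placement's start relative to core start, ties to the smaller `|offset|`)
#' for every k-mer generated from a window overlapping the core by at least
#' `min(core_width, k) - 2` bp — the register the crawl's +/-2 bp overlap
#' rule can be expected to recover; k-mers from far-flank windows carry no
#' defined register and are left out of the truth map.
#'
#' @param model a [binding_energy_model].
#' @param k k-mer length (>= 5).
#' @param noise Gaussian noise standard deviation as a fraction of the
#'   consensus score (default 0.05).
#' @param n_background number of unenriched background k-mers (default 2000).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return An object of class `selex_simulation`: list with `table` (a
#'   [kmer_table] of log enrichments), `true_offset` (named integer vector),
#'   `model`, `k`, `noise` and `seed`.
#' @export
simulate_kmer_table <- function(model, k = 10L, noise = 0.05,
                                n_background = 2000L, seed = 1L) {
  stopifnot(inherits(model, "binding_energy_model"))
  k <- as.integer(k)
  if (k < 5L) stop_tdc("k must be >= 5")
  if (noise < 0) stop_tdc("noise must be >= 0")
  w <- model$width
  with_seed(seed, {
    flank_l <- paste(sample(BASES, k - 1L, replace = TRUE), collapse = "")
    flank_r <- paste(sample(BASES, k - 1L, replace = TRUE), collapse = "")
    site <- paste0(flank_l, model$consensus, flank_r)
    offsets <- (-(k - 1L)):(w - 1L)            # every window overlapping the core

    # signal k-mers: each placement's window plus single-base variants at
    # core-covered positions; track the best core overlap of the placements
    # that generated each k-mer
    signal <- character(0)
    gen_overlap <- integer(0)
    overlap_at <- function(o) min(o + k, w) - max(o, 0L)
    for (o in offsets) {
      start <- o + k                            # 1-based start within site
      win <- substr(site, start, start + k - 1L)
      core_cols <- which((o + seq_len(k) - 1L) >= 0L & (o + seq_len(k) - 1L) < w)
      chars <- strsplit(win, "", fixed = TRUE)[[1L]]
      muts <- win
      for (j in core_cols) {
        for (b in BASES[BASES != chars[j]]) {
          mut <- chars
          mut[j] <- b
          muts <- c(muts, paste(mut, collapse = ""))
        }
      }
      signal <- c(signal, muts)
      gen_overlap <- c(gen_overlap, rep(overlap_at(o), length(muts)))
    }
    gen_overlap <- vapply(split(gen_overlap, signal), max, integer(1))
    signal <- names(gen_overlap)

    # per k-mer: best placement score and argmax offset (ties to smaller |o|)
    o_pref <- offsets[order(abs(offsets), offsets)]
    best_score <- numeric(length(signal))
    best_offset <- integer(length(signal))
    for (i in seq_along(signal)) {
      base_idx <- match(strsplit(signal[i], "", fixed = TRUE)[[1L]], BASES)
      sc <- vapply(o_pref, function(o) placement_score(base_idx, o, model$energy),
                   numeric(1))
      best <- which.max(sc)                     # first max in preference order
      best_score[i] <- sc[best]
      best_offset[i] <- o_pref[best]
    }
    reach <- gen_overlap >= min(w, k) - 2L
    true_offset <- stats::setNames(best_offset[reach], signal[reach])

    bg <- setdiff(unique(random_kmers(n_background, k)), signal)
    seqs <- c(signal, bg)
    scores <- c(best_score, rep(0, length(bg)))
    metrics <- scores + stats::rnorm(length(scores), sd = noise * model$consensus_score)
    structure(list(table = kmer_table(seqs, metrics),
                   true_offset = true_offset,
                   model = model, k = k, noise = noise, seed = seed),
              class = "selex_simulation")
  })
}

#' @export
print.selex_simulation <- function(x, ...) {
  cat(sprintf("synthetic SELEX k-mer table: %d k-mers (k = %d), core width %d, noise %.3g\n",
              length(x$table$sequences), x$k, x$model$width, x$noise))
  cat(sprintf("  %d k-mers carry a ground-truth offset\n", length(x$true_offset)))
  invisible(x)
}

#' Fraction of ground-truth offsets recovered by an alignment
#'
#' Compares crawl (or other) shifts with a simulation's true offsets after
#' origin reconciliation (the two coordinate systems differ by a constant),
#' over the k-mers present in both.
#'
#' @param alignment a [tdc_alignment].
#' @param sim a `selex_simulation`.
#' @return Fraction in `[0, 1]`.
#' @export
offset_recovery <- function(alignment, sim) {
  stopifnot(inherits(alignment, "tdc_alignment"), inherits(sim, "selex_simulation"))
  shifts <- stats::setNames(alignment$shifts, alignment$sequences)
  eligible <- intersect(names(sim$true_offset), names(shifts))
  if (length(eligible) == 0L) return(0)
  # unaligned truth k-mers count as failures
  shift_agreement(shifts, sim$true_offset, eligible) *
    length(eligible) / length(sim$true_offset)
}
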