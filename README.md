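# tdcrawl

Rank-dependent, motif-free alignment of k-mer level protein–DNA binding
data.

High-throughput binding assays (SELEX-seq, protein binding microarrays,
SMiLE-seq) measure binding affinity most reproducibly at the level of the
k-mer, but a k-mer's enrichment says nothing about *where* along the binding
site it sits. `tdcrawl` implements the Top-Down Crawl (TDC) algorithm, which
assigns every k-mer an integer shift using only the rank order of its
binding metric — no PWM fitting, no experiment-specific parameters:

1. the k-mer with the largest metric seeds the alignment at shift 0 and
   becomes the first reference;
2. unaligned k-mers one substitution away from the reference inherit its
   shift; unaligned k-mers overlapping the reference by k−1 or k−2 bp get
   the reference's shift ±1 or ±2 bp according to the overlapping end;
3. the reference is marked complete, the highest-metric aligned-but-not-
   complete k-mer becomes the next reference, and the crawl stops when all
   aligned k-mers are complete.

Around the core aligner the package provides:

* gap-padded (`_`) tab-delimited alignment I/O and minimal MEME-format PWM
  I/O (`read_kmer_table`, `write_alignment`, `read_pwm`, `write_pwm`);
* enrichment-weighted PWM construction from an alignment
  (`pwm_from_alignment`) and a PWM-based comparison aligner that slides
  k-mers along a neutrally padded matrix (`pwm_align_kmers`), plus an
  origin-reconciled shift-agreement statistic (`shift_agreement`);
* pentamer DNA-shape features — minor groove width and electrostatic
  potential (`load_shape_table`, `shape_profile`, `synthetic_shape_table`);
* an alignment-quality harness: Z-score filtering, one-hot + shape feature
  encoding, and elastic-net regression of log enrichment with 5-fold
  cross-validation reporting the median held-out R²
  (`zscore_filter`, `encode_features`, `fit_mlr_cv`, `evaluate_alignment`);
* a synthetic SELEX-like generator with known ground-truth registers for
  end-to-end validation (`binding_energy_model`, `simulate_kmer_table`,
  `offset_recovery`).

## Worked example

```r
library(tdcrawl)

tab <- kmer_table(c("GTAAACA", "AGTAAAC", "GTAAACT", "TAAACAG"),
                  c(9, 5, 7, 4))
top_down_crawl(tab)
#> Top-Down Crawl result: 4 aligned, 0 unaligned, 4 rounds
#> alignment: 4 k-mers (k = 7), shifts -1..1
#>   _GTAAACA_  +0  9
#>   _GTAAACT_  +0  7
#>   AGTAAAC__  -1  5
#>   __TAAACAG  +1  4
```

`GTAAACA` has the largest metric, so it anchors shift 0. `GTAAACT` is one
substitution away and inherits shift 0. `AGTAAAC` shares its last six bases
with the reference's first six — it extends the 5' end and is placed at
−1 bp — while `TAAACAG` is the 3' mirror at +1 bp. The padded output shows
the same geometry with `_` as the gap character.

The same pipeline on simulated SELEX-like data with known truth:

```r
m   <- binding_energy_model(core_width = 7, seed = 1)
sim <- simulate_kmer_table(m, k = 10, noise = 0.05, n_background = 2000, seed = 1)
res <- top_down_crawl(sim$table)
offset_recovery(res$alignment, sim)
#> [1] 0.9430380
```

94% of the k-mers carrying a ground-truth register are aligned to that
register (after reconciling the constant origin offset between the crawl's
and the generator's coordinates). Alignment quality can also be scored
without truth, as the median cross-validated R² of an elastic-net model
predicting log enrichment from one-hot sequence and DNA-shape features over
the aligned window:

```r
keep <- abs(res$alignment$shifts) <= 5
al <- tdc_alignment(res$alignment$sequences[keep],
                    res$alignment$shifts[keep],
                    res$alignment$metrics[keep])
evaluate_alignment(al, seed = 1)
#> elastic-net CV (5 folds, n = 198): median R2 = 0.4428
#>   per-fold R2: 0.5616 0.4428 0.3062 0.4691 0.2566
```

The same k-mers encoded without alignment (all shifts forced to 0) score a
median R² roughly 0.2 lower — aligning first is what lets position-specific
base changes predict affinity.

A command-line front end wrapping these functions (subcommands `align`,
`logo`, `pwm-align`, `compare`, `evaluate`, `simulate`) is installed at
`inst/scripts/tdcrawl`; see the vignette in `vignettes/top-down-crawl.Rmd`
for the model, conventions and limitations.

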