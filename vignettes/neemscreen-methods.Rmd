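---
title: "Methods: two-arm drug-mechanism analysis with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-arm drug-mechanism analysis with planted-truth validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neemscreen)
```

# The analysis this package implements

`neemscreen` implements a two-arm strategy for characterizing how a drug (or
crude extract) acts on a cancer cell line:

1. **Functional arm — pooled shRNA screen.** Cells carrying a genome-wide
   pooled shRNA library are grown with and without treatment. The relative
   abundance ("clone size") of each hairpin is read out by sequencing its DNA
   barcode. Hairpins whose clone size more than doubles under treatment
   (ratio > 2) mark knockdowns that favor growth under drug; hairpins
   depleted below half (ratio < 0.5) mark synthetic-lethal knockdowns.
   A gene becomes a hit only when at least two of its hairpins agree,
   guarding against off-target single-hairpin artifacts.
2. **Expression arm — treatment/rescue time course.** Transcript levels are
   measured over nine time points (5, 10, 15, 30 min, 1, 3, 6, 10, 24 h)
   under treatment, and again after drug withdrawal ("rescue"), each against
   time-matched vehicle controls. Genes are short-listed when their
   expression ratio stays above 1.2 or below 0.8 for at least four
   consecutive treatment time points ("serial regulation"). Additional
   filters flag genes whose post-treatment trajectory freezes (standard
   deviation of the last treatment point plus all rescue points at most
   0.01 on the log2 fold-change scale — "non-rescued"), and classify
   temporal trends by Pearson correlation of log2 fold change against the
   time-point index (|R| >= 0.6).

Hits from both arms are consolidated into one non-redundant gene list,
tested for pathway over-representation with an exact hypergeometric tail and
Benjamini–Hochberg FDR control, and assembled into a gene–drug interaction
network annotated with FDA-approval status and clinical-trial counts.

# Normalization chain for the expression arm

Raw intensities pass through three steps before fold changes:

* **Started-log VST.** `vst_transform()` applies `log2(x + c)` with `c = 1`
  per array. A full bead-level variance-stabilizing transform needs
  within-probe variance estimates that a plain expression matrix does not
  carry; the started log preserves the two properties the downstream filters
  rely on — monotonicity and damping of low-intensity variance — and behaves
  as plain `log2` for bright probes. The offset is a parameter for users who
  want a different low-end behavior.
* **LOESS against the mean pseudo-array.** For each array, the difference to
  the gene-wise mean pseudo-array (an MA-style residual) is regressed on the
  pseudo-array with `stats::loess` (span 0.4, degree 1) and the fitted trend
  subtracted. This removes array-specific intensity-dependent bias; two
  identical arrays are left untouched, and a constant offset between arrays
  is absorbed into the common mean.
* **Batch correction.** `batch_correct()` standardizes each gene within each
  batch toward its pooled mean and, in the default `"scale"` mode, its
  pooled standard deviation. `"mean"` mode shifts batch means only, and
  `"eb"` delegates to empirical-Bayes ComBat (sva). The pooled per-gene mean
  is preserved exactly in the built-in modes.

**A practical note on batch mode and the flatness filter.** When treated and
control columns of the same time point share a batch — the usual chip
layout — additive batch offsets cancel exactly in the fold change, so
mean-only correction leaves fold changes invariant. The scale mode instead
multiplies each gene's within-batch deviations by a pooled-to-batch SD
ratio estimated from few samples; for genes that are genuinely frozen after
treatment this noisy per-batch rescaling can inflate the trajectory SD far
beyond the 0.01 flatness bound and mask true non-rescued genes. The
end-to-end demo therefore runs `method = "mean"`; use `"scale"` (or `"eb"`)
when batches are suspected to differ in dynamic range, and prefer the
non-rescue filter only under location-type correction.

# Thresholds and defaults

| parameter | default | meaning |
|---|---|---|
| clone-size enrichment / depletion | > 2 / < 0.5 | hairpin-level hit bounds; values exactly on a bound are neutral |
| `min_support` | 2 | concordant hairpins required per gene hit |
| `pseudocount` | 0.5 | added to both normalized counts; makes a treated/control swap map every ratio to its exact reciprocal |
| fold bounds | 1.2 / 0.8 | serial-regulation ratio bounds, taken as stated (note 1/1.2 ≈ 0.833 ≠ 0.8, so the pair is deliberately asymmetric; a symmetric mode using 1/1.2 is available for the anti-symmetry property) |
| `min_run` | 4 | consecutive time points required |
| `sd_threshold` | 0.01 | non-rescue flatness bound, applied to log2 fold changes (a 0.01 SD is only plausible on a ratio/log scale, not on raw intensities; a configuration switch exists) |
| `r_up` / `r_down` | 0.6 / −0.6 | temporal correlation classes, computed against the time-point index 0..8 (indices, not raw minutes, because the grid is close to geometric; minutes or log-minutes are available) |
| `max_mismatches` | 0 | exact barcode membership, matching a QC rule that discards "non-existing" sequences; 1-mismatch mode is available and is unambiguous by construction (see below) |
| `fdr_alpha` | 0.05 | pathway FDR cut |

Run detection reports the longest qualifying window, breaking ties by the
earliest start; when up- and down-runs tie in length the earlier run wins,
then "up". A gene can qualify in both directions only through disjoint
windows; the longer run defines the primary direction.

# What the synthetic generator emulates

The generator is first-class, tested code: every downstream stage is
validated against planted ground truth without any external download.

**Screen.** `generate_shrna_library()` builds a 27,500-hairpin library
(5,500 genes × 5) by default. Barcodes are codewords of a shortened Hamming
code over GF(4): `r` parity symbols are chosen so the parity-check columns
are pairwise linearly independent, guaranteeing pairwise Hamming distance
>= 3 in O(n) construction time. Single-mismatch demultiplexing therefore can
never be ambiguous, and the property is exact, not probabilistic.
`simulate_screen_counts()` draws negative-binomial counts around a common
per-hairpin mean (`depth / library_size`), multiplying planted ratios (4 for
enriched, 0.25 for depleted by default) into the treated means. Planted hit
genes carry the effect on 3 of their 5 hairpins, emulating heterogeneous
knockdown efficacy while satisfying the two-hairpin support rule.
`simulate_screen_reads()` serializes the same counts as 4-line FASTQ and
corrupts a configured read fraction (half truncated, half random no-match
sequence) to exercise QC.

The default dispersion is 0.002. This is the technical/counting-noise regime
of a single infected pool split into control and treated arms, and it is
pinned down by a Monte-Carlo calibration of the count model: a hairpin
planted at ratio 4 must land in empirical ratio [3, 5] with probability at
least 0.99 at typical per-hairpin coverage, which bounds the dispersion at
roughly 0.003. Screens with independently infected biological replicates
show substantially higher dispersion; raise the parameter accordingly, and
expect the plain ratio-threshold caller to lose specificity there — it has
no variance moderation by design (rank/statistical callers are out of scope).

**Time course.** `simulate_timecourse_matrix()` emits one column per
condition (treated, rescue, vehicle control) and time point over the
nine-point grid. Planted log2 amplitudes default to 0.585 (ratio 1.5,
mid-range of the pathway-level maxima the method is meant to detect);
Gaussian noise SD is 0.05 on the log2 scale; two processing batches split
the time grid across all conditions with N(0, 0.3) scalar offsets.
Serial genes exceed the bounds over a random window of >= 4 points and
return to baseline during rescue. Non-rescued genes ramp monotonically
during treatment (giving |Pearson R| near 1, so they double as the
temporally correlated classes) and then freeze: on the coordinates the
flatness rule inspects, their noise is shrunk to SD 0.002, below the 0.01
bound — otherwise a 0.05-noise simulation could never contain detectable
flat genes. Values are exported as raw intensities `2^x` so the started-log
transform reconstructs the log2 grid up to its `+1` offset.

**What the generator does not model.** Probe chemistry and detection
p-values; read errors beyond uniform substitution; PCR amplification bias;
guide-efficacy correlation structure beyond the 3-of-5 rule; intensity-
dependent noise (the log-scale noise is homoscedastic, which flatters the
VST); dropout of low-abundance hairpins under bottlenecks. Passing the
planted-truth tests therefore demonstrates the correctness of the selection
logic and the calibration of the pipeline under idealized noise — not
performance on real microarray or Ion Torrent data.

# Integration details

The consolidated list is the case-folded union of both arms' hits with
per-gene provenance flags. The over-representation universe is a mandatory,
logged parameter; the demo uses all profiled genes plus all library genes.
The hypergeometric p is an exact tail sum, cross-checked in the tests
against one-sided Fisher tests on the equivalent 2×2 tables; BH adjustment
delegates to `stats::p.adjust`. Two service-style options are emulated
locally: `unique_assignment()` keeps each query gene only in its smallest
containing pathway, and `include_interactors()` widens gene sets with
first-degree neighbors from a user-supplied interaction table. The bundled
pathway, interaction and drug tables under `inst/extdata` are synthetic
fixtures built around TGF-β- and HSF-1-related gene lists so that the
end-to-end demo exercises a realistic enrichment outcome; they are not
claims about any curated database.

# Numerical and degenerate-input choices

* Boundary ratios exactly 2.0/0.5 and fold changes exactly 1.2/0.8 never
  qualify (strict inequalities).
* The hypergeometric tail is capped at 1 (floating summation can exceed 1 by
  ~1e-16 on a full-support tail).
* Zero-variance profiles have no defined temporal correlation; they are
  classified "none" with a warning rather than an error.
* Samples with zero QC-pass reads, singleton batches (unless explicitly
  allowed), missing controls, and sub-4-point time grids are hard errors
  with classed conditions (`ns_config_error`, `ns_design_error`, ...).
* Ambiguous barcode matches (two library barcodes at equal best distance)
  are discarded and tallied separately — impossible at `max_mismatches <= 1`
  with generated libraries, but reachable with user-supplied ones.

# Problem sizes used by the test-suite and acceptance script

Recovery properties are asserted over 20 seeds at the study scale the
generator defaults encode: 27,500 hairpins at 1e6 reads per sample for the
screen (run at the count level; the FASTQ path is exercised end-to-end at
1e5–3e5 reads where string handling stays cheap), and 98 planted serial
genes over 5,000 background genes at noise 0.05 for the time course. The
demo (`run_demo()`) uses a 200-gene screen at 2e5 reads and 2,000 background
genes so a full end-to-end run completes in seconds.

# Known limitations

* The ratio-threshold screen caller has no variance model; its error rates
  are honest only in the low-dispersion regime described above.
* The serial filter treats replicate columns by log-scale averaging; it does
  not weight by replicate variance.
* The flatness rule is scale-sensitive (see the batch-mode note): under
  scale-type batch correction its miss rate on genuinely frozen genes rises
  sharply.
* Symbol harmonization is a pass-through (case-fold and trim only); probe
  annotation versions are the user's responsibility.
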