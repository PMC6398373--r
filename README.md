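# neemscreen

Two-arm drug-mechanism analysis for cancer cell lines, built as a tested,
reusable R pipeline:

* a **pooled shRNA screen arm** — barcode-region FASTQ reads are QC-filtered
  and deconvolved against the library, per-hairpin clone sizes are compared
  between treated and control samples, and genes are called as hits when at
  least two hairpins agree;
* a **treatment/rescue expression time-course arm** — an intensity matrix
  over nine treatment time points, nine rescue time points and matched
  vehicle controls is normalized (started-log VST, LOESS against a mean
  pseudo-array, per-batch correction), converted to fold changes, and
  filtered by temporal rules: serial regulation, rescue reversal,
  non-rescue flatness and temporal correlation;
* an **integration arm** — hits from both arms are consolidated, tested for
  pathway over-representation, and assembled into a gene–drug interaction
  network.

A synthetic-data generator with planted ground truth (shRNA libraries with
guaranteed barcode separation, negative-binomial screen counts, time-course
matrices with planted serial/non-rescued genes) makes every stage testable
offline.

## The rules at the core

For hairpin *i* with reads-per-million counts `t_i` (treated) and `c_i`
(control) and pseudocount `p = 0.5`:

```
ratio_i = (t_i + p) / (c_i + p)
enriched:  ratio_i > 2      depleted:  ratio_i < 0.5      (boundaries neutral)
gene hit:  >= 2 hairpins of the gene share a class
```

For gene *g* with log2 fold change `f_g(t)` versus the time-matched control
at treatment time points `t = 1..9`:

```
serial:        some window of >= 4 consecutive points with 2^f > 1.2 (up)
               or 2^f < 0.8 (down), strict inequalities
rescue-reversed: no such same-direction window during rescue
non-rescued:   SD( f at last treatment point, all rescue points ) <= 0.01
temporal class: Pearson R of f against index 0..8; up if R >= 0.6, down if R <= -0.6
```

Pathway over-representation uses the exact hypergeometric upper tail
`P(X >= k)`, `X ~ Hypergeom(N, K, n)`, with Benjamini–Hochberg control
across gene sets.

## Worked example

The one-command demo generates both synthetic arms, runs the full pipeline
and compares recovered hits to the planted truth:

```r
library(neemscreen)
res <- run_demo(seed = 42, out_dir = "demo_out")
cat(readLines(res$report), sep = "\n")
```

```
# Synthetic end-to-end demo report

- seed: 42; package version 0.1.0

## Screen arm
- QC-pass fraction: control 0.8998, treated 0.8993
- planted hit genes: 20 up, 20 down; recovered hit genes: 40
- gene-level sensitivity 1.0000, FDR 0.0000

## Time-course arm
- planted serial genes: 98; selected genes: 123
- serial sensitivity 1.0000, background FPR 0.0000
- non-rescued flagged: 28 (planted 28)

## Integration
- consolidated gene list: 166 genes
- top pathway: TGFB_SIGNALING (FDR 4e-34)
- network: 166 gene nodes, 48 edges, drug-target edge fraction 0.667

## Status: PASS
- all recovery floors met
```

Reading the report: 10% of simulated reads were deliberately corrupted, so a
~0.90 QC-pass fraction means the read filter is removing exactly the planted
junk. All 40 planted screen hit genes and all 98 planted serial genes are
recovered with no false gene calls; the 123 selected genes additionally
include the planted non-rescued genes, whose monotone ramps also satisfy the
serial rule. The TGF-β gene set tops the enrichment because the demo plants
its members as serially up-regulated. Stage outputs (counts, clone sizes,
serial calls, trajectories, enrichment table, GraphML network, QC JSON,
resolved config) are written to `demo_out/`.

Individual stages are plain functions, e.g.:

```r
lib    <- generate_shrna_library(n_genes = 5500, shrnas_per_gene = 5, seed = 1)
truth  <- plant_screen_truth(lib, n_up = 100, n_down = 100, depth = 1e6)
counts <- simulate_screen_counts(lib, truth, depth = 1e6, seed = 2)
hits   <- aggregate_genes(compute_clone_size_ratio(counts))
screen_recovery(hits, truth)
```

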