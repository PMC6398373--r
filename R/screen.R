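# Screen arm: read QC and barcode deconvolution, per-sample count
# normalization, clone-size ratios, and gene-level hit aggregation.

#' QC-filter reads and assign them to library barcodes
#'
#' A read is kept iff its length is at least `min_length` and its barcode
#' region (the read prefix of barcode length) matches exactly one library
#' barcode within `max_mismatches`. Reads matching nothing are discarded as
#' carrying non-existing shRNA sequences; reads tied between two or more
#' barcodes at the best distance are discarded as ambiguous and tallied
#' separately.
#'
#' @param reads Data.frame from [read_fastq()].
#' @param library An `shrna_library`.
#' @param min_length Minimum read length; defaults to the barcode length.
#'   Must be at least the barcode length when `max_mismatches = 0`.
#' @param max_mismatches Maximum Hamming distance for a barcode match
#'   (default 0: exact membership).
#' @param sample_id Label attached to the returned assignments.
#' @return A list with `assignments` (data.frame `read_id`, `shrna_id`,
#'   `sample_id`) and `report` (a `screen_qc_report`: total reads, category
#'   tallies, QC-pass fraction, unique shRNAs detected and detection
#'   fraction).
#' @export
qc_filter_reads <- function(reads, library, min_length = NULL,
                            max_mismatches = 0L, sample_id = "sample") {
  validate_shrna_library(library)
  max_mismatches <- assert_scalar_count(max_mismatches, "max_mismatches", min = 0L)
  bl <- nchar(library$barcode[1L])
  min_length <- if (is.null(min_length)) bl else
    assert_scalar_count(min_length, "min_length")
  if (max_mismatches == 0L && min_length < bl) {
    ns_stop("ns_config_error",
            "min_length (%d) must be >= barcode length (%d) for exact matching",
            min_length, bl)
  }

  total <- nrow(reads)
  lens <- nchar(reads$sequence)
  long_enough <- lens >= min_length
  too_short <- sum(!long_enough)

  region <- substr(reads$sequence[long_enough], 1L, bl)
  idx <- match(region, library$barcode)
  ambiguous <- 0L
  if (max_mismatches > 0L && anyNA(idx)) {
    unmatched <- which(is.na(idx))
    libmat <- do.call(cbind, strsplit(library$barcode, "", fixed = TRUE))
    for (u in unmatched) {
      rchars <- strsplit(region[u], "", fixed = TRUE)[[1L]]
      if (length(rchars) != bl) next
      d <- colSums(libmat != rchars)
      best <- min(d)
      if (best <= max_mismatches) {
        hits <- which(d == best)
        if (length(hits) == 1L) idx[u] <- hits else ambiguous <- ambiguous + 1L
      }
    }
  }
  matched <- !is.na(idx)
  no_match <- sum(!matched) - ambiguous
  assignments <- data.frame(
    read_id = reads$read_id[long_enough][matched],
    shrna_id = library$shrna_id[idx[matched]],
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  qc_pass <- nrow(assignments)
  detected <- length(unique(assignments$shrna_id))
  report <- structure(list(
    sample_id = sample_id,
    total_reads = total,
    too_short = too_short,
    no_match = no_match,
    ambiguous = ambiguous,
    qc_pass_reads = qc_pass,
    qc_pass_fraction = if (total > 0L) qc_pass / total else NA_real_,
    unique_shrnas_detected = detected,
    library_size = nrow(library),
    detection_fraction = detected / nrow(library)
  ), class = "screen_qc_report")
  list(assignments = assignments, report = report)
}

#' Count assigned reads per shRNA and normalize to reads per million
#'
#' Raw counts are tallied per shRNA per sample (zero-count shRNAs retained);
#' normalized counts are `raw * 1e6 / sample total`, making samples of
#' unequal depth comparable.
#'
#' @param assignments Data.frame with `shrna_id` and `sample_id` (rbind
#'   several samples' assignments to count them together).
#' @param library An `shrna_library`.
#' @return A `barcode_counts` data.frame: `shrna_id`, `gene`, `sample_id`,
#'   `raw_count`, `norm_count`.
#' @export
count_and_normalize <- function(assignments, library) {
  validate_shrna_library(library)
  if (nrow(assignments) == 0L) {
    ns_stop("ns_config_error", "no assignments to count")
  }
  unknown <- setdiff(unique(assignments$shrna_id), library$shrna_id)
  if (length(unknown)) {
    ns_stop("ns_data_error", "assignment(s) to shRNA(s) absent from library: %s",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  samples <- unique(assignments$sample_id)
  tab <- table(factor(assignments$shrna_id, levels = library$shrna_id),
               factor(assignments$sample_id, levels = samples))
  counts <- data.frame(
    shrna_id = rep(library$shrna_id, times = length(samples)),
    gene = rep(library$gene, times = length(samples)),
    sample_id = rep(samples, each = nrow(library)),
    raw_count = as.integer(as.vector(tab)),
    stringsAsFactors = FALSE
  )
  normalize_counts(counts)
}

#' Normalize raw barcode counts to reads per million
#' @param counts Data.frame with `shrna_id`, `sample_id`, `raw_count`.
#' @return The same table with a `norm_count` column; per-sample norm_count
#'   sums are 1e6 whenever the sample has any read.
#' @export
normalize_counts <- function(counts) {
  totals <- tapply(counts$raw_count, counts$sample_id, sum)
  zero <- names(totals)[totals == 0L]
  if (length(zero)) {
    ns_stop("ns_data_error", "sample(s) with zero QC-pass reads: %s",
            paste(zero, collapse = ", "))
  }
  counts$norm_count <- counts$raw_count * 1e6 / as.numeric(totals[counts$sample_id])
  class(counts) <- c("barcode_counts", "data.frame")
  counts
}

#' Clone-size ratios per shRNA
#'
#' Ratio of pseudocounted normalized counts, treated over control:
#' `(norm_treated + pseudocount) / (norm_control + pseudocount)`. Hairpins
#' with ratio strictly above `enrich_threshold` are classed `enriched`,
#' strictly below `deplete_threshold` `depleted`, otherwise `neutral` —
#' boundary values are neutral. The symmetric pseudocount makes swapping the
#' two samples map every ratio to its reciprocal exactly.
#'
#' @param counts A `barcode_counts` table containing both samples.
#' @param treated_sample,control_sample Sample identifiers.
#' @param pseudocount Positive stabilizer added to both normalized counts
#'   (default 0.5).
#' @param enrich_threshold,deplete_threshold Classification bounds
#'   (defaults 2 and 0.5).
#' @return A `clone_size_table` data.frame: `shrna_id`, `gene`,
#'   `norm_control`, `norm_treated`, `ratio`, `klass`.
#' @export
compute_clone_size_ratio <- function(counts, treated_sample = "treated",
                                     control_sample = "control",
                                     pseudocount = 0.5,
                                     enrich_threshold = 2,
                                     deplete_threshold = 0.5) {
  if (pseudocount <= 0) ns_stop("ns_config_error", "pseudocount must be > 0")
  for (s in c(treated_sample, control_sample)) {
    if (!s %in% counts$sample_id) {
      ns_stop("ns_config_error", "sample '%s' not present in counts", s)
    }
  }
  trt <- counts[counts$sample_id == treated_sample, ]
  ctl <- counts[counts$sample_id == control_sample, ]
  ctl <- ctl[match(trt$shrna_id, ctl$shrna_id), ]
  ratio <- (trt$norm_count + pseudocount) / (ctl$norm_count + pseudocount)
  klass <- ifelse(ratio > enrich_threshold, "enriched",
                  ifelse(ratio < deplete_threshold, "depleted", "neutral"))
  out <- data.frame(
    shrna_id = trt$shrna_id, gene = trt$gene,
    norm_control = ctl$norm_count, norm_treated = trt$norm_count,
    ratio = ratio, klass = klass, stringsAsFactors = FALSE
  )
  class(out) <- c("clone_size_table", "data.frame")
  out
}

#' Aggregate shRNA clone-size calls into gene-level hits
#'
#' A gene is a hit in a direction iff at least `min_support` of its hairpins
#' share that class (enriched hairpins support an `up` hit: knockdown favors
#' growth under treatment; depleted hairpins support a `down` hit: synthetic
#' lethality). Neutral hairpins are ignored. A gene can appear in both
#' directions when both criteria are met independently.
#'
#' @param records A `clone_size_table`.
#' @param min_support Minimum concordant hairpins per hit (default 2).
#' @return A `gene_hits` data.frame: `gene`, `direction`, `n_support`,
#'   `supporting_shrnas` (list column).
#' @export
aggregate_genes <- function(records, min_support = 2L) {
  min_support <- assert_scalar_count(min_support, "min_support")
  hits <- list()
  for (dir in c("up", "down")) {
    kl <- if (dir == "up") "enriched" else "depleted"
    sub <- records[records$klass == kl, , drop = FALSE]
    if (!nrow(sub)) next
    by_gene <- split(sub$shrna_id, sub$gene)
    keep <- by_gene[lengths(by_gene) >= min_support]
    if (!length(keep)) next
    hits[[dir]] <- data.frame(
      gene = names(keep), direction = dir,
      n_support = lengths(keep), stringsAsFactors = FALSE, row.names = NULL
    )
    hits[[dir]]$supporting_shrnas <- unname(keep)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(), direction = character(),
               n_support = integer(),
               supporting_shrnas = I(list()), stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_hits", "data.frame")
  out
}

#' Intersect gene hits across independently analyzed doses
#'
#' Consensus mode for screens run at several drug doses against a shared
#' control: keeps (gene, direction) pairs present in every dose's hit table.
#'
#' @param hit_tables A list of `gene_hits` tables.
#' @return A data.frame with `gene` and `direction`.
#' @export
consensus_hits <- function(hit_tables) {
  if (!length(hit_tables)) {
    ns_stop("ns_config_error", "no hit tables supplied")
  }
  keys <- lapply(hit_tables, function(h) paste(h$gene, h$direction, sep = "|"))
  common <- Reduce(intersect, keys)
  if (!length(common)) {
    return(data.frame(gene = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(sort(common), "|", fixed = TRUE)
  data.frame(gene = vapply(parts, `[`, "", 1L),
             direction = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Log-log clone-size scatter (screen overview plot)
#'
#' Normalized treated versus control counts on log10 axes, colored by class,
#' with the enrichment/depletion threshold lines.
#'
#' @param clone_table A `clone_size_table`.
#' @param pseudocount Pseudocount used for plotting on log axes.
#' @param enrich_threshold,deplete_threshold Threshold lines to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_clone_sizes <- function(clone_table, pseudocount = 0.5,
                             enrich_threshold = 2, deplete_threshold = 0.5, ...) {
  x <- clone_table$norm_control + pseudocount
  y <- clone_table$norm_treated + pseudocount
  cols <- c(enriched = "#D55E00", depleted = "#0072B2", neutral = "grey60")
  graphics::plot(x, y, log = "xy", pch = 16, cex = 0.4,
                 col = cols[clone_table$klass],
                 xlab = "control (reads per million + pseudocount)",
                 ylab = "treated (reads per million + pseudocount)", ...)
  graphics::abline(a = log10(enrich_threshold), b = 1, untf = FALSE, col = cols[["enriched"]], lty = 2)
  graphics::abline(a = log10(deplete_threshold), b = 1, untf = FALSE, col = cols[["depleted"]], lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16, bty = "n")
  invisible(NULL)
}
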