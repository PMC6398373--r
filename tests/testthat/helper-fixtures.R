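# Shared fixture builders; everything is generated in code at test time.

# Tiny deterministic library without the code-based generator, for tests that
# need hand-controlled barcodes.
toy_library <- function() {
  structure(
    data.frame(
      shrna_id = c("G1_sh1", "G1_sh2", "G2_sh1", "G2_sh2"),
      barcode = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG", "TTTTTTTTTT"),
      gene = c("G1", "G1", "G2", "G2"),
      stringsAsFactors = FALSE
    ),
    class = c("shrna_library", "data.frame")
  )
}

toy_reads <- function(sequences, ids = sprintf("r%d", seq_along(sequences))) {
  data.frame(read_id = ids, sequence = sequences,
             quality = strrep("I", nchar(sequences)), stringsAsFactors = FALSE)
}

# Counts table built directly from raw counts given as a named-by-sample list
# of vectors aligned to `library`.
toy_counts <- function(library, raw_by_sample) {
  counts <- do.call(rbind, lapply(names(raw_by_sample), function(s) {
    data.frame(shrna_id = library$shrna_id, gene = library$gene,
               sample_id = s, raw_count = raw_by_sample[[s]],
               stringsAsFactors = FALSE)
  }))
  normalize_counts(counts)
}

# clone_size_table with prescribed classes, for gene aggregation tests.
toy_clone_records <- function(genes, klasses) {
  structure(
    data.frame(
      shrna_id = sprintf("%s_sh%d", genes, stats::ave(seq_along(genes), genes, FUN = seq_along)),
      gene = genes,
      norm_control = 100, norm_treated = 100,
      ratio = ifelse(klasses == "enriched", 3, ifelse(klasses == "depleted", 0.3, 1)),
      klass = klasses, stringsAsFactors = FALSE
    ),
    class = c("clone_size_table", "data.frame")
  )
}

# Hand-built timecourse_profiles object.
make_profiles <- function(log2fc_treat, log2fc_rescue = NULL) {
  stopifnot(is.matrix(log2fc_treat))
  structure(list(
    genes = rownames(log2fc_treat),
    time_min = seq_len(ncol(log2fc_treat)),
    rescue_time_min = if (is.null(log2fc_rescue)) numeric() else seq_len(ncol(log2fc_rescue)),
    log2fc_treatment = log2fc_treat,
    log2fc_rescue = log2fc_rescue,
    fc_treatment = 2^log2fc_treat,
    fc_rescue = if (is.null(log2fc_rescue)) NULL else 2^log2fc_rescue
  ), class = "timecourse_profiles")
}

# Small expression matrix: baseline 8 plus prescribed per-condition log2
# offsets; 4 time points, treated/rescue/control.
toy_expression <- function(n_genes = 20, times = c(5, 10, 15, 30)) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- data.frame(
    sample_id = c(paste0("trt", seq_along(times)), paste0("rsc", seq_along(times)),
                  paste0("ctl", seq_along(times))),
    condition = rep(c("treated", "rescue", "control"), each = length(times)),
    time_min = rep(times, 3), batch = "B1", stringsAsFactors = FALSE
  )
  v <- matrix(8, nrow = n_genes, ncol = nrow(samples),
              dimnames = list(genes, samples$sample_id))
  expression_matrix(v, samples, scale = "log2")
}

# Independent brute-force oracle for serial-run detection: enumerate every
# window of length >= min_run, in each direction; longest qualifying window,
# earliest start on ties; direction by longer run, earlier start, then up.
oracle_serial <- function(ratios, up_bound = 1.2, down_bound = 0.8, min_run = 4) {
  n <- length(ratios)
  best <- function(pred) {
    hit <- c(start = NA_integer_, length = 0L)
    for (len in n:min_run) {
      for (start in 1:(n - len + 1)) {
        if (all(pred(ratios[start:(start + len - 1)]))) {
          if (len > hit["length"]) hit <- c(start = start, length = len)
        }
      }
    }
    hit
  }
  up <- best(function(x) x > up_bound)
  down <- best(function(x) x < down_bound)
  # earliest start for the winning length
  refine <- function(pred, hit) {
    if (hit["length"] == 0L) return(hit)
    len <- unname(hit["length"])
    for (start in 1:(n - len + 1)) {
      if (all(pred(ratios[start:(start + len - 1)]))) {
        return(c(start = start, length = len))
      }
    }
  }
  up <- refine(function(x) x > up_bound, up)
  down <- refine(function(x) x < down_bound, down)
  up_ok <- up["length"] >= min_run
  down_ok <- down["length"] >= min_run
  if (!up_ok && !down_ok) {
    list(selected = FALSE, direction = "none",
         run_start_index = NA_integer_, run_length = 0L)
  } else if (up_ok && (!down_ok || up["length"] > down["length"] ||
                       (up["length"] == down["length"] && up["start"] <= down["start"]))) {
    list(selected = TRUE, direction = "up",
         run_start_index = unname(up["start"]), run_length = unname(up["length"]))
  } else {
    list(selected = TRUE, direction = "down",
         run_start_index = unname(down["start"]), run_length = unname(down["length"]))
  }
}
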