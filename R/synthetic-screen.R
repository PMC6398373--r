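# Synthetic pooled-screen data: shRNA libraries with guaranteed barcode
# separation, planted enrichment/depletion truth, and negative-binomial
# barcode counts serialized as FASTQ.

## ---- GF(4) arithmetic -------------------------------------------------------
# Barcodes are codewords of a shortened Hamming code over GF(4) = {0,1,2,3}
# (A,C,G,T). Columns of the parity-check matrix are pairwise linearly
# independent, so the minimum Hamming distance is 3 by construction; this makes
# mismatch-tolerant (1-error) demultiplexing unambiguous without an O(n^2)
# rejection loop.

.gf4_mul_table <- matrix(
  c(0L, 0L, 0L, 0L,
    0L, 1L, 2L, 3L,
    0L, 2L, 3L, 1L,
    0L, 3L, 1L, 2L),
  nrow = 4, byrow = TRUE
)

.gf4_mul <- function(a, b) .gf4_mul_table[cbind(a + 1L, b + 1L)]

# All 1-dimensional subspaces of GF(4)^r, one representative each (first
# non-zero coordinate normalized to 1), unit vectors moved last so the code is
# systematic: H = [A | I_r].
.gf4_parity_points <- function(r) {
  vecs <- as.matrix(expand.grid(rep(list(0:3), r)))[-1L, , drop = FALSE]
  first_nz <- apply(vecs, 1L, function(v) v[which(v != 0L)[1L]])
  pts <- vecs[first_nz == 1L, , drop = FALSE]
  unit <- rowSums(pts != 0L) == 1L
  units <- pts[unit, , drop = FALSE]
  units <- units[order(apply(units, 1L, function(v) which(v != 0L))), , drop = FALSE]
  rbind(pts[!unit, , drop = FALSE], units)
}

# Encode integer message indices (0-based) into barcode strings of length
# `len` with minimum pairwise Hamming distance 3.
.encode_barcodes <- function(message_idx, len, r) {
  k <- len - r
  pts <- .gf4_parity_points(r)
  A <- t(pts[seq_len(k), , drop = FALSE])          # r x k message columns
  msg <- matrix(0L, nrow = length(message_idx), ncol = k)
  rem <- message_idx
  for (j in seq_len(k)) {
    msg[, j] <- as.integer(rem %% 4)
    rem <- rem %/% 4
  }
  par <- matrix(0L, nrow = length(message_idx), ncol = r)
  for (i in seq_len(r)) {
    acc <- integer(length(message_idx))
    for (j in seq_len(k)) {
      acc <- bitwXor(acc, .gf4_mul(msg[, j], rep(A[i, j], nrow(msg))))
    }
    par[, i] <- acc
  }
  sym <- cbind(msg, par)
  letters4 <- c("A", "C", "G", "T")
  chars <- matrix(letters4[sym + 1L], nrow = nrow(sym))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

## ---- library generation -----------------------------------------------------

#' Generate a synthetic shRNA library
#'
#' Builds an shRNA-to-gene lookup table with unique DNA barcodes. Barcodes are
#' codewords of a shortened Hamming code over GF(4), so any two barcodes differ
#' at three or more positions; single-mismatch demultiplexing can therefore
#' never be ambiguous.
#'
#' @param n_genes Number of target genes.
#' @param shrnas_per_gene Hairpins per gene (the classic genome-wide signaling
#'   module is ~27,500 shRNAs over ~5,500 genes, i.e. 5 per gene).
#' @param barcode_length Barcode length in nucleotides (default 18).
#' @param seed Integer seed; the result is bit-identical for a fixed seed.
#'
#' @return A `data.frame` of class `shrna_library` with columns `shrna_id`,
#'   `barcode` and `gene`.
#' @examples
#' lib <- generate_shrna_library(n_genes = 2, shrnas_per_gene = 3, seed = 7)
#' nrow(lib)  # 6
#' @export
generate_shrna_library <- function(n_genes, shrnas_per_gene = 5L,
                                   barcode_length = 18L, seed = 1L) {
  n_genes <- assert_scalar_count(n_genes, "n_genes")
  shrnas_per_gene <- assert_scalar_count(shrnas_per_gene, "shrnas_per_gene")
  n <- n_genes * shrnas_per_gene

  if (barcode_length < 8L) {
    ns_stop("ns_sizing_error",
            paste0("barcode_length %d cannot hold %d barcodes at pairwise ",
                   "Hamming distance >= 3; use barcode_length >= %d"),
            barcode_length, n, max(8L, .required_barcode_length(n)))
  }
  # r parity symbols; (4^r - 1)/3 pairwise-independent parity columns exist.
  r <- 3L
  while ((4^r - 1) / 3 < barcode_length) r <- r + 1L
  k <- barcode_length - r
  capacity <- 4^k
  if (capacity < n) {
    ns_stop("ns_sizing_error",
            paste0("barcode space too small: %d barcodes requested but length ",
                   "%d encodes at most %s at distance >= 3; use barcode_length >= %d"),
            n, barcode_length, format(capacity, big.mark = ","),
            .required_barcode_length(n))
  }

  set.seed(seed)
  if (capacity <= .Machine$integer.max) {
    idx <- sample.int(capacity, n) - 1
  } else {
    idx <- unique(floor(stats::runif(2L * n) * capacity))
    while (length(idx) < n) {
      idx <- unique(c(idx, floor(stats::runif(n) * capacity)))
    }
    idx <- idx[seq_len(n)]
  }

  genes <- sprintf("GENE%05d", seq_len(n_genes))
  gene_col <- rep(genes, each = shrnas_per_gene)
  shrna_id <- paste0(gene_col, "_sh", rep(seq_len(shrnas_per_gene), times = n_genes))
  lib <- data.frame(
    shrna_id = shrna_id,
    barcode = .encode_barcodes(idx, barcode_length, r),
    gene = gene_col,
    stringsAsFactors = FALSE
  )
  class(lib) <- c("shrna_library", "data.frame")
  lib
}

.required_barcode_length <- function(n) {
  k <- ceiling(log(max(n, 2), base = 4))
  r <- 3L
  while ((4^r - 1) / 3 < k + r) r <- r + 1L
  as.integer(k + r)
}

validate_shrna_library <- function(library) {
  if (!is.data.frame(library) || nrow(library) == 0L) {
    ns_stop("ns_config_error", "shRNA library is empty or not a data.frame")
  }
  need <- c("shrna_id", "barcode", "gene")
  miss <- setdiff(need, names(library))
  if (length(miss)) {
    ns_stop("ns_config_error", "shRNA library lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  if (anyDuplicated(library$shrna_id)) {
    ns_stop("ns_data_error", "duplicated shrna_id in library")
  }
  if (any(!grepl("^[ACGT]+$", library$barcode))) {
    ns_stop("ns_data_error", "library barcodes must be non-empty uppercase ACGT strings")
  }
  if (length(unique(nchar(library$barcode))) != 1L) {
    ns_stop("ns_data_error", "library barcodes must share one length")
  }
  invisible(library)
}

## ---- planted truth ----------------------------------------------------------

#' Plant ground-truth clone-size effects into a library
#'
#' Selects disjoint sets of hit genes whose hairpins are planted as enriched
#' (treated/control abundance ratio > 2) or depleted (ratio < 0.5). For each
#' hit gene, `shrnas_per_hit` of its hairpins carry the effect; the remainder
#' behave neutrally, emulating heterogeneous knockdown efficacy.
#'
#' @param library An `shrna_library`.
#' @param n_up,n_down Number of planted enriched / depleted hit genes.
#' @param shrnas_per_hit Concordant hairpins per hit gene (>= 2).
#' @param ratio_up,ratio_down Planted abundance ratios (must satisfy
#'   `ratio_up > 2`, `ratio_down < 0.5`).
#' @param depth Target sequencing depth per sample (reads).
#' @param seed Integer seed.
#' @return A list of class `planted_screen_truth`.
#' @export
plant_screen_truth <- function(library, n_up = 100L, n_down = 100L,
                               shrnas_per_hit = 3L, ratio_up = 4,
                               ratio_down = 0.25, depth = 7e6, seed = 1L) {
  validate_shrna_library(library)
  n_up <- assert_scalar_count(n_up, "n_up", min = 0L)
  n_down <- assert_scalar_count(n_down, "n_down", min = 0L)
  shrnas_per_hit <- assert_scalar_count(shrnas_per_hit, "shrnas_per_hit", min = 2L)
  if (ratio_up <= 2) ns_stop("ns_config_error", "ratio_up must exceed 2")
  if (ratio_down >= 0.5 || ratio_down <= 0) {
    ns_stop("ns_config_error", "ratio_down must lie in (0, 0.5)")
  }

  per_gene <- table(library$gene)
  eligible <- names(per_gene)[per_gene >= shrnas_per_hit]
  if (length(eligible) < n_up + n_down) {
    ns_stop("ns_config_error",
            "library has %d genes with >= %d shRNAs but %d hit genes requested",
            length(eligible), shrnas_per_hit, n_up + n_down)
  }

  set.seed(seed)
  picked <- sample(eligible, n_up + n_down)
  genes_up <- sort(picked[seq_len(n_up)])
  genes_down <- sort(picked[n_up + seq_len(n_down)])

  pick_shrnas <- function(genes) {
    if (!length(genes)) return(character())
    unlist(lapply(genes, function(g) {
      ids <- library$shrna_id[library$gene == g]
      sample(ids, shrnas_per_hit)
    }), use.names = FALSE)
  }
  truth <- list(
    enriched_shrna_ids = pick_shrnas(genes_up),
    depleted_shrna_ids = pick_shrnas(genes_down),
    hit_genes_up = genes_up,
    hit_genes_down = genes_down,
    ratio_up = ratio_up,
    ratio_down = ratio_down,
    library_size = nrow(library),
    reads_per_sample = depth
  )
  class(truth) <- "planted_screen_truth"
  truth
}

.validate_screen_truth <- function(library, truth) {
  if (!inherits(truth, "planted_screen_truth")) {
    ns_stop("ns_config_error", "`truth` must come from plant_screen_truth()")
  }
  planted <- c(truth$enriched_shrna_ids, truth$depleted_shrna_ids)
  if (length(intersect(truth$enriched_shrna_ids, truth$depleted_shrna_ids))) {
    ns_stop("ns_data_error", "enriched and depleted shRNA sets overlap")
  }
  absent <- setdiff(planted, library$shrna_id)
  if (length(absent)) {
    ns_stop("ns_data_error", "planted shRNA(s) absent from library: %s",
            paste(utils::head(absent, 5L), collapse = ", "))
  }
  invisible(truth)
}

## ---- count simulation -------------------------------------------------------

#' Simulate barcode read counts for a control/treated screen pair
#'
#' Control abundances are negative-binomial around a common per-hairpin mean
#' `depth / library_size`; treated means are multiplied by the planted ratios
#' before resampling. `dispersion = 0` reduces to Poisson counts.
#'
#' @param library An `shrna_library`.
#' @param truth A `planted_screen_truth`.
#' @param depth Expected total reads per sample.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param seed Integer seed.
#' @return A `barcode_counts` data.frame (`shrna_id`, `gene`, `sample_id`,
#'   `raw_count`, `norm_count` in reads per million).
#' @export
simulate_screen_counts <- function(library, truth, depth = truth$reads_per_sample,
                                   dispersion = 0.002, seed = 1L) {
  validate_shrna_library(library)
  .validate_screen_truth(library, truth)
  depth <- assert_scalar_count(depth, "depth")
  if (dispersion < 0) ns_stop("ns_config_error", "dispersion must be >= 0")

  set.seed(seed)
  n <- nrow(library)
  mu0 <- depth / n
  ratio <- rep(1, n)
  ratio[match(truth$enriched_shrna_ids, library$shrna_id)] <- truth$ratio_up
  ratio[match(truth$depleted_shrna_ids, library$shrna_id)] <- truth$ratio_down

  draw <- function(mu) {
    if (dispersion == 0) stats::rpois(n, mu) else
      stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  control <- draw(rep(mu0, n))
  treated <- draw(mu0 * ratio)

  counts <- data.frame(
    shrna_id = rep(library$shrna_id, 2L),
    gene = rep(library$gene, 2L),
    sample_id = rep(c("control", "treated"), each = n),
    raw_count = c(control, treated),
    stringsAsFactors = FALSE
  )
  normalize_counts(counts)
}

## ---- FASTQ simulation -------------------------------------------------------

.random_dna <- function(n, len) {
  if (n == 0L) return(character())
  chars <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' Simulate a screen as a pair of FASTQ files
#'
#' Draws negative-binomial counts (see [simulate_screen_counts()]) and writes
#' one read per counted molecule as 4-line Sanger FASTQ. A configured fraction
#' of reads is corrupted to exercise QC: half are truncated below the barcode
#' length, half are replaced by random sequence absent from the library.
#' Uniform substitution errors can be layered on clean reads via `error_rate`.
#' The planted truth is serialized as JSON next to the outputs.
#'
#' @inheritParams simulate_screen_counts
#' @param error_rate Per-base substitution probability on clean reads (<= 0.05).
#' @param corrupt_fraction Fraction of reads corrupted into no-match or short
#'   reads.
#' @param control_path,treated_path Output FASTQ paths (`.gz` supported).
#' @return Invisibly, a list with `control`, `treated`, `truth_json` paths, the
#'   `counts` table and the `truth` record.
#' @export
simulate_screen_reads <- function(library, truth, depth = 1e5,
                                  error_rate = 0, corrupt_fraction = 0,
                                  dispersion = 0.002, seed = 1L,
                                  control_path = tempfile("control_", fileext = ".fastq"),
                                  treated_path = tempfile("treated_", fileext = ".fastq")) {
  error_rate <- assert_probability(error_rate, "error_rate", max = 0.05)
  corrupt_fraction <- assert_probability(corrupt_fraction, "corrupt_fraction")
  counts <- simulate_screen_counts(library, truth, depth = depth,
                                   dispersion = dispersion, seed = seed)
  bl <- nchar(library$barcode[1L])
  lib_env <- new.env(parent = emptyenv())
  for (b in library$barcode) assign(b, TRUE, envir = lib_env)

  write_sample <- function(sample, path, prefix) {
    sub <- counts[counts$sample_id == sample, ]
    seqs <- rep(library$barcode[match(sub$shrna_id, library$shrna_id)],
                sub$raw_count)
    nr <- length(seqs)
    if (nr == 0L) ns_stop("ns_data_error", "sample %s drew zero reads", sample)
    seqs <- sample(seqs)                    # shuffle pool order
    if (error_rate > 0) {
      n_mut <- stats::rbinom(1L, nr * bl, error_rate)
      if (n_mut > 0L) {
        pos <- sample.int(nr * bl, n_mut)
        ridx <- (pos - 1L) %/% bl + 1L
        cidx <- (pos - 1L) %% bl + 1L
        for (m in seq_len(n_mut)) {
          old <- substr(seqs[ridx[m]], cidx[m], cidx[m])
          substr(seqs[ridx[m]], cidx[m], cidx[m]) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }
    if (corrupt_fraction > 0) {
      bad <- which(stats::runif(nr) < corrupt_fraction)
      if (length(bad)) {
        half <- seq_along(bad) %% 2L == 0L
        # truncated reads: too short to pass the length filter
        seqs[bad[half]] <- substr(seqs[bad[half]], 1L, max(4L, bl %/% 2L))
        # no-match reads: random sequence verified absent from the library
        repl <- .random_dna(sum(!half), bl)
        hit <- vapply(repl, exists, logical(1L), envir = lib_env)
        while (any(hit)) {
          repl[hit] <- .random_dna(sum(hit), bl)
          hit <- vapply(repl, exists, logical(1L), envir = lib_env)
        }
        seqs[bad[!half]] <- repl
      }
    }
    ids <- sprintf("%s:%d", prefix, seq_len(nr))
    write_fastq(data.frame(read_id = ids, sequence = seqs,
                           quality = strrep("I", nchar(seqs)),
                           stringsAsFactors = FALSE), path)
    path
  }

  control_path <- write_sample("control", control_path, "ctrl")
  treated_path <- write_sample("treated", treated_path, "trt")
  truth_json <- file.path(dirname(control_path), "screen_truth.json")
  jsonlite::write_json(unclass(truth), truth_json, auto_unbox = TRUE, digits = NA)

  invisible(list(control = control_path, treated = treated_path,
                 truth_json = truth_json, counts = counts, truth = truth))
}
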