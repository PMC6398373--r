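# Tab-separated readers/writers: shRNA library tables, GMT gene sets, sample
# sheets, expression matrices, interaction and drug-target tables. TSV is used
# throughout (gene symbols never contain tabs).

#' Read an shRNA library table
#'
#' Expects a TSV with header columns `shrna_id`, `barcode`, `gene`.
#' @param path TSV path.
#' @return An `shrna_library` data.frame.
#' @export
read_shrna_library <- function(path) {
  if (!file.exists(path)) ns_stop("ns_config_error", "file not found: %s", path)
  lib <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_shrna_library(lib)
  class(lib) <- c("shrna_library", "data.frame")
  lib
}

#' Write an shRNA library table
#' @param library An `shrna_library`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_shrna_library <- function(library, path) {
  validate_shrna_library(library)
  utils::write.table(library, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a line are removed with a warning.
#'
#' @param path GMT path.
#' @return A list of gene sets, each a list with `name`, `description`,
#'   `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ns_stop("ns_config_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      ns_stop("ns_parse_error", "GMT line %d has %d field(s); at least 3 required",
              i, length(fields))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      ns_warn("ns_dedup_warning", "GMT set '%s' (line %d): %d duplicate gene(s) removed",
              fields[1L], i, sum(duplicated(genes)))
      genes <- unique(genes)
    }
    if (!length(genes)) {
      ns_stop("ns_parse_error", "GMT set '%s' (line %d) has no genes", fields[1L], i)
    }
    out[[i]] <- list(name = fields[1L], description = fields[2L], genes = genes)
  }
  out
}

#' Write pathway gene sets in GMT format
#' @param gene_sets A list as returned by [read_gmt()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$name, gs$description, gs$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `condition` (treated/rescue/control), `time_min`,
#' `batch`, optional `dose`.
#' @param path TSV path.
#' @return A validated data.frame.
#' @export
read_samplesheet <- function(path) {
  if (!file.exists(path)) ns_stop("ns_config_error", "file not found: %s", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_samplesheet(sheet)
}

validate_samplesheet <- function(sheet) {
  need <- c("sample_id", "condition", "time_min", "batch")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    ns_stop("ns_parse_error", "sample sheet lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    ns_stop("ns_data_error", "duplicated sample_id in sample sheet")
  }
  bad <- setdiff(unique(sheet$condition), c("treated", "rescue", "control"))
  if (length(bad)) {
    ns_stop("ns_data_error", "unknown condition(s): %s (expected treated/rescue/control)",
            paste(bad, collapse = ", "))
  }
  if (!is.numeric(sheet$time_min) || any(is.na(sheet$time_min)) || any(sheet$time_min < 0)) {
    ns_stop("ns_data_error", "time_min must be non-negative numbers")
  }
  sheet
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix TSV has probe/gene identifiers in the first column and one
#' column per sample; the header must reconcile exactly with the sample
#' sheet's `sample_id` column.
#'
#' @param matrix_path Expression TSV path.
#' @param samplesheet_path Sample sheet TSV path.
#' @param scale Scale of the stored values, `"raw"` or `"log2"`.
#' @param impute_missing If `TRUE`, missing cells are replaced by the probe
#'   mean with a warning; by default missing values are an error.
#' @return An `ExpressionMatrix`: a [SummarizedExperiment::SummarizedExperiment]
#'   with assay `exprs`, the sample sheet as column data, and the scale flag in
#'   its metadata.
#' @export
read_expression_matrix <- function(matrix_path, samplesheet_path,
                                   scale = c("raw", "log2"),
                                   impute_missing = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(matrix_path)) ns_stop("ns_config_error", "file not found: %s", matrix_path)
  sheet <- read_samplesheet(samplesheet_path)
  raw <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) ns_stop("ns_parse_error", "expression matrix needs >= 2 columns")
  probes <- raw[[1L]]
  if (anyDuplicated(probes)) ns_stop("ns_data_error", "duplicated probe identifiers")
  sample_cols <- names(raw)[-1L]

  only_matrix <- setdiff(sample_cols, sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, sample_cols)
  if (length(only_matrix) || length(only_sheet)) {
    ns_stop("ns_reconcile_error",
            "matrix/sample-sheet mismatch: in matrix only [%s]; in sheet only [%s]",
            paste(only_matrix, collapse = ", "), paste(only_sheet, collapse = ", "))
  }

  values <- matrix(NA_real_, nrow = length(probes), ncol = length(sample_cols),
                   dimnames = list(probes, sample_cols))
  for (j in seq_along(sample_cols)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(col) & col != "NA")
    if (length(bad)) {
      ns_stop("ns_parse_error", "non-numeric cell '%s' at probe '%s', sample '%s'",
              col[bad[1L]], probes[bad[1L]], sample_cols[j])
    }
    values[, j] <- num
  }
  if (anyNA(values)) {
    if (!impute_missing) {
      idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
      ns_stop("ns_data_error", "missing value at probe '%s', sample '%s' (set impute_missing = TRUE to mean-impute)",
              probes[idx[1L]], sample_cols[idx[2L]])
    }
    ns_warn("ns_impute_warning", "%d missing value(s) mean-imputed per probe",
            sum(is.na(values)))
    for (i in which(rowSums(is.na(values)) > 0L)) {
      values[i, is.na(values[i, ])] <- mean(values[i, ], na.rm = TRUE)
    }
  }
  expression_matrix(values, sheet[match(sample_cols, sheet$sample_id), , drop = FALSE],
                    scale = scale)
}

#' Write an expression matrix and its sample sheet as TSV
#' @param em An `ExpressionMatrix` (see [expression_matrix()]).
#' @param matrix_path,samplesheet_path Output TSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_matrix <- function(em, matrix_path, samplesheet_path) {
  v <- em_values(em)
  out <- data.frame(probe_id = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(em_samples(em), samplesheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a gene-gene interaction table
#'
#' TSV with columns `gene_a`, `gene_b`, `type` (header required).
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_interactions <- function(path) {
  .read_strict_tsv(path, c("gene_a", "gene_b", "type"))
}

#' Read a drug-target table
#'
#' TSV with columns `drug`, `target`, `fda_approved` (TRUE/FALSE),
#' `n_trials` (integer).
#' @param path TSV path.
#' @return A data.frame with typed columns.
#' @export
read_drug_targets <- function(path) {
  df <- .read_strict_tsv(path, c("drug", "target", "fda_approved", "n_trials"))
  fda <- toupper(df$fda_approved)
  bad <- which(!fda %in% c("TRUE", "FALSE"))
  if (length(bad)) {
    ns_stop("ns_parse_error", "malformed drug record at line %d: fda_approved '%s' is not TRUE/FALSE",
            bad[1L] + 1L, df$fda_approved[bad[1L]])
  }
  n_trials <- suppressWarnings(as.integer(df$n_trials))
  bad <- which(is.na(n_trials))
  if (length(bad)) {
    ns_stop("ns_parse_error", "malformed drug record at line %d: n_trials '%s' is not an integer",
            bad[1L] + 1L, df$n_trials[bad[1L]])
  }
  data.frame(drug = df$drug, target = df$target, fda_approved = fda == "TRUE",
             n_trials = n_trials, stringsAsFactors = FALSE)
}

# Strict TSV reader: every line must have exactly the header's field count;
# errors carry 1-based file line numbers (header is line 1).
.read_strict_tsv <- function(path, required) {
  if (!file.exists(path)) ns_stop("ns_config_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) ns_stop("ns_parse_error", "empty table: %s", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  miss <- setdiff(required, header)
  if (length(miss)) {
    ns_stop("ns_parse_error", "%s lacks column(s): %s", path, paste(miss, collapse = ", "))
  }
  body <- lapply(seq_along(lines)[-1L], function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(header)) {
      ns_stop("ns_parse_error", "line %d of %s has %d field(s); expected %d",
              i, path, length(fields), length(header))
    }
    fields
  })
  if (!length(body)) {
    df <- as.data.frame(matrix(character(), ncol = length(header)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  }
  names(df) <- header
  df
}
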