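# The expression container is a SummarizedExperiment: assay "exprs" holds the
# probe x sample grid, colData holds the sample sheet, metadata$scale records
# whether values are raw intensities or log2.

#' Construct an expression matrix object
#'
#' @param values Numeric probe/gene-by-sample matrix with row and column names.
#' @param samples Sample sheet data.frame (`sample_id`, `condition`,
#'   `time_min`, `batch`, optional `dose`); one row per matrix column.
#' @param scale `"raw"` (positive intensities) or `"log2"`.
#' @return A [SummarizedExperiment::SummarizedExperiment].
#' @export
expression_matrix <- function(values, samples, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    ns_stop("ns_config_error", "`values` must be a numeric matrix")
  }
  samples <- validate_samplesheet(as.data.frame(samples, stringsAsFactors = FALSE))
  if (ncol(values) != nrow(samples)) {
    ns_stop("ns_reconcile_error", "matrix has %d columns but sample sheet %d rows",
            ncol(values), nrow(samples))
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), samples$sample_id)) {
    if (!setequal(colnames(values), samples$sample_id)) {
      ns_stop("ns_reconcile_error", "matrix columns and sample sheet sample_ids differ")
    }
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  )
  S4Vectors::metadata(se)$scale <- scale
  se
}

#' @rdname expression_matrix
#' @param em An expression matrix object.
#' @export
em_values <- function(em) SummarizedExperiment::assay(em, "exprs")

#' @rdname expression_matrix
#' @export
em_samples <- function(em) {
  as.data.frame(SummarizedExperiment::colData(em), stringsAsFactors = FALSE)
}

#' @rdname expression_matrix
#' @export
em_scale <- function(em) S4Vectors::metadata(em)$scale %||% "raw"

.em_replace <- function(em, values, scale = em_scale(em)) {
  SummarizedExperiment::assay(em, "exprs") <- values
  S4Vectors::metadata(em)$scale <- scale
  em
}
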