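# Validating 4-line FASTQ reader/writer. Barcode demultiplexing is
# alignment-free, so the only requirements are strict record structure,
# matched sequence/quality lengths, and transparent gzip.

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ path; `.gz` files are decompressed transparently.
#' @return A `data.frame` with columns `read_id`, `sequence`, `quality`,
#'   in file order.
#' @details Truncated records and sequence/quality length mismatches raise a
#'   parse error naming the offending line.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) ns_stop("ns_config_error", "file not found: %s", path)
  con <- ns_connection(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    ns_stop("ns_parse_error", "truncated FASTQ record starting at line %d in %s",
            4L * (n %/% 4L) + 1L, path)
  }
  head_idx <- seq(1L, n, by = 4L)
  plus_idx <- seq(3L, n, by = 4L)
  bad_head <- which(!startsWith(lines[head_idx], "@"))
  if (length(bad_head)) {
    ns_stop("ns_parse_error", "FASTQ header at line %d does not start with '@'",
            head_idx[bad_head[1L]])
  }
  bad_plus <- which(!startsWith(lines[plus_idx], "+"))
  if (length(bad_plus)) {
    ns_stop("ns_parse_error", "FASTQ separator at line %d does not start with '+'",
            plus_idx[bad_plus[1L]])
  }
  seqs <- lines[seq(2L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len)) {
    ns_stop("ns_parse_error",
            "sequence/quality length mismatch for record at line %d (quality line %d)",
            head_idx[bad_len[1L]], head_idx[bad_len[1L]] + 3L)
  }
  data.frame(
    read_id = sub("^@", "", lines[head_idx]),
    sequence = seqs,
    quality = quals,
    stringsAsFactors = FALSE
  )
}

#' Write reads as 4-line FASTQ
#'
#' @param reads A data.frame with `read_id`, `sequence`, `quality`.
#' @param path Output path; a `.gz` extension triggers gzip compression.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  need <- c("read_id", "sequence", "quality")
  if (!all(need %in% names(reads))) {
    ns_stop("ns_config_error", "`reads` needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    ns_stop("ns_data_error", "sequence/quality lengths differ")
  }
  n <- nrow(reads)
  out <- character(4L * n)
  out[seq(1L, length.out = n, by = 4L)] <- paste0("@", reads$read_id)
  out[seq(2L, length.out = n, by = 4L)] <- reads$sequence
  out[seq(3L, length.out = n, by = 4L)] <- "+"
  out[seq(4L, length.out = n, by = 4L)] <- reads$quality
  con <- ns_connection(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
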