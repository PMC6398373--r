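# Integration arm: consolidate hits from both experimental arms, test pathway
# over-representation with an exact hypergeometric upper tail and
# Benjamini-Hochberg control.

#' Consolidate hit lists from the expression and screen arms
#'
#' Set union of gene symbols with per-gene provenance flags
#' (`expression_serial`, `expression_non_rescued`, `shrna_up`, `shrna_down`).
#' Symbols are case-folded to upper case and whitespace-stripped before the
#' union; the output is sorted lexicographically for determinism.
#'
#' @param expression_serial Gene symbols selected by the serial-regulation
#'   filter.
#' @param shrna_hits A `gene_hits` table (or a data.frame with `gene` and
#'   `direction`).
#' @param expression_non_rescued Gene symbols failing to rescue.
#' @return A `consolidated_genes` data.frame: `gene` plus four logical
#'   provenance columns; every gene carries at least one flag.
#' @export
consolidate_gene_lists <- function(expression_serial, shrna_hits = NULL,
                                   expression_non_rescued = character()) {
  clean <- function(x) unique(toupper(trimws(as.character(x))))
  expr <- clean(expression_serial)
  nonres <- clean(expression_non_rescued)
  up <- character()
  down <- character()
  if (!is.null(shrna_hits) && nrow(shrna_hits)) {
    up <- clean(shrna_hits$gene[shrna_hits$direction == "up"])
    down <- clean(shrna_hits$gene[shrna_hits$direction == "down"])
  }
  genes <- sort(unique(c(expr, nonres, up, down)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) {
    ns_warn("ns_empty_warning", "consolidation produced an empty gene list")
  }
  out <- data.frame(
    gene = genes,
    expression_serial = genes %in% expr,
    expression_non_rescued = genes %in% nonres,
    shrna_up = genes %in% up,
    shrna_down = genes %in% down,
    stringsAsFactors = FALSE
  )
  class(out) <- c("consolidated_genes", "data.frame")
  out
}

#' Exact hypergeometric upper tail
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (universe of `N` genes, `K`
#' in the pathway, `n` drawn in the query), computed by exact summation of
#' point masses.
#'
#' @param k Observed overlap.
#' @param K Pathway size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(K, n) > N) || any(c(k, K, n, N) < 0)) {
    ns_stop("ns_config_error", "need 0 <= k and K, n <= N")
  }
  if (k <= 0L) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  min(1, sum(stats::dhyper(k:hi, K, N - K, n)))
}
.hyper_upper_tail <- hypergeom_tail

#' Hypergeometric pathway over-representation
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under sampling without replacement from the universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the universe
#' size, `K` the in-universe pathway size, `n` the in-universe query size and
#' `k` the overlap, computed by exact summation. Benjamini-Hochberg adjusted
#' values are attached across all tested sets and records are sorted by
#' p-value.
#'
#' @param query A `consolidated_genes` table or a character vector of gene
#'   symbols. Query genes outside the universe are dropped with a warning.
#' @param gene_sets A list of gene sets as from [read_gmt()]; each set is
#'   intersected with the universe before testing.
#' @param universe Character vector of background gene symbols.
#' @return An `enrichment_table` data.frame: `pathway`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `overlap_genes` (list column).
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  if (is.data.frame(query)) query <- query$gene
  universe <- unique(toupper(trimws(universe)))
  if (!length(universe)) ns_stop("ns_config_error", "empty universe")
  query <- unique(toupper(trimws(query)))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    ns_warn("ns_universe_warning", "%d query gene(s) outside the universe dropped",
            length(outside))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(gene_sets, function(gs) {
    members <- intersect(unique(toupper(gs$genes)), universe)
    overlap <- intersect(members, query)
    k <- length(overlap)
    K <- length(members)
    data.frame(pathway = gs$name, k = k, K = K, n = n, N = N,
               p_value = .hyper_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$overlap_genes <- lapply(gene_sets, function(gs) {
    sort(intersect(intersect(unique(toupper(gs$genes)), universe), query))
  })
  out$fdr <- bh_fdr(out$p_value)
  ord <- order(out$p_value, out$pathway)
  out <- out[ord, c("pathway", "k", "K", "n", "N", "p_value", "fdr", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard step-up adjustment `adj_i = min_{j >= i} (m * p_(j) / j)` capped
#' at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the same order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) {
    ns_stop("ns_config_error", "p-values must be numeric")
  }
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    ns_stop("ns_config_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Restrict each query gene to its smallest containing pathway
#'
#' Unique-assignment mode for over-representation: every query gene is kept
#' only in the smallest gene set containing it (ties broken by set order), so
#' overlapping pathway definitions do not count a gene twice. Returns a
#' modified copy of `gene_sets` for use with [hypergeometric_enrichment()].
#'
#' @param query Character vector of query gene symbols.
#' @param gene_sets A list of gene sets.
#' @return The gene sets with query genes removed from all but their smallest
#'   containing set.
#' @export
unique_assignment <- function(query, gene_sets) {
  query <- unique(toupper(trimws(query)))
  sizes <- vapply(gene_sets, function(gs) length(unique(gs$genes)), integer(1L))
  for (g in query) {
    holders <- which(vapply(gene_sets, function(gs) g %in% toupper(gs$genes), logical(1L)))
    if (length(holders) > 1L) {
      keep <- holders[which.min(sizes[holders])]
      for (h in setdiff(holders, keep)) {
        gene_sets[[h]]$genes <- setdiff(gene_sets[[h]]$genes, g)
      }
    }
  }
  gene_sets
}

#' Expand gene sets with first-degree interactors
#'
#' Interactor-inclusion mode: each gene set is widened with the immediate
#' neighbors of its members in a user-supplied interaction table, increasing
#' the analysis background the way interactor-aware over-representation
#' services do.
#'
#' @param gene_sets A list of gene sets.
#' @param interactions Data.frame with `gene_a`, `gene_b`.
#' @return The expanded gene sets.
#' @export
include_interactors <- function(gene_sets, interactions) {
  a <- toupper(interactions$gene_a)
  b <- toupper(interactions$gene_b)
  lapply(gene_sets, function(gs) {
    members <- toupper(gs$genes)
    nb <- c(b[a %in% members], a[b %in% members])
    gs$genes <- sort(unique(c(members, nb)))
    gs
  })
}
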