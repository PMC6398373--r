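# Gene-drug interaction network assembly on top of igraph.

#' Build the gene-drug interaction network
#'
#' Gene nodes are the consolidated query genes, the overlap genes of the
#' enriched pathways, and any user-supplied extra genes (e.g. most-altered
#' genes from an external cohort). Gene-gene edges are taken from the
#' interaction table restricted to the node-induced subgraph; drug-target
#' edges attach drug nodes to their target genes with FDA-approval and
#' clinical-trial annotations. Table rows naming symbols outside the node set
#' are ignored and counted.
#'
#' @param query A `consolidated_genes` table or character vector.
#' @param enriched Optional `enrichment_table`; overlap genes of sets with
#'   `fdr <= fdr_alpha` join the node set.
#' @param interactions Optional data.frame `gene_a`, `gene_b`, `type`.
#' @param drugs Optional data.frame `drug`, `target`, `fda_approved`,
#'   `n_trials`.
#' @param extra_genes Optional character vector of additional gene nodes.
#' @param fdr_alpha FDR cutoff selecting enriched pathways (default 0.05).
#' @return An `interaction_network`: list with `graph` (igraph object; node
#'   attributes `is_query`, `is_drug`, edge attribute `type`) and `summary`
#'   (node/edge counts, `drug_edge_fraction`, counts of ignored table rows).
#' @export
build_network <- function(query, enriched = NULL, interactions = NULL,
                          drugs = NULL, extra_genes = NULL, fdr_alpha = 0.05) {
  if (is.data.frame(query)) query <- query$gene
  query <- unique(toupper(trimws(query)))
  nodes <- query
  if (!is.null(enriched) && nrow(enriched)) {
    sel <- enriched$fdr <= fdr_alpha
    nodes <- union(nodes, toupper(unlist(enriched$overlap_genes[sel])))
  }
  if (!is.null(extra_genes)) nodes <- union(nodes, unique(toupper(trimws(extra_genes))))
  nodes <- sort(nodes[nzchar(nodes)])

  edges <- data.frame(from = character(), to = character(), type = character(),
                      stringsAsFactors = FALSE)
  ignored_interactions <- 0L
  if (!is.null(interactions) && nrow(interactions)) {
    a <- toupper(trimws(interactions$gene_a))
    b <- toupper(trimws(interactions$gene_b))
    keep <- a %in% nodes & b %in% nodes
    ignored_interactions <- sum(!keep)
    if (any(keep)) {
      edges <- rbind(edges, data.frame(
        from = a[keep], to = b[keep],
        type = as.character(interactions$type[keep]),
        stringsAsFactors = FALSE
      ))
    }
  }

  drug_nodes <- character()
  drug_attr <- NULL
  ignored_drugs <- 0L
  if (!is.null(drugs) && nrow(drugs)) {
    target <- toupper(trimws(drugs$target))
    keep <- target %in% nodes
    ignored_drugs <- sum(!keep)
    if (any(keep)) {
      dsub <- drugs[keep, , drop = FALSE]
      dsub$target <- target[keep]
      drug_nodes <- unique(dsub$drug)
      drug_attr <- dsub
      edges <- rbind(edges, data.frame(
        from = dsub$drug, to = dsub$target, type = "drug-target",
        stringsAsFactors = FALSE
      ))
    }
  }

  all_nodes <- c(nodes, drug_nodes)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(
      name = all_nodes,
      is_query = all_nodes %in% query,
      is_drug = all_nodes %in% drug_nodes,
      stringsAsFactors = FALSE
    )
  )
  if (!is.null(drug_attr)) {
    first <- drug_attr[!duplicated(drug_attr$drug), , drop = FALSE]
    idx <- match(drug_nodes, first$drug)
    g <- igraph::set_vertex_attr(g, "fda_approved",
                                 index = drug_nodes, first$fda_approved[idx])
    g <- igraph::set_vertex_attr(g, "n_trials",
                                 index = drug_nodes, first$n_trials[idx])
  }
  n_edges <- as.integer(igraph::ecount(g))
  n_drug_edges <- if (n_edges) sum(igraph::E(g)$type == "drug-target") else 0L
  net <- list(
    graph = g,
    summary = list(
      n_nodes = as.integer(igraph::vcount(g)),
      n_gene_nodes = length(nodes),
      n_drug_nodes = length(drug_nodes),
      n_edges = n_edges,
      n_drug_edges = n_drug_edges,
      drug_edge_fraction = if (n_edges) n_drug_edges / n_edges else NA_real_,
      ignored_interaction_rows = ignored_interactions,
      ignored_drug_rows = ignored_drugs
    )
  )
  class(net) <- "interaction_network"
  net
}

#' Write a network as GraphML plus node/edge TSVs
#'
#' @param network An `interaction_network` from [build_network()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for `*.graphml`, `*_nodes.tsv`, `*_edges.tsv`.
#' @return The GraphML path, invisibly.
#' @export
write_network <- function(network, dir, basename = "network") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  graphml <- file.path(dir, paste0(basename, ".graphml"))
  igraph::write_graph(network$graph, graphml, format = "graphml")
  parts <- igraph::as_data_frame(network$graph, what = "both")
  utils::write.table(parts$vertices, file.path(dir, paste0(basename, "_nodes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(parts$edges, file.path(dir, paste0(basename, "_edges.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(graphml)
}
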