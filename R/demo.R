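# One-command synthetic end-to-end run: screen arm from FASTQ, time-course
# arm from a simulated matrix, integration against the bundled synthetic
# pathway/interaction/drug fixtures, plus a markdown report comparing planted
# truth with recovered hits.

#' Bundled synthetic fixture path
#' @param file File name under the package's `extdata` (empty to list).
#' @return The file path.
#' @export
ns_fixture <- function(file = "") {
  system.file("extdata", file, package = "neemscreen", mustWork = nzchar(file))
}

#' Run the synthetic end-to-end demo
#'
#' Generates a pooled-screen FASTQ pair and a treatment/rescue expression
#' matrix with planted truth, runs both pipeline arms, consolidates the hits,
#' performs pathway over-representation against the bundled synthetic gene
#' sets and assembles the gene-drug network. Writes the resolved
#' configuration, a markdown report and the stage outputs into `out_dir`.
#'
#' @param seed Integer seed; two runs with the same seed are byte-identical.
#' @param out_dir Output directory.
#' @param floors Named list of recovery floors; the run fails (status 1) when
#'   `screen_sensitivity`, `serial_sensitivity` fall below, or `screen_fdr`,
#'   `serial_fpr` rise above, their floor.
#' @param screen_genes,screen_depth Screen arm size (genes at 5 hairpins each)
#'   and per-sample read depth.
#' @param n_background_genes Background genes in the time-course arm.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 ok / 1 below floors), the
#'   recovery `metrics`, and the `report` path.
#' @export
run_demo <- function(seed = 42L, out_dir = tempfile("neemscreen_demo_"),
                     floors = list(screen_sensitivity = 0.9, screen_fdr = 0.1,
                                   serial_sensitivity = 0.9, serial_fpr = 0.02),
                     screen_genes = 200L, screen_depth = 2e5,
                     n_background_genes = 2000L, quiet = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  config <- list(
    seed = seed, ratio_enrich = 2, ratio_deplete = 0.5, fold_up = 1.2,
    fold_down = 0.8, min_run = 4, sd_threshold = 0.01, r_threshold = 0.6,
    min_support = 2, fdr_alpha = 0.05, pseudocount = 0.5,
    screen_genes = screen_genes, screen_depth = screen_depth,
    corrupt_fraction = 0.1, dispersion = 0.002,
    n_background_genes = n_background_genes, floors = floors,
    package_version = as.character(utils::packageVersion("neemscreen"))
  )
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## --- screen arm -----------------------------------------------------------
  say("screen arm: simulating %d-gene library", screen_genes)
  lib <- generate_shrna_library(screen_genes, 5L, seed = seed)
  truth_s <- plant_screen_truth(lib, n_up = 20L, n_down = 20L, depth = screen_depth,
                                seed = seed)
  sim <- simulate_screen_reads(
    lib, truth_s, depth = screen_depth, corrupt_fraction = 0.1, seed = seed,
    control_path = file.path(out_dir, "control.fastq.gz"),
    treated_path = file.path(out_dir, "treated.fastq.gz")
  )
  qc_c <- qc_filter_reads(read_fastq(sim$control), lib, sample_id = "control")
  qc_t <- qc_filter_reads(read_fastq(sim$treated), lib, sample_id = "treated")
  counts <- count_and_normalize(rbind(qc_c$assignments, qc_t$assignments), lib)
  clones <- compute_clone_size_ratio(counts, "treated", "control",
                                     pseudocount = config$pseudocount)
  hits <- aggregate_genes(clones, min_support = config$min_support)
  utils::write.table(counts, file.path(out_dir, "barcode_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clones, file.path(out_dir, "clone_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(control = unclass(qc_c$report),
                            treated = unclass(qc_t$report)),
                       file.path(out_dir, "screen_qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  screen_metrics <- screen_recovery(hits, truth_s)

  ## --- time-course arm ------------------------------------------------------
  say("time-course arm: %d background genes", n_background_genes)
  gmt <- read_gmt(ns_fixture("pathways_synthetic.gmt"))
  tgfb <- gmt[[which(vapply(gmt, `[[`, "", "name") == "TGFB_SIGNALING")]]$genes
  hsf1 <- gmt[[which(vapply(gmt, `[[`, "", "name") == "HSF1_ACTIVATION")]]$genes
  pathway_up <- unique(c(tgfb, hsf1))
  n_pad <- max(0L, 93L - length(pathway_up))
  truth_t <- plant_timecourse_truth(
    serial_up_genes = c(pathway_up, sprintf("SERUP%04d", seq_len(n_pad))),
    seed = seed
  )
  sim_t <- simulate_timecourse_matrix(truth_t, n_background_genes = n_background_genes,
                                      seed = seed)
  # mean-only batch mode: fold changes are exactly invariant to the additive
  # per-batch offsets this design carries, and the non-rescue flatness rule
  # stays interpretable (see the methods vignette)
  em <- batch_correct(loess_normalize(vst_transform(sim_t$matrix)), method = "mean")
  profiles <- compute_fold_changes(em)
  calls <- call_serial_regulation(profiles,
                                  up_bound = config$fold_up,
                                  down_bound = config$fold_down,
                                  min_run = config$min_run,
                                  sd_threshold = config$sd_threshold,
                                  r_up = config$r_threshold,
                                  r_down = -config$r_threshold)
  utils::write.table(calls, file.path(out_dir, "serial_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # decoy sets with no planted member are expected here; the skip is the point
  traj <- withCallingHandlers(
    pathway_trajectory_summary(profiles, gmt),
    ns_empty_set_warning = function(w) invokeRestart("muffleWarning")
  )
  utils::write.table(traj$trajectories, file.path(out_dir, "pathway_trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tc_metrics <- timecourse_recovery(calls, truth_t)

  ## --- integration ----------------------------------------------------------
  say("integration: consolidation, enrichment, network")
  consolidated <- consolidate_gene_lists(
    expression_serial = calls$gene[calls$selected],
    shrna_hits = hits,
    expression_non_rescued = calls$gene[!is.na(calls$non_rescued) & calls$non_rescued]
  )
  universe <- unique(toupper(c(profiles$genes, lib$gene)))
  enr <- hypergeometric_enrichment(consolidated, gmt, universe)
  utils::write.table(enr[, setdiff(names(enr), "overlap_genes")],
                     file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  net <- build_network(
    consolidated, enriched = enr,
    interactions = read_interactions(ns_fixture("interactions_synthetic.tsv")),
    drugs = read_drug_targets(ns_fixture("drug_targets_synthetic.tsv")),
    fdr_alpha = config$fdr_alpha
  )
  write_network(net, out_dir)

  metrics <- c(screen_metrics, tc_metrics,
               list(n_consolidated_genes = nrow(consolidated),
                    top_pathway = enr$pathway[1L],
                    top_pathway_fdr = enr$fdr[1L],
                    drug_edge_fraction = net$summary$drug_edge_fraction))
  status <- 0L
  fails <- character()
  check <- function(name, value, floor, higher_is_better) {
    bad <- if (higher_is_better) value < floor else value > floor
    if (isTRUE(bad)) fails <<- c(fails, sprintf("%s = %.4f (floor %.4f)", name, value, floor))
  }
  check("screen_sensitivity", metrics$screen_sensitivity, floors$screen_sensitivity, TRUE)
  check("screen_fdr", metrics$screen_fdr, floors$screen_fdr, FALSE)
  check("serial_sensitivity", metrics$serial_sensitivity, floors$serial_sensitivity, TRUE)
  check("serial_fpr", metrics$serial_fpr, floors$serial_fpr, FALSE)
  if (length(fails)) status <- 1L

  report <- file.path(out_dir, "report.md")
  lines <- c(
    "# Synthetic end-to-end demo report",
    "",
    sprintf("- seed: %d; package version %s", seed, config$package_version),
    "",
    "## Screen arm",
    sprintf("- QC-pass fraction: control %.4f, treated %.4f",
            qc_c$report$qc_pass_fraction, qc_t$report$qc_pass_fraction),
    sprintf("- planted hit genes: %d up, %d down; recovered hit genes: %d",
            length(truth_s$hit_genes_up), length(truth_s$hit_genes_down), nrow(hits)),
    sprintf("- gene-level sensitivity %.4f, FDR %.4f",
            metrics$screen_sensitivity, metrics$screen_fdr),
    "",
    "## Time-course arm",
    sprintf("- planted serial genes: %d; selected genes: %d",
            length(truth_t$serial_up_genes) + length(truth_t$serial_down_genes),
            sum(calls$selected)),
    sprintf("- serial sensitivity %.4f, background FPR %.4f",
            metrics$serial_sensitivity, metrics$serial_fpr),
    sprintf("- non-rescued flagged: %d (planted %d)",
            sum(calls$non_rescued, na.rm = TRUE), length(truth_t$non_rescued_genes)),
    "",
    "## Integration",
    sprintf("- consolidated gene list: %d genes", nrow(consolidated)),
    sprintf("- top pathway: %s (FDR %.3g)", metrics$top_pathway, metrics$top_pathway_fdr),
    sprintf("- network: %d gene nodes, %d edges, drug-target edge fraction %.3f",
            net$summary$n_gene_nodes, net$summary$n_edges,
            net$summary$drug_edge_fraction),
    "",
    sprintf("## Status: %s", if (status == 0L) "PASS" else "FAIL"),
    if (length(fails)) paste0("- ", fails) else "- all recovery floors met"
  )
  writeLines(lines, report)
  invisible(list(status = status, metrics = metrics, report = report))
}

#' Gene-level recovery of a planted screen truth
#' @param hits A `gene_hits` table.
#' @param truth A `planted_screen_truth`.
#' @return A list with `screen_sensitivity` (planted hit genes recovered with
#'   the correct direction) and `screen_fdr` (fraction of called hits not
#'   planted).
#' @export
screen_recovery <- function(hits, truth) {
  called_up <- hits$gene[hits$direction == "up"]
  called_down <- hits$gene[hits$direction == "down"]
  tp <- sum(truth$hit_genes_up %in% called_up) +
    sum(truth$hit_genes_down %in% called_down)
  n_planted <- length(truth$hit_genes_up) + length(truth$hit_genes_down)
  n_called <- length(called_up) + length(called_down)
  fp <- sum(!called_up %in% truth$hit_genes_up) +
    sum(!called_down %in% truth$hit_genes_down)
  list(
    screen_sensitivity = if (n_planted) tp / n_planted else NA_real_,
    screen_fdr = if (n_called) fp / n_called else 0
  )
}

#' Recovery of a planted time-course truth
#' @param calls A `serial_regulation_calls` table.
#' @param truth A `planted_timecourse_truth`.
#' @return A list with `serial_sensitivity` (planted serial genes selected
#'   with the correct direction) and `serial_fpr` (fraction of background
#'   genes selected).
#' @export
timecourse_recovery <- function(calls, truth) {
  sel_up <- calls$gene[calls$selected & calls$direction == "up"]
  sel_down <- calls$gene[calls$selected & calls$direction == "down"]
  tp <- sum(truth$serial_up_genes %in% sel_up) +
    sum(truth$serial_down_genes %in% sel_down)
  n_planted <- length(truth$serial_up_genes) + length(truth$serial_down_genes)
  planted_all <- c(truth$serial_up_genes, truth$serial_down_genes,
                   truth$non_rescued_genes)
  background <- setdiff(calls$gene, planted_all)
  fp <- sum(calls$selected[calls$gene %in% background])
  list(
    serial_sensitivity = if (n_planted) tp / n_planted else NA_real_,
    serial_fpr = if (length(background)) fp / length(background) else NA_real_
  )
}
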