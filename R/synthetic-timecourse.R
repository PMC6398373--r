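# Synthetic treatment/rescue expression matrices with planted truth:
# serially regulated genes (>= 4 consecutive points beyond the fold bounds,
# reversed on rescue), non-rescued genes (flat from the last treatment point
# through rescue, with monotone treatment trends driving the temporal
# correlation classes), background genes, batch structure and Gaussian noise.

#' Plant ground truth for a treatment/rescue time course
#'
#' Default planted set sizes mirror a study design with 93 serially
#' up-regulated and 5 serially down-regulated genes plus 28 non-rescued genes
#' (8 with rising, 20 with falling temporal trends). Planted gene sets are
#' pairwise disjoint; the temporally correlated sets coincide with the
#' non-rescued genes by construction (rising trends give Pearson R near +1,
#' falling near -1).
#'
#' @param n_serial_up,n_serial_down Counts of serially up-/down-regulated
#'   genes (ignored when explicit gene names are given).
#' @param n_non_rescued_up,n_non_rescued_down Counts of non-rescued genes with
#'   rising / falling temporal trends.
#' @param serial_up_genes,serial_down_genes,non_rescued_up_genes,non_rescued_down_genes
#'   Optional explicit gene symbols for the planted sets.
#' @param time_grid_minutes Ordered treatment time grid; default is the
#'   nine-point grid 5, 10, 15, 30, 60, 180, 360, 600, 1440 minutes.
#' @param rescue_grid_minutes Ordered rescue time grid (same default).
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param log2fc_amplitude Planted |log2 fold change| (default 0.585, i.e.
#'   ratio 1.5).
#' @param jitter_sd Residual noise on the frozen coordinates of non-rescued
#'   genes; kept well below the 0.01 flatness SD rule.
#' @param batch_sd SD of the per-batch scalar offsets.
#' @param n_batches Number of processing batches (samples split by time-block
#'   across all conditions).
#' @param min_run Minimum planted run length for serial genes.
#' @param seed Integer seed.
#' @return A list of class `planted_timecourse_truth`.
#' @export
plant_timecourse_truth <- function(n_serial_up = 93L, n_serial_down = 5L,
                                   n_non_rescued_up = 8L, n_non_rescued_down = 20L,
                                   serial_up_genes = NULL, serial_down_genes = NULL,
                                   non_rescued_up_genes = NULL,
                                   non_rescued_down_genes = NULL,
                                   time_grid_minutes = c(5, 10, 15, 30, 60, 180, 360, 600, 1440),
                                   rescue_grid_minutes = time_grid_minutes,
                                   noise_sd = 0.05, log2fc_amplitude = 0.585,
                                   jitter_sd = 0.002, batch_sd = 0.3,
                                   n_batches = 2L, min_run = 4L, seed = 1L) {
  if (is.unsorted(time_grid_minutes, strictly = TRUE)) {
    ns_stop("ns_design_error", "time_grid_minutes must be strictly increasing")
  }
  if (is.unsorted(rescue_grid_minutes, strictly = TRUE)) {
    ns_stop("ns_design_error", "rescue_grid_minutes must be strictly increasing")
  }
  min_run <- assert_scalar_count(min_run, "min_run")
  if (length(time_grid_minutes) < min_run) {
    ns_stop("ns_design_error", "need >= %d treatment time points, got %d",
            min_run, length(time_grid_minutes))
  }
  if (noise_sd < 0) ns_stop("ns_config_error", "noise_sd must be >= 0")

  name_or <- function(names, n, prefix) {
    if (!is.null(names)) unique(names) else if (n > 0) sprintf("%s%04d", prefix, seq_len(n))
    else character()
  }
  serial_up <- name_or(serial_up_genes, n_serial_up, "SERUP")
  serial_down <- name_or(serial_down_genes, n_serial_down, "SERDN")
  nonres_up <- name_or(non_rescued_up_genes, n_non_rescued_up, "NRUP")
  nonres_down <- name_or(non_rescued_down_genes, n_non_rescued_down, "NRDN")
  planted <- c(serial_up, serial_down, nonres_up, nonres_down)
  if (anyDuplicated(planted)) {
    ns_stop("ns_config_error", "planted gene sets must be pairwise disjoint")
  }

  set.seed(seed)
  Tn <- length(time_grid_minutes)
  windows <- lapply(seq_len(length(serial_up) + length(serial_down)), function(i) {
    start <- sample.int(Tn - min_run + 1L, 1L)
    lens <- seq.int(min_run, Tn - start + 1L)
    c(start = start, length = lens[sample.int(length(lens), 1L)])
  })
  names(windows) <- c(serial_up, serial_down)

  truth <- list(
    serial_up_genes = serial_up,
    serial_down_genes = serial_down,
    non_rescued_genes = c(nonres_up, nonres_down),
    correlated_up = nonres_up,
    correlated_down = nonres_down,
    run_windows = windows,
    time_grid_minutes = time_grid_minutes,
    rescue_grid_minutes = rescue_grid_minutes,
    noise_sd = noise_sd,
    log2fc_amplitude = log2fc_amplitude,
    jitter_sd = jitter_sd,
    batch_sd = batch_sd,
    n_batches = as.integer(n_batches),
    min_run = min_run
  )
  class(truth) <- "planted_timecourse_truth"
  truth
}

#' Simulate a treatment/rescue expression matrix with planted truth
#'
#' Produces one column per (condition, time point) for treated, rescue and
#' DMSO-control conditions. Background genes fluctuate within the fold bounds;
#' planted serial genes exceed them over their planted window and return
#' within bounds during rescue; non-rescued genes ramp monotonically during
#' treatment and stay frozen from the last treatment point through rescue.
#' Batch offsets are added per the truth's batch structure. Values are emitted
#' as raw intensities `2^x` so the started-log transform recovers the log2
#' grid (up to its +1 offset).
#'
#' @param truth A `planted_timecourse_truth`.
#' @param n_background_genes Number of unplanted background genes.
#' @param seed Integer seed; output is bit-identical per seed.
#' @return A list with `matrix` (raw-scale expression object, see
#'   [expression_matrix()]) and `truth`.
#' @export
simulate_timecourse_matrix <- function(truth, n_background_genes = 5000L, seed = 1L) {
  if (!inherits(truth, "planted_timecourse_truth")) {
    ns_stop("ns_config_error", "`truth` must come from plant_timecourse_truth()")
  }
  n_background_genes <- assert_scalar_count(n_background_genes, "n_background_genes", min = 0L)
  tg <- truth$time_grid_minutes
  rg <- truth$rescue_grid_minutes
  Tn <- length(tg)
  Rn <- length(rg)
  if (Tn < 4L) ns_stop("ns_design_error", "need >= 4 treatment time points, got %d", Tn)

  genes <- c(truth$serial_up_genes, truth$serial_down_genes,
             truth$correlated_up, truth$correlated_down,
             sprintf("BG%05d", seq_len(n_background_genes)))
  ng <- length(genes)
  amp <- truth$log2fc_amplitude

  # planted log2 fold-change programs
  fc_treat <- matrix(0, nrow = ng, ncol = Tn, dimnames = list(genes, NULL))
  fc_rescue <- matrix(0, nrow = ng, ncol = Rn, dimnames = list(genes, NULL))
  for (g in truth$serial_up_genes) {
    w <- truth$run_windows[[g]]
    fc_treat[g, seq.int(w["start"], length.out = w["length"])] <- amp
  }
  for (g in truth$serial_down_genes) {
    w <- truth$run_windows[[g]]
    fc_treat[g, seq.int(w["start"], length.out = w["length"])] <- -amp
  }
  ramp <- seq(0, 1, length.out = Tn)
  for (g in truth$correlated_up) {
    fc_treat[g, ] <- amp * ramp
    fc_rescue[g, ] <- amp
  }
  for (g in truth$correlated_down) {
    fc_treat[g, ] <- -amp * ramp
    fc_rescue[g, ] <- -amp
  }

  set.seed(seed)
  baseline <- stats::rnorm(ng, mean = 8, sd = 1.5)
  sample_id <- c(sprintf("trt_t%02d", seq_len(Tn)),
                 sprintf("rsc_t%02d", seq_len(Rn)),
                 sprintf("ctl_t%02d", seq_len(Tn)))
  condition <- c(rep("treated", Tn), rep("rescue", Rn), rep("control", Tn))
  time_min <- c(tg, rg, tg)
  ns_total <- length(sample_id)

  # batches split the time grid into contiguous blocks across all conditions,
  # emulating chips processed on different days
  n_batches <- max(1L, min(truth$n_batches, Tn))
  block <- cut(match(time_min, sort(unique(time_min))), breaks = n_batches,
               labels = FALSE)
  batch <- paste0("B", block)
  batch_offset <- stats::rnorm(n_batches, mean = 0, sd = truth$batch_sd)

  log2v <- matrix(baseline, nrow = ng, ncol = ns_total,
                  dimnames = list(genes, sample_id))
  log2v[, condition == "treated"] <- log2v[, condition == "treated"] + fc_treat
  log2v[, condition == "rescue"] <- log2v[, condition == "rescue"] + fc_rescue

  noise <- matrix(stats::rnorm(ng * ns_total, sd = truth$noise_sd),
                  nrow = ng, ncol = ns_total)
  # non-rescued genes are frozen (sub-threshold jitter) on the coordinates the
  # flatness rule inspects: last treatment point, all rescue and all control
  # columns
  nr_rows <- match(truth$non_rescued_genes, genes)
  frozen_cols <- which(condition == "control" | condition == "rescue" |
                         (condition == "treated" & time_min == tg[Tn]))
  if (length(nr_rows) && truth$noise_sd > 0) {
    shrink <- min(truth$jitter_sd / truth$noise_sd, 1)
    noise[nr_rows, frozen_cols] <- noise[nr_rows, frozen_cols] * shrink
  }
  log2v <- log2v + noise
  log2v <- sweep(log2v, 2L, batch_offset[block], "+")

  samples <- data.frame(sample_id = sample_id, condition = condition,
                        time_min = time_min, batch = batch,
                        stringsAsFactors = FALSE)
  em <- expression_matrix(2^log2v, samples, scale = "raw")
  list(matrix = em, truth = truth)
}
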