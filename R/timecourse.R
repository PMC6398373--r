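# Time-course arm: normalization (started-log VST, MA-style LOESS, per-batch
# location/scale correction), fold changes versus matched controls, and the
# temporal selection rules: serial-regulation runs, rescue reversal,
# non-rescue flatness, temporal correlation, pathway trajectories.

#' Variance-stabilizing transform (started log)
#'
#' Applies the monotone transform `log2(x + offset)` per array. The default
#' offset of 1 flattens the low-intensity variance inflation while behaving as
#' plain `log2` for bright probes, preserving the ordering the downstream
#' threshold filters depend on.
#'
#' @param em Expression matrix on the raw scale (all values > 0).
#' @param offset Started-log constant `c` in `log2(x + c)`.
#' @return The matrix on the log2 scale.
#' @export
vst_transform <- function(em, offset = 1) {
  if (em_scale(em) != "raw") {
    ns_stop("ns_config_error", "vst_transform expects raw-scale intensities")
  }
  v <- em_values(em)
  if (any(v <= 0)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1L, ]
    ns_stop("ns_data_error", "non-positive intensity %.4g at probe '%s', sample '%s'",
            v[idx[1L], idx[2L]], rownames(v)[idx[1L]], colnames(v)[idx[2L]])
  }
  .em_replace(em, log2(v + offset), scale = "log2")
}

#' LOESS normalization against the mean pseudo-array
#'
#' MA-style intensity-dependent correction: for each array, the difference to
#' the gene-wise mean pseudo-array is regressed on the pseudo-array with
#' [stats::loess()] and the fitted trend is subtracted, removing array-specific
#' intensity-dependent bias.
#'
#' @param em Expression matrix on the log2 scale.
#' @param span LOESS span (fraction of points in each local fit).
#' @return The corrected matrix.
#' @export
loess_normalize <- function(em, span = 0.4) {
  if (em_scale(em) != "log2") {
    ns_stop("ns_config_error", "loess_normalize expects log2-scale values")
  }
  v <- em_values(em)
  if (nrow(v) < 10L) {
    ns_stop("ns_data_error", "loess normalization needs >= 10 genes, got %d", nrow(v))
  }
  pseudo <- rowMeans(v)
  for (j in seq_len(ncol(v))) {
    m <- v[, j] - pseudo
    fit <- stats::loess(m ~ pseudo, span = span, degree = 1L,
                        family = "gaussian")
    v[, j] <- v[, j] - stats::fitted(fit)
  }
  .em_replace(em, v)
}

#' Per-batch location/scale batch correction
#'
#' Standardizes each gene within each batch toward the pooled per-gene mean and
#' standard deviation (`method = "scale"`), or shifts batch means only
#' (`method = "mean"`). The pooled per-gene mean is preserved exactly. With
#' `method = "eb"` the correction is delegated to empirical-Bayes ComBat from
#' the sva package (shrinks batch effect estimates across genes).
#'
#' @param em Expression matrix on the log2 scale with a `batch` column in its
#'   sample sheet.
#' @param method `"scale"` (default), `"mean"`, or `"eb"`.
#' @param allow_singleton If `TRUE`, batches with a single sample are passed
#'   through uncorrected with a warning instead of raising an error.
#' @return The corrected matrix.
#' @export
batch_correct <- function(em, method = c("scale", "mean", "eb"),
                          allow_singleton = FALSE) {
  method <- match.arg(method)
  if (em_scale(em) != "log2") {
    ns_stop("ns_config_error", "batch_correct expects log2-scale values")
  }
  v <- em_values(em)
  batch <- em_samples(em)$batch
  sizes <- table(batch)
  if (length(sizes) < 2L) return(em)

  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons)) {
    if (!allow_singleton) {
      ns_stop("ns_config_error",
              "batch(es) with a single sample: %s (set allow_singleton = TRUE to pass through)",
              paste(singletons, collapse = ", "))
    }
    ns_warn("ns_singleton_warning", "singleton batch(es) left uncorrected: %s",
            paste(singletons, collapse = ", "))
  }
  if (method == "eb") {
    if (!requireNamespace("sva", quietly = TRUE)) {
      ns_stop("ns_config_error", "method = 'eb' requires the sva package")
    }
    corrected <- sva::ComBat(dat = v, batch = batch)
    return(.em_replace(em, corrected))
  }

  m <- rowMeans(v)
  s <- apply(v, 1L, stats::sd)
  out <- v
  for (b in setdiff(names(sizes), singletons)) {
    cols <- which(batch == b)
    mb <- rowMeans(v[, cols, drop = FALSE])
    centered <- v[, cols, drop = FALSE] - mb
    if (method == "scale") {
      sb <- apply(v[, cols, drop = FALSE], 1L, stats::sd)
      scale_fac <- ifelse(sb > 1e-12 & s > 1e-12, s / sb, 1)
      centered <- centered * scale_fac
    }
    out[, cols] <- centered + m
  }
  .em_replace(em, out)
}

#' Fold changes versus matched controls over the time grid
#'
#' For each time point and each of the treated and rescue conditions, the mean
#' log2 value of replicate columns is compared with the control columns at the
#' same time point (or with the pooled control mean when no matched control
#' exists; that fallback is messaged once). Ratios are `2^(log2 difference)`.
#'
#' @param em Expression matrix on the log2 scale whose sample sheet contains
#'   treated (and/or rescue) and control samples.
#' @return A `timecourse_profiles` object: gene-by-time matrices
#'   `log2fc_treatment`, `log2fc_rescue` (and their `fc_*` ratio forms), with
#'   the ordered `time_min` / `rescue_time_min` grids.
#' @export
compute_fold_changes <- function(em) {
  if (em_scale(em) != "log2") {
    ns_stop("ns_config_error", "compute_fold_changes expects log2-scale values")
  }
  v <- em_values(em)
  sheet <- em_samples(em)
  if (!any(sheet$condition == "control")) {
    ns_stop("ns_design_error", "no control samples present")
  }
  ctrl <- sheet$condition == "control"
  pooled_ctrl <- rowMeans(v[, ctrl, drop = FALSE])
  pooled_used <- FALSE

  fc_for <- function(condition) {
    times <- sort(unique(sheet$time_min[sheet$condition == condition]))
    if (!length(times)) return(NULL)
    fc <- matrix(NA_real_, nrow = nrow(v), ncol = length(times),
                 dimnames = list(rownames(v), paste0("t", times)))
    for (i in seq_along(times)) {
      tcols <- which(sheet$condition == condition & sheet$time_min == times[i])
      ccols <- which(ctrl & sheet$time_min == times[i])
      tmean <- rowMeans(v[, tcols, drop = FALSE])
      if (length(ccols)) {
        cmean <- rowMeans(v[, ccols, drop = FALSE])
      } else {
        cmean <- pooled_ctrl
        pooled_used <<- TRUE
      }
      fc[, i] <- tmean - cmean
    }
    list(times = times, log2fc = fc)
  }

  trt <- fc_for("treated")
  if (is.null(trt)) ns_stop("ns_design_error", "no treated samples present")
  rsc <- fc_for("rescue")
  if (pooled_used) {
    message("no time-matched control for some time points; pooled control mean used")
  }

  profiles <- list(
    genes = rownames(v),
    time_min = trt$times,
    rescue_time_min = if (is.null(rsc)) numeric() else rsc$times,
    log2fc_treatment = trt$log2fc,
    log2fc_rescue = if (is.null(rsc)) NULL else rsc$log2fc
  )
  profiles$fc_treatment <- 2^profiles$log2fc_treatment
  profiles$fc_rescue <- if (is.null(rsc)) NULL else 2^profiles$log2fc_rescue
  class(profiles) <- "timecourse_profiles"
  profiles
}

## ---- temporal selection rules ----------------------------------------------

# Longest run of TRUE in a logical vector; earliest start breaks length ties.
.best_run <- function(flag) {
  r <- rle(unname(flag))
  if (!any(r$values)) return(c(start = NA_integer_, length = 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]   # which.max -> earliest of maxima
  c(start = starts[best], length = r$lengths[best])
}

#' Detect serial up-/down-regulation in one fold-change profile
#'
#' A gene is selected when some window of at least `min_run` consecutive
#' treatment time points has every ratio strictly above `up_bound` (direction
#' `"up"`) or strictly below `down_bound` (direction `"down"`). Boundary
#' values equal to a bound never qualify. The longest qualifying run is
#' reported (earliest start on ties; when both directions tie in length, the
#' earlier-starting run wins, then `"up"`). If rescue ratios are supplied,
#' `rescue_reversed` is `TRUE` when no qualifying same-direction run of
#' `min_run` points exists during rescue.
#'
#' @param fc_treatment Ordered vector of treatment fold-change ratios.
#' @param fc_rescue Optional ordered vector of rescue fold-change ratios.
#' @param up_bound,down_bound Ratio bounds (defaults 1.2 / 0.8).
#' @param min_run Minimum run length (default 4).
#' @return A list of class `serial_regulation_call` with fields `selected`,
#'   `direction`, `run_start_index` (1-based), `run_length`,
#'   `rescue_reversed`.
#' @export
detect_serial_regulation <- function(fc_treatment, fc_rescue = NULL,
                                     up_bound = 1.2, down_bound = 0.8,
                                     min_run = 4L) {
  min_run <- assert_scalar_count(min_run, "min_run")
  if (length(fc_treatment) < min_run) {
    ns_stop("ns_design_error", "profile has %d treatment points; min_run is %d",
            length(fc_treatment), min_run)
  }
  up <- .best_run(fc_treatment > up_bound)
  down <- .best_run(fc_treatment < down_bound)
  up_ok <- up["length"] >= min_run
  down_ok <- down["length"] >= min_run

  if (!up_ok && !down_ok) {
    direction <- "none"
    run <- c(start = NA_integer_, length = 0L)
  } else if (up_ok && (!down_ok ||
                       up["length"] > down["length"] ||
                       (up["length"] == down["length"] && up["start"] <= down["start"]))) {
    direction <- "up"
    run <- up
  } else {
    direction <- "down"
    run <- down
  }

  rescue_reversed <- NA
  if (!is.null(fc_rescue) && direction != "none") {
    flag <- if (direction == "up") fc_rescue > up_bound else fc_rescue < down_bound
    rescue_reversed <- .best_run(flag)["length"] < min_run
    names(rescue_reversed) <- NULL
  }

  structure(list(
    selected = direction != "none",
    direction = direction,
    run_start_index = unname(run["start"]),
    run_length = unname(run["length"]),
    rescue_reversed = rescue_reversed
  ), class = "serial_regulation_call")
}

#' Non-rescue flatness test
#'
#' `TRUE` when the sample standard deviation of the supplied values (the log2
#' fold change at the last treatment time point concatenated with all rescue
#' time points) does not exceed `sd_threshold`: expression stays frozen after
#' drug withdrawal.
#'
#' @param values Numeric vector of length >= 2.
#' @param sd_threshold Flatness bound (default 0.01).
#' @return Logical scalar.
#' @export
detect_non_rescued <- function(values, sd_threshold = 0.01) {
  if (length(values) < 2L) {
    ns_stop("ns_config_error", "non-rescue test needs >= 2 values")
  }
  stats::sd(values) <= sd_threshold
}

#' Temporal correlation classification
#'
#' Pearson correlation of the treatment log2 fold changes against the
#' time-point index `0, 1, ..., T-1`. Classified `"up"` when `R >= r_up`,
#' `"down"` when `R <= r_down`, otherwise `"none"`. A zero-variance profile
#' has no defined correlation and is classified `"none"` with a warning.
#'
#' @param log2fc Ordered treatment log2 fold changes (length >= 3).
#' @param r_up,r_down Classification thresholds (defaults 0.6 / -0.6).
#' @return A list with `R` and `class`.
#' @export
temporal_correlation <- function(log2fc, r_up = 0.6, r_down = -0.6) {
  if (length(log2fc) < 3L) {
    ns_stop("ns_config_error", "temporal correlation needs >= 3 time points")
  }
  if (stats::sd(log2fc) == 0) {
    ns_warn("ns_degenerate_warning", "zero-variance profile: correlation undefined, classified 'none'")
    return(list(R = NA_real_, class = "none"))
  }
  r <- stats::cor(log2fc, seq_along(log2fc) - 1)
  cls <- if (r >= r_up) "up" else if (r <= r_down) "down" else "none"
  list(R = r, class = cls)
}

#' Apply all temporal selection rules across genes
#'
#' Runs [detect_serial_regulation()], [detect_non_rescued()] (on the last
#' treatment point plus all rescue points of the log2 fold changes) and
#' [temporal_correlation()] for every gene in a `timecourse_profiles` object.
#'
#' @param profiles A `timecourse_profiles` object from
#'   [compute_fold_changes()].
#' @inheritParams detect_serial_regulation
#' @param sd_threshold Non-rescue flatness bound (default 0.01).
#' @param r_up,r_down Temporal correlation thresholds.
#' @return A data.frame of class `serial_regulation_calls`, one row per gene:
#'   `gene`, `selected`, `direction`, `run_start_index`, `run_length`,
#'   `rescue_reversed`, `non_rescued`, `temporal_R`, `temporal_class`.
#' @export
call_serial_regulation <- function(profiles, up_bound = 1.2, down_bound = 0.8,
                                   min_run = 4L, sd_threshold = 0.01,
                                   r_up = 0.6, r_down = -0.6) {
  if (!inherits(profiles, "timecourse_profiles")) {
    ns_stop("ns_config_error", "`profiles` must come from compute_fold_changes()")
  }
  n <- length(profiles$genes)
  has_rescue <- !is.null(profiles$fc_rescue)
  out <- data.frame(
    gene = profiles$genes,
    selected = logical(n), direction = character(n),
    run_start_index = integer(n), run_length = integer(n),
    rescue_reversed = rep(NA, n), non_rescued = rep(NA, n),
    temporal_R = numeric(n), temporal_class = character(n),
    stringsAsFactors = FALSE
  )
  tlast <- ncol(profiles$log2fc_treatment)
  for (i in seq_len(n)) {
    call <- detect_serial_regulation(
      profiles$fc_treatment[i, ],
      if (has_rescue) profiles$fc_rescue[i, ] else NULL,
      up_bound = up_bound, down_bound = down_bound, min_run = min_run
    )
    out$selected[i] <- call$selected
    out$direction[i] <- call$direction
    out$run_start_index[i] <- call$run_start_index
    out$run_length[i] <- call$run_length
    out$rescue_reversed[i] <- call$rescue_reversed
    if (has_rescue) {
      tail_vals <- c(profiles$log2fc_treatment[i, tlast],
                     profiles$log2fc_rescue[i, ])
      out$non_rescued[i] <- detect_non_rescued(tail_vals, sd_threshold)
    }
    tc <- withCallingHandlers(
      temporal_correlation(profiles$log2fc_treatment[i, ], r_up, r_down),
      ns_degenerate_warning = function(w) invokeRestart("muffleWarning")
    )
    out$temporal_R[i] <- tc$R
    out$temporal_class[i] <- tc$class
  }
  class(out) <- c("serial_regulation_calls", "data.frame")
  out
}

#' Mean pathway trajectories over the time grid
#'
#' For each gene set, the arithmetic mean of member genes' log2 fold-change
#' ratios at each treatment and rescue time point, plus the maximum absolute
#' mean log2 ratio reached during treatment (the pathway's peak expression
#' change). Sets with no member among the profiled genes are skipped with a
#' warning.
#'
#' @param profiles A `timecourse_profiles` object.
#' @param gene_sets A list of gene sets as returned by [read_gmt()].
#' @return A list with `trajectories` (long data.frame: `pathway`, `phase`,
#'   `time_min`, `mean_log2fc`) and `summary` (per pathway: `n_genes`,
#'   `max_abs_log2fc`, `peak_log2fc`, `peak_time_min`).
#' @export
pathway_trajectory_summary <- function(profiles, gene_sets) {
  if (!inherits(profiles, "timecourse_profiles")) {
    ns_stop("ns_config_error", "`profiles` must come from compute_fold_changes()")
  }
  traj <- list()
  summ <- list()
  for (gs in gene_sets) {
    members <- intersect(gs$genes, profiles$genes)
    if (!length(members)) {
      ns_warn("ns_empty_set_warning", "gene set '%s' has no gene in the profiles; skipped",
              gs$name)
      next
    }
    idx <- match(members, profiles$genes)
    mt <- colMeans(profiles$log2fc_treatment[idx, , drop = FALSE])
    traj[[length(traj) + 1L]] <- data.frame(
      pathway = gs$name, phase = "treatment", time_min = profiles$time_min,
      mean_log2fc = unname(mt), stringsAsFactors = FALSE
    )
    if (!is.null(profiles$log2fc_rescue)) {
      mr <- colMeans(profiles$log2fc_rescue[idx, , drop = FALSE])
      traj[[length(traj) + 1L]] <- data.frame(
        pathway = gs$name, phase = "rescue", time_min = profiles$rescue_time_min,
        mean_log2fc = unname(mr), stringsAsFactors = FALSE
      )
    }
    peak <- which.max(abs(mt))
    summ[[length(summ) + 1L]] <- data.frame(
      pathway = gs$name, n_genes = length(members),
      max_abs_log2fc = abs(mt[peak]), peak_log2fc = unname(mt[peak]),
      peak_time_min = profiles$time_min[peak], stringsAsFactors = FALSE
    )
  }
  list(
    trajectories = if (length(traj)) do.call(rbind, traj) else
      data.frame(pathway = character(), phase = character(),
                 time_min = numeric(), mean_log2fc = numeric()),
    summary = if (length(summ)) do.call(rbind, summ) else
      data.frame(pathway = character(), n_genes = integer(),
                 max_abs_log2fc = numeric(), peak_log2fc = numeric(),
                 peak_time_min = numeric())
  )
}
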