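test_that("library generation counts, uniqueness and barcode separation", {
  lib <- generate_shrna_library(n_genes = 2, shrnas_per_gene = 3,
                                barcode_length = 18, seed = 7)
  expect_identical(nrow(lib), 6L)
  expect_identical(length(unique(lib$barcode)), 6L)
  expect_true(all(nchar(lib$barcode) == 18L))

  # exhaustive pairwise Hamming distance >= 3 on a small library
  lib2 <- generate_shrna_library(30, 4, seed = 3)
  chars <- do.call(rbind, strsplit(lib2$barcode, "", fixed = TRUE))
  dmin <- min(vapply(seq_len(nrow(chars) - 1L), function(i) {
    min(colSums(t(chars[-seq_len(i), , drop = FALSE]) != chars[i, ]))
  }, numeric(1L)))
  expect_gte(dmin, 3)
})

test_that("genome-wide library scale: 5,500 genes x 5 hairpins = 27,500 records", {
  lib <- generate_shrna_library(n_genes = 5500, shrnas_per_gene = 5,
                                barcode_length = 18, seed = 1)
  expect_identical(nrow(lib), 27500L)
  expect_false(anyDuplicated(lib$barcode) > 0L)
  # sampled pairs respect the distance-3 code guarantee
  set.seed(99)
  i <- sample.int(27500, 2000, replace = TRUE)
  j <- sample.int(27500, 2000, replace = TRUE)
  keep <- i != j
  a <- do.call(rbind, strsplit(lib$barcode[i[keep]], "", fixed = TRUE))
  b <- do.call(rbind, strsplit(lib$barcode[j[keep]], "", fixed = TRUE))
  expect_gte(min(rowSums(a != b)), 3)
})

test_that("barcode space too small raises a sizing error naming a usable length", {
  err <- tryCatch(generate_shrna_library(1, 1, barcode_length = 2, seed = 0),
                  error = identity)
  expect_s3_class(err, "ns_sizing_error")
  expect_match(conditionMessage(err), "barcode_length >= ")
  expect_error(generate_shrna_library(5000, 5, barcode_length = 8, seed = 0),
               class = "ns_sizing_error")
})

test_that("generators are bit-identical for a fixed seed", {
  expect_identical(generate_shrna_library(50, 3, seed = 5),
                   generate_shrna_library(50, 3, seed = 5))
  lib <- generate_shrna_library(50, 3, seed = 5)
  tr <- plant_screen_truth(lib, n_up = 5, n_down = 5, shrnas_per_hit = 2,
                           depth = 1e5, seed = 2)
  expect_identical(simulate_screen_counts(lib, tr, seed = 9),
                   simulate_screen_counts(lib, tr, seed = 9))
  tt <- plant_timecourse_truth(n_serial_up = 5, n_serial_down = 2, seed = 4)
  expect_identical(simulate_timecourse_matrix(tt, 50, seed = 8)$matrix,
                   simulate_timecourse_matrix(tt, 50, seed = 8)$matrix)
})

test_that("planted screen truth satisfies its invariants", {
  lib <- generate_shrna_library(100, 5, seed = 1)
  tr <- plant_screen_truth(lib, n_up = 10, n_down = 10, shrnas_per_hit = 3, seed = 1)
  expect_length(intersect(tr$enriched_shrna_ids, tr$depleted_shrna_ids), 0L)
  expect_length(intersect(tr$hit_genes_up, tr$hit_genes_down), 0L)
  up_genes <- lib$gene[match(tr$enriched_shrna_ids, lib$shrna_id)]
  expect_true(all(table(up_genes)[tr$hit_genes_up] >= 2L))
  down_genes <- lib$gene[match(tr$depleted_shrna_ids, lib$shrna_id)]
  expect_true(all(table(down_genes)[tr$hit_genes_down] >= 2L))
})

test_that("planted shRNA absent from the library is a consistency error", {
  lib <- generate_shrna_library(10, 2, seed = 1)
  tr <- plant_screen_truth(lib, n_up = 2, n_down = 2, shrnas_per_hit = 2, seed = 1)
  tr$enriched_shrna_ids[1] <- "NOT_A_REAL_ID"
  expect_error(simulate_screen_counts(lib, tr, depth = 1e4, seed = 1),
               "absent", class = "ns_data_error")
})

test_that("null screen simulation gives per-shRNA ratios near 1", {
  lib <- generate_shrna_library(100, 2, seed = 2)
  tr <- plant_screen_truth(lib, n_up = 0, n_down = 0, depth = 1e6, seed = 1)
  counts <- simulate_screen_counts(lib, tr, depth = 1e6, seed = 3)
  cl <- compute_clone_size_ratio(counts)
  expect_equal(mean(cl$ratio), 1, tolerance = 0.02)
  expect_equal(stats::median(cl$ratio), 1, tolerance = 0.05)
})

test_that("a hairpin planted at ratio 4 lands in [3, 5] at deep coverage", {
  lib <- generate_shrna_library(50, 2, seed = 2)
  for (s in 1:5) {
    tr <- plant_screen_truth(lib, n_up = 1, n_down = 0, shrnas_per_hit = 2,
                             ratio_up = 4, depth = 1e6, seed = s)
    counts <- simulate_screen_counts(lib, tr, depth = 1e6, seed = 100 + s)
    cl <- compute_clone_size_ratio(counts)
    planted <- cl$ratio[cl$shrna_id %in% tr$enriched_shrna_ids]
    expect_true(all(planted >= 3 & planted <= 5))
  }
})

test_that("corrupted reads are rejected at the planted rate (binomial oracle)", {
  lib <- generate_shrna_library(200, 5, seed = 4)
  tr <- plant_screen_truth(lib, n_up = 0, n_down = 0, depth = 1e5, seed = 1)
  sim <- simulate_screen_reads(lib, tr, depth = 1e5, corrupt_fraction = 0.1, seed = 6)
  qc <- qc_filter_reads(read_fastq(sim$control), lib)
  # binomial sd at n ~ 1e5 is ~0.001; spec tolerance 0.01
  expect_equal(qc$report$qc_pass_fraction, 0.9, tolerance = 0.0125)
  expect_gt(qc$report$too_short, 0L)
  expect_gt(qc$report$no_match, 0L)
})

test_that("noiseless timecourse recovery is exact for one planted gene", {
  tt <- plant_timecourse_truth(
    serial_up_genes = "PLANTX", n_serial_down = 0,
    n_non_rescued_up = 0, n_non_rescued_down = 0,
    noise_sd = 0, batch_sd = 0, log2fc_amplitude = 0.5, seed = 1
  )
  tt$run_windows[["PLANTX"]] <- c(start = 4L, length = 6L)
  sim <- simulate_timecourse_matrix(tt, n_background_genes = 100, seed = 1)
  em <- batch_correct(loess_normalize(vst_transform(sim$matrix)), method = "mean")
  calls <- call_serial_regulation(compute_fold_changes(em))
  expect_identical(calls$gene[calls$selected], "PLANTX")
  sel <- calls[calls$selected, ]
  expect_identical(sel$direction, "up")
  expect_identical(sel$run_start_index, 4L)
  expect_identical(sel$run_length, 6L)
  expect_true(sel$rescue_reversed)
})

test_that("planted non-rescued genes are flat over last-treatment + rescue points", {
  tt <- plant_timecourse_truth(n_serial_up = 0, n_serial_down = 0,
                               n_non_rescued_up = 2, n_non_rescued_down = 2,
                               noise_sd = 0, batch_sd = 0, seed = 2)
  sim <- simulate_timecourse_matrix(tt, n_background_genes = 20, seed = 2)
  pr <- compute_fold_changes(vst_transform(sim$matrix))
  for (g in tt$non_rescued_genes) {
    i <- match(g, pr$genes)
    tail_vals <- c(pr$log2fc_treatment[i, ncol(pr$log2fc_treatment)],
                   pr$log2fc_rescue[i, ])
    expect_equal(stats::sd(tail_vals), 0, tolerance = 1e-12)
    expect_true(detect_non_rescued(tail_vals))
  }
})

test_that("background false-positive serial calls are rare", {
  fp <- 0L
  n_bg <- 0L
  for (s in 1:5) {
    tt <- plant_timecourse_truth(n_serial_up = 0, n_serial_down = 0,
                                 n_non_rescued_up = 0, n_non_rescued_down = 0,
                                 noise_sd = 0.05, seed = s)
    sim <- simulate_timecourse_matrix(tt, n_background_genes = 100, seed = s)
    em <- batch_correct(loess_normalize(vst_transform(sim$matrix)), method = "mean")
    calls <- call_serial_regulation(compute_fold_changes(em))
    fp <- fp + sum(calls$selected)
    n_bg <- n_bg + nrow(calls)
  }
  expect_lte(fp / n_bg, 0.01)
})

test_that("a time grid shorter than the minimum run is a design error", {
  expect_error(plant_timecourse_truth(time_grid_minutes = c(5, 10, 15)),
               class = "ns_design_error")
  expect_error(plant_timecourse_truth(time_grid_minutes = c(5, 10, 10, 30)),
               "strictly increasing", class = "ns_design_error")
})
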