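test_that("started-log transform: closed form, monotonicity, constants", {
  em <- toy_expression(n_genes = 12)
  v <- em_values(em)
  v[] <- 2^10 - 1
  raw <- expression_matrix(v, em_samples(em), scale = "raw")
  out <- vst_transform(raw, offset = 1)
  expect_equal(unname(em_values(out)[1, 1]), 10)
  expect_identical(em_scale(out), "log2")

  set.seed(1)
  x <- sort(stats::runif(1000, 0.01, 1e5))
  t1 <- log2(x[-1000] + 1)
  t2 <- log2(x[-1] + 1)
  expect_true(all(t2 > t1))

  v[] <- -1
  bad <- expression_matrix(v, em_samples(em), scale = "raw")
  err <- tryCatch(vst_transform(bad), error = identity)
  expect_s3_class(err, "ns_data_error")
  expect_match(conditionMessage(err), "G001")
})

test_that("loess normalization: identity, offset removal, bias flattening", {
  set.seed(7)
  n <- 500
  base <- stats::rnorm(n, 8, 1.5)
  samples <- data.frame(sample_id = c("a", "b"), condition = c("treated", "control"),
                        time_min = c(5, 5), batch = "B1", stringsAsFactors = FALSE)

  # two identical arrays: zero correction
  v <- cbind(a = base, b = base)
  rownames(v) <- sprintf("g%03d", seq_len(n))
  em <- expression_matrix(v, samples, scale = "log2")
  expect_equal(em_values(loess_normalize(em)), v, tolerance = 1e-8)

  # constant offset removed
  v2 <- cbind(a = base, b = base + 0.5)
  rownames(v2) <- rownames(v)
  out <- em_values(loess_normalize(expression_matrix(v2, samples, scale = "log2")))
  expect_lt(abs(mean(out[, "a"] - out[, "b"])), 0.01)

  # linear intensity-dependent bias flattened
  v3 <- cbind(a = base, b = base + 0.15 * (base - mean(base)))
  rownames(v3) <- rownames(v)
  out3 <- em_values(loess_normalize(expression_matrix(v3, samples, scale = "log2")))
  resid <- out3[, "b"] - rowMeans(out3)
  slope <- stats::coef(stats::lm(resid ~ rowMeans(out3)))[2]
  expect_lt(abs(slope), 0.01)

  small <- expression_matrix(v[1:5, ], samples, scale = "log2")
  expect_error(loess_normalize(small), class = "ns_data_error")
})

test_that("batch correction: identity, planted offset removal, mean conservation", {
  set.seed(11)
  n <- 200
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    condition = rep(c("treated", "control"), 4),
    time_min = rep(c(5, 5, 10, 10), 2),
    batch = rep(c("B1", "B2"), each = 4), stringsAsFactors = FALSE
  )
  v <- matrix(stats::rnorm(n * 8, 8, 1), nrow = n,
              dimnames = list(sprintf("g%03d", 1:n), samples$sample_id))

  one_batch <- samples
  one_batch$batch <- "B1"
  em1 <- expression_matrix(v, one_batch, scale = "log2")
  expect_identical(em_values(batch_correct(em1)), v)

  v2 <- v
  v2[, samples$batch == "B2"] <- v2[, samples$batch == "B2"] + 1
  em2 <- expression_matrix(v2, samples, scale = "log2")
  for (meth in c("scale", "mean")) {
    out <- em_values(batch_correct(em2, method = meth))
    gap <- rowMeans(out[, samples$batch == "B1"]) - rowMeans(out[, samples$batch == "B2"])
    expect_lt(max(abs(gap)), 0.01)
    expect_equal(rowMeans(out), rowMeans(v2), tolerance = 1e-9)
  }

  lone <- samples
  lone$batch[8] <- "B3"
  em3 <- expression_matrix(v2, lone, scale = "log2")
  expect_error(batch_correct(em3), "single sample", class = "ns_config_error")
  expect_warning(batch_correct(em3, allow_singleton = TRUE),
                 class = "ns_singleton_warning")
})

test_that("fold changes: identity, closed form, replicate averaging on log scale", {
  em <- toy_expression(n_genes = 15)
  pr <- compute_fold_changes(em)
  expect_equal(unname(pr$fc_treatment), matrix(1, 15, 4))
  expect_equal(unname(pr$fc_rescue), matrix(1, 15, 4))

  v <- em_values(em)
  v["G001", "trt2"] <- 9  # log2 difference of 1 at one point
  pr2 <- compute_fold_changes(expression_matrix(v, em_samples(em), scale = "log2"))
  expect_equal(unname(pr2$fc_treatment["G001", 2]), 2)
  expect_equal(unname(pr2$fc_treatment["G001", 1]), 1)

  # replicate treated columns {8, 9, 10} average to 9 on the log scale
  samples <- data.frame(
    sample_id = c("t1a", "t1b", "t1c", "c1"),
    condition = c("treated", "treated", "treated", "control"),
    time_min = c(5, 5, 5, 5), batch = "B1", stringsAsFactors = FALSE
  )
  # four treatment points required downstream, but fold change itself works per point
  v3 <- matrix(c(8, 9, 10, 8), nrow = 1, dimnames = list("G1", samples$sample_id))
  pr3 <- compute_fold_changes(expression_matrix(v3, samples, scale = "log2"))
  expect_equal(unname(pr3$fc_treatment[1, 1]), 2)

  no_ctrl <- toy_expression()
  sheet <- em_samples(no_ctrl)
  sheet$condition[sheet$condition == "control"] <- "rescue"
  sheet$time_min[sheet$condition == "rescue"] <- rep(c(5, 10, 15, 30), 2)
  expect_error(compute_fold_changes(expression_matrix(em_values(no_ctrl), sheet, scale = "log2")),
               class = "ns_design_error")
})

test_that("serial regulation: worked examples from the selection rule", {
  up4 <- detect_serial_regulation(c(1.3, 1.25, 1.4, 1.3, 1.0, 1.0, 1.0, 1.0, 1.0))
  expect_true(up4$selected)
  expect_identical(up4$direction, "up")
  expect_identical(up4$run_start_index, 1L)
  expect_identical(up4$run_length, 4L)

  broken <- detect_serial_regulation(c(1.3, 1.3, 1.3, 1.19, 1.3, 1.3, 1.3, 1.0, 1.0))
  expect_false(broken$selected)

  # boundary values do not qualify
  expect_false(detect_serial_regulation(c(1.2, 1.2, 1.2, 1.2, 1, 1, 1, 1, 1))$selected)
  expect_false(detect_serial_regulation(c(0.8, 0.8, 0.8, 0.8, 1, 1, 1, 1, 1))$selected)

  down <- detect_serial_regulation(c(0.7, 0.7, 0.75, 0.79, 0.7, 1, 1, 1, 1))
  expect_identical(down$direction, "down")
  expect_identical(down$run_length, 5L)

  # rescue reversal: qualifying rescue run in the same direction blocks it
  r1 <- detect_serial_regulation(rep(1.3, 9), fc_rescue = rep(1.0, 9))
  expect_true(r1$rescue_reversed)
  r2 <- detect_serial_regulation(rep(1.3, 9), fc_rescue = rep(1.3, 9))
  expect_false(r2$rescue_reversed)
  r3 <- detect_serial_regulation(rep(1.3, 9), fc_rescue = rep(0.7, 9))
  expect_true(r3$rescue_reversed)  # opposite-direction rescue run still reverses
})

test_that("serial regulation agrees with the exhaustive window-scan oracle", {
  # every 2^9 above/below pattern, in each direction, plus mixed alphabets
  for (pattern in 0:511) {
    bits <- as.integer(intToBits(pattern))[1:9]
    up_ratios <- ifelse(bits == 1L, 1.3, 1.0)
    got <- detect_serial_regulation(up_ratios)
    want <- oracle_serial(up_ratios)
    expect_identical(got$selected, want$selected)
    expect_identical(got$direction, want$direction)
    expect_identical(got$run_length, as.integer(want$run_length))
    down_ratios <- ifelse(bits == 1L, 0.7, 1.0)
    got_d <- detect_serial_regulation(down_ratios)
    want_d <- oracle_serial(down_ratios)
    expect_identical(got_d$direction, want_d$direction)
    expect_identical(got_d$run_length, as.integer(want_d$run_length))
  }
  set.seed(41)
  for (i in 1:200) {
    ratios <- sample(c(0.7, 1.0, 1.3), 9, replace = TRUE)
    got <- detect_serial_regulation(ratios)
    want <- oracle_serial(ratios)
    expect_identical(got$selected, want$selected)
    expect_identical(got$direction, want$direction)
    expect_identical(got$run_start_index, as.integer(want$run_start_index))
    expect_identical(got$run_length, as.integer(want$run_length))
  }
})

test_that("serial call is invariant to values outside the qualifying window", {
  base <- c(1.0, 1.3, 1.3, 1.3, 1.3, 1.0, 1.0, 1.0, 1.0)
  ref <- detect_serial_regulation(base)
  for (val in c(0.5, 1.0, 1.19)) {
    mod <- base
    mod[c(1, 7, 9)] <- val
    got <- detect_serial_regulation(mod)
    expect_identical(got$run_start_index, ref$run_start_index)
    expect_identical(got$run_length, ref$run_length)
    expect_identical(got$direction, "up")
  }
})

test_that("reciprocal profiles swap directions exactly under symmetric bounds", {
  set.seed(43)
  for (i in 1:100) {
    ratios <- exp(stats::rnorm(9, 0, 0.4))
    a <- detect_serial_regulation(ratios, up_bound = 1.2, down_bound = 1 / 1.2)
    b <- detect_serial_regulation(1 / ratios, up_bound = 1.2, down_bound = 1 / 1.2)
    swap <- c(up = "down", down = "up", none = "none")
    expect_identical(unname(swap[a$direction]), b$direction)
    expect_identical(a$run_length, b$run_length)
    expect_identical(a$run_start_index, b$run_start_index)
  }
})

test_that("non-rescue flatness matches the direct SD formula", {
  expect_true(detect_non_rescued(rep(0.3, 10)))
  expect_false(detect_non_rescued(c(0, 0.1)))  # sd ~ 0.0707
  expect_equal(stats::sd(c(0, 0.1)), 0.07071068, tolerance = 1e-6)
  set.seed(47)
  for (i in 1:1000) {
    x <- stats::rnorm(sample(2:12, 1), sd = stats::runif(1, 0, 0.05))
    expect_identical(detect_non_rescued(x), stats::sd(x) <= 0.01)
  }
  expect_error(detect_non_rescued(0.5), class = "ns_config_error")
})

test_that("temporal correlation classifies monotone and degenerate profiles", {
  inc <- temporal_correlation(seq(0, 1, length.out = 9))
  expect_equal(inc$R, 1)
  expect_identical(inc$class, "up")
  dec <- temporal_correlation(seq(1, 0, length.out = 9))
  expect_equal(dec$R, -1)
  expect_identical(dec$class, "down")
  expect_warning(flat <- temporal_correlation(rep(0.2, 9)),
                 class = "ns_degenerate_warning")
  expect_identical(flat$class, "none")
  expect_true(is.na(flat$R))
  mid <- temporal_correlation(c(0, 1, 0, 1, 0, 1, 0, 1, 0))
  expect_identical(mid$class, "none")
})

test_that("pathway trajectories: identity, cancellation, planted peak", {
  fc <- matrix(0, nrow = 3, ncol = 9,
               dimnames = list(c("A", "B", "C"), NULL))
  fc["A", ] <- seq(0.1, 0.9, by = 0.1)
  fc["B", ] <- -seq(0.1, 0.9, by = 0.1)
  fc["C", ] <- c(0.2, 0.4, 0.75, 0.6, 0.5, 0.3, 0.2, 0.1, 0)
  pr <- make_profiles(fc, log2fc_rescue = fc * 0)

  single <- pathway_trajectory_summary(pr, list(list(name = "solo", description = "", genes = "C")))
  expect_equal(single$trajectories$mean_log2fc[single$trajectories$phase == "treatment"],
               unname(fc["C", ]))
  expect_equal(single$summary$max_abs_log2fc, 0.75)

  both <- pathway_trajectory_summary(pr, list(list(name = "pair", description = "", genes = c("A", "B"))))
  expect_equal(both$trajectories$mean_log2fc[both$trajectories$phase == "treatment"],
               rep(0, 9))

  expect_warning(
    empty <- pathway_trajectory_summary(pr, list(list(name = "none", description = "", genes = "ZZZ"))),
    class = "ns_empty_set_warning"
  )
  expect_identical(nrow(empty$summary), 0L)
})
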