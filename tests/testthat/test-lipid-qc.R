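make_raw <- function(x, expected = NULL, observed = NULL,
                     roles = NULL, dilution = NULL) {
  nf <- nrow(x); ns <- ncol(x)
  if (is.null(expected)) expected <- rep(800, nf)
  if (is.null(observed)) observed <- expected
  if (is.null(roles)) roles <- rep("study", ns)
  if (is.null(dilution)) dilution <- ifelse(roles == "qc_dilution", 1, NA)
  raw_feature_table(
    x,
    data.frame(feature = paste0("f", seq_len(nf)),
               expected_mass = expected, observed_mass = observed),
    data.frame(sample = paste0("s", seq_len(ns)), role = roles,
               dilution_factor = dilution)
  )
}

test_that("qc metrics follow their definitions", {
  # worked ppm example: 760.5851 Da expected vs 760.5889 observed -> 5 ppm
  rt <- make_raw(matrix(1, 1, 3), expected = 760.5851, observed = 760.5889)
  expect_equal(compute_qc_metrics(rt)$ppm_deviation, 5.0, tolerance = 1e-3)

  # all-zero blanks give an infinite ratio that passes the filter
  x <- matrix(10, 1, 5)
  x[1, 4:5] <- 0
  rt <- make_raw(x, roles = c("study", "study", "study", "blank", "blank"))
  m <- compute_qc_metrics(rt)
  expect_identical(m$blank_ratio, Inf)
  expect_true(apply_qc_filters(rt)$report$pass_blank_ratio)

  # intensities proportional to the dilution factor: r = 1
  dil <- c(NA, NA, NA, 1, 0.5, 0.25, 0.125)
  roles <- c(rep("study", 3), rep("qc_dilution", 4))
  x <- matrix(c(5, 5, 5, 100 * dil[4:7]), 1, 7)
  rt <- make_raw(x, roles = roles, dilution = dil)
  expect_equal(compute_qc_metrics(rt)$dilution_r, 1, tolerance = 1e-12)
})

test_that("not-evaluable filters pass by default with a message", {
  rt <- make_raw(matrix(1, 2, 3))
  expect_message(m <- compute_qc_metrics(rt), "no blank samples")
  expect_true(all(is.na(m$blank_ratio)))
  suppressMessages(res <- apply_qc_filters(rt))
  expect_true(all(res$report$pass_blank_ratio))
  expect_true(all(res$report$pass_dilution_r))
})

test_that("four disjoint violations leave six survivors, one per step", {
  vs <- list(ppm = 7L, blank = 2L, zero = 9L, dilution = 5L)
  sr <- simulate_raw_features(10, 30, violation_spec = vs, seed = 3L)
  res <- apply_qc_filters(sr$raw)
  expect_equal(nrow(res$filtered$intensities), 6L)
  expect_equal(res$attrition$removed, rep(1L, 4))
  expect_equal(res$report$removed_at[7], "ppm")
  expect_equal(res$report$removed_at[2], "blank_ratio")
  expect_equal(res$report$removed_at[9], "zero_fraction")
  expect_equal(res$report$removed_at[5], "dilution_r")
  expect_equal(res$report$pass_overall, sr$truth$overall)
})

test_that("all features passing returns the input unchanged", {
  sr <- simulate_raw_features(12, 28, seed = 4L)
  res <- apply_qc_filters(sr$raw)
  expect_identical(res$filtered$intensities, sr$raw$intensities)
  expect_identical(res$filtered$feature_meta, sr$raw$feature_meta)
})

test_that("boundary values at exact thresholds are retained", {
  # ppm exactly 5: expected 1e6 Da gives exact floating-point arithmetic
  rt <- make_raw(matrix(1, 1, 10), expected = 1e6, observed = 1000005)
  m <- compute_qc_metrics(rt)
  expect_identical(m$ppm_deviation, 5)
  expect_true(apply_qc_filters(rt)$report$pass_ppm)

  # blank ratio exactly 5 and zero fraction exactly 0.10
  x <- matrix(c(rep(50, 10), 10, 10), 1, 12)
  x[1, 1] <- 0                     # 1 zero of 10 study samples
  x[1, 11:12] <- mean(x[1, 1:10]) / 5
  rt <- make_raw(x, roles = c(rep("study", 10), "blank", "blank"))
  m <- compute_qc_metrics(rt)
  expect_identical(m$blank_ratio, 5)
  expect_identical(m$zero_fraction, 0.1)
  rep2 <- apply_qc_filters(rt)$report
  expect_true(rep2$pass_blank_ratio && rep2$pass_zero_fraction)
})

test_that("filters are conjunctive and monotone in their thresholds", {
  vs <- list(ppm = c(1L, 2L), blank = c(2L, 3L), zero = 8L,
             dilution = c(4L, 8L))  # overlapping violations
  sr <- simulate_raw_features(12, 30, violation_spec = vs, seed = 5L)
  res <- apply_qc_filters(sr$raw)
  with(res$report, expect_equal(
    pass_overall,
    pass_ppm & pass_blank_ratio & pass_zero_fraction & pass_dilution_r))
  # loosening any threshold never removes a survivor
  loose <- apply_qc_filters(sr$raw, qc_thresholds(
    ppm = 10, blank_ratio = 2, zero_fraction = 0.5, dilution_r = 0.5))
  expect_true(all(res$report$pass_overall <= loose$report$pass_overall))
})

test_that("empty survivor set warns rather than errors", {
  sr <- simulate_raw_features(3, 25,
                              violation_spec = list(ppm = 1:3), seed = 6L)
  expect_warning(res <- apply_qc_filters(sr$raw), "no features survive")
  expect_equal(nrow(res$filtered$intensities), 0L)
})
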