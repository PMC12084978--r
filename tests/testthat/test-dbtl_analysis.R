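test_that("success rates reproduce the build-funnel percentages", {
  expect_identical(success_rate(51, 56), 91.1)
  expect_identical(success_rate(48, 56), 85.7)
  expect_identical(success_rate(0, 56), 0)
  expect_equal(success_rate(51, 56, raw = TRUE), 5100 / 56)
  expect_error(success_rate(57, 56), class = "dopaflow_validation_error")
  # monotone in the numerator
  for (a in c(0, 10, 30)) {
    expect_gte(success_rate(a + 5, 56, raw = TRUE),
               success_rate(a, 56, raw = TRUE))
  }
})

test_that("fold change and percent increase match the headline arithmetic", {
  expect_identical(fold_change(69.03, 27), 2.6)
  expect_identical(fold_change(34.34, 5.17), 6.6)
  expect_identical(fold_change(3.3, 3.3), 1)
  expect_identical(percent_increase(0.83, 0.60), 38)
  expect_identical(percent_increase(2.5, 2.5), 0)
  expect_identical(percent_increase(1.5, 1.0), 50)
  expect_error(fold_change(1, 0), class = "dopaflow_validation_error")
  expect_error(percent_increase(1, 0), class = "dopaflow_validation_error")
  # consistency: percent_increase = 100 * (fold - 1) before rounding
  for (pair in list(c(0.83, 0.60), c(69.03, 27), c(5, 4))) {
    expect_equal(percent_increase(pair[1], pair[2], raw = TRUE),
                 100 * (fold_change(pair[1], pair[2], raw = TRUE) - 1))
  }
})

test_that("mM to mg/L conversion uses formula masses", {
  # independent oracle: hand-summed conventional atomic masses
  # dopamine C8H11NO2 = 8*12.011 + 11*1.008 + 14.007 + 2*15.999
  expect_equal(convert_mM_to_mg_per_L(1, "dopamine"), 153.181)
  expect_equal(round(convert_mM_to_mg_per_L(1, "dopamine"), 2), 153.18)
  # l-DOPA C9H11NO4, 5 mM
  expect_equal(round(convert_mM_to_mg_per_L(5, "dopa"), 2), 985.95)
  expect_equal(convert_mM_to_mg_per_L(0, "tyrosine"), 0)
  expect_error(convert_mM_to_mg_per_L(1, "serotonin"))
  expect_error(convert_mM_to_mg_per_L(-1, "dopamine"),
               class = "dopaflow_validation_error")
})

test_that("specific yield is division and scales linearly", {
  expect_equal(specific_yield(69.03, 69.03 / 34.34), 34.34)
  expect_equal(round(specific_yield(69.03, 2.0102), 2), 34.34)
  expect_identical(specific_yield(0, 2), 0)
  expect_identical(specific_yield(7.5, 1), 7.5)
  t <- c(10, 20)
  expect_equal(specific_yield(2 * t, 1.7), 2 * specific_yield(t, 1.7))
  expect_error(specific_yield(1, 0), class = "dopaflow_validation_error")
})

make_results <- function(gc_h, gc_d, titre, dopa = 0, id = NULL) {
  if (is.null(id)) id <- sprintf("S%02d", seq_along(gc_h))
  tibble::tibble(
    design_id = id,
    dopamine_mg_per_L = titre,
    dopa_mg_per_L = dopa,
    biomass_g_per_L = 2,
    gc_hpaBC = gc_h,
    gc_ddc = gc_d
  )
}

test_that("gc_stratified_analysis recovers planted monotone trends", {
  gc_d <- seq(0, 1, by = 0.1)
  dec <- make_results(gc_h = rep(0.9, 11), gc_d = gc_d,
                      titre = 60 - 40 * gc_d)
  out <- gc_stratified_analysis(dec, "hpaBC", c(0.8, 1))
  expect_identical(out$direction, "negative")
  expect_equal(out$rho, -1)
  expect_identical(out$n, 11L)
  expect_identical(out$free_context, "ddc")

  # mirrored: ddc fixed high-GC, titres planted decreasing in falling gc_hpaBC
  gc_h <- seq(0, 1, by = 0.1)
  inc <- make_results(gc_h = gc_h, gc_d = rep(0.95, 11),
                      titre = 10 + 50 * gc_h)
  out2 <- gc_stratified_analysis(inc, "ddc", c(0.8, 1))
  expect_identical(out2$direction, "positive")
  expect_equal(out2$rho, 1)
})

test_that("flat titres give direction none, sparse bands error", {
  flat <- make_results(rep(0.9, 5), seq(0, 1, length.out = 5), rep(42, 5))
  out <- gc_stratified_analysis(flat, "hpaBC", c(0.8, 1))
  expect_identical(out$direction, "none")
  sparse <- make_results(c(0.1, 0.2, 0.9), c(0.3, 0.4, 0.5), c(1, 2, 3))
  expect_error(gc_stratified_analysis(sparse, "hpaBC", c(0.8, 1)),
               class = "dopaflow_insufficient_data_error")
})

test_that("dopa accumulation flags exactly the planted accumulators", {
  res <- make_results(
    gc_h = rep(0.5, 6), gc_d = rep(0.5, 6),
    titre = c(50, 40, 0, 10, 30, 20),
    dopa = c(10, 80, 5, 25, 0, 20.0001),
    id = c("B.03", "A.01", "B.06", "A.04", "B.08", "B.09")
  )
  flags <- dopa_accumulation_flags(res, threshold_ratio = 1)
  # dopa/dopamine: 0.2, 2, Inf-guarded, 2.5, 0, just over 1
  expect_identical(flags, c("A.01", "A.04", "B.06", "B.09"))
  # dopamine == 0 with any dopa is flagged; zero dopa never flagged
  expect_true("B.06" %in% flags)
  expect_false("B.08" %in% flags)
  expect_identical(dopa_accumulation_flags(res, threshold_ratio = 10), "B.06")
})

test_that("build funnel counts stages and validates the ladder", {
  log <- tibble::tibble(
    design_id = sprintf("A.%02d", 1:8),
    pcr_ok = c(rep(TRUE, 7), FALSE),
    assembled_ok = c(rep(TRUE, 6), FALSE, FALSE),
    sequence_verified = c(rep(TRUE, 5), FALSE, FALSE, FALSE)
  )
  funnel <- build_funnel(log)
  expect_equal(funnel$count, c(8L, 7L, 6L, 5L))
  expect_equal(funnel$success_rate_percent[4], success_rate(5, 8))
  bad <- dplyr::mutate(log, sequence_verified = TRUE)
  expect_error(build_funnel(bad), class = "dopaflow_validation_error")
})

test_that("estimate_optimal_ratio finds a planted log-Gaussian peak", {
  truth <- response_surface_truth(optimal_expr_ratio = 2.6)
  ratios <- exp(seq(-1, 3.5, length.out = 40))
  res <- tibble::tibble(
    expr_ratio = ratios,
    dopamine_mg_per_L = truth_titre(truth, ratios)
  )
  est <- estimate_optimal_ratio(res)
  expect_identical(est$method, "quadratic")
  expect_equal(est$optimal_ratio, 2.6, tolerance = 1e-6)
  expect_lt(est$curvature, 0)
  # a monotone (rising) cohort falls back to the observed argmax
  mono <- tibble::tibble(expr_ratio = 1:10,
                         dopamine_mg_per_L = exp(0.5 * log(1:10)))
  est2 <- estimate_optimal_ratio(mono)
  expect_lte(est2$optimal_ratio, 10 + 1e-9)
})
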