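test_that("generated libraries are deterministic and span all GC levels", {
  l1 <- gen_rbs_library(n_per_context = 30, seed = 5)
  l2 <- gen_rbs_library(n_per_context = 30, seed = 5)
  expect_identical(l1, l2)
  l3 <- gen_rbs_library(n_per_context = 30, seed = 6)
  expect_false(identical(l1$sd_sequence, l3$sd_sequence))
  for (ctx in c("hpaBC", "ddc")) {
    sub <- l1[l1$context == ctx, ]
    expect_equal(nrow(sub), 30)
    expect_setequal(round(sub$gc_fraction * 6), 0:6)
    expect_true("AGGAGA" %in% sub$sd_sequence)
    expect_false(any(duplicated(sub$sd_sequence)))
  }
  # output satisfies the consumer invariants by construction
  expect_silent(validate_rbs_library(l1))
})

test_that("exhaustive library covers the whole SD space per context", {
  lib <- gen_rbs_library(n_per_context = 4096, seed = 1)
  for (ctx in c("hpaBC", "ddc")) {
    expect_setequal(lib$sd_sequence[lib$context == ctx], enumerate_sd_space(6))
  }
  expect_error(gen_rbs_library(n_per_context = 4097, seed = 1),
               class = "dopaflow_validation_error")
})

test_that("noise-free TIR ordering equals GC ordering", {
  lib <- gen_rbs_library(
    n_per_context = 25,
    model_hpaBC = strength_model(0, 2, 0),
    model_ddc = strength_model(0.845, -2, 0),
    seed = 17
  )
  h <- lib[lib$context == "hpaBC", ]
  d <- lib[lib$context == "ddc", ]
  expect_identical(order(h$tir), order(h$gc_fraction))
  expect_identical(order(d$tir), order(-d$gc_fraction))
})

test_that("planted truth is unimodal with the optimum where designed", {
  truth <- response_surface_truth()
  ratios <- exp(seq(-2, 4, length.out = 201))
  titres <- truth_titre(truth, ratios)
  peak <- ratios[which.max(titres)]
  expect_equal(peak, 2.6, tolerance = 0.02)
  # unimodal: increasing before the peak, decreasing after
  k <- which.max(titres)
  expect_true(all(diff(titres[1:k]) > 0))
  expect_true(all(diff(titres[k:length(titres)]) < 0))
  # l-DOPA leak is zero at/below the optimum and rising above it
  expect_equal(truth_dopa_leak(truth, c(0.5, 2.6)), c(0, 0))
  leak <- truth_dopa_leak(truth, c(3, 10, 30))
  expect_true(all(diff(leak) > 0))
  expect_error(response_surface_truth(expr_model_hpaBC = strength_model(0, -1, 0)),
               class = "dopaflow_validation_error")
})

test_that("noise-free cohorts lie exactly on the planted surface", {
  lib <- fixture_library(seed = 401, n_per_context = 40)
  sheet <- fixture_design_sheet(lib, seed = 402)
  truth <- response_surface_truth(measurement_cv = 0)
  res <- gen_strain_results(sheet, truth, seed = 403, replicates = 1,
                            biomass_cv = 0)
  ratio <- truth_expr_ratio(truth, res$gc_hpaBC, res$gc_ddc)
  expect_equal(res$dopamine_mg_per_L, truth_titre(truth, ratio))
  expect_equal(res$dopa_mg_per_L, truth_dopa_leak(truth, ratio))
  expect_equal(res$biomass_g_per_L, rep(2.0102, nrow(res)))
  # the design closest to the planted optimal ratio has the top titre
  best <- which.max(res$dopamine_mg_per_L)
  delta <- abs(log(ratio / truth$optimal_expr_ratio))
  expect_lte(delta[best], min(delta) + 1e-9)
})

test_that("strain results are seed-deterministic with replicate structure", {
  lib <- fixture_library(seed = 404, n_per_context = 30)
  sheet <- fixture_design_sheet(lib, seed = 405)
  r1 <- gen_strain_results(sheet, seed = 7)
  r2 <- gen_strain_results(sheet, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3 * nrow(sheet))
  expect_equal(sort(unique(r1$replicate)), 1:3)
  expect_silent(gc_stratified_analysis(r1, "hpaBC", c(0, 1)))
})

test_that("build logs respect the stage ladder and probabilities", {
  ids <- sprintf("A.%02d", 1:56)
  all_pass <- gen_build_log(ids, c(1, 1, 1), seed = 1)
  expect_true(all(all_pass$sequence_verified))
  no_seq <- gen_build_log(ids, c(1, 1, 0), seed = 1)
  expect_true(all(no_seq$assembled_ok))
  expect_false(any(no_seq$sequence_verified))
  expect_identical(success_rate(sum(no_seq$sequence_verified), 56), 0)
  log <- gen_build_log(ids, c(0.9, 0.8, 0.7), seed = 2)
  expect_true(all(log$assembled_ok <= log$pcr_ok))
  expect_true(all(log$sequence_verified <= log$assembled_ok))
  expect_identical(gen_build_log(ids, c(0.9, 0.8, 0.7), seed = 2), log)
  expect_error(gen_build_log(ids, c(1.2, 1, 1), seed = 1),
               class = "dopaflow_validation_error")
})

test_that("default truth reproduces the qualitative pathway findings", {
  lib <- fixture_library(seed = 406)
  sheet <- fixture_design_sheet(lib, seed = 407)
  res <- gen_strain_results(sheet, seed = 408)
  # ddc trend: hpaBC GC held high, titre falls as ddc GC rises
  trend_d <- gc_stratified_analysis(res, "hpaBC", c(0.8, 1))
  expect_identical(trend_d$direction, "negative")
  # hpaBC trend: ddc GC held low (strong Ddc), titre rises with hpaBC GC
  trend_h <- gc_stratified_analysis(res, "ddc", c(0, 0.2))
  expect_identical(trend_h$direction, "positive")
  # accumulators sit where the expression ratio overshoots the optimum
  truth <- response_surface_truth()
  flags <- dopa_accumulation_flags(res, threshold_ratio = 1)
  per_design <- res[!duplicated(res$design_id), ]
  ratio <- truth_expr_ratio(truth, per_design$gc_hpaBC, per_design$gc_ddc)
  overshoot <- per_design$design_id[ratio > truth$optimal_expr_ratio]
  expect_true(all(flags %in% overshoot))
})
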