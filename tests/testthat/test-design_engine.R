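test_that("design targets follow the ddc/hpaBC numeric-ratio convention", {
  tg <- design_targets(c(1, 2, 100))
  expect_equal(tg$numeric_ratio, c(1, 0.5, 0.01))
  expect_equal(tg$numeric_ratio * tg$hpaBC_to_ddc_ratio, rep(1, 3))
  expect_error(design_targets(c(2, -1)), class = "dopaflow_validation_error")
})

test_that("an exact-ratio pair ranks first with zero distance", {
  lib <- toy_library(tirs_h = c(2, 1), tirs_d = c(1, 5))
  # pair (h=2, d=1): tir_d/tir_h = 0.5 == numeric target of 2:1
  out <- strategy_a_match(lib, targets = 2, n_per_target = 1)
  expect_equal(out$numeric_tir_ratio, 0.5)
  expect_equal(out$log_distance, 0)
})

test_that("strategy A equals the exhaustive cross-product oracle", {
  lib <- fixture_library(seed = 301, n_per_context = 50)
  for (target in c(1, 2.6, 10, 100)) {
    got <- strategy_a_match(lib, targets = target, n_per_target = 5)
    oracle <- brute_force_match(lib, 1 / target, 5)
    expect_equal(got$numeric_tir_ratio, oracle$ratio)
    expect_equal(got$rbs_hpaBC_seq, oracle$seq_h)
    expect_equal(got$rbs_ddc_seq, oracle$seq_d)
    # no unselected pair beats any selected pair
    expect_true(all(diff(got$log_distance) >= 0))
    all_dists <- sort(abs(log(brute_force_match(lib, 1 / target,
                                                50 * 50)$ratio) -
                            log(1 / target)))
    expect_lte(max(got$log_distance), all_dists[6])
  }
})

test_that("strategy A distances are within-target sorted and pairs unique", {
  lib <- fixture_library(seed = 302, n_per_context = 30)
  out <- strategy_a_match(lib, targets = c(1, 2, 5, 10), n_per_target = 3)
  expect_equal(nrow(out), 12)
  for (tr in unique(out$target_ratio)) {
    sub <- out[out$target_ratio == tr, ]
    expect_true(all(diff(sub$log_distance) >= 0))
    expect_false(any(duplicated(paste(sub$rbs_hpaBC_id, sub$rbs_ddc_id))))
  }
  expect_true(all(out$log_distance ==
                    abs(log(out$numeric_tir_ratio) - log(out$numeric_target))))
})

test_that("mirrored library with inverted targets yields the mirrored designs", {
  lib <- fixture_library(seed = 303, n_per_context = 20)
  swapped <- dplyr::mutate(
    lib,
    context = dplyr::case_match(context, "hpaBC" ~ "ddc", "ddc" ~ "hpaBC",
                                .default = context)
  )
  for (target in c(2, 10)) {
    fwd <- strategy_a_match(lib, targets = target, n_per_target = 4)
    mir <- strategy_a_match(swapped, targets = 1 / target, n_per_target = 4)
    expect_setequal(
      paste(fwd$rbs_hpaBC_id, fwd$rbs_ddc_id),
      paste(mir$rbs_ddc_id, mir$rbs_hpaBC_id)
    )
    expect_equal(sort(fwd$log_distance), sort(mir$log_distance))
  }
})

test_that("strategy B is seed-stable, duplicate-free, and anchored", {
  lib <- fixture_library(seed = 304)
  b1 <- strategy_b_sample(lib, n = 41, seed = 9)
  b2 <- strategy_b_sample(lib, n = 41, seed = 9)
  expect_identical(b1, b2)
  b3 <- strategy_b_sample(lib, n = 41, seed = 10)
  expect_false(identical(b1$rbs_hpaBC_id, b3$rbs_hpaBC_id) &&
                 identical(b1$rbs_ddc_id, b3$rbs_ddc_id))
  expect_equal(nrow(b1), 41)
  expect_false(any(duplicated(paste(b1$rbs_hpaBC_id, b1$rbs_ddc_id))))
  # strongest candidates of both contexts appear
  h <- lib[lib$context == "hpaBC", ]
  d <- lib[lib$context == "ddc", ]
  expect_true(h$id[which.max(h$tir)] %in% b1$rbs_hpaBC_id)
  expect_true(d$id[which.max(d$tir)] %in% b1$rbs_ddc_id)
  # reference AGGAGA/AGGAGA pair is present (library includes the reference)
  expect_true(any(b1$rbs_hpaBC_seq == "AGGAGA" & b1$rbs_ddc_seq == "AGGAGA"))
})

test_that("strategy B at full pair count returns every pair", {
  lib <- toy_library()
  out <- strategy_b_sample(lib, n = 9, seed = 1)
  expect_equal(nrow(out), 9)
  expect_equal(dplyr::n_distinct(paste(out$rbs_hpaBC_id, out$rbs_ddc_id)), 9)
  expect_error(strategy_b_sample(lib, n = 10, seed = 1),
               class = "dopaflow_validation_error")
})

test_that("design sheet labels A then B in order and handles duplicates", {
  lib <- fixture_library(seed = 305, n_per_context = 25)
  a <- strategy_a_match(lib, targets = c(1, 2, 5), n_per_target = 5)
  b <- strategy_b_sample(lib, n = 41, seed = 3)
  sheet <- assemble_design_sheet(a, b)
  n_dup <- sum(sheet$cross_strategy_duplicate)
  expect_equal(nrow(sheet), 15 + 41 - n_dup)
  a_ids <- sheet$design_id[startsWith(sheet$design_id, "A")]
  expect_identical(a_ids, sprintf("A.%02d", seq_along(a_ids)))
  if (n_dup > 0) {
    expect_true(all(sheet$strategy[sheet$cross_strategy_duplicate] == "A+B"))
  }
  # empty strategy B: sheet is just the labeled A list
  only_a <- assemble_design_sheet(a, b[0, ])
  expect_equal(nrow(only_a), 15)
  expect_identical(only_a$design_id, sprintf("A.%02d", 1:15))
  expect_true(all(only_a$strategy == "A"))
})

test_that("cross-target exclusion yields fresh pairs per target", {
  lib <- fixture_library(seed = 306, n_per_context = 40)
  # adjacent extreme targets would otherwise re-select the same pairs
  slate <- strategy_a_match(lib, targets = c(1, 2, 5, 10, 20, 50, 100),
                            n_per_target = c(2, 2, 2, 2, 2, 2, 3),
                            distinct_across_targets = TRUE)
  expect_equal(nrow(slate), 15)
  expect_false(any(duplicated(paste(slate$rbs_hpaBC_id, slate$rbs_ddc_id))))
  # without exclusion the same extreme pair may serve several targets
  free <- strategy_a_match(lib, targets = c(50, 100), n_per_target = 2)
  expect_equal(nrow(free), 4)
})

test_that("context-missing libraries are rejected", {
  lib <- toy_library()
  only_h <- lib[lib$context == "hpaBC", ]
  expect_error(strategy_a_match(only_h, targets = 1),
               class = "dopaflow_validation_error")
  expect_error(strategy_b_sample(only_h, n = 2, seed = 1),
               class = "dopaflow_validation_error")
})
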