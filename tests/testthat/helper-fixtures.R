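# Shared synthetic fixtures, built once per test run.

# A paper-scale characterized library and a 56-design sheet (15 strategy A
# + 41 strategy B) under the default planted truth.
fixture_library <- function(seed = 101, n_per_context = 60) {
  gen_rbs_library(n_per_context = n_per_context, seed = seed)
}

fixture_design_sheet <- function(library, seed = 202) {
  a <- strategy_a_match(library, targets = c(1, 2, 5, 10, 20, 50, 100),
                        n_per_target = c(2, 2, 2, 2, 2, 2, 3),
                        distinct_across_targets = TRUE)
  b <- strategy_b_sample(library, n = 41, seed = seed)
  assemble_design_sheet(a, b)
}

# Tiny handcrafted library where every expected selection can be checked by
# hand or exhaustive enumeration.
toy_library <- function(tirs_h = c(1, 2, 4), tirs_d = c(1, 3, 9)) {
  seqs_h <- c("AAAAAA", "AGGAGA", "GGGGGG")[seq_along(tirs_h)]
  seqs_d <- c("TTTTTT", "AGGAGA", "CCCCCC")[seq_along(tirs_d)]
  validate_rbs_library(tibble::tibble(
    id = c(paste0("h", seq_along(tirs_h)), paste0("d", seq_along(tirs_d))),
    sd_sequence = c(seqs_h, seqs_d),
    context = c(rep("hpaBC", length(tirs_h)), rep("ddc", length(tirs_d))),
    tir = c(tirs_h, tirs_d)
  ))
}

# Exhaustive strategy-A oracle: brute-force the full cross product and sort.
brute_force_match <- function(library, numeric_target, n) {
  h <- library[library$context == "hpaBC", ]
  d <- library[library$context == "ddc", ]
  grid <- expand.grid(hi = seq_len(nrow(h)), di = seq_len(nrow(d)))
  grid$ratio <- d$tir[grid$di] / h$tir[grid$hi]
  grid$dist <- abs(log(grid$ratio) - log(numeric_target))
  grid$seq_h <- h$sd_sequence[grid$hi]
  grid$seq_d <- d$sd_sequence[grid$di]
  ord <- order(grid$dist, grid$seq_h, grid$seq_d,
               h$id[grid$hi], d$id[grid$di])
  grid[ord[seq_len(n)], ]
}
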