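#' Build design targets from HpaBC:Ddc ratios
#'
#' Converts enzyme ratios into the numeric TIR-ratio convention used for
#' matching: a target of 2 ("2:1" HpaBC:Ddc) corresponds to a numeric ratio
#' of 0.5, because the numeric ratio is defined as TIR(ddc)/TIR(hpaBC).
#'
#' @param hpaBC_to_ddc_ratio Numeric vector of target enzyme ratios, > 0.
#' @return A tibble with columns `hpaBC_to_ddc_ratio` and `numeric_ratio`.
#' @examples
#' design_targets(c(1, 2, 100))
#' @export
design_targets <- function(hpaBC_to_ddc_ratio) {
  if (!is.numeric(hpaBC_to_ddc_ratio) || length(hpaBC_to_ddc_ratio) == 0 ||
      any(!is.finite(hpaBC_to_ddc_ratio)) || any(hpaBC_to_ddc_ratio <= 0)) {
    abort_validation("target ratios must be positive finite numbers.")
  }
  tibble::tibble(
    hpaBC_to_ddc_ratio = hpaBC_to_ddc_ratio,
    numeric_ratio = 1 / hpaBC_to_ddc_ratio
  )
}

split_library_contexts <- function(library) {
  library <- validate_rbs_library(library)
  h <- dplyr::filter(library, .data$context == "hpaBC")
  d <- dplyr::filter(library, .data$context == "ddc")
  if (nrow(h) == 0 || nrow(d) == 0) {
    abort_validation("library must contain entries for both contexts hpaBC and ddc.")
  }
  list(hpaBC = h, ddc = d)
}

pair_cross_product <- function(h, d) {
  grid <- tidyr::expand_grid(hi = seq_len(nrow(h)), di = seq_len(nrow(d)))
  tibble::tibble(
    rbs_hpaBC_id = h$id[grid$hi],
    rbs_hpaBC_seq = h$sd_sequence[grid$hi],
    gc_hpaBC = h$gc_fraction[grid$hi],
    tir_hpaBC = h$tir[grid$hi],
    rbs_ddc_id = d$id[grid$di],
    rbs_ddc_seq = d$sd_sequence[grid$di],
    gc_ddc = d$gc_fraction[grid$di],
    tir_ddc = d$tir[grid$di],
    numeric_tir_ratio = d$tir[grid$di] / h$tir[grid$hi]
  )
}

#' Strategy A: TIR-ratio matching against in vitro targets
#'
#' For each target enzyme ratio, scans the full cross product of
#' hpaBC-context and ddc-context library entries and selects the
#' `n_per_target` pairs whose numeric TIR ratio (TIR_ddc / TIR_hpaBC) is
#' closest to the target's numeric ratio in log space, so that 2:1 and 1:2
#' mismatches are penalized symmetrically. Ties are broken lexicographically
#' on (hpaBC sequence, ddc sequence) for deterministic output.
#'
#' @param library An RBS library with entries for both contexts.
#' @param targets A tibble from [design_targets()], or a numeric vector of
#'   HpaBC:Ddc ratios.
#' @param n_per_target Number of pairs to select per target (default 2);
#'   either a single count or one count per target.
#' @param distinct_across_targets If `TRUE`, a pair selected for an earlier
#'   target is excluded for later targets, so each target contributes
#'   `n_per_target` fresh designs (nearby targets would otherwise re-select
#'   the same extreme pairs). Default `FALSE`: targets are matched
#'   independently over the full cross product.
#' @return A tibble of candidate designs, sorted by (target order,
#'   log distance, hpaBC sequence, ddc sequence), with columns including
#'   `target_ratio`, `numeric_target`, sequences, TIRs, GC fractions,
#'   `numeric_tir_ratio`, `log_distance` and `strategy = "A"`.
#' @examples
#' lib <- gen_rbs_library(n_per_context = 15, seed = 7)
#' strategy_a_match(lib, targets = c(2, 10), n_per_target = 2)
#' @export
strategy_a_match <- function(library, targets, n_per_target = 2,
                             distinct_across_targets = FALSE) {
  if (is.numeric(targets)) targets <- design_targets(targets)
  require_columns(targets, c("hpaBC_to_ddc_ratio", "numeric_ratio"), "targets")
  if (nrow(targets) == 0) abort_validation("`targets` must be non-empty.")
  if (!is.numeric(n_per_target) ||
      !length(n_per_target) %in% c(1L, nrow(targets)) ||
      any(!is.finite(n_per_target)) || any(n_per_target < 1)) {
    abort_validation("`n_per_target` must be one positive count, or one per target.")
  }
  n_per_target <- rep_len(n_per_target, nrow(targets))
  parts <- split_library_contexts(library)
  pairs <- pair_cross_product(parts$hpaBC, parts$ddc)
  taken <- character(0)
  purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    tgt <- targets[i, ]
    pool <- pairs
    if (distinct_across_targets && length(taken) > 0) {
      pool <- pool[!paste(pool$rbs_hpaBC_id, pool$rbs_ddc_id) %in% taken, ]
    }
    selected <- pool |>
      dplyr::mutate(
        target_ratio = tgt$hpaBC_to_ddc_ratio,
        numeric_target = tgt$numeric_ratio,
        log_distance = abs(log(.data$numeric_tir_ratio) -
                             log(tgt$numeric_ratio))
      ) |>
      dplyr::distinct(.data$rbs_hpaBC_id, .data$rbs_ddc_id,
                      .keep_all = TRUE) |>
      dplyr::arrange(.data$log_distance, .data$rbs_hpaBC_seq,
                     .data$rbs_ddc_seq, .data$rbs_hpaBC_id,
                     .data$rbs_ddc_id) |>
      dplyr::slice_head(n = n_per_target[i])
    taken <<- c(taken, paste(selected$rbs_hpaBC_id, selected$rbs_ddc_id))
    selected
  }) |>
    dplyr::mutate(strategy = "A") |>
    dplyr::relocate("strategy", "target_ratio", "numeric_target")
}

#' Strategy B: seeded boundary exploration of the pair space
#'
#' Samples `n` distinct (hpaBC, ddc) RBS pairs to probe the system boundary:
#' the pair of strongest-TIR entries from each context is always included,
#' the AGGAGA/AGGAGA reference pair is included whenever both contexts
#' contain the reference sequence, and the remaining slots are filled by
#' seeded sampling stratified across the GC-fraction bins (width 1/6) of
#' both contexts, so the whole GC plane is probed. Deterministic given the
#' seed.
#'
#' @param library An RBS library with entries for both contexts.
#' @param n Number of distinct pairs to return (default 41); must not exceed
#'   the number of available distinct pairs.
#' @param seed Integer seed (mandatory; no hidden global randomness).
#' @return A tibble of designs with `strategy = "B"` and the same sequence,
#'   GC and TIR columns as [strategy_a_match()] (target columns are `NA`).
#' @export
strategy_b_sample <- function(library, n = 41, seed) {
  stop_if_not_scalar_number(n, "n", positive = TRUE)
  stop_if_not_scalar_number(seed, "seed")
  parts <- split_library_contexts(library)
  h <- parts$hpaBC
  d <- parts$ddc
  n_pairs <- nrow(h) * nrow(d)
  if (n > n_pairs) {
    abort_validation(sprintf(
      "requested %d pairs but only %d distinct pairs exist.", n, n_pairs
    ))
  }

  pick_key <- function(hi, di) paste(h$id[hi], d$id[di], sep = "\r")
  chosen_h <- integer(0)
  chosen_d <- integer(0)
  chosen_keys <- character(0)
  add_pair <- function(hi, di) {
    key <- pick_key(hi, di)
    if (!key %in% chosen_keys) {
      chosen_h <<- c(chosen_h, hi)
      chosen_d <<- c(chosen_d, di)
      chosen_keys <<- c(chosen_keys, key)
    }
  }

  # strongest-TIR candidates from each context (ties -> first by id order)
  add_pair(which.max(h$tir), which.max(d$tir))
  # reference AGGAGA/AGGAGA pair when characterized in both contexts
  ref_h <- which(h$sd_sequence == "AGGAGA")
  ref_d <- which(d$sd_sequence == "AGGAGA")
  if (length(ref_h) > 0 && length(ref_d) > 0 && length(chosen_keys) < n) {
    add_pair(ref_h[1], ref_d[1])
  }

  bin_of <- function(gc) pmin(floor(gc * 6), 5L)  # six bins of width 1/6
  h_bins <- bin_of(h$gc_fraction)
  d_bins <- bin_of(d$gc_fraction)

  withr::with_seed(seed, {
    while (length(chosen_keys) < n) {
      added_this_sweep <- FALSE
      combos <- tidyr::expand_grid(bh = 0:5, bd = 0:5)
      combos <- combos[sample.int(nrow(combos)), ]
      for (j in seq_len(nrow(combos))) {
        if (length(chosen_keys) >= n) break
        hi_cand <- which(h_bins == combos$bh[j])
        di_cand <- which(d_bins == combos$bd[j])
        if (length(hi_cand) == 0 || length(di_cand) == 0) next
        hi <- hi_cand[sample.int(length(hi_cand), 1)]
        di <- di_cand[sample.int(length(di_cand), 1)]
        if (!pick_key(hi, di) %in% chosen_keys) {
          add_pair(hi, di)
          added_this_sweep <- TRUE
        }
      }
      if (!added_this_sweep && length(chosen_keys) < n) {
        # bins effectively exhausted: fill uniformly from remaining pairs
        all_pairs <- tidyr::expand_grid(hi = seq_len(nrow(h)),
                                        di = seq_len(nrow(d)))
        keys <- pick_key(all_pairs$hi, all_pairs$di)
        remaining <- which(!keys %in% chosen_keys)
        need <- n - length(chosen_keys)
        take <- remaining[sample.int(length(remaining), need)]
        for (idx in take) add_pair(all_pairs$hi[idx], all_pairs$di[idx])
      }
    }
  })

  tibble::tibble(
    strategy = "B",
    target_ratio = NA_real_,
    numeric_target = NA_real_,
    rbs_hpaBC_id = h$id[chosen_h],
    rbs_hpaBC_seq = h$sd_sequence[chosen_h],
    gc_hpaBC = h$gc_fraction[chosen_h],
    tir_hpaBC = h$tir[chosen_h],
    rbs_ddc_id = d$id[chosen_d],
    rbs_ddc_seq = d$sd_sequence[chosen_d],
    gc_ddc = d$gc_fraction[chosen_d],
    tir_ddc = d$tir[chosen_d],
    numeric_tir_ratio = d$tir[chosen_d] / h$tir[chosen_h],
    log_distance = NA_real_
  )
}

#' Assemble the combined design sheet
#'
#' Concatenates strategy A and strategy B designs into one table with stable
#' design ids (`A.01`, `A.02`, ... then `B.01`, ...) assigned in input order.
#' A (hpaBC, ddc) sequence pair appearing in both strategies is flagged and
#' kept once, with both provenance tags joined as `"A+B"`.
#'
#' @param strategy_a Tibble from [strategy_a_match()] (may have zero rows).
#' @param strategy_b Tibble from [strategy_b_sample()] (may have zero rows).
#' @return The design sheet: one row per retained design with `design_id`,
#'   `strategy`, sequences, GC fractions, TIRs, `numeric_tir_ratio`,
#'   `target_ratio`, `log_distance` and a `cross_strategy_duplicate` flag.
#' @export
assemble_design_sheet <- function(strategy_a, strategy_b = NULL) {
  label <- function(df, prefix) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df$design_id <- sprintf("%s.%02d", prefix, seq_len(nrow(df)))
    df
  }
  a <- label(strategy_a, "A")
  b <- label(strategy_b, "B")
  sheet <- dplyr::bind_rows(a, b)
  if (is.null(sheet) || nrow(sheet) == 0) {
    abort_validation("both strategy lists are empty.")
  }
  key <- paste(sheet$rbs_hpaBC_seq, sheet$rbs_ddc_seq, sep = "\r")
  dup_first <- key %in% key[duplicated(key)] & !duplicated(key)
  sheet$cross_strategy_duplicate <- dup_first
  if (any(duplicated(key))) {
    strategies_of <- vapply(
      key[dup_first],
      function(k) paste(sort(unique(sheet$strategy[key == k])), collapse = "+"),
      character(1)
    )
    sheet$strategy[dup_first] <- strategies_of
    sheet <- sheet[!duplicated(key), ]
  }
  dplyr::relocate(
    tibble::as_tibble(sheet),
    "design_id", "strategy", "rbs_hpaBC_seq", "rbs_ddc_seq",
    "gc_hpaBC", "gc_ddc", "tir_hpaBC", "tir_ddc",
    "numeric_tir_ratio", "target_ratio", "log_distance"
  )
}
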