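#' Build success rate
#'
#' Percentage of designs passing a build stage relative to the number
#' designed, e.g. 51 of 56 constructs gives 91.1 and 48 of 56 sequence-
#' verified strains gives 85.7.
#'
#' @param numerator_count Designs passing the stage (non-negative integer).
#' @param designed_count Designs attempted (positive integer), `>=`
#'   `numerator_count`.
#' @param raw If `TRUE` return the unrounded percentage; default rounds to
#'   one decimal, half away from zero.
#' @return A percentage.
#' @examples
#' success_rate(51, 56)
#' success_rate(48, 56)
#' @export
success_rate <- function(numerator_count, designed_count, raw = FALSE) {
  stop_if_not_scalar_number(numerator_count, "numerator_count", nonneg = TRUE)
  stop_if_not_scalar_number(designed_count, "designed_count", positive = TRUE)
  if (numerator_count > designed_count) {
    abort_validation("`numerator_count` cannot exceed `designed_count`.")
  }
  value <- 100 * numerator_count / designed_count
  if (raw) value else round_half_up(value, 1)
}

#' Fold change relative to a benchmark
#'
#' @param new_value New performance value, > 0 context typical (>= 0 allowed).
#' @param benchmark_value Benchmark value, > 0.
#' @param raw If `TRUE` return unrounded; default rounds to one decimal,
#'   half away from zero.
#' @return Dimensionless fold change `new/benchmark`.
#' @examples
#' fold_change(69.03, 27)    # titre vs literature benchmark
#' fold_change(34.34, 5.17)  # specific yield vs benchmark
#' @export
fold_change <- function(new_value, benchmark_value, raw = FALSE) {
  stop_if_not_scalar_number(new_value, "new_value", nonneg = TRUE)
  stop_if_not_scalar_number(benchmark_value, "benchmark_value", positive = TRUE)
  value <- new_value / benchmark_value
  if (raw) value else round_half_up(value, 1)
}

#' Percent increase over an old value
#'
#' @param new_value New value, >= 0.
#' @param old_value Old value, > 0.
#' @param raw If `TRUE` return unrounded; default rounds to the nearest
#'   integer (half away from zero), the convention used for reporting.
#' @return Percentage increase `100 * (new - old) / old`.
#' @examples
#' percent_increase(0.83, 0.60)
#' @export
percent_increase <- function(new_value, old_value, raw = FALSE) {
  stop_if_not_scalar_number(new_value, "new_value", nonneg = TRUE)
  stop_if_not_scalar_number(old_value, "old_value", positive = TRUE)
  value <- 100 * (new_value - old_value) / old_value
  if (raw) value else round_half_up(value, 0)
}

# IUPAC 2021 conventional atomic masses, fixed so conversions are bit-stable
ATOMIC_MASSES <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)

COMPOUND_FORMULAS <- list(
  tyrosine = c(C = 9, H = 11, N = 1, O = 3),
  dopa     = c(C = 9, H = 11, N = 1, O = 4),
  dopamine = c(C = 8, H = 11, N = 1, O = 2)
)

#' Molar mass of a pathway compound
#'
#' Computed as the atomic-mass sum over the molecular formula
#' (l-tyrosine C9H11NO3, l-DOPA C9H11NO4, dopamine C8H11NO2) using a fixed
#' embedded table of conventional atomic masses.
#'
#' @param compound One of `"tyrosine"`, `"dopa"`, `"dopamine"`.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("dopamine")
#' @export
molar_mass <- function(compound) {
  compound <- match.arg(compound, names(COMPOUND_FORMULAS))
  formula <- COMPOUND_FORMULAS[[compound]]
  sum(formula * ATOMIC_MASSES[names(formula)])
}

#' Convert a concentration from mM to mg/L
#'
#' HPLC standards are specified in mM while titres are reported in mg/L;
#' this bridges the two via the compound's molar mass (1 mM of a compound
#' with molar mass M g/mol is M mg/L).
#'
#' @param conc_mM Numeric vector of concentrations (mM), >= 0.
#' @param compound One of `"tyrosine"`, `"dopa"`, `"dopamine"`.
#' @return Concentrations in mg/L.
#' @examples
#' convert_mM_to_mg_per_L(1, "dopamine")
#' @export
convert_mM_to_mg_per_L <- function(conc_mM, compound) {
  if (!is.numeric(conc_mM) || any(!is.finite(conc_mM)) || any(conc_mM < 0)) {
    abort_validation("`conc_mM` must be finite and >= 0.")
  }
  conc_mM * molar_mass(compound)
}

#' Biomass-specific product yield
#'
#' @param titre_mg_per_L Product titre (mg/L), >= 0.
#' @param biomass_g_per_L Biomass concentration (g/L), > 0.
#' @return Specific yield in mg product per g biomass.
#' @examples
#' specific_yield(69.03, 2.0102)
#' @export
specific_yield <- function(titre_mg_per_L, biomass_g_per_L) {
  if (!is.numeric(titre_mg_per_L) || any(!is.finite(titre_mg_per_L)) ||
      any(titre_mg_per_L < 0)) {
    abort_validation("`titre_mg_per_L` must be finite and >= 0.")
  }
  if (!is.numeric(biomass_g_per_L) || any(!is.finite(biomass_g_per_L)) ||
      any(biomass_g_per_L <= 0)) {
    abort_validation("`biomass_g_per_L` must be finite and > 0.")
  }
  titre_mg_per_L / biomass_g_per_L
}

validate_strain_results <- function(results) {
  require_columns(
    results,
    c("design_id", "dopamine_mg_per_L", "dopa_mg_per_L",
      "biomass_g_per_L", "gc_hpaBC", "gc_ddc"),
    "strain results"
  )
  if (any(results$dopamine_mg_per_L < 0) || any(results$dopa_mg_per_L < 0)) {
    abort_validation("strain result concentrations must be >= 0.")
  }
  if (any(results$biomass_g_per_L <= 0)) {
    abort_validation("strain result biomass must be > 0.")
  }
  if (any(results$gc_hpaBC < 0 | results$gc_hpaBC > 1) ||
      any(results$gc_ddc < 0 | results$gc_ddc > 1)) {
    abort_validation("GC fractions must lie in [0, 1].")
  }
  tibble::as_tibble(results)
}

#' GC-content stratified trend analysis
#'
#' Holds one RBS's GC content inside a band and asks how the other RBS's GC
#' content relates to the dopamine titre, via Spearman rank correlation
#' (the direction, not a linear effect size, is the claim of interest).
#' With the hpaBC RBS held at high GC (band 0.8-1), a negative direction for
#' the ddc RBS reproduces the "low GC in RBS_ddc amplifies production"
#' observation.
#'
#' @param results Strain-result tibble (see [gen_strain_results()] for the
#'   schema).
#' @param fixed_context `"hpaBC"` or `"ddc"`: which RBS's GC is restricted.
#' @param gc_band Length-2 numeric interval for the fixed context's GC.
#' @return A one-row tibble: `fixed_context`, `free_context`, `direction`
#'   (`"positive"`, `"negative"` or `"none"`), `rho`, `p_value`, `n`.
#' @export
gc_stratified_analysis <- function(results, fixed_context = c("hpaBC", "ddc"),
                                   gc_band = c(0.8, 1)) {
  fixed_context <- match.arg(fixed_context)
  results <- validate_strain_results(results)
  if (!is.numeric(gc_band) || length(gc_band) != 2 || gc_band[1] > gc_band[2]) {
    abort_validation("`gc_band` must be an interval c(lo, hi) with lo <= hi.")
  }
  fixed_col <- if (fixed_context == "hpaBC") "gc_hpaBC" else "gc_ddc"
  free_col <- if (fixed_context == "hpaBC") "gc_ddc" else "gc_hpaBC"
  in_band <- results[[fixed_col]] >= gc_band[1] &
    results[[fixed_col]] <= gc_band[2]
  sub <- results[in_band, ]
  if (nrow(sub) < 3) {
    rlang::abort(
      sprintf("only %d results fall in the GC band [%g, %g]; >= 3 required.",
              nrow(sub), gc_band[1], gc_band[2]),
      class = "dopaflow_insufficient_data_error"
    )
  }
  if (stats::sd(sub$dopamine_mg_per_L) == 0 || stats::sd(sub[[free_col]]) == 0) {
    rho <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(sub[[free_col]], sub$dopamine_mg_per_L,
                      method = "spearman", exact = FALSE)
    )
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  direction <- if (is.na(rho) || rho == 0) {
    "none"
  } else if (rho > 0) "positive" else "negative"
  tibble::tibble(
    fixed_context = fixed_context,
    free_context = if (fixed_context == "hpaBC") "ddc" else "hpaBC",
    direction = direction,
    rho = rho,
    p_value = p,
    n = nrow(sub)
  )
}

#' Flag strains accumulating l-DOPA
#'
#' Marks designs whose l-DOPA to dopamine ratio exceeds a threshold,
#' indicating insufficient Ddc activity. A small epsilon guards the division
#' when dopamine is zero.
#'
#' @param results Strain-result tibble.
#' @param threshold_ratio Flagging threshold on dopa/dopamine (default 1).
#' @param eps Guard added to the denominator (default 1e-9 mg/L).
#' @return Sorted character vector of flagged design ids.
#' @export
dopa_accumulation_flags <- function(results, threshold_ratio = 1,
                                    eps = 1e-9) {
  stop_if_not_scalar_number(threshold_ratio, "threshold_ratio", positive = TRUE)
  results <- validate_strain_results(results)
  per_design <- results |>
    dplyr::group_by(.data$design_id) |>
    dplyr::summarise(
      dopa = mean(.data$dopa_mg_per_L),
      dopamine = mean(.data$dopamine_mg_per_L),
      .groups = "drop"
    )
  flagged <- per_design$design_id[
    per_design$dopa / pmax(per_design$dopamine, eps) > threshold_ratio
  ]
  sort(flagged)
}

#' Summarise a build log as a stage funnel
#'
#' @param build_log Tibble with columns `design_id`, `pcr_ok`,
#'   `assembled_ok`, `sequence_verified` (logical stage ladder: a stage can
#'   only succeed if the previous one did).
#' @return A tibble with one row per stage: count passing and success rate
#'   (percent of designed, one decimal).
#' @examples
#' log <- gen_build_log(sprintf("A.%02d", 1:10), c(1, 1, 0.8), seed = 1)
#' build_funnel(log)
#' @export
build_funnel <- function(build_log) {
  require_columns(build_log,
                  c("design_id", "pcr_ok", "assembled_ok", "sequence_verified"),
                  "build log")
  if (any(build_log$assembled_ok & !build_log$pcr_ok) ||
      any(build_log$sequence_verified & !build_log$assembled_ok)) {
    abort_validation("build log violates the monotone stage ladder.")
  }
  n <- nrow(build_log)
  counts <- c(
    designed = n,
    pcr_ok = sum(build_log$pcr_ok),
    assembled_ok = sum(build_log$assembled_ok),
    sequence_verified = sum(build_log$sequence_verified)
  )
  tibble::tibble(
    stage = names(counts),
    count = as.integer(counts),
    success_rate_percent = vapply(unname(counts), success_rate, numeric(1),
                                  designed_count = n)
  )
}

#' Estimate the optimal expression ratio from a strain cohort
#'
#' Fits a quadratic in log expression ratio to log titre and reports the
#' peak. Because the planted (and the assumed biological) titre surface is
#' log-Gaussian in the HpaBC:Ddc expression ratio, the quadratic is the
#' exactly matching parametric shape; when the fitted curvature is not
#' negative the observed argmax is returned instead. The peak is clamped to
#' the observed ratio range (no extrapolation).
#'
#' @param results Strain-result tibble joined with an `expr_ratio` column
#'   (predicted HpaBC:Ddc expression ratio per strain, > 0).
#' @return One-row tibble: `optimal_ratio`, `curvature` (on log-log scale),
#'   `n`, and `method` (`"quadratic"` or `"argmax"`).
#' @export
estimate_optimal_ratio <- function(results) {
  require_columns(results, c("expr_ratio", "dopamine_mg_per_L"),
                  "results with expression ratios")
  if (any(results$expr_ratio <= 0)) {
    abort_validation("`expr_ratio` must be > 0.")
  }
  ok <- results$dopamine_mg_per_L > 0
  dat <- results[ok, ]
  if (nrow(dat) < 3) {
    rlang::abort("need >= 3 strains with positive titre to locate a peak.",
                 class = "dopaflow_insufficient_data_error")
  }
  x <- log(dat$expr_ratio)
  y <- log(dat$dopamine_mg_per_L)
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  curv <- unname(cf[3])
  if (is.finite(curv) && curv < 0) {
    peak <- -unname(cf[2]) / (2 * curv)
    peak <- min(max(peak, min(x)), max(x))
    method <- "quadratic"
  } else {
    peak <- x[which.max(y)]
    method <- "argmax"
  }
  tibble::tibble(
    optimal_ratio = exp(peak),
    curvature = curv,
    n = nrow(dat),
    method = method
  )
}

#' Recover the optimal expression ratio from designs plus measurements
#'
#' The "learn" step of the DBTL loop: fits per-context RBS strength models
#' from the characterized library, predicts each design's noise-free
#' HpaBC:Ddc expression ratio from its two SD sequences, joins the predicted
#' ratios onto the measured cohort, and locates the titre peak with
#' [estimate_optimal_ratio()].
#'
#' @param design_sheet Design sheet from [assemble_design_sheet()].
#' @param results Strain-result tibble for (a subset of) those designs.
#' @param library The characterized RBS library the designs were drawn from.
#' @return One-row tibble as from [estimate_optimal_ratio()].
#' @export
recover_optimal_ratio <- function(design_sheet, results, library) {
  require_columns(design_sheet,
                  c("design_id", "rbs_hpaBC_seq", "rbs_ddc_seq"),
                  "design sheet")
  results <- validate_strain_results(results)
  fit <- fit_strength_model(library)
  predicted <- design_sheet |>
    dplyr::mutate(
      expr_ratio = predict(fit, .data$rbs_hpaBC_seq, "hpaBC") /
        predict(fit, .data$rbs_ddc_seq, "ddc")
    ) |>
    dplyr::select("design_id", "expr_ratio")
  joined <- dplyr::inner_join(results, predicted, by = "design_id")
  if (nrow(joined) == 0) {
    abort_validation("no overlap between results and design sheet ids.")
  }
  estimate_optimal_ratio(joined)
}
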