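#' Default context-dependent strength models
#'
#' The hpaBC model has a positive GC slope (higher GC, stronger RBS), the
#' ddc model a negative slope of equal magnitude (the opposite direction),
#' both with lognormal characterization noise of 0.2 on the log scale. The
#' ddc intercept of 0.845 places the noise-free HpaBC:Ddc expression ratio
#' at exp(-0.845 + 2 gc_hpaBC + 2 gc_ddc), so the planted optimum of 2.6:1
#' is reached along the line gc_hpaBC + gc_ddc = 0.9 - interior to the GC
#' plane and, at high hpaBC GC, requiring low ddc GC, mirroring the
#' high-GC-hpaBC / low-GC-ddc optimum observed in vivo.
#'
#' @return Named list of two [strength_model()] objects (`hpaBC`, `ddc`).
#' @export
default_strength_models <- function() {
  list(
    hpaBC = strength_model(intercept = 0, gc_slope = 2, noise_sd = 0.2),
    ddc = strength_model(intercept = 0.845, gc_slope = -2, noise_sd = 0.2)
  )
}

#' Planted ground truth for synthetic strain cohorts
#'
#' Describes the response surface the generator plants: exponential-in-GC
#' expression maps (increasing for hpaBC, decreasing for ddc), a titre
#' surface that is log-Gaussian (hence unimodal) in the HpaBC:Ddc expression
#' ratio with its peak at `optimal_expr_ratio`, an l-DOPA leak rising once
#' the ratio exceeds the optimum (insufficient Ddc), and multiplicative
#' lognormal measurement noise.
#'
#' @param optimal_expr_ratio Expression ratio at the titre peak (default
#'   2.6, the ideal HpaBC:Ddc ratio determined in vivo).
#' @param sigma_log Width of the log-Gaussian titre surface (default 0.8).
#' @param max_titre_mg_per_L Peak dopamine titre (default 69.03 mg/L, the
#'   headline titre, used as a scenario parameter).
#' @param measurement_cv Coefficient of variation of titre/l-DOPA
#'   measurements (default 0.017, from the printed 1.2/69.03).
#' @param dopa_leak_scale mg/L of l-DOPA per unit log-ratio excess above the
#'   optimum (default 25).
#' @param expr_model_hpaBC,expr_model_ddc Noise-free [strength_model()]s
#'   defining the expression maps; defaults are the noise-free versions of
#'   [default_strength_models()].
#' @return An object of class `response_surface_truth`.
#' @export
response_surface_truth <- function(optimal_expr_ratio = 2.6,
                                   sigma_log = 0.8,
                                   max_titre_mg_per_L = 69.03,
                                   measurement_cv = 0.017,
                                   dopa_leak_scale = 25,
                                   expr_model_hpaBC = NULL,
                                   expr_model_ddc = NULL) {
  stop_if_not_scalar_number(optimal_expr_ratio, "optimal_expr_ratio",
                            positive = TRUE)
  stop_if_not_scalar_number(sigma_log, "sigma_log", positive = TRUE)
  stop_if_not_scalar_number(max_titre_mg_per_L, "max_titre_mg_per_L",
                            positive = TRUE)
  stop_if_not_scalar_number(measurement_cv, "measurement_cv", nonneg = TRUE)
  stop_if_not_scalar_number(dopa_leak_scale, "dopa_leak_scale", nonneg = TRUE)
  defaults <- default_strength_models()
  if (is.null(expr_model_hpaBC)) {
    expr_model_hpaBC <- strength_model(defaults$hpaBC$intercept,
                                       defaults$hpaBC$gc_slope, 0)
  }
  if (is.null(expr_model_ddc)) {
    expr_model_ddc <- strength_model(defaults$ddc$intercept,
                                     defaults$ddc$gc_slope, 0)
  }
  if (expr_model_hpaBC$gc_slope <= 0) {
    abort_validation("hpaBC expression map must be increasing in GC.")
  }
  if (expr_model_ddc$gc_slope >= 0) {
    abort_validation("ddc expression map must be decreasing in GC.")
  }
  structure(
    list(
      optimal_expr_ratio = optimal_expr_ratio,
      sigma_log = sigma_log,
      max_titre_mg_per_L = max_titre_mg_per_L,
      measurement_cv = measurement_cv,
      dopa_leak_scale = dopa_leak_scale,
      expr_model_hpaBC = expr_model_hpaBC,
      expr_model_ddc = expr_model_ddc
    ),
    class = "response_surface_truth"
  )
}

#' @describeIn response_surface_truth Noise-free HpaBC:Ddc expression ratio
#'   implied by the truth's expression maps at the given GC fractions.
#' @param truth A `response_surface_truth`.
#' @param gc_hpaBC,gc_ddc GC fractions in `[0, 1]`.
#' @export
truth_expr_ratio <- function(truth, gc_hpaBC, gc_ddc) {
  stopifnot(inherits(truth, "response_surface_truth"))
  eh <- exp(truth$expr_model_hpaBC$intercept +
              truth$expr_model_hpaBC$gc_slope * gc_hpaBC)
  ed <- exp(truth$expr_model_ddc$intercept +
              truth$expr_model_ddc$gc_slope * gc_ddc)
  eh / ed
}

#' @describeIn response_surface_truth Noise-free dopamine titre (mg/L) at an
#'   expression ratio: log-Gaussian, peaked at `optimal_expr_ratio`.
#' @param expr_ratio HpaBC:Ddc expression ratio, > 0.
#' @export
truth_titre <- function(truth, expr_ratio) {
  stopifnot(inherits(truth, "response_surface_truth"))
  truth$max_titre_mg_per_L *
    exp(-(log(expr_ratio / truth$optimal_expr_ratio))^2 /
          (2 * truth$sigma_log^2))
}

#' @describeIn response_surface_truth Noise-free l-DOPA leak (mg/L): zero at
#'   or below the optimal ratio, rising linearly in log-ratio excess above it
#'   (HpaBC outpacing Ddc).
#' @export
truth_dopa_leak <- function(truth, expr_ratio) {
  stopifnot(inherits(truth, "response_surface_truth"))
  truth$dopa_leak_scale * pmax(log(expr_ratio / truth$optimal_expr_ratio), 0)
}

# allocate n draws across the seven GC levels of the SD hexamer as evenly
# as the per-level space sizes allow
allocate_gc_levels <- function(n) {
  capacity <- choose(6, 0:6) * 2^6  # sequences per GC count
  alloc <- integer(7)
  while (sum(alloc) < n) {
    open <- which(alloc < capacity)
    # round-robin over open levels, lowest current allocation first
    lvl <- open[order(alloc[open], open)][1]
    alloc[lvl] <- alloc[lvl] + 1L
  }
  alloc
}

#' Generate a synthetic RBS characterization library
#'
#' Emulates a characterized Shine-Dalgarno library: for each of the two
#' operon contexts it draws distinct SD hexamers spanning all seven GC
#' levels (0/6 to 6/6) as evenly as possible, and assigns TIRs from the
#' context's strength model with seeded multiplicative lognormal noise.
#' The reference sequence AGGAGA is included in both contexts by default.
#' Deterministic given the seed.
#'
#' @param n_per_context Entries per context, at most 4096.
#' @param model_hpaBC,model_ddc [strength_model()]s used to assign TIRs;
#'   defaults from [default_strength_models()].
#' @param seed Integer seed (mandatory).
#' @param include_reference Force AGGAGA into both contexts (default TRUE).
#' @return A validated RBS library tibble (columns `id`, `sd_sequence`,
#'   `context`, `gc_fraction`, `tir`).
#' @examples
#' gen_rbs_library(n_per_context = 10, seed = 42)
#' @export
gen_rbs_library <- function(n_per_context = 60,
                            model_hpaBC = default_strength_models()$hpaBC,
                            model_ddc = default_strength_models()$ddc,
                            seed,
                            include_reference = TRUE) {
  stop_if_not_scalar_number(n_per_context, "n_per_context", positive = TRUE)
  if (n_per_context > 4096) {
    abort_validation("`n_per_context` cannot exceed the SD space size 4096.")
  }
  stop_if_not_scalar_number(seed, "seed")
  space <- enumerate_sd_space(6)
  gc_counts <- round(gc_content(space) * 6)
  models <- list(hpaBC = model_hpaBC, ddc = model_ddc)
  prefixes <- c(hpaBC = "H", ddc = "D")
  withr::with_seed(seed, {
    libs <- purrr::imap(models, function(model, ctx) {
      alloc <- allocate_gc_levels(n_per_context)
      seqs <- unlist(lapply(0:6, function(g) {
        pool <- space[gc_counts == g]
        k <- alloc[g + 1]
        if (k == 0) character(0) else pool[sample.int(length(pool), k)]
      }))
      if (include_reference && !"AGGAGA" %in% seqs) {
        # swap the reference in for a drawn sequence of the same GC level
        swap <- which(round(gc_content(seqs) * 6) == 3)[1]
        if (is.na(swap)) swap <- 1L
        seqs[swap] <- "AGGAGA"
      }
      noise <- stats::rnorm(length(seqs), 0, model$noise_sd)
      tir <- exp(model$intercept + model$gc_slope * gc_content(seqs) + noise)
      tibble::tibble(
        id = sprintf("%s%03d", prefixes[[ctx]], seq_along(seqs)),
        sd_sequence = seqs,
        context = ctx,
        gc_fraction = gc_content(seqs),
        tir = tir
      )
    })
    validate_rbs_library(dplyr::bind_rows(libs))
  })
}

#' Generate synthetic strain results from a planted response surface
#'
#' For each design and replicate, evaluates the truth's expression maps at
#' the design's two GC fractions, reads titre and l-DOPA off the planted
#' surfaces, applies multiplicative lognormal measurement noise with
#' coefficient of variation `measurement_cv`, and draws biomass around a
#' configurable mean. Deterministic given the seed.
#'
#' @param designs Design sheet (needs `design_id`, `gc_hpaBC`, `gc_ddc`).
#' @param truth A [response_surface_truth()].
#' @param seed Integer seed (mandatory).
#' @param replicates Replicate measurements per design (default 3,
#'   mirroring triplicate cultivations).
#' @param biomass_mean_g_per_L Mean biomass (default 2.0102 g/L, the value
#'   implied by the 69.03 mg/L and 34.34 mg/g headline pair).
#' @param biomass_cv Coefficient of variation of biomass (default 0.02).
#' @return Strain-result tibble: `design_id`, `replicate`,
#'   `dopamine_mg_per_L`, `dopa_mg_per_L`, `biomass_g_per_L`, `gc_hpaBC`,
#'   `gc_ddc`.
#' @export
gen_strain_results <- function(designs, truth = response_surface_truth(),
                               seed, replicates = 3,
                               biomass_mean_g_per_L = 2.0102,
                               biomass_cv = 0.02) {
  require_columns(designs, c("design_id", "gc_hpaBC", "gc_ddc"),
                  "design sheet")
  if (nrow(designs) == 0) abort_validation("design sheet is empty.")
  stopifnot(inherits(truth, "response_surface_truth"))
  stop_if_not_scalar_number(seed, "seed")
  stop_if_not_scalar_number(replicates, "replicates", positive = TRUE)
  stop_if_not_scalar_number(biomass_mean_g_per_L, "biomass_mean_g_per_L",
                            positive = TRUE)
  stop_if_not_scalar_number(biomass_cv, "biomass_cv", nonneg = TRUE)

  grid <- tidyr::expand_grid(
    i = seq_len(nrow(designs)),
    replicate = seq_len(replicates)
  )
  ratio <- truth_expr_ratio(truth, designs$gc_hpaBC[grid$i],
                            designs$gc_ddc[grid$i])
  titre0 <- truth_titre(truth, ratio)
  dopa0 <- truth_dopa_leak(truth, ratio)
  # lognormal with median at the surface value and the requested CV
  sdlog_meas <- sqrt(log(1 + truth$measurement_cv^2))
  sdlog_bio <- sqrt(log(1 + biomass_cv^2))
  n <- nrow(grid)
  withr::with_seed(seed, {
    noise_titre <- exp(stats::rnorm(n, 0, sdlog_meas))
    noise_dopa <- exp(stats::rnorm(n, 0, sdlog_meas))
    biomass <- biomass_mean_g_per_L * exp(stats::rnorm(n, 0, sdlog_bio))
  })
  tibble::tibble(
    design_id = designs$design_id[grid$i],
    replicate = grid$replicate,
    dopamine_mg_per_L = titre0 * noise_titre,
    dopa_mg_per_L = dopa0 * noise_dopa,
    biomass_g_per_L = biomass,
    gc_hpaBC = designs$gc_hpaBC[grid$i],
    gc_ddc = designs$gc_ddc[grid$i]
  )
}

#' Generate a synthetic build log
#'
#' Seeded Bernoulli draw per stage (PCR, assembly/transformation, sequence
#' verification) with the monotone stage ladder enforced: a stage can only
#' succeed if the previous one did. Emulates the construction-failure
#' taxonomy of a high-throughput strain-building workflow.
#'
#' @param design_ids Character vector of design ids.
#' @param stage_success_probs Numeric vector of three conditional success
#'   probabilities in `[0, 1]` (PCR; assembly given PCR; verification given
#'   assembly).
#' @param seed Integer seed (mandatory).
#' @return Tibble with columns `design_id`, `pcr_ok`, `assembled_ok`,
#'   `sequence_verified`.
#' @examples
#' gen_build_log(c("A.01", "A.02"), c(1, 1, 1), seed = 1)
#' @export
gen_build_log <- function(design_ids,
                          stage_success_probs = c(55 / 56, 51 / 55, 48 / 51),
                          seed) {
  if (!is.character(design_ids) || length(design_ids) == 0) {
    abort_validation("`design_ids` must be a non-empty character vector.")
  }
  if (!is.numeric(stage_success_probs) || length(stage_success_probs) != 3 ||
      any(!is.finite(stage_success_probs)) ||
      any(stage_success_probs < 0) || any(stage_success_probs > 1)) {
    abort_validation("`stage_success_probs` must be three probabilities in [0, 1].")
  }
  stop_if_not_scalar_number(seed, "seed")
  n <- length(design_ids)
  withr::with_seed(seed, {
    pcr <- stats::runif(n) < stage_success_probs[1]
    asm <- pcr & (stats::runif(n) < stage_success_probs[2])
    ver <- asm & (stats::runif(n) < stage_success_probs[3])
  })
  tibble::tibble(
    design_id = design_ids,
    pcr_ok = pcr,
    assembled_ok = asm,
    sequence_verified = ver
  )
}
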