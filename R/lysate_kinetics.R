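#' Kinetic parameters of the HpaBC -> Ddc cascade
#'
#' Rate constants for the two-step Michaelis-Menten cascade
#' l-tyrosine -> l-DOPA -> dopamine in the mixed crude-lysate system, plus an
#' optional first-order l-DOPA oxidation sink (spontaneous loss to melanin).
#' `vmax_*_total` is the maximal rate contributed by a lysate at mixing
#' fraction 1; mixing dilutes each enzyme by its volume fraction.
#'
#' Defaults: the Ddc Michaelis constant for l-DOPA is 0.092 mM (literature
#' value). HpaBC is not characterised on l-tyrosine; the default K_M of
#' 0.1 mM sits inside the 0.0094-0.514 mM range reported for its other
#' substrates. The vmax pair (0.02 and 50 mM/h) is a trend preset: it is
#' calibrated so that the 1:1 to 100:1 lysate titration reproduces the
#' observed converging increase in dopamine (Ddc catalytically far more
#' efficient than HpaBC, so high HpaBC fractions pay off), not to absolute
#' measured values, which are not available. Oxidation defaults to off.
#'
#' @param vmax_hpaBC_total HpaBC maximal rate at lysate fraction 1 (mM/h).
#' @param km_hpaBC_tyr HpaBC Michaelis constant for l-tyrosine (mM), > 0.
#' @param vmax_ddc_total Ddc maximal rate at lysate fraction 1 (mM/h).
#' @param km_ddc_dopa Ddc Michaelis constant for l-DOPA (mM), > 0.
#' @param k_oxidation First-order l-DOPA oxidation rate to melanin (1/h).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(vmax_hpaBC_total = 0.02,
                           km_hpaBC_tyr = 0.1,
                           vmax_ddc_total = 50,
                           km_ddc_dopa = 0.092,
                           k_oxidation = 0) {
  stop_if_not_scalar_number(vmax_hpaBC_total, "vmax_hpaBC_total", nonneg = TRUE)
  stop_if_not_scalar_number(km_hpaBC_tyr, "km_hpaBC_tyr", positive = TRUE)
  stop_if_not_scalar_number(vmax_ddc_total, "vmax_ddc_total", nonneg = TRUE)
  stop_if_not_scalar_number(km_ddc_dopa, "km_ddc_dopa", positive = TRUE)
  stop_if_not_scalar_number(k_oxidation, "k_oxidation", nonneg = TRUE)
  structure(
    list(
      vmax_hpaBC_total = vmax_hpaBC_total, km_hpaBC_tyr = km_hpaBC_tyr,
      vmax_ddc_total = vmax_ddc_total, km_ddc_dopa = km_ddc_dopa,
      k_oxidation = k_oxidation
    ),
    class = "kinetic_params"
  )
}

#' Specification of one lysate mixing experiment
#'
#' Two lysates (HpaBC-expressing and Ddc-expressing) are combined at volume
#' ratio `r` into a fixed total volume, so the HpaBC lysate occupies fraction
#' `r/(r+1)` and the Ddc lysate `1/(r+1)`: raising one enzyme necessarily
#' dilutes the other. Defaults follow the crude-lysate protocol: 1 mM
#' l-tyrosine substrate, 20 h reaction.
#'
#' @param ratio HpaBC:Ddc lysate volume ratio (e.g. 100 means 100:1), > 0.
#' @param substrate_tyr0 Initial l-tyrosine (mM), >= 0.
#' @param t_end Reaction duration (h), > 0.
#' @param reporting_step Output time step (h), > 0.
#' @return An object of class `mix_spec`.
#' @export
mix_spec <- function(ratio = 1, substrate_tyr0 = 1, t_end = 20,
                     reporting_step = 0.1) {
  stop_if_not_scalar_number(ratio, "ratio", positive = TRUE)
  stop_if_not_scalar_number(substrate_tyr0, "substrate_tyr0", nonneg = TRUE)
  stop_if_not_scalar_number(t_end, "t_end", positive = TRUE)
  stop_if_not_scalar_number(reporting_step, "reporting_step", positive = TRUE)
  structure(
    list(
      ratio = ratio, substrate_tyr0 = substrate_tyr0,
      t_end = t_end, reporting_step = reporting_step
    ),
    class = "mix_spec"
  )
}

#' Lysate volume fractions implied by a mixing ratio
#'
#' @param ratio HpaBC:Ddc lysate volume ratio, > 0.
#' @return Named numeric vector `c(hpaBC = r/(r+1), ddc = 1/(r+1))`; the two
#'   fractions always sum to 1.
#' @export
lysate_fractions <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort_validation("`ratio` must be finite and > 0.")
  }
  c(hpaBC = ratio / (ratio + 1), ddc = 1 / (ratio + 1))
}

#' Simulate one crude-lysate mixing experiment
#'
#' Integrates the cascade
#' \deqn{d[TYR]/dt = -v_1, \quad d[DOPA]/dt = v_1 - v_2 - k_{ox}[DOPA],}
#' \deqn{d[DA]/dt = v_2, \quad d[MEL]/dt = k_{ox}[DOPA],}
#' with \eqn{v_1 = \frac{r}{r+1} V_{max,HpaBC} \frac{[TYR]}{K_M + [TYR]}} and
#' \eqn{v_2 = \frac{1}{r+1} V_{max,Ddc} \frac{[DOPA]}{K_M + [DOPA]}},
#' using an adaptive stiff/non-stiff solver (deSolve lsoda). Mass is
#' conserved by construction; the integration is rejected if the reported
#' trajectory violates conservation or non-negativity beyond solver
#' tolerance.
#'
#' @param params A [kinetic_params()] object.
#' @param mix A [mix_spec()] object.
#' @param rtol Relative solver tolerance (default 1e-8).
#' @param atol Absolute solver tolerance (default 1e-12 mM).
#' @return A tibble of class `lysate_timecourse` with columns `time` (h) and
#'   `tyr`, `dopa`, `dopamine`, `melanin` (mM); attributes carry the inputs.
#' @examples
#' tc <- simulate_mix(kinetic_params(), mix_spec(ratio = 10))
#' tail(tc, 1)
#' @export
simulate_mix <- function(params, mix, rtol = 1e-8, atol = 1e-12) {
  if (!inherits(params, "kinetic_params")) {
    abort_validation("`params` must be a kinetic_params object.")
  }
  if (!inherits(mix, "mix_spec")) {
    abort_validation("`mix` must be a mix_spec object.")
  }
  frac <- lysate_fractions(mix$ratio)
  v1max <- frac[["hpaBC"]] * params$vmax_hpaBC_total
  v2max <- frac[["ddc"]] * params$vmax_ddc_total
  rhs <- function(t, y, p) {
    v1 <- v1max * y[1] / (params$km_hpaBC_tyr + y[1])
    v2 <- v2max * y[2] / (params$km_ddc_dopa + y[2])
    ox <- params$k_oxidation * y[2]
    list(c(-v1, v1 - v2 - ox, v2, ox))
  }
  times <- unique(c(seq(0, mix$t_end, by = mix$reporting_step), mix$t_end))
  y0 <- c(tyr = mix$substrate_tyr0, dopa = 0, dopamine = 0, melanin = 0)
  sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort(
      "ODE solver failed to meet tolerance; last accepted state attached.",
      class = "dopaflow_integration_error",
      last_state = sol[nrow(sol), ]
    )
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  # clip states that are negative only within absolute tolerance of zero
  neg_tol <- max(100 * atol, 1e-10)
  for (col in c("tyr", "dopa", "dopamine", "melanin")) {
    v <- out[[col]]
    if (any(v < -neg_tol)) {
      rlang::abort(
        sprintf("state '%s' went negative beyond tolerance (min %g).",
                col, min(v)),
        class = "dopaflow_integration_error"
      )
    }
    out[[col]] <- pmax(v, 0)
  }
  total <- out$tyr + out$dopa + out$dopamine + out$melanin
  mass_tol <- 10 * rtol * max(mix$substrate_tyr0, 1) + 100 * atol
  if (any(abs(total - mix$substrate_tyr0) > mass_tol)) {
    rlang::abort("mass conservation violated beyond solver tolerance.",
                 class = "dopaflow_integration_error")
  }
  structure(out,
    class = c("lysate_timecourse", class(out)),
    params = params, mix = mix
  )
}

#' Titrate the HpaBC:Ddc lysate ratio
#'
#' Runs [simulate_mix()] once per ratio with shared substrate and duration,
#' reporting the endpoint dopamine and residual l-DOPA. This is the in vitro
#' ratio scan that identifies how much HpaBC excess the cascade rewards.
#'
#' @param params A [kinetic_params()] object.
#' @param ratios Numeric vector of HpaBC:Ddc ratios, each > 0; default is
#'   the experimental grid 1, 2, 5, 10, 20, 50, 100.
#' @param base_mix A [mix_spec()] giving the shared substrate, duration and
#'   reporting step (its `ratio` is ignored).
#' @param ... Passed on to [simulate_mix()].
#' @return A tibble with one row per input ratio (input order preserved):
#'   `ratio`, `dopamine_mM`, `dopa_mM`, `dopamine_mg_per_L`.
#' @examples
#' titrate(kinetic_params(), ratios = c(1, 10, 100))
#' @export
titrate <- function(params, ratios = c(1, 2, 5, 10, 20, 50, 100),
                    base_mix = mix_spec(), ...) {
  if (!is.numeric(ratios) || length(ratios) == 0 ||
      any(!is.finite(ratios)) || any(ratios <= 0)) {
    abort_validation("`ratios` must be a non-empty vector of positive numbers.")
  }
  rows <- purrr::map(ratios, function(r) {
    m <- mix_spec(ratio = r, substrate_tyr0 = base_mix$substrate_tyr0,
                  t_end = base_mix$t_end,
                  reporting_step = base_mix$reporting_step)
    tc <- simulate_mix(params, m, ...)
    fin <- tc[nrow(tc), ]
    tibble::tibble(
      ratio = r,
      dopamine_mM = fin$dopamine,
      dopa_mM = fin$dopa,
      dopamine_mg_per_L = convert_mM_to_mg_per_L(fin$dopamine, "dopamine")
    )
  })
  dplyr::bind_rows(rows)
}

#' Optimal lysate ratio from a titration table
#'
#' @param titration A titration tibble from [titrate()] (>= 2 rows).
#' @param criterion `"max_dopamine"` (default) or `"min_dopa_residual"`.
#' @return The single best ratio; ties are broken toward the smaller ratio.
#' @export
optimal_ratio <- function(titration,
                          criterion = c("max_dopamine", "min_dopa_residual")) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(titration) || nrow(titration) == 0) {
    abort_validation("`titration` must be a non-empty titration table.")
  }
  if (nrow(titration) < 2) {
    abort_validation("`titration` needs >= 2 rows to pick an optimum.")
  }
  require_columns(titration, c("ratio", "dopamine_mM", "dopa_mM"),
                  "titration table")
  score <- switch(criterion,
    max_dopamine = titration$dopamine_mM,
    min_dopa_residual = -titration$dopa_mM
  )
  best <- max(score)
  candidates <- titration$ratio[score == best]
  min(candidates)
}
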