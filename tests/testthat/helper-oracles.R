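# Independent oracles used across the kinetics tests.

# Fixed-step explicit-Euler integration of the cascade. Deliberately naive:
# serves as a solver-independent reference for the adaptive integration.
euler_mix <- function(params, mix, dt = 1e-4) {
  fr <- lysate_fractions(mix$ratio)
  v1max <- fr[["hpaBC"]] * params$vmax_hpaBC_total
  v2max <- fr[["ddc"]] * params$vmax_ddc_total
  n <- ceiling(mix$t_end / dt)
  y <- c(tyr = mix$substrate_tyr0, dopa = 0, dopamine = 0, melanin = 0)
  for (i in seq_len(n)) {
    h <- min(dt, mix$t_end - (i - 1) * dt)
    v1 <- v1max * y[1] / (params$km_hpaBC_tyr + y[1])
    v2 <- v2max * y[2] / (params$km_ddc_dopa + y[2])
    ox <- params$k_oxidation * y[2]
    y <- y + h * c(-v1, v1 - v2 - ox, v2, ox)
    y <- pmax(y, 0)
  }
  y
}

# Closed-form single-substrate Michaelis-Menten depletion: with the second
# step and oxidation off, TYR(t) satisfies
#   Km * ln(TYR0 / TYR) + (TYR0 - TYR) = a * t,  a = (r/(r+1)) * vmax.
# Solve for TYR by root finding on the implicit equation.
closed_form_tyr <- function(t, tyr0, km, a) {
  f <- function(s) km * log(tyr0 / s) + (tyr0 - s) - a * t
  stats::uniroot(f, c(tyr0 * 1e-12, tyr0), tol = 1e-14)$root
}

# Deterministic randomized kinetic instances for property tests.
random_kinetics_case <- function(i) {
  withr::with_seed(1000 + i, {
    list(
      params = kinetic_params(
        vmax_hpaBC_total = stats::runif(1, 0.01, 2),
        km_hpaBC_tyr = stats::runif(1, 0.02, 1),
        vmax_ddc_total = stats::runif(1, 0.01, 20),
        km_ddc_dopa = stats::runif(1, 0.02, 1),
        k_oxidation = stats::runif(1, 0, 0.2)
      ),
      mix = mix_spec(
        ratio = stats::runif(1, 1, 100),
        substrate_tyr0 = stats::runif(1, 0.2, 5),
        t_end = 20,
        reporting_step = 0.5
      )
    )
  })
}
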