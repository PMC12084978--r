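#' Context-dependent RBS strength model
#'
#' A minimal log-linear model of translation initiation rate (TIR) as a
#' function of Shine-Dalgarno GC content:
#' `TIR = exp(intercept + gc_slope * gc + eps)`, `eps ~ N(0, noise_sd)`.
#' The sign of `gc_slope` may differ by gene context: in the dopamine
#' operon, higher GC strengthens the hpaBC RBS while the ddc RBS shows the
#' opposite direction. The functional form is a configurable stand-in; only
#' the monotone direction per context is treated as established.
#'
#' @param intercept Intercept on the log-TIR scale.
#' @param gc_slope Slope per unit GC fraction (log-TIR scale); sign sets the
#'   monotone direction.
#' @param noise_sd Standard deviation of multiplicative lognormal noise on
#'   the log scale; must be >= 0.
#' @return An object of class `strength_model`.
#' @examples
#' m <- strength_model(intercept = 0, gc_slope = 2, noise_sd = 0)
#' predict_tir(m, c("AAAAAA", "GGGGGG"))
#' @export
strength_model <- function(intercept = 0, gc_slope = 0, noise_sd = 0) {
  stop_if_not_scalar_number(intercept, "intercept")
  stop_if_not_scalar_number(gc_slope, "gc_slope")
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(
    list(intercept = intercept, gc_slope = gc_slope, noise_sd = noise_sd),
    class = "strength_model"
  )
}

#' @export
print.strength_model <- function(x, ...) {
  cat(sprintf(
    "<strength_model> log(TIR) = %.4g %+.4g * GC  (noise_sd = %.4g)\n",
    x$intercept, x$gc_slope, x$noise_sd
  ))
  invisible(x)
}

#' Predict TIR for Shine-Dalgarno sequences
#'
#' Evaluates a [strength_model()]: deterministic (noise-free) when `seed` is
#' `NULL`, and reproducibly noisy when a seed is supplied. Always strictly
#' positive.
#'
#' @param model A `strength_model`.
#' @param seq Character vector of SD sequences.
#' @param seed Optional integer seed; when given, one lognormal noise draw
#'   per sequence is applied (same seed, same result).
#' @return Numeric vector of TIRs (arbitrary relative units).
#' @export
predict_tir <- function(model, seq, seed = NULL) {
  if (!inherits(model, "strength_model")) {
    abort_validation("`model` must be a strength_model.")
  }
  gc <- gc_content(seq)
  log_tir <- model$intercept + model$gc_slope * gc
  if (!is.null(seed) && model$noise_sd > 0) {
    eps <- withr::with_seed(seed, stats::rnorm(length(gc), 0, model$noise_sd))
    log_tir <- log_tir + eps
  }
  exp(log_tir)
}

#' Fit per-context RBS strength models from a characterized library
#'
#' Ordinary least squares of `log(tir)` on GC fraction, one fit per gene
#' context present in the library. This is the "learn" half of the design
#' loop: the fitted noise-free strength models are used to translate RBS
#' sequences into predicted expression ratios.
#'
#' @param library An RBS library (see [validate_rbs_library()]).
#' @return An object of class `rbs_strength_fit`: a named list of `lm` fits
#'   plus the library used. Supports [generics::tidy()], [generics::glance()]
#'   and `predict(fit, seq, context)`.
#' @examples
#' lib <- gen_rbs_library(n_per_context = 20, seed = 1)
#' fit <- fit_strength_model(lib)
#' generics::tidy(fit)
#' @export
fit_strength_model <- function(library) {
  library <- validate_rbs_library(library)
  contexts <- unique(library$context)
  fits <- lapply(contexts, function(ctx) {
    dat <- dplyr::filter(library, .data$context == ctx)
    if (nrow(dat) < 3 || dplyr::n_distinct(dat$gc_fraction) < 2) {
      abort_validation(sprintf(
        "context '%s' needs >= 3 entries at >= 2 GC levels to fit.", ctx
      ))
    }
    stats::lm(log(tir) ~ gc_fraction, data = dat)
  })
  names(fits) <- contexts
  structure(list(fits = fits, library = library), class = "rbs_strength_fit")
}

#' @export
print.rbs_strength_fit <- function(x, ...) {
  cat("<rbs_strength_fit> contexts:", paste(names(x$fits), collapse = ", "), "\n")
  for (ctx in names(x$fits)) {
    cf <- stats::coef(x$fits[[ctx]])
    cat(sprintf("  %-8s log(TIR) = %.3f %+.3f * GC\n", ctx, cf[1], cf[2]))
  }
  invisible(x)
}

#' Extract a fitted context as a noise-free strength model
#'
#' @param fit An `rbs_strength_fit`.
#' @param context Gene context to extract.
#' @return A [strength_model()] with the fitted intercept and slope and
#'   `noise_sd` set to the residual standard error.
#' @export
as_strength_model <- function(fit, context) {
  if (!inherits(fit, "rbs_strength_fit")) {
    abort_validation("`fit` must be an rbs_strength_fit.")
  }
  if (!context %in% names(fit$fits)) {
    abort_validation(sprintf("context '%s' was not fitted.", context))
  }
  lmfit <- fit$fits[[context]]
  cf <- stats::coef(lmfit)
  strength_model(
    intercept = unname(cf[1]),
    gc_slope = unname(cf[2]),
    noise_sd = stats::sigma(lmfit)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-context RBS strength fit
#'
#' @param x An `rbs_strength_fit`.
#' @param ... Unused.
#' @return A tibble with one row per context and term: estimate, standard
#'   error, t statistic and p value.
#' @export
tidy.rbs_strength_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(ctx) {
    sm <- summary(x$fits[[ctx]])$coefficients
    tibble::tibble(
      context = ctx,
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std.error = unname(sm[, "Std. Error"]),
      statistic = unname(sm[, "t value"]),
      p.value = unname(sm[, "Pr(>|t|)"])
    )
  })
}

#' Glance at a per-context RBS strength fit
#'
#' @param x An `rbs_strength_fit`.
#' @param ... Unused.
#' @return A tibble with one row per context: r.squared, residual sigma
#'   (the lognormal noise scale), and number of library entries.
#' @export
glance.rbs_strength_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(ctx) {
    s <- summary(x$fits[[ctx]])
    tibble::tibble(
      context = ctx,
      r.squared = s$r.squared,
      sigma = s$sigma,
      nobs = stats::nobs(x$fits[[ctx]])
    )
  })
}

#' Predict baseline TIRs from a fitted strength model
#'
#' @param object An `rbs_strength_fit`.
#' @param seq Character vector of SD sequences.
#' @param context Single gene context (recycled over `seq`).
#' @param ... Unused.
#' @return Numeric vector of noise-free predicted TIRs.
#' @export
predict.rbs_strength_fit <- function(object, seq, context, ...) {
  model <- as_strength_model(object, context)
  predict_tir(strength_model(model$intercept, model$gc_slope, 0), seq)
}
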