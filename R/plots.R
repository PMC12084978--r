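#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a lysate time course
#'
#' @param object A `lysate_timecourse` from [simulate_mix()].
#' @param ... Unused.
#' @return A ggplot of all four species (mM) over time.
#' @export
autoplot.lysate_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("tyr", "dopa", "dopamine", "melanin"),
    names_to = "species", values_to = "conc_mM"
  )
  long$species <- factor(long$species,
                         levels = c("tyr", "dopa", "dopamine", "melanin"),
                         labels = c("l-tyrosine", "l-DOPA", "dopamine",
                                    "melanin"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc_mM,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = "concentration (mM)",
                  colour = NULL,
                  title = sprintf("Lysate mix, HpaBC:Ddc = %g:1",
                                  attr(object, "mix")$ratio)) +
    ggplot2::theme_minimal()
}

#' Plot a ratio titration
#'
#' Endpoint dopamine and residual l-DOPA against the HpaBC:Ddc lysate ratio
#' (log scale), the in vitro analysis figure of the workflow.
#'
#' @param titration A tibble from [titrate()].
#' @return A ggplot.
#' @export
plot_titration <- function(titration) {
  require_columns(titration, c("ratio", "dopamine_mM", "dopa_mM"),
                  "titration table")
  long <- tidyr::pivot_longer(titration, c("dopamine_mM", "dopa_mM"),
                              names_to = "species", values_to = "conc_mM")
  long$species <- factor(long$species, levels = c("dopamine_mM", "dopa_mM"),
                         labels = c("dopamine", "l-DOPA"))
  ggplot2::ggplot(long, ggplot2::aes(.data$ratio, .data$conc_mM,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "HpaBC:Ddc lysate ratio", y = "endpoint conc. (mM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a design sheet in the GC plane
#'
#' Each design is a point at (GC of RBS_hpaBC, GC of RBS_ddc), coloured by
#' strategy and sized by its numeric TIR ratio, showing how the two
#' strategies cover the sequence space.
#'
#' @param sheet A design sheet from [assemble_design_sheet()].
#' @return A ggplot.
#' @export
plot_design_space <- function(sheet) {
  require_columns(sheet, c("gc_hpaBC", "gc_ddc", "strategy",
                           "numeric_tir_ratio"), "design sheet")
  ggplot2::ggplot(sheet, ggplot2::aes(.data$gc_hpaBC, .data$gc_ddc,
                                      colour = .data$strategy,
                                      size = .data$numeric_tir_ratio)) +
    ggplot2::geom_point(alpha = 0.7,
                        position = ggplot2::position_jitter(0.01, 0.01)) +
    ggplot2::scale_size_continuous(trans = "log10") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "GC fraction, RBS hpaBC", y = "GC fraction, RBS ddc",
                  size = "TIR ddc/hpaBC", colour = "strategy") +
    ggplot2::theme_minimal()
}

#' Plot a GC-stratified trend
#'
#' Scatter of the free context's GC fraction against dopamine titre for
#' strains whose fixed context GC lies in the band, with a linear guide.
#'
#' @inheritParams gc_stratified_analysis
#' @return A ggplot.
#' @export
plot_gc_trend <- function(results, fixed_context = c("hpaBC", "ddc"),
                          gc_band = c(0.8, 1)) {
  fixed_context <- match.arg(fixed_context)
  results <- validate_strain_results(results)
  fixed_col <- if (fixed_context == "hpaBC") "gc_hpaBC" else "gc_ddc"
  free_col <- if (fixed_context == "hpaBC") "gc_ddc" else "gc_hpaBC"
  sub <- results[results[[fixed_col]] >= gc_band[1] &
                   results[[fixed_col]] <= gc_band[2], ]
  ggplot2::ggplot(sub, ggplot2::aes(.data[[free_col]],
                                    .data$dopamine_mg_per_L)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("GC fraction, RBS %s",
                  if (fixed_context == "hpaBC") "ddc" else "hpaBC"),
      y = "dopamine (mg/L)",
      title = sprintf("RBS %s GC held in [%g, %g]", fixed_context,
                      gc_band[1], gc_band[2])
    ) +
    ggplot2::theme_minimal()
}
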