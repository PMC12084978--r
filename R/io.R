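#' Read and write RBS libraries, design sheets and cohort tables
#'
#' All tables travel as plain comma-separated files with headers, matching
#' the schemas produced by the generators. Reading validates against the
#' consumer's invariants.
#'
#' @param path File path.
#' @return `read_rbs_library()` returns a validated library tibble.
#' @name dopaflow_io
NULL

#' @rdname dopaflow_io
#' @export
read_rbs_library <- function(path) {
  validate_rbs_library(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname dopaflow_io
#' @param library A validated RBS library tibble.
#' @export
write_rbs_library <- function(library, path) {
  readr::write_csv(validate_rbs_library(library), path)
  invisible(path)
}

#' @rdname dopaflow_io
#' @details `write_rbs_fasta()` exports library sequences as FASTA with the
#'   library id as record id.
#' @export
write_rbs_fasta <- function(library, path) {
  library <- validate_rbs_library(library)
  seqs <- Biostrings::DNAStringSet(library$sd_sequence)
  names(seqs) <- library$id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname dopaflow_io
#' @param sheet A design sheet from [assemble_design_sheet()].
#' @export
write_design_sheet <- function(sheet, path) {
  require_columns(sheet, c("design_id", "strategy", "rbs_hpaBC_seq",
                           "rbs_ddc_seq", "numeric_tir_ratio"),
                  "design sheet")
  readr::write_csv(sheet, path)
  invisible(path)
}

#' @rdname dopaflow_io
#' @export
read_design_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE)
  require_columns(sheet, c("design_id", "strategy", "rbs_hpaBC_seq",
                           "rbs_ddc_seq", "numeric_tir_ratio"),
                  "design sheet")
  sheet$rbs_hpaBC_seq <- as_sd_sequence(sheet$rbs_hpaBC_seq)
  sheet$rbs_ddc_seq <- as_sd_sequence(sheet$rbs_ddc_seq)
  sheet
}

#' @rdname dopaflow_io
#' @export
read_strain_results <- function(path) {
  validate_strain_results(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname dopaflow_io
#' @export
read_build_log <- function(path) {
  log <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           design_id = readr::col_character(),
                           pcr_ok = readr::col_logical(),
                           assembled_ok = readr::col_logical(),
                           sequence_verified = readr::col_logical()
                         ))
  require_columns(log, c("design_id", "pcr_ok", "assembled_ok",
                         "sequence_verified"), "build log")
  log
}

#' @rdname dopaflow_io
#' @param titration A titration tibble from [titrate()].
#' @export
write_titration <- function(titration, path) {
  require_columns(titration, c("ratio", "dopamine_mM", "dopamine_mg_per_L",
                               "dopa_mM"), "titration table")
  readr::write_csv(
    titration[, c("ratio", "dopamine_mM", "dopamine_mg_per_L", "dopa_mM")],
    path
  )
  invisible(path)
}
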