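#' @keywords internal
SD_BASES <- c("A", "C", "G", "T")

#' Canonicalize Shine-Dalgarno sequences
#'
#' Validates a character vector of Shine-Dalgarno (SD) core sequences and
#' returns it in canonical uppercase form. Lowercase input is accepted;
#' IUPAC ambiguity codes, gaps and sequences of the wrong length are
#' rejected with an error naming the first offending position.
#'
#' @param x Character vector of candidate SD sequences.
#' @param width Required sequence length (default 6, the SD hexamer).
#' @return Character vector of validated uppercase sequences.
#' @examples
#' as_sd_sequence(c("aggaga", "ACGTAC"))
#' @export
as_sd_sequence <- function(x, width = 6L) {
  if (!is.character(x) || length(x) == 0) {
    abort_validation("SD sequences must be a non-empty character vector.")
  }
  x <- toupper(x)
  nch <- nchar(x)
  bad_len <- which(nch != width | is.na(x))
  if (length(bad_len) > 0) {
    abort_validation(sprintf(
      "invalid SD sequence at index %d: '%s' has length %d, expected %d",
      bad_len[1], x[bad_len[1]], nch[bad_len[1]], width
    ))
  }
  chars <- strsplit(x, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    ok <- chars[[i]] %in% SD_BASES
    if (!all(ok)) {
      pos <- which(!ok)[1]
      abort_validation(sprintf(
        "invalid SD sequence '%s': character '%s' at position %d is not one of A, C, G, T",
        x[i], chars[[i]][pos], pos
      ))
    }
  }
  x
}

#' GC content of Shine-Dalgarno sequences
#'
#' Fraction of G and C bases, computed as an exact multiple of `1/width`
#' before any rounding. The reference SD hexamer AGGAGA has GC content 0.5.
#'
#' @param seq Character vector of SD sequences (canonicalized via
#'   [as_sd_sequence()]).
#' @param width Required sequence length (default 6).
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @seealso [gc_percent()] for the one-decimal percent rendering.
#' @examples
#' gc_content("AGGAGA")
#' gc_content(c("AAAAAA", "GGCCGC"))
#' @export
gc_content <- function(seq, width = 6L) {
  seq <- as_sd_sequence(seq, width = width)
  n_gc <- vapply(
    strsplit(seq, "", fixed = TRUE),
    function(ch) sum(ch %in% c("G", "C")),
    integer(1)
  )
  n_gc / width
}

#' @describeIn gc_content GC content rendered as a percentage, rounded to one
#'   decimal half away from zero (so AGGAGA renders as 50).
#' @export
gc_percent <- function(seq, width = 6L) {
  round_half_up(100 * gc_content(seq, width = width), 1)
}

#' Enumerate the Shine-Dalgarno design space
#'
#' All k-mers over the alphabet A, C, G, T in lexicographic order
#' (A < C < G < T), fixed so design outputs are byte-for-byte reproducible.
#' The 6-nt SD core offers 4^6 = 4,096 variants.
#'
#' @param k Word length, between 1 and 10 (guard against combinatorial
#'   blow-up).
#' @return Character vector of `4^k` distinct sequences in lexicographic
#'   order.
#' @examples
#' enumerate_sd_space(1)
#' length(enumerate_sd_space(6))
#' @export
enumerate_sd_space <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != as.integer(k)) {
    abort_validation("`k` must be a single integer.")
  }
  k <- as.integer(k)
  if (k < 1L || k > 10L) {
    abort_validation(sprintf("`k` must be between 1 and 10 (got %d).", k))
  }
  grid <- do.call(expand.grid, c(
    rep(list(SD_BASES), k),
    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ))
  # expand.grid varies the first column fastest; reversing the columns makes
  # the LAST sequence position fastest, i.e. lexicographic order
  do.call(paste0, grid[rev(seq_len(k))])
}

#' Size of the bi-cistronic pair space
#'
#' Number of ordered (RBS_hpaBC, RBS_ddc) sequence pairs, `4^k * 4^k`.
#' For the SD hexamer this is 16,777,216 (16.8 million at one decimal).
#'
#' @param k Word length, between 0 and 10; `k = 0` returns 1 (empty product).
#' @return A single number (double: the value exceeds integer range at k = 6).
#' @examples
#' pair_space_size(6)
#' @export
pair_space_size <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k != as.integer(k)) {
    abort_validation("`k` must be a single integer.")
  }
  k <- as.integer(k)
  if (k < 0L || k > 10L) {
    abort_validation(sprintf("`k` must be between 0 and 10 (got %d).", k))
  }
  4^k * 4^k
}

RBS_CONTEXTS <- c("hpaBC", "ddc", "reporter")

#' Validate an RBS characterization library
#'
#' Checks (and completes) a table of characterized RBS variants: columns
#' `id`, `sd_sequence`, `context` (one of hpaBC, ddc, reporter),
#' `gc_fraction`, `tir`. Sequences are canonicalized, TIRs must be strictly
#' positive, and `gc_fraction` must agree with the value recomputed from the
#' sequence (it is filled in when absent).
#'
#' @param library Data frame of RBS entries.
#' @return A validated tibble with the five canonical columns first.
#' @export
validate_rbs_library <- function(library) {
  require_columns(library, c("id", "sd_sequence", "context", "tir"),
                  "RBS library")
  library <- tibble::as_tibble(library)
  if (anyDuplicated(library$id) > 0) {
    abort_validation("RBS library ids must be unique.")
  }
  library$sd_sequence <- as_sd_sequence(library$sd_sequence)
  bad_ctx <- !library$context %in% RBS_CONTEXTS
  if (any(bad_ctx)) {
    abort_validation(sprintf(
      "unknown RBS context '%s' (expected one of %s)",
      library$context[which(bad_ctx)[1]], paste(RBS_CONTEXTS, collapse = ", ")
    ))
  }
  if (!is.numeric(library$tir) || any(!is.finite(library$tir)) ||
      any(library$tir <= 0)) {
    abort_validation("RBS library `tir` values must all be finite and > 0.")
  }
  gc_true <- gc_content(library$sd_sequence)
  if (!"gc_fraction" %in% names(library)) {
    library$gc_fraction <- gc_true
  } else if (any(abs(library$gc_fraction - gc_true) > 1e-9)) {
    i <- which(abs(library$gc_fraction - gc_true) > 1e-9)[1]
    abort_validation(sprintf(
      "gc_fraction of entry '%s' (%g) does not match its sequence %s (%g)",
      library$id[i], library$gc_fraction[i], library$sd_sequence[i], gc_true[i]
    ))
  }
  dplyr::relocate(library, "id", "sd_sequence", "context", "gc_fraction", "tir")
}
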