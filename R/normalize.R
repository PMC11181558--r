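#' Normalize a chemical synonym
#'
#' Canonicalizes depositor-provided chemical names before any matching or
#' voting: ASCII lower-case letters `a-z` are upper-cased, curly brackets
#' `{}` and square brackets `[]` become round brackets `()`, leading/trailing
#' whitespace is stripped and internal whitespace runs collapse to a single
#' space. No other characters are touched; in particular non-ASCII letters
#' (Greek locants, accented element names) pass through unchanged, so the
#' mapping is locale-independent.
#'
#' The function is idempotent: `normalize_name(normalize_name(x))` equals
#' `normalize_name(x)`.
#'
#' @param raw character vector of raw names.
#' @return character vector of the same length. Names that are empty after
#'   stripping are returned as `NA_character_` with a warning (callers reject
#'   such records).
#' @examples
#' normalize_name("aspirin")
#' normalize_name("N-{2-[4-chloro]}amide")
#' @export
normalize_name <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- gsub("[ \t\r\n\f\v]+", " ", trimws(raw))
  # chartr is a strict 1:1 byte/char map: only ASCII a-z and the four brackets
  out <- chartr(
    "abcdefghijklmnopqrstuvwxyz{}[]",
    "ABCDEFGHIJKLMNOPQRSTUVWXYZ()()",
    out
  )
  empty <- !is.na(out) & out == ""
  if (any(empty)) {
    warning(sprintf("%d empty name(s) after normalization", sum(empty)),
            call. = FALSE)
    out[empty] <- NA_character_
  }
  out
}
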