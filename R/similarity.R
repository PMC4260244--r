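# Windowed ungapped identity and free-end-gap global identity.  These are
# the two similarity primitives the whole pipeline is built on; the heavy
# scans live in src/core.cpp.

#' Best ungapped window match between two sequences
#'
#' Scans every relative offset of `a` against `b` (and, by default, against
#' the reverse complement of `b`) for the length-`window` block with the
#' highest per-column identity, subject to `identity >= min_identity`.
#' Comparison is ungapped -- fixed-width windows compared column by column,
#' an `N` never matching anything. Ties are broken deterministically:
#' highest identity, then forward orientation, then smallest
#' `(offset_a, offset_b)`. Offsets are 0-based.
#'
#' @param a,b Nucleotide strings.
#' @param window Window width in bases.
#' @param min_identity Minimum match fraction in (0, 1].
#' @param scan_rc Also scan the reverse complement of `b` (default TRUE:
#'   short-read data is unstranded).
#' @return A list with `found = FALSE`, or `found = TRUE` plus `offset_a`,
#'   `offset_b`, `identity` and `orientation` (`"forward"` or
#'   `"reverse-complement"`, referring to `b`).
#' @examples
#' s <- strrep("ACGT", 30)
#' best_window_match(s, s, 100, 0.7)$identity # 1
#' @export
best_window_match <- function(a, b, window, min_identity, scan_rc = TRUE) {
  stopifnot(window >= 1)
  cpp_best_window_match(a, b, as.integer(window), min_identity, scan_rc, FALSE)
}

#' Semi-global sequence identity
#'
#' Computes an optimal global alignment with lightly penalised end gaps
#' (match +1, mismatch -1, internal gap -2, terminal gap -1 per base) and
#' returns matches divided by the alignment columns between the first and
#' last aligned pair, i.e. terminal overhangs are excluded from the
#' denominator. The half-cost end gaps make the alignment prefer terminal
#' overhangs over internal gaps while still preferring a substitution
#' over shifting a sequence by its ends. `N` never matches. Symmetric in
#' its arguments up to alignment ties.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' global_identity("AAAA", "AAAT") # 0.75
#' @export
global_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  cpp_global_identity(a, b)
}

#' Reverse complement
#'
#' @param x Character vector of nucleotide strings; non-ACGT bases map to N.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) cpp_revcomp(x)
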