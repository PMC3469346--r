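#' Semi-global pairwise alignment of two sequences
#'
#' Needleman-Wunsch alignment with linear gap costs (match +1, mismatch -1,
#' gap -2) and free terminal gaps, so that partial transcripts (ESTs) align
#' against full-length cDNAs without end-gap penalties. Identity is computed
#' over the aligned columns only (terminal overhangs excluded).
#'
#' @param a,b Sequence strings (or single-row sequence tibbles).
#' @param match,mismatch,gap Scoring parameters.
#' @return One-row tibble: `score`, `identity`, `matches`, `columns` (aligned
#'   columns, i.e. the overlap length including internal gaps), `aligned_a`,
#'   `aligned_b`, and 0-based half-open aligned ranges `a_start`, `a_end`,
#'   `b_start`, `b_end`.
#' @export
align_overlap <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- if (is.data.frame(a)) a$seq[1] else a
  b <- if (is.data.frame(b)) b$seq[1] else b
  stopifnot(is_scalar_string(a), is_scalar_string(b),
            nchar(a) > 0, nchar(b) > 0)
  as_tibble(.nw_overlap(a, b, match, mismatch, gap))
}

#' Pairwise identity between two sequences
#'
#' Fraction of matching columns in the optimal semi-global alignment of
#' [align_overlap()], excluding terminal-gap columns. Symmetric in its
#' arguments.
#'
#' @inheritParams align_overlap
#' @return Numeric identity in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT") # 0.75
#' @export
pairwise_identity <- function(a, b) {
  align_overlap(a, b)$identity
}
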