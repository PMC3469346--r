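AA20X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Default TG2 deamidation rule table
#'
#' Tissue transglutaminase (TG2) converts specific glutamines to glutamate.
#' The default rules are: (R1) a Q followed two positions later by P, with
#' the intervening residue not P (the QxP motif), is a *primary* target;
#' (R2) a Q immediately followed by P is *not* deamidated; (R3) a Q whose
#' centred sequence context appears in a curated moderate-context list is a
#' *moderate* target; otherwise no deamidation. The moderate list is
#' data-driven (shipped as `moderate_contexts.tsv`, curated from published
#' deamidation annotations of natural gliadin peptides) because no
#' position-free local rule reproduces the published moderate annotations;
#' contexts are `window` residues either side of the Q, `-`-padded at peptide
#' ends.
#'
#' @param moderate_contexts Character vector of centred contexts; defaults to
#'   the curated list shipped with the package.
#' @param window Context half-width in residues (default 3).
#' @return List with elements `moderate_contexts` and `window`.
#' @export
default_deamidation_rules <- function(moderate_contexts = NULL, window = 3L) {
  if (is.null(moderate_contexts)) {
    path <- system.file("extdata", "moderate_contexts.tsv",
                        package = "gliascan")
    moderate_contexts <- read.delim(path, stringsAsFactors = FALSE)$context
  }
  list(moderate_contexts = moderate_contexts, window = as.integer(window))
}

q_context <- function(res, i, window) {
  n <- length(res)
  idx <- (i - window):(i + window)
  out <- ifelse(idx >= 1L & idx <= n, res[pmax(pmin(idx, n), 1L)], "-")
  paste(out, collapse = "")
}

#' Classify glutamine deamidation targets along a peptide
#'
#' Pure function of the peptide and the rule table (see
#' [default_deamidation_rules()]). Every Q position is classified as
#' `primary`, `moderate` or `none`, and each classification carries the id of
#' the rule that fired.
#'
#' @param peptide Amino-acid string.
#' @param rules Rule table from [default_deamidation_rules()].
#' @return Tibble `position` (0-based), `class`, `rule`.
#' @examples
#' annotate_deamidation("QPQQPFPQ")
#' @export
annotate_deamidation <- function(peptide, rules = default_deamidation_rules()) {
  stopifnot(is_scalar_string(peptide), nchar(peptide) > 0)
  res <- chars(peptide)
  bad <- setdiff(res, AA20X)
  if (length(bad))
    abort(paste0("non-amino-acid character(s): ",
                 paste(unique(bad), collapse = ", ")))
  qpos <- which(res == "Q")
  n <- length(res)
  cls <- character(length(qpos))
  rid <- character(length(qpos))
  for (k in seq_along(qpos)) {
    i <- qpos[k]
    if (i + 1L <= n && res[i + 1L] == "P") {
      cls[k] <- "none"; rid[k] <- "R2"
    } else if (i + 2L <= n && res[i + 2L] == "P") {
      cls[k] <- "primary"; rid[k] <- "R1"
    } else if (q_context(res, i, rules$window) %in% rules$moderate_contexts) {
      cls[k] <- "moderate"; rid[k] <- "R3"
    } else {
      cls[k] <- "none"; rid[k] <- "default"
    }
  }
  tibble(position = qpos - 1L, class = cls, rule = rid)
}

#' Emit the TG2-deamidated form of a peptide
#'
#' Primary-target glutamines are replaced by glutamate (E); moderate targets
#' optionally too.
#'
#' @inheritParams annotate_deamidation
#' @param include_moderate Also deamidate moderate targets (default FALSE).
#' @return The deamidated peptide string.
#' @export
deamidate_peptide <- function(peptide, rules = default_deamidation_rules(),
                              include_moderate = FALSE) {
  prof <- annotate_deamidation(peptide, rules)
  res <- chars(peptide)
  hit <- prof$position[prof$class == "primary" |
                         (include_moderate & prof$class == "moderate")]
  res[hit + 1L] <- "E"
  paste(res, collapse = "")
}

#' Render deamidation markup for human inspection
#'
#' Two-line text rendering: the peptide with moderate-target glutamines in
#' lowercase, and a marker line with `^` under primary targets (a plain-text
#' proxy for the underline/italics convention used in the literature).
#'
#' @inheritParams annotate_deamidation
#' @return Character vector of two lines.
#' @export
render_deamidation <- function(peptide,
                               rules = default_deamidation_rules()) {
  prof <- annotate_deamidation(peptide, rules)
  res <- chars(peptide)
  res[prof$position[prof$class == "moderate"] + 1L] <- "q"
  marks <- rep(" ", length(res))
  marks[prof$position[prof$class == "primary"] + 1L] <- "^"
  c(paste(res, collapse = ""), paste(marks, collapse = ""))
}
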