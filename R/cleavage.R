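#' Default protease cleavage rule table
#'
#' Rules follow the standard specificity tables for in-silico digestion:
#' trypsin cleaves after K or R unless the next residue is P;
#' chymotrypsin (high specificity) after F, Y or W unless before P;
#' chymotrypsin (low specificity) after F, L, M, W, Y or H unless before P,
#' with the additional exception that H is not cleaved before M or W.
#' The table is overridable, e.g. to add pepsin rules.
#'
#' @return Tibble `enzyme`, `residues`, `blocked_next`, `blocked_pairs`
#'   (comma-separated two-residue exceptions, may be `NA`).
#' @export
default_enzyme_table <- function() {
  tibble(
    enzyme = c("trypsin", "chymotrypsin_high", "chymotrypsin_low"),
    residues = c("KR", "FYW", "FLMWYH"),
    blocked_next = c("P", "P", "P"),
    blocked_pairs = c(NA, NA, "HM,HW"))
}

#' Predict protease cleavage sites
#'
#' @param protein Amino-acid string or protein tibble (`id`, `aa`).
#' @param enzymes Character vector of enzyme names from the rule table.
#' @param table Cleavage rule table (default [default_enzyme_table()]).
#' @return Tibble `id`, `enzyme`, `position`: cleavage occurs to the right
#'   (C-terminal side) of the 0-based `position`; the terminal residue never
#'   yields a site.
#' @examples
#' predict_cleavage("AKAA", enzymes = "trypsin")
#' @export
predict_cleavage <- function(protein,
                             enzymes = c("trypsin", "chymotrypsin_high"),
                             table = default_enzyme_table()) {
  if (!is.data.frame(protein)) protein <- tibble(id = "protein", aa = protein)
  missing <- setdiff(enzymes, table$enzyme)
  if (length(missing))
    abort(paste0("unknown enzyme(s): ", paste(missing, collapse = ", ")))
  out <- list()
  for (k in seq_len(nrow(protein))) {
    res <- chars(protein$aa[k])
    n <- length(res)
    if (n < 2L) next
    for (e in enzymes) {
      row <- table[table$enzyme == e, ]
      targets <- chars(row$residues)
      blocked <- chars(row$blocked_next)
      pairs <- if (is.na(row$blocked_pairs)) character(0) else
        strsplit(row$blocked_pairs, ",", fixed = TRUE)[[1]]
      pos <- which(res[-n] %in% targets)
      pos <- pos[!(res[pos + 1L] %in% blocked)]
      if (length(pairs))
        pos <- pos[!(paste0(res[pos], res[pos + 1L]) %in% pairs)]
      if (length(pos))
        out[[length(out) + 1L]] <- tibble(id = protein$id[k], enzyme = e,
                                          position = as.integer(pos - 1L))
    }
  }
  if (!length(out))
    return(tibble(id = character(), enzyme = character(),
                  position = integer()))
  bind_rows(out) |> arrange(.data$id, .data$position, .data$enzyme)
}

#' Find proteolysis-resistant fragments containing epitopes
#'
#' The cleavage sites of the considered enzymes partition the protein into
#' maximal fragments with no internal cleavage site; fragments containing at
#' least `min_epitope_instances` epitope matches fully inside are reported.
#' Proline/glutamine-rich gliadin repeats typically contain no tryptic sites
#' at all, making their stacked epitopes resistant to digestion.
#'
#' @inheritParams predict_cleavage
#' @param min_epitope_instances Minimum epitope matches per fragment
#'   (default 1; 0 returns the full fragment partition).
#' @param registry Epitope registry for [scan_epitopes()].
#' @return Tibble `id`, `start`, `end` (0-based half-open), `n_instances`,
#'   `labels` (list of matched epitope labels), `enzymes` (comma-joined).
#' @export
find_resistant_fragments <- function(protein,
                                     enzymes = c("trypsin",
                                                 "chymotrypsin_high"),
                                     min_epitope_instances = 1L,
                                     registry = default_epitope_registry(),
                                     table = default_enzyme_table()) {
  if (!is.data.frame(protein)) protein <- tibble(id = "protein", aa = protein)
  sites <- predict_cleavage(protein, enzymes, table)
  matches <- scan_epitopes(protein, registry)
  out <- list()
  for (k in seq_len(nrow(protein))) {
    n <- nchar(protein$aa[k])
    s <- sort(unique(sites$position[sites$id == protein$id[k]]))
    starts <- c(0L, s + 1L)
    ends <- c(s + 1L, n)
    m <- matches[matches$id == protein$id[k], ]
    for (f in seq_along(starts)) {
      inside <- m$start >= starts[f] & m$start + 9L <= ends[f]
      if (sum(inside) >= min_epitope_instances)
        out[[length(out) + 1L]] <- tibble(
          id = protein$id[k], start = starts[f], end = ends[f],
          n_instances = sum(inside), labels = list(m$label[inside]),
          enzymes = paste(enzymes, collapse = ","))
    }
  }
  if (!length(out))
    return(tibble(id = character(), start = integer(), end = integer(),
                  n_instances = integer(), labels = list(),
                  enzymes = character()))
  bind_rows(out)
}
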