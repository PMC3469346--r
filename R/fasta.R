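#' Read sequences from a FASTA file into a tibble
#'
#' Sequence records are represented throughout the package as tibbles with one
#' row per sequence: columns `id` (first whitespace-delimited token of the
#' header), `desc` (remainder of the header, `NA` if none), `seq` (upper-cased
#' sequence), `source` (free-text genome/taxon label, parsed from a
#' `genome=...` tag in the header when present) and `depth_hint` (positive
#' integer, default 1).
#'
#' @param path Path to a FASTA file.
#' @param alignment If `TRUE` the file is declared an alignment and gap
#'   characters (`-`) are preserved; otherwise gaps are stripped on read.
#' @return A tibble with columns `id`, `desc`, `seq`, `source`, `depth_hint`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "atgc"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alignment = FALSE) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("FASTA file is empty: ", path))
  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate sequence id(s) in FASTA: ",
                 paste(dup, collapse = ", ")))
  }
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+"))
  desc[desc == ""] <- NA_character_
  seqs <- toupper(as.character(set))
  if (!alignment) seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0L)) abort("FASTA contains a zero-length sequence")
  src <- stringr::str_match(desc, "genome=(\\S+)")[, 2]
  tibble(id = unname(ids), desc = unname(desc), seq = unname(seqs),
         source = unname(src), depth_hint = 1L)
}

#' Write a sequence tibble to FASTA
#'
#' Sequences are wrapped at 60 columns. Headers are `id` followed by `desc`
#' when present.
#'
#' @param records Tibble with at least `id` and `seq` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  headers <- records$id
  if ("desc" %in% names(records)) {
    has_desc <- !is.na(records$desc)
    headers[has_desc] <- paste(records$id[has_desc], records$desc[has_desc])
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
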