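IUPAC_NT <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V")

translate_one <- function(seq, frame) {
  cods <- codon_split(seq, frame)
  if (length(cods) == 0L)
    abort("sequence shorter than one codon in the requested frame")
  gc <- Biostrings::GENETIC_CODE
  aa <- character(length(cods))
  for (k in seq_along(cods)) {
    cod <- cods[k]
    if (grepl("[^ACGT]", cod)) {
      # ambiguity codes (incl. N) translate to X; anything else is an error
      bad <- setdiff(chars(cod), IUPAC_NT)
      if (length(bad) > 0L)
        abort(paste0("non-nucleotide character in sequence: ",
                     paste(unique(bad), collapse = ", ")))
      aa[k] <- "X"
    } else {
      aa[k] <- unname(gc[cod])
    }
  }
  stops <- which(aa == "*")
  internal <- stops[stops < length(aa)]
  if (length(internal) > 0L) {
    sp <- internal[1]
    list(aa = paste(aa[seq_len(sp - 1L)], collapse = ""),
         truncated = TRUE, stop_position = sp - 1L)
  } else {
    # a terminal stop is dropped; the protein is full-length
    if (length(stops) > 0L) aa <- aa[-length(aa)]
    list(aa = paste(aa, collapse = ""), truncated = FALSE,
         stop_position = NA_integer_)
  }
}

#' Translate coding sequences with internal-stop bookkeeping
#'
#' Standard genetic code translation from a fixed frame on the given strand
#' (inputs are coding-strand by contract; no reverse-complement search). The
#' trailing partial codon is dropped. A codon containing `N` or another IUPAC
#' ambiguity code translates to `X`. If an internal stop codon occurs the
#' protein is truncated at the stop: `truncated = TRUE` and `stop_position`
#' records the 0-based codon index of the stop, which is excluded from `aa`.
#' A terminal stop codon is silently dropped.
#'
#' @param records Sequence tibble (see [read_fasta()]).
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return A protein tibble: the input columns minus `seq`, plus `aa`,
#'   `truncated`, `stop_position`.
#' @examples
#' translate_cds(tibble::tibble(id = "x", seq = "ATGAAG"))
#' @export
translate_cds <- function(records, frame = 0) {
  stopifnot(frame %in% 0:2, all(c("id", "seq") %in% names(records)))
  tr <- map(unname(records$seq), translate_one, frame = frame)
  out <- records[setdiff(names(records), "seq")]
  out$aa <- map_chr(tr, "aa")
  out$truncated <- map_lgl(tr, "truncated")
  out$stop_position <- map_int(tr, "stop_position")
  as_tibble(out)
}

#' Flag pseudogenes (internal stop codons) in translated proteins
#'
#' A transcript is called a pseudogene when its translation hit an internal
#' stop codon. The report includes the up-to-12 residues immediately
#' preceding the stop, the motif the genomic surveys use to characterise
#' recurrent C-to-T truncations in the repetitive domain.
#'
#' @param proteins Protein tibble from [translate_cds()].
#' @return The input with `is_pseudogene` and `preceding_12mer` columns.
#' @export
detect_pseudogene <- function(proteins) {
  stopifnot(all(c("aa", "truncated") %in% names(proteins)))
  proteins |>
    mutate(
      is_pseudogene = .data$truncated,
      preceding_12mer = dplyr::if_else(
        .data$truncated,
        stringr::str_sub(.data$aa, pmax(1L, nchar(.data$aa) - 11L)),
        NA_character_))
}
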