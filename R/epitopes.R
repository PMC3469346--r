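#' The canonical gamma-gliadin CD-epitope registry
#'
#' The nine 9-mer T-cell epitope cores known from gamma-gliadins, in both the
#' classical and the revised (DQ2.5-glia-*) nomenclature. `alt_label` is `NA`
#' for cores without a revised name.
#'
#' @return Tibble `label`, `alt_label`, `core` (nine rows, cores pairwise
#'   distinct, each exactly 9 residues).
#' @export
default_epitope_registry <- function() {
  tibble(
    label = c("DQ2-gamma-VIIb", "DQ2-gamma-VI", "DQ2-glia-gamma2a",
              "DQ2-gamma-II", "DQ2-gamma-I", "DQ2-gamma-VIIa",
              "DQ2-gamma-IV", "DQ2-gamma-III", "DQ2-glia-gamma2b"),
    alt_label = c("DQ2.5-glia-gamma4c", "DQ2.5-glia-gamma5", NA,
                  "DQ2.5-glia-gamma2", "DQ2.5-glia-gamma1",
                  "DQ2.5-glia-gamma4b", "DQ2.5-glia-gamma4a",
                  "DQ2.5-glia-gamma3", NA),
    core = c("QQPQQPFPQ", "QQPFPQQPQ", "FPQQPQQPF",
             "IQPQQPAQL", "PQQSFPQQQ", "PQPQQQFPQ",
             "SQPQQQFPQ", "QQPQQPYPQ", "YPQQPQQPF"))
}

#' Read an epitope registry from TSV
#'
#' @param path TSV with columns `label`, `alt_label`, `core`.
#' @return Registry tibble as in [default_epitope_registry()].
#' @export
read_epitope_registry <- function(path) {
  reg <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  stopifnot(all(c("label", "core") %in% names(reg)))
  if (!"alt_label" %in% names(reg)) reg$alt_label <- NA_character_
  if (any(nchar(reg$core) != 9L)) abort("epitope cores must be 9 residues")
  if (anyDuplicated(reg$label)) abort("epitope labels must be unique")
  reg[c("label", "alt_label", "core")]
}

#' Scan a protein for exact CD-epitope core matches
#'
#' Every exact occurrence of every registry core is reported, including
#' overlapping occurrences (the gliadin repeats stack epitopes on top of each
#' other, so overlap counting is essential for the census). Matching is exact
#' by design: the census semantics count canonical cores, not fuzzy variants.
#'
#' @param protein Amino-acid string, or a protein tibble (columns `id`, `aa`)
#'   whose rows are scanned jointly.
#' @param registry Epitope registry tibble (default
#'   [default_epitope_registry()]).
#' @param region Optional 0-based half-open interval `c(start, end)`
#'   restricting matches to those fully inside it.
#' @return Tibble sorted by (`id`, `start`, `label`): `id`, `label`, `start`
#'   (0-based), `match` (the 9-mer), `flank_left`, `flank_right` (up to 4
#'   residues each).
#' @examples
#' scan_epitopes("QQPQQPFPQQPQQPFPQ")
#' @export
scan_epitopes <- function(protein, registry = default_epitope_registry(),
                          region = NULL) {
  if (!is.data.frame(protein))
    protein <- tibble(id = "protein", aa = protein)
  out <- vector("list", nrow(protein))
  for (k in seq_len(nrow(protein))) {
    aa <- protein$aa[k]
    hits <- list()
    if (nchar(aa) >= 9L) {
      for (e in seq_len(nrow(registry))) {
        loc <- stringi::stri_locate_all_fixed(aa, registry$core[e],
                                              overlap = TRUE)[[1]]
        if (is.na(loc[1, 1])) next
        starts <- loc[, 1] - 1L # to 0-based
        hits[[length(hits) + 1L]] <- tibble(
          id = protein$id[k],
          label = registry$label[e],
          start = as.integer(starts),
          match = registry$core[e],
          flank_left = substr(rep(aa, length(starts)),
                              pmax(1L, starts - 3L), starts),
          flank_right = substr(rep(aa, length(starts)),
                               starts + 11L,
                               pmin(nchar(aa), starts + 14L)))
      }
    }
    out[[k]] <- if (length(hits)) bind_rows(hits) else
      tibble(id = character(), label = character(), start = integer(),
             match = character(), flank_left = character(),
             flank_right = character())
  }
  res <- bind_rows(out)
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    res <- filter(res, .data$start >= region[1],
                  .data$start + 9L <= region[2])
  }
  arrange(res, .data$id, .data$start, .data$label)
}

#' Count distinct epitope types in a match set
#' @param matches Output of [scan_epitopes()].
#' @return Integer: number of unique epitope labels.
#' @export
count_distinct_epitopes <- function(matches) length(unique(matches$label))

#' Count epitope instances (occurrences) in a match set
#' @param matches Output of [scan_epitopes()].
#' @return Integer: number of matches, overlapping occurrences all counted.
#' @export
count_instances <- function(matches) nrow(matches)

#' Extract flanked peptide contexts of an epitope
#'
#' For each match of `epitope_label`, the 9-mer core plus up to `flank`
#' residues on each side (shorter at the protein ends, no padding) — the
#' "natural context" used to enumerate flanking-sequence variants.
#'
#' @param protein Amino-acid string or protein tibble.
#' @param epitope_label Registry label to extract.
#' @param registry Epitope registry tibble.
#' @param flank Flank width in residues (default 4).
#' @return Tibble `id`, `start`, `context`.
#' @export
extract_epitope_context <- function(protein, epitope_label,
                                    registry = default_epitope_registry(),
                                    flank = 4L) {
  stopifnot(flank >= 0L)
  if (!is.data.frame(protein))
    protein <- tibble(id = "protein", aa = protein)
  m <- scan_epitopes(protein, registry) |>
    filter(.data$label == epitope_label)
  aa_by_id <- setNames(protein$aa, protein$id)
  m |>
    mutate(context = map2_chr(.data$id, .data$start, function(i, s) {
      aa <- aa_by_id[[i]]
      substr(aa, max(1L, s + 1L - flank), min(nchar(aa), s + 9L + flank))
    })) |>
    select("id", "start", "context")
}
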