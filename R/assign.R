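# nucleotide region spanning domains III-V (NR1 start .. NR2 end), the region
# shared by partial transcripts and genomic references; falls back to the full
# sequence when the anchors cannot both be located
domain35_region <- function(seq) {
  prot <- translate_cds(tibble(id = "x", seq = seq))
  if (nchar(prot$aa) < 20L) return(seq)
  seg <- segment_domains(prot, full_length = startsWith(prot$aa, "M"))
  if (!all(c("NR1", "NR2") %in% seg$domain)) return(seq)
  aa_start <- seg$start[seg$domain == "NR1"]
  aa_end <- seg$end[seg$domain == "NR2"]
  substr(seq, aa_start * 3L + 1L, aa_end * 3L)
}

pair_distance <- function(a, b, model, gap_mode, gap = -8) {
  # stiff gap penalty: in low-complexity prolamin repeats a cheap gap lets
  # the aligner re-register repeat units and erase lineage signal, so gaps
  # are reserved for genuine repeat-count differences
  al <- .nw_overlap(a, b, gap = gap)
  dm <- suppressWarnings(compute_distances(
    c(x = al$aligned_a, y = al$aligned_b), model = model,
    gap_mode = gap_mode))
  dm[1, 2]
}

#' Assign contigs to their genome of origin
#'
#' Each contig consensus is aligned pairwise against every labelled diploid
#' reference sequence and a model distance is computed over the aligned
#' columns (gap and ambiguous columns excluded pairwise). The contig is
#' assigned to the locus of the genome with the smallest mean distance when
#' the margin to the second-best genome is at least `min_margin`
#' substitutions/site; otherwise it is reported `unassigned`. By default the
#' comparison is restricted to the region spanning domains III-V (NPC through
#' MCN), the region shared by partial transcripts and genomic clones.
#'
#' @param contigs Contig tibble from [cluster_transcripts()] (or any tibble
#'   with `contig_id` and `consensus`; a `depth` column is carried through).
#' @param references Sequence tibble whose `source` column labels each
#'   reference with its genome (e.g. "A", "B", "D"); at least two genomes.
#' @param model,gap_mode Passed to [compute_distances()].
#' @param min_margin Minimum distance margin for assignment (default 0.01
#'   substitutions/site).
#' @param region `"domain3to5"` (default) or `"full"`.
#' @return Tibble: `contig_id`, `locus` (`Gli-A1`/`Gli-B1`/`Gli-D1`/... or
#'   `unassigned`), one `dist_<genome>` column per genome, `margin`, `depth`,
#'   `reason` (NA unless unassigned).
#' @export
assign_genome <- function(contigs, references, model = "K2P",
                          gap_mode = "pairwise_deletion", min_margin = 0.01,
                          region = c("domain3to5", "full")) {
  region <- match.arg(region)
  stopifnot(all(c("contig_id", "consensus") %in% names(contigs)),
            all(c("id", "seq", "source") %in% names(references)))
  genomes <- sort(unique(references$source))
  if (length(genomes) < 2L)
    abort("references must carry genome labels from at least 2 genomes")
  ref_seqs <- references$seq
  if (region == "domain3to5")
    ref_seqs <- map_chr(ref_seqs, domain35_region)
  depth <- if ("depth" %in% names(contigs)) contigs$depth else
    rep(NA_integer_, nrow(contigs))

  rows <- vector("list", nrow(contigs))
  for (k in seq_len(nrow(contigs))) {
    cons <- contigs$consensus[k]
    if (region == "domain3to5") cons <- domain35_region(cons)
    res <- tryCatch({
      dists <- map_dbl(ref_seqs, ~ pair_distance(cons, .x, model, gap_mode))
      means <- map_dbl(genomes, ~ mean(dists[references$source == .x]))
      names(means) <- genomes
      ord <- order(means)
      margin <- means[ord[2]] - means[ord[1]]
      locus <- if (margin >= min_margin) {
        paste0("Gli-", genomes[ord[1]], "1")
      } else "unassigned"
      list(locus = locus, means = means, margin = unname(margin),
           reason = if (locus == "unassigned") "margin below minimum"
                    else NA_character_)
    }, error = function(e) {
      list(locus = "unassigned",
           means = setNames(rep(NA_real_, length(genomes)), genomes),
           margin = NA_real_, reason = conditionMessage(e))
    })
    row <- tibble(contig_id = contigs$contig_id[k], locus = res$locus)
    for (g in genomes) row[[paste0("dist_", g)]] <- unname(res$means[g])
    row$margin <- res$margin
    row$depth <- depth[k]
    row$reason <- res$reason
    rows[[k]] <- row
  }
  bind_rows(rows)
}
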