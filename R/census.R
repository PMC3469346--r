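#' Per-locus CD-epitope census of a contig set
#'
#' Each transcript in a contig contributes the epitope matches of the contig's
#' deduced (consensus) protein, so a cell of the census is
#' `instances x depth`. Contigs whose deduced protein carries an internal stop
#' codon (pseudogenes) are excluded by default — the census describes
#' expressed protein — and the number excluded is recorded.
#'
#' @param contigs Contig tibble from [cluster_transcripts()].
#' @param assignments Assignment tibble from [assign_genome()] (columns
#'   `contig_id`, `locus`). Unassigned contigs form their own group.
#' @param registry Epitope registry tibble.
#' @param include_pseudogenes Include internal-stop contigs (default FALSE).
#' @param region `"full"` (default) scans the whole deduced protein;
#'   `"r1_nr2"` restricts scanning to the epitope-bearing repetitive domain
#'   R1 and C-terminal domain NR2.
#' @return An object of class `epitope_census`: list with `cells` (tibble
#'   `epitope`, `group`, `locus`, `instances`, `depth`, `count`), `by_group`,
#'   `by_locus`, `total` and `n_excluded_pseudogenes`. Frequencies are
#'   rounded half-away-from-zero to one decimal; shares to integer percent.
#' @export
census <- function(contigs, assignments,
                   registry = default_epitope_registry(),
                   include_pseudogenes = FALSE,
                   region = c("full", "r1_nr2")) {
  region <- match.arg(region)
  if (nrow(contigs) == 0L) {
    return(new_epitope_census(
      tibble(epitope = character(), group = character(), locus = character(),
             instances = integer(), depth = integer(), count = integer()),
      registry, 0L))
  }
  prots <- translate_cds(contigs |>
                           select(id = "contig_id", seq = "consensus"))
  pseudo <- prots$truncated
  n_excluded <- if (include_pseudogenes) 0L else sum(pseudo)
  keep <- if (include_pseudogenes) rep(TRUE, nrow(prots)) else !pseudo
  loci <- setNames(assignments$locus, assignments$contig_id)
  cells <- list()
  for (k in which(keep)) {
    aa <- prots$aa[k]
    reg_int <- NULL
    if (region == "r1_nr2" && nchar(aa) >= 20L) {
      seg <- segment_domains(prots[k, ], full_length = startsWith(aa, "M"))
      doms <- seg[seg$domain %in% c("R1", "NR2"), ]
      m <- list()
      for (d in seq_len(nrow(doms)))
        m[[d]] <- scan_epitopes(aa, registry,
                                region = c(doms$start[d], doms$end[d]))
      m <- bind_rows(m)
    } else {
      m <- scan_epitopes(aa, registry)
    }
    inst <- table(factor(m$label, levels = registry$label))
    cells[[length(cells) + 1L]] <- tibble(
      epitope = registry$label,
      group = contigs$contig_id[k],
      locus = unname(loci[contigs$contig_id[k]]) %||% "unassigned",
      instances = as.integer(inst),
      depth = contigs$depth[k],
      count = as.integer(inst) * contigs$depth[k])
  }
  cells <- bind_rows(cells) |>
    mutate(locus = dplyr::coalesce(.data$locus, "unassigned"))
  new_epitope_census(cells, registry, n_excluded)
}

new_epitope_census <- function(cells, registry, n_excluded) {
  by_group <- cells |>
    group_by(.data$group, .data$locus) |>
    summarise(n_epitopes = sum(.data$count),
              n_transcripts = .data$depth[1] %||% 0L, .groups = "drop") |>
    mutate(frequency = round_half_up(.data$n_epitopes /
                                       .data$n_transcripts, 1))
  by_locus <- summarise_loci(by_group)
  total <- list(
    n_epitopes = sum(cells$count),
    n_transcripts = sum(by_group$n_transcripts),
    n_distinct = length(unique(cells$epitope[cells$count > 0])))
  structure(list(cells = cells, by_group = by_group, by_locus = by_locus,
                 total = total, registry = registry,
                 n_excluded_pseudogenes = n_excluded),
            class = "epitope_census")
}

summarise_loci <- function(by_group) {
  grand <- sum(by_group$n_epitopes)
  total_tr <- sum(by_group$n_transcripts)
  by_group |>
    group_by(.data$locus) |>
    summarise(n_epitopes = sum(.data$n_epitopes),
              n_transcripts = sum(.data$n_transcripts), .groups = "drop") |>
    mutate(
      frequency = ifelse(.data$n_transcripts > 0,
                         round_half_up(.data$n_epitopes /
                                         .data$n_transcripts, 1), NA_real_),
      epitope_share_pct = if (grand > 0)
        round_half_up(100 * .data$n_epitopes / grand) else NA_real_,
      transcript_share_pct = if (total_tr > 0)
        round_half_up(100 * .data$n_transcripts / total_tr) else NA_real_)
}

#' Aggregate a printed epitope-count table into per-locus figures
#'
#' Pure arithmetic on an epitope-by-group count matrix: per-locus epitope
#' totals, per-transcript frequencies (one decimal, half-away-from-zero) and
#' integer-percent shares of epitopes and transcripts. Shares use the
#' recomputed grand totals; when printed row/grand totals are supplied they
#' are checked and discrepancies reported in the `discrepancies` attribute,
#' never silently corrected.
#'
#' @param counts Long tibble `epitope`, `group`, `count` (non-negative
#'   integers).
#' @param groups Tibble `group`, `locus`, `n_transcripts`.
#' @param printed_row_sums Optional tibble `epitope`, `printed_sum`.
#' @param printed_grand_total Optional printed grand total.
#' @return List with `by_group`, `by_locus` (as in [census()]) and `total`;
#'   attribute `discrepancies` is a tibble of mismatches against printed
#'   totals (empty when none supplied or none found).
#' @export
aggregate_printed_counts <- function(counts, groups,
                                     printed_row_sums = NULL,
                                     printed_grand_total = NULL) {
  stopifnot(all(c("epitope", "group", "count") %in% names(counts)),
            all(c("group", "locus", "n_transcripts") %in% names(groups)),
            all(counts$count >= 0))
  counts <- mutate(counts, group = as.character(.data$group))
  groups <- mutate(groups, group = as.character(.data$group))
  by_group <- counts |>
    group_by(.data$group) |>
    summarise(n_epitopes = sum(.data$count), .groups = "drop") |>
    left_join(groups, by = "group") |>
    mutate(frequency = ifelse(.data$n_transcripts > 0,
                              round_half_up(.data$n_epitopes /
                                              .data$n_transcripts, 1),
                              NA_real_),
           transcript_share_pct = if (sum(groups$n_transcripts) > 0)
             round_half_up(100 * .data$n_transcripts /
                             sum(groups$n_transcripts)) else NA_real_) |>
    select("group", "locus", "n_epitopes", "n_transcripts", "frequency",
           "transcript_share_pct")
  by_locus <- summarise_loci(by_group)
  disc <- tibble(what = character(), recomputed = numeric(),
                 printed = numeric())
  if (!is.null(printed_row_sums)) {
    rs <- counts |>
      group_by(.data$epitope) |>
      summarise(recomputed = sum(.data$count), .groups = "drop") |>
      left_join(printed_row_sums, by = "epitope") |>
      filter(!is.na(.data$printed_sum),
             .data$recomputed != .data$printed_sum)
    if (nrow(rs))
      disc <- bind_rows(disc, tibble(what = paste0("row sum: ", rs$epitope),
                                     recomputed = rs$recomputed,
                                     printed = rs$printed_sum))
  }
  grand <- sum(counts$count)
  if (!is.null(printed_grand_total) && grand != printed_grand_total)
    disc <- bind_rows(disc, tibble(what = "grand total",
                                   recomputed = grand,
                                   printed = printed_grand_total))
  out <- list(by_group = by_group, by_locus = by_locus,
              total = list(n_epitopes = grand,
                           n_transcripts = sum(groups$n_transcripts),
                           frequency = round_half_up(
                             grand / sum(groups$n_transcripts), 1)))
  attr(out, "discrepancies") <- disc
  out
}

#' Published epitope-count census of the bread-wheat gamma-gliadin
#' transcriptome
#'
#' Loads the published per-group CD-epitope instance counts (epitope by
#' neighbor-joining topology group, with group-to-locus map and per-group
#' transcript counts) shipped with the package, for use as input to
#' [aggregate_printed_counts()].
#'
#' @return List `counts` (long tibble), `groups`, `printed_row_sums`,
#'   `printed_grand_total`.
#' @export
published_census_counts <- function() {
  wide <- as_tibble(read.delim(
    system.file("extdata", "taestivum_epitope_counts.tsv",
                package = "gliascan"),
    check.names = FALSE, stringsAsFactors = FALSE))
  groups <- as_tibble(read.delim(
    system.file("extdata", "taestivum_groups.tsv", package = "gliascan"),
    colClasses = c("character", "character", "integer")))
  counts <- wide |>
    select(-"printed_sum") |>
    tidyr::pivot_longer(-"epitope", names_to = "group",
                        values_to = "count")
  list(counts = counts, groups = groups,
       printed_row_sums = wide |>
         select("epitope", printed_sum = "printed_sum"),
       printed_grand_total = 6006L)
}

#' Render an epitope census as TSV
#'
#' Deterministic wide rendering: one row per epitope (ordered by descending
#' grand total, ties lexicographic), one column per group, plus summary rows
#' `N_instances`, `N_distinct`, `N_transcripts`. Byte-identical across runs.
#'
#' @param x An `epitope_census` object.
#' @param path Optional output file.
#' @return The TSV text, invisibly if written to `path`.
#' @export
render_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "epitope_census"))
  cells <- x$cells
  groups <- unique(cells$group)
  ep_order <- cells |>
    group_by(.data$epitope) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    arrange(desc(.data$total), .data$epitope) |>
    pull("epitope")
  wide <- cells |>
    select("epitope", "group", "count") |>
    tidyr::pivot_wider(names_from = "group", values_from = "count",
                       values_fill = 0L)
  wide <- wide[match(ep_order, wide$epitope), , drop = FALSE]
  lines <- c(paste(c("epitope", groups), collapse = "\t"))
  for (r in seq_len(nrow(wide)))
    lines <- c(lines, paste(unlist(wide[r, c("epitope", groups)]),
                            collapse = "\t"))
  bg <- x$by_group
  sum_row <- function(name, vals) paste(c(name, vals), collapse = "\t")
  inst <- map_int(groups, ~ sum(cells$count[cells$group == .x]))
  dist <- map_int(groups,
                  ~ sum(cells$count[cells$group == .x] > 0L))
  ntr <- map_int(groups,
                 ~ bg$n_transcripts[bg$group == .x][1])
  lines <- c(lines,
             sum_row("N_instances", inst),
             sum_row("N_distinct", dist),
             sum_row("N_transcripts", ntr))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Parse a rendered census TSV back into its count cells
#'
#' @param text TSV text produced by [render_report()] (or a file path).
#' @return Long tibble `epitope`, `group`, `count` plus a `n_transcripts`
#'   attribute (named integer vector per group).
#' @export
parse_report <- function(text) {
  lines <- if (length(text) == 1L && !grepl("\n", text) &&
                 file.exists(text)) readLines(text) else
    strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[lines != ""]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  groups <- header[-1]
  body <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  names(body) <- map_chr(body, 1)
  ep_rows <- body[!names(body) %in% c("N_instances", "N_distinct",
                                      "N_transcripts")]
  cells <- bind_rows(lapply(ep_rows, function(r)
    tibble(epitope = r[1], group = groups,
           count = as.integer(r[-1]))))
  ntr <- as.integer(body[["N_transcripts"]][-1])
  attr(cells, "n_transcripts") <- setNames(ntr, groups)
  cells
}

#' @export
print.epitope_census <- function(x, ...) {
  cat("<epitope_census>\n")
  cat("  groups:", nrow(x$by_group), " loci:", nrow(x$by_locus), "\n")
  cat("  total instances:", x$total$n_epitopes,
      "over", x$total$n_transcripts, "transcripts\n")
  if (x$n_excluded_pseudogenes > 0)
    cat("  pseudogene contigs excluded:", x$n_excluded_pseudogenes, "\n")
  print(x$by_locus)
  invisible(x)
}

#' @export
tidy.epitope_census <- function(x, ...) x$cells

#' @export
glance.epitope_census <- function(x, ...) {
  tibble(n_groups = nrow(x$by_group),
         n_loci = nrow(x$by_locus),
         n_epitopes = x$total$n_epitopes,
         n_transcripts = x$total$n_transcripts,
         overall_frequency = round_half_up(
           x$total$n_epitopes / max(x$total$n_transcripts, 1L), 1),
         n_excluded_pseudogenes = x$n_excluded_pseudogenes)
}

#' Write the machine-readable JSON summary of a census
#'
#' @param x An `epitope_census` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
census_json <- function(x, path) {
  stopifnot(inherits(x, "epitope_census"))
  loci <- split(x$by_locus, x$by_locus$locus)
  payload <- lapply(loci, function(l) list(
    n_transcripts = l$n_transcripts, n_epitopes = l$n_epitopes,
    frequency = l$frequency, epitope_share_pct = l$epitope_share_pct,
    transcript_share_pct = l$transcript_share_pct))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
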