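contig_of <- function(aa, id = "ctg001", depth = 3L) {
  tibble::tibble(contig_id = id,
                 consensus = gliascan:::reverse_translate(aa),
                 depth = depth)
}
assign_of <- function(ids, locus) tibble::tibble(contig_id = ids,
                                                 locus = locus)

test_that("census weights instances by contig depth", {
  aa <- paste0("MSSEV", "QQPQQPFPQQPQQPFPQ", "LEVISS")
  cen <- census(contig_of(aa, depth = 3L), assign_of("ctg001", "Gli-D1"))
  expect_equal(cen$by_locus$n_epitopes, 12L) # 4 instances x depth 3
  expect_equal(cen$by_locus$n_transcripts, 3L)
  expect_equal(cen$by_locus$frequency, 4.0)
  expect_equal(glance(cen)$n_epitopes, 12L)
  expect_equal(sum(tidy(cen)$count), 12L)
})

test_that("pseudogene contigs are excluded by default, included on request", {
  aa <- paste0("MSSEV", "QQPQQPFPQQPQQPFPQ", "LEVISS")
  nt <- gliascan:::reverse_translate(aa)
  nt_pseudo <- nt
  substr(nt_pseudo, 5 * 3 + 1, 5 * 3 + 1) <- "T" # CAA -> TAA at residue 6
  contigs <- tibble::tibble(contig_id = c("c1", "c2"),
                            consensus = c(nt, nt_pseudo), depth = c(3L, 5L))
  asn <- assign_of(c("c1", "c2"), c("Gli-D1", "Gli-D1"))
  cen <- census(contigs, asn)
  expect_equal(cen$n_excluded_pseudogenes, 1L)
  expect_equal(cen$total$n_epitopes, 12L)
  cen2 <- census(contigs, asn, include_pseudogenes = TRUE)
  expect_equal(cen2$n_excluded_pseudogenes, 0L)
  expect_equal(nrow(cen2$by_group), 2L)
})

test_that("doubling every depth doubles counts and preserves frequencies", {
  cfg <- synthetic_config(genes_per_genome = 2L, seed = 33L)
  g <- generate_reference_genes(cfg)
  contigs <- tibble::tibble(contig_id = g$genes$id, consensus = g$genes$seq,
                            depth = c(4L, 7L, 5L, 9L, 4L, 6L))
  asn <- assign_of(g$genes$id, paste0("Gli-", g$genes$source, "1"))
  c1 <- census(contigs, asn)
  contigs2 <- contigs
  contigs2$depth <- contigs2$depth * 2L
  c2 <- census(contigs2, asn)
  expect_equal(c2$by_locus$n_epitopes, 2L * c1$by_locus$n_epitopes)
  expect_equal(c2$by_locus$frequency, c1$by_locus$frequency)
})

test_that("census conserves the grand total at every aggregation level", {
  cfg <- synthetic_config(genes_per_genome = 2L, seed = 35L)
  g <- generate_reference_genes(cfg)
  contigs <- tibble::tibble(contig_id = g$genes$id, consensus = g$genes$seq,
                            depth = 4:9)
  asn <- assign_of(g$genes$id,
                   c("Gli-A1", "Gli-A1", "Gli-B1", "unassigned",
                     "Gli-D1", "Gli-D1"))
  cen <- census(contigs, asn)
  expect_equal(sum(cen$cells$count), cen$total$n_epitopes)
  expect_equal(sum(cen$by_group$n_epitopes), cen$total$n_epitopes)
  expect_equal(sum(cen$by_locus$n_epitopes), cen$total$n_epitopes)
  expect_equal(sum(cen$by_locus$n_transcripts), sum(contigs$depth))
})

test_that("an empty contig set yields an empty census, not an error", {
  cen <- census(tibble::tibble(contig_id = character(),
                               consensus = character(), depth = integer()),
                tibble::tibble(contig_id = character(), locus = character()))
  expect_s3_class(cen, "epitope_census")
  expect_equal(nrow(cen$cells), 0L)
})

test_that("census on generator output equals the planted truth exactly", {
  cfg <- synthetic_config(genes_per_genome = 2L, depth_range = c(4L, 20L),
                          pseudogene_rate = 0, seed = 37L)
  g <- generate_reference_genes(cfg)
  tx <- sample_transcripts(g, cfg)
  depth_of <- table(tx$truth$gene_id)
  contigs <- tibble::tibble(contig_id = g$genes$id, consensus = g$genes$seq,
                            depth = as.integer(depth_of[g$genes$id]))
  asn <- assign_of(g$genes$id, paste0("Gli-", g$genes$source, "1"))
  cen <- census(contigs, asn)
  truth <- merge(g$truth_epitopes,
                 data.frame(id = names(depth_of),
                            depth = as.integer(depth_of)))
  truth$count <- truth$instances * truth$depth
  got <- cen$cells[order(cen$cells$group, cen$cells$epitope), ]
  want <- truth[order(truth$id, truth$epitope), ]
  expect_equal(got$count, want$count)
  expect_equal(got$instances, want$instances)
})

test_that("aggregating the published per-group counts reproduces the printed figures", {
  pub <- published_census_counts()
  agg <- aggregate_printed_counts(pub$counts, pub$groups,
                                  printed_row_sums = pub$printed_row_sums,
                                  printed_grand_total = pub$printed_grand_total)
  loc <- agg$by_locus
  expect_equal(loc$n_epitopes[loc$locus == "Gli-A1"], 1533)
  expect_equal(loc$n_epitopes[loc$locus == "Gli-B1"], 1005)
  expect_equal(loc$n_epitopes[loc$locus == "Gli-D1"], 3588)
  expect_equal(loc$frequency[loc$locus == "Gli-A1"], 8.6)
  expect_equal(loc$frequency[loc$locus == "Gli-B1"], 5.4)
  expect_equal(loc$frequency[loc$locus == "Gli-D1"], 10.1)
  expect_equal(loc$epitope_share_pct[loc$locus == "Gli-D1"], 59)
  expect_equal(loc$epitope_share_pct[loc$locus == "Gli-A1"], 25)
  expect_equal(loc$epitope_share_pct[loc$locus == "Gli-B1"], 16)
  expect_equal(loc$transcript_share_pct[loc$locus == "Gli-D1"], 49)
  grp <- agg$by_group
  expect_equal(max(grp$frequency), 10.9)
  expect_equal(grp$transcript_share_pct[grp$group == "10"], 9)
  # the printed table's internal inconsistencies are flagged, not corrected
  disc <- attr(agg, "discrepancies")
  expect_true(any(grepl("DQ2-gamma-I$", disc$what)))
  expect_true("grand total" %in% disc$what)
  expect_equal(disc$recomputed[disc$what == "grand total"], 6126)
})

test_that("degenerate aggregation inputs behave per contract", {
  counts <- tibble::tibble(epitope = "e", group = c("g1", "g2"),
                           count = c(0L, 0L))
  groups <- tibble::tibble(group = c("g1", "g2"), locus = c("L1", "L2"),
                           n_transcripts = c(5L, 0L))
  agg <- aggregate_printed_counts(counts, groups)
  expect_equal(agg$total$n_epitopes, 0L)
  expect_true(is.na(agg$by_locus$frequency[agg$by_locus$locus == "L2"]))
  expect_true(all(is.na(agg$by_locus$epitope_share_pct)))
  single <- aggregate_printed_counts(
    tibble::tibble(epitope = "e", group = "g", count = 10L),
    tibble::tibble(group = "g", locus = "L", n_transcripts = 2L))
  expect_equal(single$by_locus$epitope_share_pct, 100)
  expect_equal(single$by_locus$transcript_share_pct, 100)
})

test_that("report rendering is deterministic and parses back", {
  aa1 <- paste0("MSSEV", "QQPQQPFPQQPQQPFPQ", "LEVISS")
  aa2 <- paste0("MSSEV", "PQQSFPQQQ", "LEVISS")
  contigs <- dplyr::bind_rows(contig_of(aa1, "c1", 4L),
                              contig_of(aa2, "c2", 6L))
  cen <- census(contigs, assign_of(c("c1", "c2"), c("Gli-D1", "Gli-A1")))
  txt1 <- render_report(cen)
  txt2 <- render_report(cen)
  expect_identical(txt1, txt2)
  cells <- parse_report(txt1)
  got <- merge(cells, cen$cells, by = c("epitope", "group"))
  expect_equal(got$count.x, got$count.y)
  # sum row equals column sums
  ntr <- attr(cells, "n_transcripts")
  expect_equal(unname(ntr), c(4L, 6L))
  f <- tempfile(fileext = ".tsv")
  render_report(cen, f)
  expect_identical(readLines(f), strsplit(txt1, "\n")[[1]])
})

test_that("the machine-readable JSON summary round trips", {
  aa <- paste0("MSSEV", "QQPQQPFPQQPQQPFPQ", "LEVISS")
  cen <- census(contig_of(aa), assign_of("ctg001", "Gli-D1"))
  f <- tempfile(fileext = ".json")
  census_json(cen, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$`Gli-D1`$n_epitopes, 12L)
  expect_equal(j$`Gli-D1`$frequency, 4.0)
})
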