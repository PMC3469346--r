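test_that("the generator is deterministic for a fixed seed", {
  cfg <- synthetic_config(genes_per_genome = 2L, depth_range = c(4L, 12L),
                          seed = 8L)
  d1 <- simulate_gliadin_dataset(cfg)
  d2 <- simulate_gliadin_dataset(cfg)
  expect_identical(d1$genes$genes, d2$genes$genes)
  expect_identical(d1$transcripts$transcripts, d2$transcripts$transcripts)
  o1 <- tempfile(); o2 <- tempfile()
  p1 <- emit_synthetic(d1$references, d1$transcripts, o1)
  p2 <- emit_synthetic(d2$references, d2$transcripts, o2)
  expect_equal(unname(tools::md5sum(unname(p1))),
               unname(tools::md5sum(unname(p2))))
})

test_that("emitted FASTA re-ingests to the same records and counts", {
  cfg <- synthetic_config(genes_per_genome = 2L, depth_range = c(4L, 6L),
                          seed = 15L)
  ds <- simulate_gliadin_dataset(cfg)
  out <- tempfile()
  paths <- emit_synthetic(ds$references, ds$transcripts, out)
  back <- read_fasta(paths[["transcripts"]])
  expect_equal(nrow(back), nrow(ds$transcripts$transcripts))
  expect_equal(back$seq, ds$transcripts$transcripts$seq)
  expect_equal(nrow(ds$transcripts$truth), nrow(back))
  truth <- read.delim(paths[["truth_transcripts"]])
  expect_equal(truth$transcript_id, back$id)
})

test_that("zero divergence plants identical-architecture genes with the grammar's epitopes", {
  cfg <- synthetic_config(within_genome_divergence = 0,
                          between_genome_divergence = 0,
                          genes_per_genome = 1L, repeat_jitter = FALSE,
                          pseudogene_rate = 0, seed = 3L)
  g <- generate_reference_genes(cfg)
  prots <- translate_cds(g$genes)
  # epitope content equals the planted truth, which at zero divergence is
  # the grammar's own count
  for (k in seq_len(nrow(prots))) {
    m <- scan_epitopes(prots$aa[k])
    truth <- g$truth_epitopes[g$truth_epitopes$id == prots$id[k], ]
    got <- table(factor(m$label, levels = truth$epitope))
    expect_equal(as.integer(got), truth$instances)
  }
})

test_that("generated full-length proteins always pass the cysteine QC", {
  for (seed in c(1L, 2L, 3L)) {
    g <- generate_reference_genes(synthetic_config(seed = seed))
    prots <- translate_cds(g$genes)
    cys <- count_domain_cysteines(prots, segment_domains(prots))
    expect_false(any(cys$qc_flag), info = paste("seed", seed))
  }
})

test_that("realised substitution rate matches the configured divergence", {
  # poly-L codons admit every single-base substitution without creating a
  # stop or cysteine, so no proposals are rejected
  nt <- gliascan:::reverse_translate(strrep("L", 300))
  for (d in c(0.05, 0.2)) {
    m <- gliascan:::with_seed(51, mutate_sequence(nt, d))
    p <- mean(gliascan:::chars(nt) != gliascan:::chars(m))
    se <- sqrt(d * (1 - d) / nchar(nt))
    expect_lt(abs(p - d), 3 * se)
  }
})

test_that("transition:transversion ratio is respected", {
  nt <- gliascan:::reverse_translate(strrep("L", 400))
  m <- gliascan:::with_seed(52, mutate_sequence(nt, 0.3, ts_tv_ratio = 2))
  a <- gliascan:::chars(nt); b <- gliascan:::chars(m)
  diff <- which(a != b)
  is_ts <- (a[diff] == "A" & b[diff] == "G") | (a[diff] == "G" & b[diff] == "A") |
    (a[diff] == "C" & b[diff] == "T") | (a[diff] == "T" & b[diff] == "C")
  frac <- mean(is_ts)
  se <- sqrt(2 / 3 * 1 / 3 / length(diff))
  expect_lt(abs(frac - 2 / 3), 4 * se)
})

test_that("a degenerate depth distribution gives exactly that depth", {
  cfg <- synthetic_config(genes_per_genome = 2L, depth_range = c(4L, 4L),
                          pseudogene_rate = 0, truncate_prob = 0, seed = 6L)
  g <- generate_reference_genes(cfg)
  tx <- sample_transcripts(g, cfg)
  depths <- table(tx$truth$gene_id)
  expect_true(all(depths == 4L))
})

test_that("depths fall in the configured range with low-depth skew", {
  cfg <- synthetic_config(genes_per_genome = 30L, depth_range = c(4L, 220L),
                          truncate_prob = 0, seed = 44L)
  g <- generate_reference_genes(cfg)
  tx <- sample_transcripts(g, cfg)
  depths <- as.integer(table(tx$truth$gene_id))
  expect_true(all(depths >= 4L & depths <= 220L))
  expect_lt(median(depths), mean(depths)) # right-skew
})

test_that("pseudogene injection matches the configured rate and is detectable", {
  cfg <- synthetic_config(n_genomes = 1L, genome_labels = "D",
                          repeat_units = list(D = c(QQPQQPFPQ = 1)),
                          r1_repeats = list(D = c(6L, 6L)),
                          r2_repeats = list(D = c(4L, 4L)),
                          genes_per_genome = 16L, depth_range = c(4L, 4L),
                          truncate_prob = 0, pseudogene_rate = 0.25,
                          seed = 29L)
  g <- generate_reference_genes(cfg)
  tx <- sample_transcripts(g, cfg)
  flagged_genes <- unique(tx$truth$gene_id[tx$truth$pseudogene])
  # binomial(16, 0.25): expected 4, allow 3 standard deviations
  expect_lt(abs(length(flagged_genes) - 4), 3 * sqrt(16 * 0.25 * 0.75) + 1e-9)
  # detect_pseudogene agrees with the injected truth, transcript by transcript
  flags <- detect_pseudogene(translate_cds(tx$transcripts))
  expect_identical(flags$is_pseudogene, tx$truth$pseudogene)
  # the stop lands in R1 and preserves reading frame up to it
  one <- flags[flags$is_pseudogene, ][1, ]
  expect_false(is.na(one$stop_position))
})

test_that("truncated transcripts keep the domain III-V region and 300 nt", {
  cfg <- synthetic_config(genes_per_genome = 2L, depth_range = c(10L, 10L),
                          truncate_prob = 1, pseudogene_rate = 0, seed = 55L)
  g <- generate_reference_genes(cfg)
  tx <- sample_transcripts(g, cfg)
  expect_true(any(tx$truth$truncated_5p))
  expect_true(all(nchar(tx$transcripts$seq) >= 300L))
  # every truncated transcript still contains the NPC..MCN nucleotides
  for (k in which(tx$truth$truncated_5p)[1:5]) {
    aa <- translate_cds(tx$transcripts[k, ])$aa
    expect_match(aa, "NPC")
    expect_match(aa, "MCN")
  }
})
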