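test_that("pairwise identity matches hand examples and is symmetric", {
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAT", "AAAA"), 0.75)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  # a contained partial sequence aligns with free end gaps
  g <- "ATGCATGCATGCAAATTTGGGCCC"
  al <- align_overlap(substr(g, 5, 20), g)
  expect_equal(al$identity, 1)
  expect_equal(al$columns, 16L)
  expect_equal(al$b_start, 4L)
})

test_that("aligner agrees with a pure-R dynamic-programming oracle", {
  set.seed(11)
  # optimal scores are unique and must agree exactly on arbitrary inputs
  for (r in 1:40) {
    a <- random_dna(30)
    b <- random_dna(sample(15:35, 1))
    expect_equal(align_overlap(a, b)$score, oracle_fit_identity(a, b)$score,
                 info = paste(a, b))
  }
  # on substitution-only pairs the gapless alignment is the unique optimum,
  # so identities must agree exactly (and equal 1 - hamming/length)
  for (r in 1:20) {
    a <- random_dna(30)
    b <- gliascan:::with_seed(200 + r, mutate_sequence(a, 0.1))
    orc <- oracle_fit_identity(a, b)
    expect_equal(pairwise_identity(a, b), orc$identity, info = paste(a, b))
    expect_equal(orc$identity,
                 mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]))
  }
})

test_that("identical copies cluster into one contig of full depth", {
  g <- random_dna(400)
  recs <- tibble::tibble(id = paste0("t", 1:5), seq = g)
  cl <- cluster_transcripts(recs, min_members = 4L, min_overlap = 300L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$depth, 5L)
  expect_equal(cl$consensus, g)
})

test_that("sequences below the identity threshold never merge", {
  set.seed(2)
  a <- random_dna(400)
  b <- gliascan:::with_seed(3, mutate_sequence(a, 0.1))
  expect_lt(pairwise_identity(a, b), 0.98)
  recs <- tibble::tibble(id = paste0("t", 1:6), seq = c(rep(a, 3), rep(b, 3)))
  cl <- cluster_transcripts(recs, min_members = 3L, min_overlap = 300L)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$depth), c(3L, 3L))
})

test_that("clustering is a partition and the minor bin is reported", {
  set.seed(4)
  recs <- tibble::tibble(id = paste0("t", 1:9),
                         seq = c(rep(random_dna(350), 5),
                                 rep(random_dna(350), 2),
                                 random_dna(350), random_dna(350)))
  cl <- cluster_transcripts(recs, min_members = 4L, min_overlap = 300L)
  members <- contig_members(cl)
  expect_setequal(members$transcript_id, recs$id)
  expect_equal(sum(cl$depth) + length(attr(cl, "minor_ids")), nrow(recs))
})

test_that("raising the identity threshold only refines the partition", {
  cfg <- synthetic_config(genes_per_genome = 2L, depth_range = c(4L, 6L),
                          truncate_prob = 0, pseudogene_rate = 0, seed = 13L)
  ds <- simulate_gliadin_dataset(cfg)
  tx <- ds$transcripts$transcripts
  lo <- contig_members(cluster_transcripts(tx, identity_threshold = 0.7,
                                           min_members = 1L))
  hi <- contig_members(cluster_transcripts(tx, identity_threshold = 0.99,
                                           min_members = 1L))
  joined <- merge(lo, hi, by = "transcript_id", suffixes = c(".lo", ".hi"))
  # every high-threshold cluster maps into exactly one low-threshold cluster
  split_by_hi <- split(joined$contig_id.lo, joined$contig_id.hi)
  expect_true(all(vapply(split_by_hi, function(x)
    length(unique(x)) == 1L, TRUE)))
})

test_that("at threshold 1.0 clusters are exact-duplicate classes", {
  set.seed(5)
  base <- random_dna(320)
  variant <- base
  substr(variant, 10, 10) <- ifelse(substr(base, 10, 10) == "A", "C", "A")
  recs <- tibble::tibble(id = paste0("t", 1:7),
                         seq = c(rep(base, 4), rep(variant, 3)))
  cl <- cluster_transcripts(recs, identity_threshold = 1.0,
                            min_members = 1L, min_overlap = 300L)
  hash_classes <- sort(unname(table(recs$seq)))
  expect_equal(sort(cl$depth), as.integer(hash_classes))
})

test_that("consensus takes the per-column majority with fixed tie-breaking", {
  expect_equal(call_consensus(c("AAT", "AAT", "ACT")), "AAT")
  expect_equal(call_consensus(rep("ACGT", 3)), "ACGT")
  # tie at a column resolves in base order A < C < G < T
  expect_equal(call_consensus(c("AAT", "ACT")), "AAT")
})

test_that("consensus of noisy members recovers the true gene at depth >= 9", {
  cfg <- synthetic_config(genes_per_genome = 1L, n_genomes = 1L,
                          genome_labels = "D",
                          repeat_units = list(D = c(QQPQQPFPQ = 1)),
                          r1_repeats = list(D = c(6L, 6L)),
                          r2_repeats = list(D = c(4L, 4L)),
                          within_genome_divergence = 0, repeat_jitter = FALSE,
                          between_genome_divergence = 0, pseudogene_rate = 0,
                          truncate_prob = 0, depth_range = c(15L, 15L),
                          transcript_error_rate = 0.005, seed = 31L)
  ds <- simulate_gliadin_dataset(cfg)
  true_gene <- ds$genes$genes$seq[1]
  cons <- call_consensus(ds$transcripts$transcripts$seq)
  expect_equal(cons, true_gene)
})

test_that("generator transcripts at zero noise recover the gene partition", {
  cfg <- synthetic_config(genes_per_genome = 4L, ref_genes_per_genome = 1L,
                          depth_range = c(4L, 220L), pseudogene_rate = 0,
                          seed = 17L)
  ds <- simulate_gliadin_dataset(cfg)
  cl <- cluster_transcripts(ds$transcripts$transcripts)
  truth <- ds$transcripts$truth
  expect_equal(nrow(cl), 12L) # 4 genes x 3 genomes
  members <- contig_members(cl)
  joined <- merge(members, truth, by = "transcript_id")
  by_contig <- split(joined$gene_id, joined$contig_id)
  by_contig <- by_contig[names(by_contig) != "minor"]
  expect_true(all(vapply(by_contig, function(x)
    length(unique(x)) == 1L, TRUE)))
  # per-contig depth equals the generator's drawn depth
  truth_depth <- table(truth$gene_id)
  got_depth <- vapply(by_contig, length, 1L)
  expect_equal(sort(as.integer(got_depth)), sort(as.integer(truth_depth)))
  # consensus equals the true gene sequence
  gene_of <- vapply(by_contig, function(x) unique(x), "")
  for (cid in names(gene_of)) {
    expect_equal(cl$consensus[cl$contig_id == cid],
                 ds$genes$genes$seq[ds$genes$genes$id == gene_of[[cid]]])
  }
})
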