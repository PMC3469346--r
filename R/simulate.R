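# Fixed reverse-translation codon table (one common wheat codon per amino
# acid; Q = CAA so a C->T transition yields the TAA stop seen in natural
# gliadin pseudogenes)
CODON_OF <- c(A = "GCA", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
              G = "GGA", H = "CAC", I = "ATC", K = "AAG", L = "CTC",
              M = "ATG", N = "AAC", P = "CCA", Q = "CAA", R = "AGG",
              S = "TCA", T = "ACA", V = "GTG", W = "TGG", Y = "TAC")

# Idealised gamma-gliadin scaffold. The signal peptide and the non-repetitive
# domains are P/Q-poor and the repeat units P/Q-rich, so the segmentation
# window heuristic recovers the construction boundaries exactly; NR1 starts
# with the NPC anchor and carries six cysteines, NR2 two (one in the MCN
# anchor).
SYN_SIGNAL <- "MKTFLIFALLAVVATSAIA"                  # 19 aa, no P/Q
SYN_DOMAIN_I <- "NMQVDPSGEVNW"                       # 12 aa, P/Q-sparse
SYN_NR1 <- "NPCKNYCLLERCCHAICSLVCAESRTVMGSVI"        # 32 aa, 6 cysteines
SYN_NR2 <- "SQPVSSSEVIRSCVLRTLPTMCN"                 # 23 aa, 2 cysteines

reverse_translate <- function(aa) {
  paste(CODON_OF[chars(aa)], collapse = "")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic gamma-gliadin family generator
#'
#' The generator emulates a prolamin multigene family on three homoeologous
#' genomes: a common ancestral gene diverges into per-genome ancestors, which
#' diverge into genes; transcripts are sampled per gene with skewed depth.
#' Divergences are *pairwise* substitutions/site (each branch carries half).
#' Defaults: within-genome divergence 0.216 (the scale observed among
#' D-genome genomic clones), between-genome 0.45, depth log-uniform on 4-220,
#' transition:transversion 2:1. Anchor motifs (NPC/MCN) and cysteine codons
#' are invariant, emulating their observed absolute conservation.
#'
#' @param n_genomes Number of genomes (default 3).
#' @param genome_labels Genome labels (default A, B, D).
#' @param genes_per_genome Expressed genes per genome (default 3).
#' @param ref_genes_per_genome Genomic reference clones per genome (default 3).
#' @param repeat_units Named list (per genome) of weighted repeat units.
#' @param r1_repeats,r2_repeats Named list (per genome) of `c(min, max)`
#'   repeat-unit counts for R1 and R2.
#' @param within_genome_divergence,between_genome_divergence Pairwise
#'   divergence in substitutions/site, each in `[0, 0.8]`.
#' @param ts_tv_ratio Transition:transversion ratio (default 2).
#' @param depth_range Transcript depth range, default `c(4, 220)`,
#'   log-uniform (skewed toward low depth).
#' @param pseudogene_rate Per-gene probability of a C->T stop injection in R1
#'   (default 0.1).
#' @param transcript_error_rate Per-base transcript error rate (default 0).
#' @param truncate_prob Probability a transcript is 5'-truncated like a
#'   partial EST (default 0.3); truncation is codon-aligned, in 10-codon
#'   steps, and always preserves the domain III-V region plus 300 nt.
#' @param repeat_jitter Vary gene repeat counts by +/- one unit around the
#'   genome ancestor (default TRUE).
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_genomes = 3L,
    genome_labels = c("A", "B", "D"),
    genes_per_genome = 3L,
    ref_genes_per_genome = 3L,
    repeat_units = list(
      A = c(QQPQQPFPQ = 2, PQQSFPQQQ = 1),
      B = c(QQPFPQQPQ = 1, PQQSFPQQQ = 1),
      D = c(QQPQQPFPQ = 2, QQPFPQQPQ = 1, PQQSFPQQQ = 1)),
    r1_repeats = list(A = c(5L, 7L), B = c(3L, 5L), D = c(6L, 8L)),
    r2_repeats = list(A = c(3L, 5L), B = c(3L, 4L), D = c(3L, 5L)),
    within_genome_divergence = 0.216,
    between_genome_divergence = 0.45,
    ts_tv_ratio = 2,
    depth_range = c(4L, 220L),
    pseudogene_rate = 0.1,
    transcript_error_rate = 0,
    truncate_prob = 0.3,
    repeat_jitter = TRUE,
    seed = 1L) {
  stopifnot(n_genomes >= 1L, length(genome_labels) == n_genomes,
            within_genome_divergence >= 0, within_genome_divergence <= 0.8,
            between_genome_divergence >= 0, between_genome_divergence <= 0.8,
            genes_per_genome >= 1L, depth_range[1] >= 1L,
            depth_range[2] >= depth_range[1],
            pseudogene_rate >= 0, pseudogene_rate <= 1)
  if (!all(genome_labels %in% names(repeat_units)))
    abort("repeat_units must name every genome label")
  structure(list(
    n_genomes = n_genomes, genome_labels = genome_labels,
    genes_per_genome = genes_per_genome,
    ref_genes_per_genome = ref_genes_per_genome,
    repeat_units = repeat_units, r1_repeats = r1_repeats,
    r2_repeats = r2_repeats,
    within_genome_divergence = within_genome_divergence,
    between_genome_divergence = between_genome_divergence,
    ts_tv_ratio = ts_tv_ratio, depth_range = as.integer(depth_range),
    pseudogene_rate = pseudogene_rate,
    transcript_error_rate = transcript_error_rate,
    truncate_prob = truncate_prob, repeat_jitter = repeat_jitter,
    seed = as.integer(seed)), class = "synthetic_config")
}

# sample repeat-unit names by weight
sample_units <- function(units, n) {
  sample(names(units), n, replace = TRUE, prob = units / sum(units))
}

# architecture = list of repeat-unit names for R1 and R2
build_gene_aa <- function(r1_units, r2_units) {
  paste0(SYN_SIGNAL, SYN_DOMAIN_I, paste(r1_units, collapse = ""),
         SYN_NR1, paste(r2_units, collapse = ""), SYN_NR2)
}

truth_domains_of <- function(r1_units, r2_units) {
  l <- c(S = nchar(SYN_SIGNAL), I = nchar(SYN_DOMAIN_I),
         R1 = sum(nchar(r1_units)), NR1 = nchar(SYN_NR1),
         R2 = sum(nchar(r2_units)), NR2 = nchar(SYN_NR2))
  ends <- cumsum(l)
  tibble(domain = names(l), start = as.integer(ends - l),
         end = as.integer(ends))
}

#' Mutate a coding sequence at a given divergence
#'
#' Each site is substituted independently with probability `divergence`;
#' substitutions are transitions with odds `ts_tv_ratio`:1 over each
#' transversion pair. Substitutions that would create a stop codon, create or
#' destroy a cysteine, or touch the NPC/MCN anchor or signal-start codons are
#' rejected (those sites are treated as invariant), so full-length proteins
#' stay full-length and anchors stay in place.
#'
#' @param seq Coding nucleotide string (length a multiple of 3).
#' @param divergence Expected substitutions/site on this branch.
#' @param ts_tv_ratio Transition:transversion ratio.
#' @param protect_codons Optional integer vector of additional 0-based codon
#'   indices to hold invariant.
#' @return Mutated nucleotide string.
#' @export
mutate_sequence <- function(seq, divergence, ts_tv_ratio = 2,
                            protect_codons = integer(0)) {
  if (divergence <= 0) return(seq)
  nt <- chars(seq)
  n <- length(nt)
  gc <- Biostrings::GENETIC_CODE
  aa0 <- unname(gc[codon_split(seq)])
  invariant <- which(aa0 %in% c("C", "M", "W") | aa0 == "*") - 1L
  # the NPC / MCN anchor motifs are invariant in full
  aa_str <- paste(aa0, collapse = "")
  anchors <- rbind(stringi::stri_locate_all_fixed(aa_str, "NPC")[[1]],
                   stringi::stri_locate_all_fixed(aa_str, "MCN")[[1]])
  anchor_codons <- unlist(lapply(which(!is.na(anchors[, 1])), function(r)
    seq(anchors[r, 1] - 1L, anchors[r, 2] - 1L)))
  protect <- unique(c(protect_codons, invariant, invariant - 1L,
                      invariant + 1L, anchor_codons))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  hit <- which(runif(n) < divergence)
  for (i in hit) {
    codon_idx <- (i - 1L) %/% 3L
    if (codon_idx %in% protect) next
    old <- nt[i]
    if (!old %in% c("A", "C", "G", "T")) next
    # candidate bases in preference order (transition first with the
    # configured odds); a candidate creating a stop or a cysteine is
    # rejected and the next one tried, keeping the realised rate close to
    # nominal
    tv <- sample(transversions[[old]])
    cands <- if (runif(1) < ts_tv_ratio / (ts_tv_ratio + 1)) {
      c(transitions[[old]], tv)
    } else c(tv, transitions[[old]])
    cstart <- codon_idx * 3L + 1L
    cod <- nt[cstart:(cstart + 2L)]
    for (new in cands) {
      cod2 <- cod
      cod2[i - cstart + 1L] <- new
      new_aa <- gc[paste(cod2, collapse = "")]
      if (!is.na(new_aa) && !new_aa %in% c("*", "C")) {
        nt[i] <- new
        break
      }
    }
  }
  paste(nt, collapse = "")
}

make_ancestors <- function(cfg) {
  anc <- list()
  for (g in cfg$genome_labels) {
    units <- cfg$repeat_units[[g]]
    n1 <- sample(seq(cfg$r1_repeats[[g]][1], cfg$r1_repeats[[g]][2]), 1L)
    n2 <- sample(seq(cfg$r2_repeats[[g]][1], cfg$r2_repeats[[g]][2]), 1L)
    r1 <- sample_units(units, n1)
    r2 <- sample_units(units, n2)
    nt <- reverse_translate(build_gene_aa(r1, r2))
    nt <- mutate_sequence(nt, cfg$between_genome_divergence / 2,
                          cfg$ts_tv_ratio)
    anc[[g]] <- list(nt = nt, r1 = r1, r2 = r2, units = units)
  }
  anc
}

draw_genes_from <- function(anc, cfg, n_per_genome, prefix) {
  rows <- list()
  doms <- list()
  for (g in cfg$genome_labels) {
    a <- anc[[g]]
    for (k in seq_len(n_per_genome)) {
      r1 <- a$r1; r2 <- a$r2
      if (cfg$repeat_jitter) {
        j <- sample(c(-1L, 0L, 1L), 1L, prob = c(0.25, 0.5, 0.25))
        if (j == -1L && length(r1) > 1L) r1 <- r1[-length(r1)]
        if (j == 1L) r1 <- c(r1, sample_units(a$units, 1L))
      }
      nt <- reverse_translate(build_gene_aa(r1, r2))
      nt <- mutate_sequence(nt, cfg$within_genome_divergence / 2,
                            cfg$ts_tv_ratio)
      id <- sprintf("%s_%s%d", g, prefix, k)
      rows[[id]] <- tibble(id = id, desc = paste0("genome=", g), seq = nt,
                           source = g, depth_hint = 1L)
      d <- truth_domains_of(r1, r2)
      d$id <- id
      doms[[id]] <- d[c("id", "domain", "start", "end")]
    }
  }
  list(genes = bind_rows(rows), domains = bind_rows(doms))
}

# independent brute-force window scan used only to record planted truth
count_planted_epitopes <- function(aa, registry) {
  counts <- integer(nrow(registry))
  for (e in seq_len(nrow(registry))) {
    core <- registry$core[e]
    hits <- 0L
    if (nchar(aa) >= 9L)
      for (s in 1:(nchar(aa) - 8L))
        if (substr(aa, s, s + 8L) == core) hits <- hits + 1L
    counts[e] <- hits
  }
  tibble(epitope = registry$label, instances = counts)
}

#' Generate synthetic gamma-gliadin genes with ground truth
#'
#' Builds per-genome ancestral genes from the repeat grammar and derives
#' `n_per_genome` genes per genome by seeded substitution. Returns the gene
#' records together with the construction truth: domain intervals, protein,
#' and per-epitope planted instance counts (counted by an independent
#' brute-force window scan).
#'
#' @param cfg A [synthetic_config()].
#' @param n_per_genome Genes per genome (default `cfg$genes_per_genome`).
#' @param prefix Id prefix, `"g"` for expressed genes, `"r"` for genomic
#'   references.
#' @param registry Epitope registry used for the truth counts.
#' @return List: `genes` (sequence tibble with `source` genome labels),
#'   `truth_domains`, `truth_proteins` (`id`, `aa`), `truth_epitopes`
#'   (`id`, `epitope`, `instances`), `ancestors` (internal, reusable via the
#'   `ancestors` argument).
#' @param ancestors Reuse the per-genome ancestors from a previous call so
#'   that references and expressed genes descend from the same family.
#' @export
generate_reference_genes <- function(cfg, n_per_genome = NULL, prefix = "g",
                                     ancestors = NULL,
                                     registry = default_epitope_registry()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_per_genome <- n_per_genome %||% cfg$genes_per_genome
  with_seed(cfg$seed + match(prefix, c("g", "r"), nomatch = 3L) * 1000L, {
    if (is.null(ancestors)) ancestors <- make_ancestors(cfg)
    drawn <- draw_genes_from(ancestors, cfg, n_per_genome, prefix)
    prots <- translate_cds(drawn$genes)
    if (any(prots$truncated))
      abort("internal: generator produced a truncated protein")
    truth_ep <- bind_rows(lapply(seq_len(nrow(prots)), function(k) {
      te <- count_planted_epitopes(prots$aa[k], registry)
      te$id <- prots$id[k]
      te[c("id", "epitope", "instances")]
    }))
    list(genes = drawn$genes, truth_domains = drawn$domains,
         truth_proteins = prots[c("id", "aa")], truth_epitopes = truth_ep,
         ancestors = ancestors)
  })
}

#' Sample transcripts from synthetic genes
#'
#' Per gene, a transcript depth is drawn log-uniformly from
#' `cfg$depth_range` (skewed toward low depth, emulating the wide redundancy
#' range of EST sets). With probability `cfg$pseudogene_rate` a gene receives
#' a C->T transition converting a CAA codon in R1 to a TAA stop, carried by
#' all of its transcripts. Transcripts are optionally 5'-truncated
#' (codon-aligned) and carry independent per-base errors at
#' `cfg$transcript_error_rate`.
#'
#' @param genes Output of [generate_reference_genes()].
#' @param cfg The [synthetic_config()] used to generate them.
#' @return List: `transcripts` (sequence tibble), `truth` (tibble
#'   `transcript_id`, `gene_id`, `genome`, `pseudogene`, `truncated_5p`).
#' @export
sample_transcripts <- function(genes, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  gene_tbl <- genes$genes
  doms <- genes$truth_domains
  with_seed(cfg$seed + 7919L, {
    recs <- list(); truth <- list()
    tcount <- 0L
    for (k in seq_len(nrow(gene_tbl))) {
      gid <- gene_tbl$id[k]
      nt <- gene_tbl$seq[k]
      gdom <- doms[doms$id == gid, ]
      depth <- if (cfg$depth_range[1] == cfg$depth_range[2]) {
        cfg$depth_range[1]
      } else {
        as.integer(round(exp(runif(1, log(cfg$depth_range[1]),
                                   log(cfg$depth_range[2])))))
      }
      pseudo <- runif(1) < cfg$pseudogene_rate
      stop_nt <- NA_integer_
      if (pseudo) {
        r1 <- gdom[gdom$domain == "R1", ]
        cods <- codon_split(nt)
        r1_cod <- (r1$start):(r1$end - 1L)
        qpos <- r1_cod[cods[r1_cod + 1L] == "CAA"]
        if (length(qpos) > 0L) {
          at <- qpos[ceiling(length(qpos) / 2)]
          substr(nt, at * 3L + 1L, at * 3L + 1L) <- "T"
          stop_nt <- at * 3L
        } else pseudo <- FALSE
      }
      nr1_start_nt <- gdom$start[gdom$domain == "NR1"] * 3L
      # truncation must not cut away an injected stop codon
      if (!is.na(stop_nt)) nr1_start_nt <- min(nr1_start_nt, stop_nt)
      for (t in seq_len(depth)) {
        tcount <- tcount + 1L
        tid <- sprintf("t%05d", tcount)
        ts <- nt
        trunc5 <- FALSE
        if (runif(1) < cfg$truncate_prob) {
          max_cut_nt <- min(nr1_start_nt, nchar(nt) - 310L)
          cuts <- seq(30L, max_cut_nt %/% 30L * 30L, by = 30L)
          if (length(cuts) > 0L && max_cut_nt >= 30L) {
            cut <- sample(cuts, 1L)
            ts <- substr(ts, cut + 1L, nchar(ts))
            trunc5 <- TRUE
          }
        }
        if (cfg$transcript_error_rate > 0) {
          ch <- chars(ts)
          err <- which(runif(length(ch)) < cfg$transcript_error_rate)
          for (i in err)
            ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
          ts <- paste(ch, collapse = "")
        }
        recs[[tid]] <- tibble(id = tid,
                              desc = paste0("gene=", gid, " genome=",
                                            gene_tbl$source[k]),
                              seq = ts, source = gene_tbl$source[k],
                              depth_hint = 1L)
        truth[[tid]] <- tibble(transcript_id = tid, gene_id = gid,
                               genome = gene_tbl$source[k],
                               pseudogene = pseudo, truncated_5p = trunc5)
      }
    }
    list(transcripts = bind_rows(recs), truth = bind_rows(truth))
  })
}

#' Write a synthetic dataset to disk
#'
#' @param refs Output of [generate_reference_genes()] (genomic references).
#' @param transcripts Output of [sample_transcripts()].
#' @param outdir Output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
emit_synthetic <- function(refs, transcripts, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    references = file.path(outdir, "references.fasta"),
    transcripts = file.path(outdir, "transcripts.fasta"),
    truth_transcripts = file.path(outdir, "truth_transcripts.tsv"),
    truth_domains = file.path(outdir, "truth_domains.tsv"),
    truth_epitopes = file.path(outdir, "truth_epitopes.tsv"))
  write_fasta(refs$genes, paths["references"])
  write_fasta(transcripts$transcripts, paths["transcripts"])
  write.table(transcripts$truth, paths["truth_transcripts"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(refs$truth_domains, paths["truth_domains"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(refs$truth_epitopes, paths["truth_epitopes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Generate a full synthetic dataset (references, genes, transcripts, truth)
#'
#' Convenience wrapper: one family of genome ancestors, a set of genomic
#' reference clones and a set of expressed genes descending from them, and
#' transcripts sampled from the expressed genes.
#'
#' @param cfg A [synthetic_config()].
#' @return List `references`, `genes`, `transcripts` (each with their truth
#'   tables as returned by the underlying generators).
#' @export
simulate_gliadin_dataset <- function(cfg) {
  genes <- generate_reference_genes(cfg, prefix = "g")
  refs <- generate_reference_genes(cfg, n_per_genome = cfg$ref_genes_per_genome,
                                   prefix = "r", ancestors = genes$ancestors)
  tx <- sample_transcripts(genes, cfg)
  list(references = refs, genes = genes, transcripts = tx)
}
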