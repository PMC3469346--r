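#' Build a pipeline configuration
#'
#' @param transcripts Path to the transcript FASTA (coding strand).
#' @param references Path to the genomic reference FASTA; headers must carry
#'   `genome=<label>` tags (see [read_fasta()]).
#' @param outdir Output directory.
#' @param registry Optional path to an epitope registry TSV; default registry
#'   when `NULL`.
#' @param identity_threshold,min_members,min_overlap Clustering parameters
#'   (see [cluster_transcripts()]).
#' @param model,gap_mode Distance model and gap handling (see
#'   [compute_distances()]).
#' @param min_margin Assignment margin (see [assign_genome()]).
#' @param region Assignment/census region, `"domain3to5"` or `"full"`.
#' @param census_region `"full"` or `"r1_nr2"` (see [census()]).
#' @param include_pseudogenes Include internal-stop contigs in the census.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(transcripts, references, outdir,
                            registry = NULL,
                            identity_threshold = 0.98, min_members = 4L,
                            min_overlap = 300L, model = "K2P",
                            gap_mode = "pairwise_deletion",
                            min_margin = 0.01, region = "domain3to5",
                            census_region = "full",
                            include_pseudogenes = FALSE, seed = 1L) {
  structure(list(transcripts = transcripts, references = references,
                 outdir = outdir, registry = registry,
                 identity_threshold = identity_threshold,
                 min_members = as.integer(min_members),
                 min_overlap = as.integer(min_overlap), model = model,
                 gap_mode = gap_mode, min_margin = min_margin,
                 region = region, census_region = census_region,
                 include_pseudogenes = include_pseudogenes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the full epitope-census pipeline
#'
#' Read transcripts and references, cluster transcripts into contigs, call
#' consensus sequences, translate, flag pseudogenes, assign each contig to
#' its genome of origin, scan deduced proteins for CD-epitope cores, and
#' aggregate the depth-weighted per-locus census. All intermediates are
#' written as FASTA/TSV into `outdir`, together with the echoed configuration
#' and a run manifest (package version, seed, parameter and output hashes).
#' The run is deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()] or the path to its JSON serialisation.
#' @return Invisibly, a list with `contigs`, `assignments`, `census`,
#'   `matches` and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$transcripts, config$references,
              if (!is.null(config$registry)) config$registry)) {
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- file.path(config$outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       null = "null")
  registry <- if (is.null(config$registry)) default_epitope_registry() else
    read_epitope_registry(config$registry)

  message("[gliascan] reading inputs")
  transcripts <- read_fasta(config$transcripts)
  references <- read_fasta(config$references)
  if (all(is.na(references$source)))
    abort("references carry no genome=<label> tags")

  message("[gliascan] clustering ", nrow(transcripts), " transcripts")
  contigs <- cluster_transcripts(transcripts,
                                 identity_threshold = config$identity_threshold,
                                 min_members = config$min_members,
                                 min_overlap = config$min_overlap)
  members <- contig_members(contigs)
  proteins <- translate_cds(contigs |>
                              select(id = "contig_id", seq = "consensus")) |>
    detect_pseudogene()
  seg <- segment_domains(proteins |> filter(nchar(.data$aa) >= 20L))

  message("[gliascan] assigning ", nrow(contigs), " contigs")
  assignments <- assign_genome(contigs, references, model = config$model,
                               gap_mode = config$gap_mode,
                               min_margin = config$min_margin,
                               region = config$region)

  message("[gliascan] scanning epitopes")
  matches <- scan_epitopes(proteins, registry)
  cens <- census(contigs, assignments, registry,
                 include_pseudogenes = config$include_pseudogenes,
                 region = config$census_region)

  paths <- c(config = cfg_json,
             contigs = file.path(config$outdir, "contigs.fasta"),
             membership = file.path(config$outdir, "membership.tsv"),
             proteins = file.path(config$outdir, "proteins.fasta"),
             segmentation = file.path(config$outdir, "segmentation.tsv"),
             assignments = file.path(config$outdir, "assignments.tsv"),
             matches = file.path(config$outdir, "matches.tsv"),
             census = file.path(config$outdir, "census.tsv"),
             census_json = file.path(config$outdir, "census.json"),
             manifest = file.path(config$outdir, "manifest.json"))
  write_fasta(contigs |> select(id = "contig_id", seq = "consensus"),
              paths["contigs"])
  write_tsv0 <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_tsv0(members, paths["membership"])
  write_fasta(proteins |> select(id = "id", seq = "aa"), paths["proteins"])
  write_tsv0(seg, paths["segmentation"])
  write_tsv0(assignments |> select(-dplyr::any_of("reason")),
             paths["assignments"])
  write_tsv0(matches, paths["matches"])
  render_report(cens, paths["census"])
  census_json(cens, paths["census_json"])

  manifest <- list(
    package = "gliascan",
    version = as.character(utils::packageVersion("gliascan")),
    seed = config$seed,
    parameter_hash = rlang::hash(unclass(config)),
    n_transcripts = nrow(transcripts),
    n_contigs = nrow(contigs),
    output_md5 = as.list(tools::md5sum(unname(paths[setdiff(names(paths),
                                                            "manifest")]))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(contigs = contigs, assignments = assignments, census = cens,
                 matches = matches, paths = paths))
}
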