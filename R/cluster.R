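#' Cluster near-identical transcripts into contigs
#'
#' Single-linkage clustering on the graph whose edges join transcript pairs
#' with pairwise identity at least `identity_threshold` over an aligned
#' overlap of at least `min_overlap` nucleotides ([align_overlap()]).
#' Single linkage is used because an identity band (e.g. 98-99%) implies
#' transitive merging; free terminal gaps let partial ESTs cluster with
#' full-length cDNAs. Clusters with fewer than `min_members` transcripts are
#' diverted to a "minor" bin rather than reported as contigs. The result is
#' deterministic: contig ids are assigned by descending depth, ties broken by
#' the lexicographically smallest member id.
#'
#' @param records Sequence tibble (see [read_fasta()]).
#' @param identity_threshold Identity fraction in (0, 1], default 0.98.
#' @param min_members Minimum transcripts per contig, default 4.
#' @param min_overlap Minimum aligned overlap in nucleotides, default 300
#'   (the scale of the shortest contigs the method is designed for).
#' @return Tibble with one row per contig: `contig_id`, `depth`,
#'   `member_ids` (list column), `consensus`. The transcripts diverted to the
#'   minor bin are available via `attr(x, "minor_ids")` and in tidy form via
#'   [contig_members()].
#' @export
cluster_transcripts <- function(records, identity_threshold = 0.98,
                                min_members = 4L, min_overlap = 300L) {
  stopifnot(nrow(records) >= 1L,
            identity_threshold > 0, identity_threshold <= 1,
            min_members >= 1L)
  n <- nrow(records)
  ids <- records$id
  # exact duplicates collapse to one vertex; identity(a, a) = 1 always joins
  uniq <- match(records$seq, unique(records$seq))
  useqs <- unique(records$seq)
  nu <- length(useqs)
  edges <- integer(0)
  if (nu > 1L) {
    for (i in seq_len(nu - 1L)) {
      al <- .nw_overlap_many(useqs[(i + 1L):nu], useqs[i])
      idn <- map_dbl(al, "identity")
      cols <- map_int(al, "columns")
      hit <- which(idn >= identity_threshold & cols >= min_overlap)
      if (length(hit))
        edges <- c(edges, rbind(i, i + hit))
    }
  }
  g <- igraph::make_empty_graph(n = nu, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  cluster_of <- comp[uniq]

  members <- split(ids, cluster_of)
  depth <- lengths(members)
  keep <- depth >= min_members
  minor_ids <- unlist(members[!keep], use.names = FALSE) %||% character(0)
  members <- members[keep]
  if (length(members) == 0L) {
    out <- tibble(contig_id = character(), depth = integer(),
                  member_ids = list(), consensus = character())
    attr(out, "minor_ids") <- minor_ids
    return(out)
  }
  ord <- order(-lengths(members), map_chr(members, min))
  members <- members[ord]
  seq_by_id <- setNames(records$seq, ids)
  out <- tibble(
    contig_id = sprintf("ctg%03d", seq_along(members)),
    depth = unname(lengths(members)),
    member_ids = unname(members),
    consensus = unname(map_chr(members, ~ call_consensus(seq_by_id[.x]))))
  attr(out, "minor_ids") <- minor_ids
  out
}

#' Tidy membership table of a contig set
#'
#' @param contigs Output of [cluster_transcripts()].
#' @return Tibble `transcript_id`, `contig_id`; minor-bin transcripts carry
#'   contig id `"minor"`.
#' @export
contig_members <- function(contigs) {
  major <- contigs |>
    select("contig_id", "member_ids") |>
    tidyr::unnest_longer("member_ids", values_to = "transcript_id") |>
    select("transcript_id", "contig_id")
  minor <- attr(contigs, "minor_ids") %||% character(0)
  bind_rows(major,
            tibble(transcript_id = minor,
                   contig_id = rep("minor", length(minor))))
}

#' Majority-vote consensus of near-identical sequences
#'
#' Members are star-aligned against the longest member with the semi-global
#' aligner; each reference column takes the strict majority base over the
#' members covering it (terminal gaps do not vote, so partial ESTs never
#' erode the consensus ends; internal gaps vote as gap). Ties are broken in
#' the fixed base order A < C < G < T, and columns whose majority vote is a
#' gap are dropped.
#'
#' @param members Character vector of nucleotide sequences (or a sequence
#'   tibble).
#' @return Consensus nucleotide string.
#' @export
call_consensus <- function(members) {
  if (is.data.frame(members)) members <- members$seq
  stopifnot(length(members) >= 1L)
  if (length(unique(members)) == 1L) return(members[[1]])
  ref <- members[[which.max(nchar(members))]]
  nref <- nchar(ref)
  votes <- matrix("", nrow = length(members), ncol = nref)
  for (k in seq_along(members)) {
    al <- .nw_overlap(members[[k]], ref)
    bpos <- al$b_start # 0-based position in ref of next aligned ref char
    ca <- chars(al$aligned_a)
    cb <- chars(al$aligned_b)
    for (j in seq_along(cb)) {
      if (cb[j] != "-") {
        votes[k, bpos + 1L] <- ca[j] # '-' records a deletion vote
        bpos <- bpos + 1L
      } # insertions relative to the reference are dropped
    }
  }
  base_order <- c("A", "C", "G", "T", "-")
  cons <- character(nref)
  for (j in seq_len(nref)) {
    v <- votes[, j]
    v <- v[v != ""]
    if (length(v) == 0L) { cons[j] <- substr(ref, j, j); next }
    tab <- table(factor(v, levels = unique(c(base_order, v))))
    top <- names(tab)[tab == max(tab)]
    pick <- base_order[base_order %in% top][1] %||% top[1]
    if (is.na(pick)) pick <- top[1]
    cons[j] <- pick
  }
  paste(cons[cons != "-"], collapse = "")
}
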