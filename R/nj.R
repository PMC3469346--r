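#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion. Ties in Q are broken by the
#' lowest pair of label indices; negative branch lengths are clamped to zero
#' with the deficit transferred to the sister branch, so all branch lengths
#' are non-negative. Returns an unrooted `ape::phylo` tree; the total branch
#' length is available as `attr(tree, "total_branch_length")`.
#'
#' @param dm Distance matrix from [compute_distances()] (or any symmetric
#'   labelled matrix with zero diagonal and finite entries).
#' @return An object of class `phylo`.
#' @export
build_nj <- function(dm) {
  d <- unclass(dm)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3L) abort("neighbor joining requires at least 3 taxa")
  if (!all(is.finite(d))) abort("non-finite distances")
  # each active node carries its newick subtree representation
  rep_nwk <- labels
  active <- seq_len(n)
  total_bl <- 0
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(active) > 3L) {
    N <- length(active)
    sub <- d[active, active]
    r <- rowSums(sub)
    q <- (N - 2) * sub - outer(r, r, "+")
    diag(q) <- Inf
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      if (q[i, j] < best - 1e-12) { best <- q[i, j]; bi <- i; bj <- j }
    }
    dij <- sub[bi, bj]
    vi <- 0.5 * dij + (r[bi] - r[bj]) / (2 * (N - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
    total_bl <- total_bl + vi + vj
    ai <- active[bi]; aj <- active[bj]
    new_rep <- paste0("(", rep_nwk[ai], ":", fmt(vi), ",",
                      rep_nwk[aj], ":", fmt(vj), ")")
    # new node distances
    others <- active[-c(bi, bj)]
    newd <- 0.5 * (d[ai, others] + d[aj, others] - dij)
    d <- rbind(cbind(d, 0), 0)
    u <- nrow(d)
    d[u, others] <- d[others, u] <- newd
    rep_nwk <- c(rep_nwk, new_rep)
    active <- c(others, u)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  vb <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  vc <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  total_bl <- unname(total_bl + max(va, 0) + max(vb, 0) + max(vc, 0))
  nwk <- paste0("(", rep_nwk[a], ":", fmt(va), ",", rep_nwk[b], ":", fmt(vb),
                ",", rep_nwk[c3], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "total_branch_length") <- total_bl
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate alignment is run through [compute_distances()] and [build_nj()],
#' and the support of every internal bipartition of the original tree is the
#' percentage of replicate trees containing it. A single integer seed makes
#' the resampling reproducible.
#'
#' @inheritParams compute_distances
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param seed Integer RNG seed.
#' @return The original `phylo` tree with `node.label` set to supports in
#'   `[0, 100]` (the root label is `NA`).
#' @export
bootstrap_support <- function(alignment, model = "K2P",
                              gap_mode = "pairwise_deletion",
                              n_reps = 500L, seed = 1L) {
  if (n_reps < 1L) abort("n_reps must be >= 1")
  if (is.data.frame(alignment)) {
    seqs <- setNames(alignment$seq, alignment$id)
  } else seqs <- alignment
  len <- unique(nchar(seqs))
  if (length(len) != 1L) abort("sequences must be aligned to equal length")
  orig <- build_nj(compute_distances(seqs, model = model,
                                     gap_mode = gap_mode))
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  boot <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rs <- setNames(apply(mat[, idx, drop = FALSE], 1, paste, collapse = ""),
                   names(seqs))
    dmr <- suppressWarnings(compute_distances(rs, model = model,
                                              gap_mode = gap_mode))
    boot[[r]] <- build_nj(dmr)
  }
  counts <- ape::prop.clades(orig, boot, rooted = FALSE)
  supports <- round(100 * counts / n_reps)
  supports[1] <- NA # root bipartition is trivial on an unrooted tree
  orig$node.label <- supports
  orig
}
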