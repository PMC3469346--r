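#' Pairwise nucleotide distances from an alignment
#'
#' Distances in substitutions per site under the p (uncorrected), JC69 or K2P
#' model. Sites containing anything other than A/C/G/T (gaps, N, ambiguity
#' codes) are excluded per sequence pair (`pairwise_deletion`) or from the
#' whole alignment (`complete_deletion`). Saturated pairs (logarithm argument
#' of the correction non-positive) are capped at `saturation_cap` with a
#' warning and recorded in the `saturated` attribute rather than emitted as
#' infinities.
#'
#' @param alignment Tibble of aligned sequences (columns `id`, `seq`, equal
#'   lengths) or a named character vector.
#' @param model One of `"K2P"` (default), `"JC69"`, `"p"`.
#' @param gap_mode `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @param saturation_cap Distance assigned to saturated pairs (default 5).
#' @return A symmetric labelled matrix of class `nt_dist` with attributes
#'   `model`, `gap_mode` and `saturated` (tibble of flagged pairs).
#' @examples
#' aln <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGA"))
#' compute_distances(aln, model = "p")
#' @export
compute_distances <- function(alignment,
                              model = c("K2P", "JC69", "p"),
                              gap_mode = c("pairwise_deletion",
                                           "complete_deletion"),
                              saturation_cap = 5) {
  model <- match.arg(model)
  gap_mode <- match.arg(gap_mode)
  if (is.data.frame(alignment)) {
    seqs <- setNames(alignment$seq, alignment$id)
  } else {
    seqs <- alignment
  }
  n <- length(seqs)
  stopifnot(n >= 2L)
  if (length(unique(nchar(seqs))) != 1L)
    abort("sequences must be aligned to equal length")
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  valid <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  if (gap_mode == "complete_deletion") {
    keep <- apply(valid, 2, all)
    mat <- mat[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  labels <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- list()
  is_transition <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      nsite <- sum(ok)
      if (nsite == 0L) abort(paste0("no comparable sites between ",
                                    labels[i], " and ", labels[j]))
      xi <- mat[i, ok]; xj <- mat[j, ok]
      diffs <- xi != xj
      p <- sum(diffs) / nsite
      val <- switch(model,
        p = p,
        JC69 = {
          arg <- 1 - 4 * p / 3
          if (arg <= 0) NA_real_ else -0.75 * log(arg)
        },
        K2P = {
          P <- sum(diffs & is_transition(xi, xj)) / nsite
          Q <- sum(diffs & !is_transition(xi, xj)) / nsite
          a1 <- 1 - 2 * P - Q
          a2 <- 1 - 2 * Q
          if (a1 <= 0 || a2 <= 0) NA_real_
          else 0.5 * log(1 / a1) + 0.25 * log(1 / a2)
        })
      if (is.na(val)) {
        sat[[length(sat) + 1L]] <- tibble(id1 = labels[i], id2 = labels[j])
        val <- saturation_cap
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  sat <- if (length(sat)) bind_rows(sat) else
    tibble(id1 = character(), id2 = character())
  if (nrow(sat) > 0L)
    warn(paste0(nrow(sat), " saturated pair(s) capped at ", saturation_cap,
                " substitutions/site"))
  structure(d, class = c("nt_dist", class(d)),
            model = model, gap_mode = gap_mode, saturated = sat)
}

#' @export
tidy.nt_dist <- function(x, ...) {
  labels <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(id1 = labels[idx[, 1]], id2 = labels[idx[, 2]],
         distance = x[idx]) |>
    arrange(.data$id1, .data$id2)
}

#' Within- and between-group mean distances
#'
#' Within-group mean is the average over unordered within-group pairs;
#' between-group means average over all cross pairs of each group pair.
#' Groups with a single member have no within-group pairs and are reported
#' with `NA`.
#'
#' @param dm Distance matrix from [compute_distances()].
#' @param groups Named character vector or tibble (`id`, `group`) mapping
#'   every label of `dm` to a group.
#' @return List of two tibbles: `within` (`group`, `n`, `mean_distance`) and
#'   `between` (`group1`, `group2`, `mean_distance`).
#' @export
group_distances <- function(dm, groups) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$id)
  labels <- rownames(dm)
  if (!all(labels %in% names(groups)))
    abort("every distance-matrix label must be grouped")
  g <- unname(groups[labels])
  pairs <- tidy.nt_dist(dm) |>
    mutate(g1 = unname(groups[.data$id1]), g2 = unname(groups[.data$id2]))
  within <- tibble(group = sort(unique(g))) |>
    mutate(n = map_int(.data$group, ~ sum(g == .x)),
           mean_distance = map_dbl(.data$group, function(gr) {
             w <- pairs$distance[pairs$g1 == gr & pairs$g2 == gr]
             if (length(w) == 0L) NA_real_ else mean(w)
           }))
  cross <- pairs |>
    filter(.data$g1 != .data$g2) |>
    mutate(group1 = pmin(.data$g1, .data$g2),
           group2 = pmax(.data$g1, .data$g2)) |>
    group_by(.data$group1, .data$group2) |>
    summarise(mean_distance = mean(.data$distance), .groups = "drop")
  list(within = within, between = cross)
}
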