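DOMAIN_ORDER <- c("S", "I", "R1", "NR1", "R2", "NR2")

# P/Q content of the 8-residue window starting at 0-based position i
pq_window_ok <- function(res, i, min_frac = 0.5, width = 8L) {
  if (i + width > length(res)) return(NA)
  mean(res[(i + 1):(i + width)] %in% c("P", "Q")) >= min_frac
}

# first 0-based position at/after `from` where the 8-window is P/Q-rich and
# the position itself is a repeat residue (P or Q); NA if none. Requiring the
# boundary residue to be P/Q keeps windows that merely straddle the upstream
# domain from pulling the boundary left.
find_repeat_start <- function(res, from) {
  for (i in from:(length(res) - 1L)) {
    ok <- pq_window_ok(res, i)
    if (is.na(ok)) return(NA_integer_)
    if (ok && res[i + 1L] %in% c("P", "Q")) return(i)
  }
  NA_integer_
}

# first 0-based position after `from` where the window is P/Q-poor and the
# position itself is not P/Q: the start of a non-repetitive domain
find_repeat_end <- function(res, from) {
  if (from > length(res) - 1L) return(NA_integer_)
  for (i in from:(length(res) - 1L)) {
    ok <- pq_window_ok(res, i)
    if (is.na(ok)) return(NA_integer_)
    if (!ok && !(res[i + 1L] %in% c("P", "Q"))) return(i)
  }
  NA_integer_
}

segment_one <- function(aa, signal_length, full_length) {
  res <- chars(aa)
  n <- length(res)
  npc <- as.integer(stringi::stri_locate_first_fixed(aa, "NPC")[1, 1]) - 1L
  mcn_all <- stringi::stri_locate_all_fixed(aa, "MCN")[[1]]
  mcn <- if (is.na(mcn_all[1, 1])) NA_integer_ else
    as.integer(mcn_all[nrow(mcn_all), 1]) - 1L
  anchors <- c(if (!is.na(npc)) "NPC", if (!is.na(mcn)) "MCN")
  anchor_str <- if (length(anchors)) paste(anchors, collapse = ",") else ""

  add <- function(doms, domain, start, end) {
    if (is.na(start) || is.na(end) || end <= start) return(doms)
    bind_rows(doms, tibble(domain = domain, start = start, end = end))
  }
  doms <- tibble(domain = character(), start = integer(), end = integer())

  sig_end <- if (full_length && n > signal_length) signal_length else 0L
  if (sig_end > 0L) doms <- add(doms, "S", 0L, sig_end)

  r1_start <- find_repeat_start(res, sig_end)
  if (is.na(npc)) {
    # no NPC anchor: domains III-V cannot be placed
    i_end <- if (!is.na(r1_start)) r1_start else n
    doms <- add(doms, "I", sig_end, i_end)
    if (!is.na(r1_start)) doms <- add(doms, "R1", r1_start, n)
    return(list(doms = doms, anchors = anchor_str))
  }
  if (is.na(r1_start) || r1_start > npc) r1_start <- npc
  doms <- add(doms, "I", sig_end, r1_start)
  doms <- add(doms, "R1", r1_start, npc)

  # NR1 runs from the NPC anchor to the first repeat window after its sixth
  # cysteine (the six conserved cysteines of domain III)
  cys <- which(res == "C") - 1L
  cys_nr1 <- cys[cys >= npc & (is.na(mcn) | cys < mcn)]
  scan_from <- if (length(cys_nr1) >= 6L) cys_nr1[6L] + 1L else npc + 3L
  r2_start <- find_repeat_start(res, scan_from)
  nr2_end <- if (!is.na(mcn)) mcn + 3L else NA_integer_

  if (is.na(r2_start) || (!is.na(mcn) && r2_start >= mcn)) {
    # no repeat resumes after NR1: NR1 extends to NR2 (or protein end)
    doms <- add(doms, "NR1", npc, if (!is.na(nr2_end)) nr2_end else n)
    return(list(doms = doms, anchors = anchor_str))
  }
  doms <- add(doms, "NR1", npc, r2_start)
  nr2_start <- find_repeat_end(res, r2_start + 1L)
  if (is.na(mcn)) {
    doms <- add(doms, "R2", r2_start, if (!is.na(nr2_start)) nr2_start else n)
    return(list(doms = doms, anchors = anchor_str))
  }
  if (is.na(nr2_start) || nr2_start >= nr2_end) nr2_start <- mcn
  doms <- add(doms, "R2", r2_start, nr2_start)
  doms <- add(doms, "NR2", nr2_start, nr2_end)
  list(doms = doms, anchors = anchor_str)
}

#' Segment gamma-gliadin proteins into their canonical domains
#'
#' Gamma-gliadins have the architecture signal peptide (S), unique N-terminal
#' domain (I), repetitive domain R1, conserved non-repetitive domain NR1
#' (six conserved cysteines, starts at the NPC motif), repetitive domain R2,
#' and conserved non-repetitive domain NR2 (two cysteines, ends in the MCN
#' motif). NR1 is anchored at the first `NPC` occurrence and NR2 ends after
#' the last `MCN`. The I/R1 boundary is the first position that is itself P
#' or Q and starts an 8-residue window with at least 50% P/Q; the NR1/R2
#' boundary is the first such position after the sixth cysteine of NR1; the
#' R2/NR2 boundary is the first non-P/Q position after R2 whose window drops
#' below 50% P/Q. Intervals are 0-based, half-open, in protein coordinates.
#' Absent domains are omitted rather than reported as empty intervals. When
#' neither anchor is found only S/I (and a trailing R1, if a repeat region is
#' detected) are populated; this is never an error.
#'
#' @param proteins Protein tibble from [translate_cds()] (columns `id`, `aa`).
#' @param signal_length Fixed signal-peptide length in residues (default 19).
#'   The signal peptide is not predicted; full-length gliadins carry a
#'   19-residue signal by convention here.
#' @param full_length Logical vector (recycled): is each protein full-length
#'   (signal present)? Defaults to `aa` starting with `M`.
#' @return Tibble with columns `id`, `domain` (one of S, I, R1, NR1, R2,
#'   NR2), `start`, `end`, `anchors` (comma-joined subset of "NPC","MCN").
#' @export
segment_domains <- function(proteins, signal_length = 19L,
                            full_length = NULL) {
  stopifnot(all(c("id", "aa") %in% names(proteins)))
  if (any(nchar(proteins$aa) < 20L))
    abort("segment_domains requires proteins of length >= 20")
  if (is.null(full_length)) full_length <- startsWith(proteins$aa, "M")
  full_length <- rep_len(full_length, nrow(proteins))
  out <- vector("list", nrow(proteins))
  for (k in seq_len(nrow(proteins))) {
    s <- segment_one(proteins$aa[k], signal_length, full_length[k])
    d <- s$doms
    d$id <- proteins$id[k]
    d$anchors <- s$anchors
    out[[k]] <- d
  }
  bind_rows(out) |>
    select("id", "domain", "start", "end", "anchors") |>
    mutate(domain = factor(.data$domain, levels = DOMAIN_ORDER)) |>
    arrange(.data$id, .data$domain) |>
    mutate(domain = as.character(.data$domain))
}

#' Count cysteines per segmented domain
#'
#' Conforming gamma-gliadins carry exactly six conserved cysteines in NR1 and
#' two in NR2; `qc_flag` is raised per protein when either count deviates.
#'
#' @param proteins Protein tibble (columns `id`, `aa`).
#' @param segmentation Output of [segment_domains()].
#' @return Tibble `id`, `domain`, `n_cys`, `qc_flag` (per-id flag, repeated).
#' @export
count_domain_cysteines <- function(proteins, segmentation) {
  aa_by_id <- setNames(proteins$aa, proteins$id)
  counts <- segmentation |>
    mutate(n_cys = map_int(seq_len(n()), function(k) {
      frag <- substr(aa_by_id[[.data$id[k]]], .data$start[k] + 1L,
                     .data$end[k])
      stringr::str_count(frag, stringr::fixed("C"))
    }))
  flags <- counts |>
    group_by(.data$id) |>
    summarise(qc_flag = sum(.data$n_cys[.data$domain == "NR1"]) != 6L ||
                sum(.data$n_cys[.data$domain == "NR2"]) != 2L)
  counts |>
    select("id", "domain", "n_cys") |>
    left_join(flags, by = "id")
}
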