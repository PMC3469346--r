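# Independent pure-R oracles, deliberately distinct from the package
# implementations.

# fitting alignment of b inside a (all of b consumed, free end gaps in a),
# best of both orientations; returns identity over aligned columns
oracle_fit_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  fit <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    n <- length(ca); m <- length(cb)
    S <- matrix(-Inf, n + 1, m + 1)
    S[, 1] <- 0
    S[1, ] <- (0:m) * gap
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      S[i, j] <- max(S[i - 1, j - 1] +
                       ifelse(ca[i - 1] == cb[j - 1], match, mismatch),
                     S[i - 1, j] + gap, S[i, j - 1] + gap)
    }
    best_i <- which.max(S[, m + 1])
    # traceback for identity
    i <- best_i; j <- m + 1; mt <- 0L; cols <- 0L
    while (j > 1) {
      diag_ok <- i > 1 && S[i, j] == S[i - 1, j - 1] +
        ifelse(ca[i - 1] == cb[j - 1], match, mismatch)
      up_ok <- i > 1 && S[i, j] == S[i - 1, j] + gap
      if (diag_ok) {
        mt <- mt + (ca[i - 1] == cb[j - 1]); cols <- cols + 1L
        i <- i - 1; j <- j - 1
      } else if (up_ok) {
        cols <- cols + 1L; i <- i - 1
      } else {
        cols <- cols + 1L; j <- j - 1
      }
    }
    list(score = max(S[, m + 1]), identity = mt / cols)
  }
  f1 <- fit(a, b); f2 <- fit(b, a)
  list(score = max(f1$score, f2$score),
       identity = if (f1$score > f2$score) f1$identity
                  else if (f2$score > f1$score) f2$identity
                  else max(f1$identity, f2$identity))
}

# naive all-windows epitope scan
oracle_scan <- function(aa, registry = default_epitope_registry()) {
  out <- list()
  n <- nchar(aa)
  if (n >= 9L) {
    for (s in 1:(n - 8L)) {
      win <- substr(aa, s, s + 8L)
      hit <- registry$label[registry$core == win]
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(label = hit, start = s - 1L)
    }
  }
  if (!length(out)) return(data.frame(label = character(), start = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$label), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# P/Q-biased random peptides so epitope matches actually occur
random_gliadinish <- function(n) {
  paste(sample(c("P", "Q", "F", "S", "L", "I", "Y", "A"), n, TRUE,
               prob = c(0.3, 0.35, 0.1, 0.07, 0.05, 0.05, 0.05, 0.03)),
        collapse = "")
}

write_tmp_fasta <- function(records, dir = tempdir()) {
  f <- tempfile(fileext = ".fasta", tmpdir = dir)
  write_fasta(records, f)
  f
}

# the 13 published natural 17-mer variants of the DQ2-gamma-I epitope region
# with their deamidation markup (0-based positions; primary = bold Q,
# moderate = italic Q)
table5_variants <- function() {
  list(
    list(pep = "QPQQPQQSFPQQQQPLI", primary = c(2L, 12L), moderate = 5L),
    list(pep = "QPQQPQQSFPQQQQLMI", primary = 2L,
         moderate = c(5L, 11L, 12L, 13L)),
    list(pep = "QPQQPQQPFPQQQQPLI", primary = c(2L, 5L, 12L),
         moderate = integer(0)),
    list(pep = "QPQQPQQSFPQQQQPAI", primary = c(2L, 12L), moderate = 5L),
    list(pep = "QPQQPQQSFPQQQPSLI", primary = c(2L, 11L), moderate = 5L),
    list(pep = "QPQQPQQSSPQQQQLLI", primary = 2L,
         moderate = c(11L, 12L, 13L)),
    list(pep = "QSQQPQQSSPQQQQLLI", primary = 2L,
         moderate = c(11L, 12L, 13L)),
    list(pep = "QPQQSQQSSPQQQQLLI", primary = integer(0),
         moderate = c(11L, 12L, 13L)),
    list(pep = "QPQQPQQSFPQQQQWMI", primary = 2L,
         moderate = c(5L, 11L, 12L, 13L)),
    list(pep = "QPQQPQQSFPQQQRPFI", primary = c(2L, 12L), moderate = 5L),
    list(pep = "QPQQPQQSFPQQQRSFI", primary = 2L, moderate = c(5L, 12L)),
    list(pep = "QPQQPQQSFPQQQPPFI", primary = c(2L, 11L), moderate = 5L),
    list(pep = "QPQQPQQSFPQQQPPLI", primary = c(2L, 11L), moderate = 5L))
}
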