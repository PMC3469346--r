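# shared helpers

# round half away from zero (base round() is banker's rounding); the census
# shares/frequencies use this convention so 8.51 -> 9 and 10.14 -> 10.1
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# split a nucleotide string into codons, dropping the trailing partial codon
codon_split <- function(seq, frame = 0) {
  s <- substr(seq, frame + 1L, nchar(seq))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) return(character(0))
  starts <- seq(1L, by = 3L, length.out = n_codons)
  substring(s, starts, starts + 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
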