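#' @keywords internal
"_PACKAGE"

#' @useDynLib prfscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Single internal alphabet: uppercase DNA. RNA input (U) is converted at the
# boundary; anything outside A/C/G/T is mapped to N.
canonical_dna <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  gsub("[^ACGTN]", "N", x)
}

revcomp <- function(x) {
  if (!length(x)) return(character(0))
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(x) {
  if (!nzchar(x)) return(0)
  n <- nchar(x)
  gc <- n - nchar(gsub("[GC]", "", x))
  gc / n
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#' @keywords internal
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(BASES, BASES, paste0))), BASES, paste0
  )))
}

# Split a string into consecutive triplets, dropping a trailing partial codon.
codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

# First in-frame stop codon at or downstream of `from` (a codon start) on the
# given sequence; returns its start position or NA when none exists.
next_inframe_stop <- function(seq, from) {
  L <- nchar(seq)
  if (from < 1L || from + 2L > L) return(NA_integer_)
  starts <- seq.int(from, L - 2L, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  hit <- which(cods %in% STOP_CODONS)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1L]]
}

# Nearest in-frame stop codon strictly upstream of `from` (a codon start);
# returns its start position or NA.
prev_inframe_stop <- function(seq, from) {
  if (from - 3L < 1L) return(NA_integer_)
  starts <- seq.int(from - 3L, 1L, by = -3L)
  cods <- substring(seq, starts, starts + 2L)
  hit <- which(cods %in% STOP_CODONS)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1L]]
}

clamp01 <- function(x) pmin(1, pmax(0, x))
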