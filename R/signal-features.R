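# The eleven per-candidate translation signals:
# DIR, RBS1, RBS2, MOTIF, A0, A1, LF50, LF100, HK50, HK100, N.

FEATURE_SCHEMA_VERSION <- "1"

FEATURE_COLS <- c("DIR", "RBS1", "RBS2", "MOTIF", "A0", "A1",
                  "LF50", "LF100", "HK50", "HK100", "N")

# ---- RBS1: Shine-Dalgarno bin score (Prodigal-style) -----------------------

# Exact submotifs of AGGAGG (length 3-6) with their Prodigal match score
# (A positions score 2, G positions 3, minus a constant 2).
.sd_slices <- local({
  sd <- "AGGAGG"
  w <- c(2, 3, 3, 2, 3, 3)
  out <- list()
  for (len in 3:6) for (j in 1:(7 - len)) {
    m <- substr(sd, j, j + len - 1L)
    ctr <- sum(w[j:(j + len - 1L)]) - 2
    key <- m
    if (is.null(out[[key]]) || out[[key]]$ctr < ctr)
      out[[key]] <- list(motif = m, len = len, ctr = ctr)
  }
  out
})

.sd_spacer_flag <- function(spacer, len) {
  if (spacer > 15L) return(NA_integer_)
  if (spacer <= 4L) return(if (len < 5L) 2L else 1L)
  if (spacer <= 10L) return(0L)
  if (spacer <= 12L) return(if (len < 5L) 1L else 2L)
  3L
}

.sd_bin <- function(ctr, flag) {
  # (match score, spacer flag) -> bin; flag 0 is the ideal 5-10 nt spacer.
  key <- paste(ctr, flag)
  bins <- c(
    "6 2" = 1L, "6 3" = 2L, "6 1" = 6L, "6 0" = 13L,
    "8 3" = 3L, "8 2" = 11L, "8 1" = 12L, "8 0" = 15L,
    "9 3" = 3L, "9 2" = 11L, "9 1" = 12L, "9 0" = 16L,
    "11 3" = 10L, "11 2" = 20L, "11 1" = 21L, "11 0" = 22L,
    "12 3" = 10L, "12 2" = 20L, "12 1" = 23L, "12 0" = 24L,
    "14 3" = 10L, "14 2" = 25L, "14 1" = 26L, "14 0" = 27L
  )
  if (key %in% names(bins)) unname(bins[[key]]) else 0L
}

#' Shine-Dalgarno bin score of an upstream window
#'
#' Scores ribosome-binding-site-like content 5' of a slippery site with a
#' 28-bin integer scheme in the style of the Prodigal gene caller: every
#' contiguous submotif of AGGAGG (length 3-6) is located in the window, its
#' spacer (nt between motif end and the E-site codon start, i.e. the window
#' end) is binned, and the highest-scoring (motif, spacer) bin is returned.
#' The full AGGAGG motif at the ideal 5-10 nt spacer scores 27; a window
#' with no SD-like submotif scores 0.
#'
#' @param upstream nucleotide string ending at the base immediately before
#'   the E-site codon (21 nt is sufficient; longer input is allowed, bases
#'   beyond the scanned spacer range cannot change the score).
#' @return integer bin in 0-27.
#' @export
score_rbs_prodigal <- function(upstream) {
  upstream <- canonical_dna(upstream)
  n <- nchar(upstream)
  best <- 0L
  if (n < 3L) return(best)
  for (sl in .sd_slices) {
    len <- sl$len
    if (n < len) next
    for (pos in 1:(n - len + 1L)) {
      if (substr(upstream, pos, pos + len - 1L) != sl$motif) next
      spacer <- n - (pos + len - 1L)
      flag <- .sd_spacer_flag(spacer, len)
      if (is.na(flag)) next
      bin <- .sd_bin(sl$ctr, flag)
      if (bin > best) best <- bin
    }
  }
  best
}

# ---- RBS2: weighted-motif score (RAST-style) -------------------------------

#' Synthetic RBS motif weight table
#'
#' A (motif, spacer_size, weight) table in the style of the RAST RBS scorer,
#' which weights SD-like motifs by observed frequency at each spacer size.
#' The empirical frequencies are not redistributable, so this table is
#' synthetic: weights derive from the length of the contiguous (or
#' one-mismatch) match to AGGAGG, modulated by a spacer-size factor peaking
#' at 5-8 nt, and capped at 6.3. The same table ships as
#' `inst/extdata/rbs2_weights_synthetic.tsv`.
#'
#' @return data.frame with columns `motif`, `spacer_size`, `weight`.
#' @export
rbs2_weight_table <- function() {
  sd <- "AGGAGG"
  base_w <- c(`3` = 2.0, `4` = 3.2, `5` = 4.6, `6` = 6.3)
  motifs <- list()
  add <- function(m, w) {
    if (is.null(motifs[[m]]) || motifs[[m]] < w) motifs[[m]] <<- w
  }
  for (len in 3:6) for (j in 1:(7 - len)) {
    m <- substr(sd, j, j + len - 1L)
    add(m, base_w[[as.character(len)]])
    if (len >= 4L) {       # one-mismatch variants, down-weighted
      for (k in 1:len) for (b in BASES) {
        if (b == substr(m, k, k)) next
        v <- m
        substr(v, k, k) <- b
        add(v, base_w[[as.character(len)]] - 1.4)
      }
    }
  }
  spacers <- 3:12
  sp_factor <- ifelse(spacers >= 5 & spacers <= 8, 1.0,
                      ifelse(spacers == 4 | (spacers >= 9 & spacers <= 10),
                             0.85, 0.6))
  df <- expand.grid(motif = names(motifs), spacer_size = spacers,
                    stringsAsFactors = FALSE)
  df$weight <- round(pmin(6.3, unlist(motifs)[df$motif] *
                            sp_factor[match(df$spacer_size, spacers)]), 2)
  df <- df[order(df$motif, df$spacer_size), ]
  rownames(df) <- NULL
  df
}

.rbs2_env <- new.env(parent = emptyenv())

rbs2_default_table <- function() {
  if (is.null(.rbs2_env$table)) {
    path <- system.file("extdata", "rbs2_weights_synthetic.tsv",
                        package = "prfscan")
    .rbs2_env$table <- if (nzchar(path)) {
      utils::read.delim(path, stringsAsFactors = FALSE)
    } else {
      rbs2_weight_table()
    }
  }
  .rbs2_env$table
}

#' Weighted RBS motif score of an upstream window
#'
#' Maximum weight over all (motif, spacer size) pairs of the shipped weight
#' table (see [rbs2_weight_table()]) that match the window; 0.0 when nothing
#' matches. Capped at 6.3.
#'
#' @param upstream nucleotide string ending at the base immediately before
#'   the E-site codon.
#' @param table weight table (columns `motif`, `spacer_size`, `weight`);
#'   defaults to the shipped synthetic table.
#' @return numeric score in \[0, 6.3\].
#' @export
score_rbs_rast <- function(upstream, table = rbs2_default_table()) {
  upstream <- canonical_dna(upstream)
  n <- nchar(upstream)
  best <- 0
  for (i in seq_len(nrow(table))) {
    len <- nchar(table$motif[i])
    pos_end <- n - table$spacer_size[i]
    pos_start <- pos_end - len + 1L
    if (pos_start < 1L) next
    if (substr(upstream, pos_start, pos_end) == table$motif[i])
      best <- max(best, table$weight[i])
  }
  min(best, 6.3)
}

# ---- RNA folding -----------------------------------------------------------

.fold_env <- new.env(parent = emptyenv())

rnafold_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

#' Minimum free energy of RNA windows
#'
#' Folds each sequence with a thermodynamic nearest-neighbor model (the
#' ViennaRNA `RNAfold` program) and returns the minimum free energy in
#' kcal/mol (<= 0). Two engine names are exposed: `"hairpin"` for simple
#' secondary structure and `"pseudoknot"` for pseudoknot-capable folding.
#' The engine is a pluggable contract; with no pseudoknot-capable backend
#' installed both names resolve to the same thermodynamic fold, which is
#' recorded in trained model metadata.
#'
#' @param sequences character vector of nucleotide strings (1-120 nt,
#'   A/C/G/T/U only after canonicalization).
#' @param engine `"hairpin"` or `"pseudoknot"`.
#' @return numeric vector of MFE values (kcal/mol).
#' @export
fold_mfe <- function(sequences, engine = c("hairpin", "pseudoknot")) {
  engine <- match.arg(engine)
  if (!length(sequences)) return(numeric(0))
  seqs <- canonical_dna(sequences)
  if (any(grepl("N", seqs, fixed = TRUE)))
    stop("fold_mfe(): sequences must be A/C/G/T/U only")
  if (any(nchar(seqs) > 120L))
    stop("fold_mfe(): sequences longer than 120 nt are not supported")
  out <- numeric(length(seqs))
  out[nchar(seqs) == 0L] <- 0
  todo <- unique(seqs[nchar(seqs) > 0L])
  todo <- todo[!vapply(todo, function(s) !is.null(.fold_env[[s]]), logical(1))]
  if (length(todo)) {
    if (!rnafold_available())
      stop("RNAfold executable not found on PATH; install ViennaRNA to ",
           "compute minimum-free-energy features")
    fin <- tempfile(fileext = ".fa")
    on.exit(unlink(fin), add = TRUE)
    writeLines(paste0(">s", seq_along(todo), "\n", todo), fin)
    res <- suppressWarnings(
      system2("RNAfold", args = c("--noPS", "--infile", fin), stdout = TRUE))
    elines <- grep("\\)\\s*$", res, value = TRUE)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", elines))
    if (length(mfe) != length(todo) || anyNA(mfe))
      stop("could not parse RNAfold output (", length(mfe), " energies for ",
           length(todo), " sequences)")
    for (i in seq_along(todo)) .fold_env[[todo[i]]] <- min(mfe[i], 0)
  }
  nz <- nchar(seqs) > 0L
  out[nz] <- vapply(seqs[nz], function(s) .fold_env[[s]], numeric(1))
  unname(out)
}

#' Normalized minimum free energy of a fold window
#'
#' MFE scaled by window length and GC content:
#' `clamp(-mfe / (L * max(gc, 0.01)), 0, 1)`. Dividing by length makes
#' windows of different sizes comparable; dividing by GC removes the strong
#' GC bias of MFE. The 0.01 GC floor keeps AT-only windows finite, and the
#' clamp enforces the \[0, 1\] feature range. An empty window scores 0.
#'
#' @param mfe minimum free energy in kcal/mol (<= 0).
#' @param sequence the window the MFE was computed on.
#' @return numeric in \[0, 1\].
#' @export
normalized_mfe <- function(mfe, sequence) {
  L <- nchar(sequence)
  if (L == 0L) return(0)
  gc <- max(gc_fraction(sequence), 0.01)
  clamp01(-mfe / (L * gc))
}

# ---- distance to the in-frame stop -----------------------------------------

#' Distance from a slippery site to the in-frame stop codon
#'
#' Number of nucleotides strictly between the last base of the P-site codon
#' and the first base of the frame-0 (gene_a frame) stop codon; 0 when the
#' A-site codon is itself the stop.
#'
#' @param p_site_end view-coordinate position of the last base of the P-site
#'   codon.
#' @param pair the `gene_pair` the candidate belongs to.
#' @return integer N >= 0.
#' @export
distance_to_stop <- function(p_site_end, pair) {
  n <- pair$a_stop_end - p_site_end - 3L
  if (n < 0L)
    stop("P-site codon end lies past gene_a's stop codon")
  as.integer(n)
}

# ---- feature assembly ------------------------------------------------------

# Fold window sequence: starts 3 nt after the P-site codon end (just after
# the A-site codon), truncated at the contig end.
fold_window_seq <- function(vseq, p_site_end, len) {
  start <- p_site_end + 4L
  if (start > nchar(vseq)) return("")
  substr(vseq, start, min(start + len - 1L, nchar(vseq)))
}

rbs_upstream_seq <- function(vseq, p_site_end) {
  # 21 nt ending at the base before the E-site codon (E codon = p-5 .. p-3)
  hi <- p_site_end - 6L
  if (hi < 1L) return("")
  substr(vseq, max(1L, hi - 20L), hi)
}

#' Assemble the eleven-signal feature vector of one candidate
#'
#' @param candidate one row of the data.frame from [scan_overlap()].
#' @param pair the `gene_pair` the candidate belongs to.
#' @param usage codon usage from [compute_codon_usage()].
#' @param record the [genome_record()].
#' @return named numeric vector with the elements
#'   `DIR, RBS1, RBS2, MOTIF, A0, A1, LF50, LF100, HK50, HK100, N`.
#' @export
build_features <- function(candidate, pair, usage, record) {
  vseq <- view_sequence(record, pair$strand)
  p <- candidate$p_site_end
  up <- rbs_upstream_seq(vseq, p)
  w50 <- fold_window_seq(vseq, p, 50L)
  w100 <- fold_window_seq(vseq, p, 100L)
  lf50 <- if (nzchar(w50)) normalized_mfe(fold_mfe(w50, "hairpin"), w50) else 0
  lf100 <- if (nzchar(w100)) normalized_mfe(fold_mfe(w100, "hairpin"), w100) else 0
  hk50 <- if (nzchar(w50)) normalized_mfe(fold_mfe(w50, "pseudoknot"), w50) else 0
  hk100 <- if (nzchar(w100)) normalized_mfe(fold_mfe(w100, "pseudoknot"), w100) else 0
  c(DIR = as.numeric(candidate$direction),
    RBS1 = as.numeric(score_rbs_prodigal(up)),
    RBS2 = score_rbs_rast(up),
    MOTIF = as.numeric(candidate$motif_code),
    A0 = candidate$A0, A1 = candidate$A1,
    LF50 = lf50, LF100 = lf100, HK50 = hk50, HK100 = hk100,
    N = as.numeric(distance_to_stop(p, pair)))
}
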