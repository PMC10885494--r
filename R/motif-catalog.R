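# Slippery-site motif catalog.
#
# Motif classes are named after their run-length structure: "threethree" is
# three identical nucleotides followed by three identical nucleotides of a
# different base (the canonical XXXYYY slippery sequence), "fivetwo" is a run
# of five then a run of two (e.g. GGGGGAA), and so on. Eight classes describe
# backward (-1) sites and two short run classes ("four", "three") describe
# forward (+1) sites. Adjacent runs must use different nucleotides;
# non-adjacent runs are unconstrained, and there are no positional base
# restrictions (any base may fill any run).

MOTIF_CATALOG_VERSION <- "1"

.motif_defs <- list(
  six         = list(code = 0L, direction = -1L, template = c(6L)),
  threethree  = list(code = 1L, direction = -1L, template = c(3L, 3L)),
  fivetwo     = list(code = 2L, direction = -1L, template = c(5L, 2L)),
  twofive     = list(code = 3L, direction = -1L, template = c(2L, 5L)),
  twofour     = list(code = 4L, direction = -1L, template = c(2L, 4L)),
  threetwotwo = list(code = 5L, direction = -1L, template = c(3L, 2L, 2L)),
  five        = list(code = 6L, direction = -1L, template = c(5L)),
  twoonefour  = list(code = 7L, direction = -1L, template = c(2L, 1L, 4L)),
  four        = list(code = 8L, direction = 1L, template = c(4L)),
  three       = list(code = 9L, direction = 1L, template = c(3L))
)

#' The slippery-site motif classes
#'
#' @return data.frame with one row per class: `name`, `code` (0-9, stable),
#'   `direction` (-1 backward, +1 forward), `span` (total length in nt) and
#'   `prob` (probability that a uniform random window of length `span`
#'   matches the class template, see [random_probability()]).
#' @export
.motif_env <- new.env(parent = emptyenv())

motif_classes <- function() {
  if (!is.null(.motif_env$classes)) return(.motif_env$classes)
  df <- data.frame(
    name = names(.motif_defs),
    code = vapply(.motif_defs, `[[`, integer(1), "code"),
    direction = vapply(.motif_defs, `[[`, integer(1), "direction"),
    span = vapply(.motif_defs, function(d) sum(d$template), integer(1)),
    groups = vapply(.motif_defs, function(d) length(d$template), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$prob <- vapply(df$name, random_probability, numeric(1), USE.NAMES = FALSE)
  .motif_env$classes <- df
  df
}

#' Probability of a motif class occurring at random
#'
#' For a class whose template has `g` runs over a span of `n` nt, the number
#' of matching sequences over a uniform iid alphabet of 4 bases is
#' `4 * 3^(g-1)` (first run free, each subsequent run any of the 3 other
#' bases), so the probability is `4 * 3^(g-1) / 4^n`. Classes with lower
#' random probability take precedence when several match the same window.
#'
#' @param motif class name (see [motif_classes()]).
#' @return probability in (0, 1).
#' @export
random_probability <- function(motif) {
  d <- .motif_defs[[motif]]
  if (is.null(d)) stop("unknown motif class: ", motif)
  g <- length(d$template)
  n <- sum(d$template)
  4 * 3^(g - 1) / 4^n
}

# Does `s` (length == sum(template)) decompose into the template's runs, with
# adjacent runs on different nucleotides?
match_template <- function(s, template) {
  pos <- 1L
  prev <- ""
  for (len in template) {
    run <- substr(s, pos, pos + len - 1L)
    base <- substr(run, 1L, 1L)
    if (base == "N") return(FALSE)
    if (run != strrep(base, len)) return(FALSE)
    if (base == prev) return(FALSE)
    prev <- base
    pos <- pos + len
  }
  TRUE
}

#' Classify a candidate window against the motif catalog
#'
#' Every class is tested right-anchored at the window end (the last base of
#' the P-site codon): a class of span `n` must match the final `n` bases.
#' Among all matching classes the one with the lowest random-occurrence
#' probability wins; ties are broken by longer span, then by lower code.
#'
#' @param window nucleotide string (canonically 7 nt, ending at a P-site
#'   codon boundary); windows containing N never match.
#' @param directions which shift directions to consider (default both).
#' @return one-row data.frame from [motif_classes()], or `NULL` when no
#'   class matches.
#' @export
classify_window <- function(window, directions = c(-1L, 1L)) {
  if (grepl("N", window, fixed = TRUE)) return(NULL)
  classes <- motif_classes()
  classes <- classes[classes$direction %in% directions, , drop = FALSE]
  n <- nchar(window)
  best <- NULL
  for (i in seq_len(nrow(classes))) {
    sp <- classes$span[i]
    if (sp > n) next
    tail <- substr(window, n - sp + 1L, n)
    if (!match_template(tail, .motif_defs[[classes$name[i]]]$template)) next
    row <- classes[i, , drop = FALSE]
    if (is.null(best) ||
        row$prob < best$prob ||
        (row$prob == best$prob && row$span > best$span) ||
        (row$prob == best$prob && row$span == best$span && row$code < best$code)) {
      best <- row
    }
  }
  best
}

#' Scan a gene pair's overlap window for slippery-site candidates
#'
#' Slides over every in-frame (gene_a frame) P-site codon boundary inside the
#' pair's overlap window and classifies the right-anchored heptamer. Backward
#' candidates are emitted for backward-class matches when the pair's frame
#' offset is -1; forward candidates for `three`/`four` matches when the frame
#' offset is +1 **and** the shifted A-site codon (A1) is more abundant than
#' the waiting in-frame A-site codon (A0) in genome codon usage. Candidates
#' whose motif extends outside the window are suppressed.
#'
#' @param pair a `gene_pair` from [enumerate_pairs()].
#' @param usage codon usage from [compute_codon_usage()].
#' @param record the [genome_record()].
#' @return data.frame, one row per candidate: view coordinates of motif
#'   start and P-site end, motif name/code, direction, A-site codons and
#'   their usage frequencies.
#' @export
scan_overlap <- function(pair, usage, record) {
  empty <- data.frame(pos = integer(0), p_site_end = integer(0),
                      motif = character(0), motif_code = integer(0),
                      direction = integer(0), a0_codon = character(0),
                      a1_codon = character(0), A0 = numeric(0), A1 = numeric(0),
                      stringsAsFactors = FALSE)
  w <- pair$window
  if (is.null(w) || w[2L] < w[1L]) return(empty)
  vseq <- view_sequence(record, pair$strand)
  L <- nchar(vseq)
  dir <- pair$frame_offset
  # P-site codon ends in gene_a's frame: positions p with p == a_start+2 (mod 3)
  first_end <- pair$a_start + 2L
  p_all <- seq.int(first_end, w[2L], by = 3L)
  p_all <- p_all[p_all >= w[1L] + 2L]   # at least a 3-mer must fit
  rows <- list()
  for (p in p_all) {
    win_lo <- max(1L, p - 6L)
    heptamer <- substr(vseq, win_lo, p)
    cl <- classify_window(heptamer, directions = dir)
    if (is.null(cl)) next
    if (p - cl$span + 1L < w[1L]) next     # motif must lie inside the window
    if (p + 3L + max(dir, 0L) > L) next    # A-site codons must exist
    a0 <- substr(vseq, p + 1L, p + 3L)
    a1 <- substr(vseq, p + 1L + dir, p + 3L + dir)
    f0 <- if (a0 %in% names(usage$freq)) unname(usage$freq[a0]) else 0
    f1 <- if (a1 %in% names(usage$freq)) unname(usage$freq[a1]) else 0
    if (dir == 1L && !(f1 > f0)) next      # forward shifts need a favorable A1
    rows[[length(rows) + 1L]] <- data.frame(
      pos = p - cl$span + 1L, p_site_end = p, motif = cl$name,
      motif_code = cl$code, direction = dir, a0_codon = a0, a1_codon = a1,
      A0 = f0, A1 = f1, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
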