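# Geometry of gene-pair overlaps and of annotated (joined) frameshift genes.
#
# All window arithmetic happens in "view" coordinates: positions on the coding
# strand of the pair, i.e. the genome itself for plus-strand pairs and the
# reverse complement for minus-strand pairs. Genome coordinates are recovered
# with view_to_genome().

view_sequence <- function(record, strand) {
  if (strand == "+") record$sequence else revcomp(record$sequence)
}

genome_to_view <- function(pos, strand, L) {
  if (strand == "+") pos else L - pos + 1L
}

view_to_genome <- function(pos, strand, L) {
  if (strand == "+") pos else L - pos + 1L
}

# Feature span in view coordinates (start <= end on the coding strand).
feature_view_span <- function(feature, L) {
  s <- min(feature$segments[, 1L])
  e <- max(feature$segments[, 2L])
  if (feature$strand == "+") c(s, e) else c(L - e + 1L, L - s + 1L)
}

#' Split a joined CDS into its two fragments
#'
#' Joined CDS features are the de facto annotation of frameshifted genes: the
#' upstream fragment ends where the ribosome is thought to shift and the
#' downstream fragment continues in the new frame. The separation `d` between
#' the fragments (in reading direction) determines the direction of the
#' shift: `d mod 3 == 0` is a backward (-1) shift, `d mod 3 == 1` a forward
#' (+1) shift. Joins separated by more than 10 nt (introns, inteins,
#' mis-annotations) or by `d mod 3 == 2`, overlapping fragments, and features
#' with more than two segments are rejected.
#'
#' @param feature a joined [cds_feature()] (two or more segments).
#' @return list with `upstream_fragment` and `downstream_fragment`
#'   (single-segment `cds_feature`s), `separation_d`, `direction`
#'   (-1, +1 or `NA`), and `accepted`.
#' @export
split_joined <- function(feature) {
  if (!feature$joined || nrow(feature$segments) < 2L)
    stop("split_joined() requires a joined feature with >= 2 segments")
  if (nrow(feature$segments) > 2L) {
    warning("joined feature with >2 segments rejected", call. = FALSE)
    return(list(upstream_fragment = NULL, downstream_fragment = NULL,
                separation_d = NA_integer_, direction = NA_integer_,
                accepted = FALSE))
  }
  s1 <- feature$segments[1L, ]
  s2 <- feature$segments[2L, ]
  d <- if (feature$strand == "+") {
    as.integer(s2[["start"]] - s1[["end"]] - 1L)
  } else {
    as.integer(s1[["start"]] - s2[["end"]] - 1L)
  }
  direction <- NA_integer_
  accepted <- FALSE
  if (d >= 0L && d <= 10L) {
    m <- d %% 3L
    if (m == 0L) {
      direction <- -1L; accepted <- TRUE
    } else if (m == 1L) {
      direction <- 1L; accepted <- TRUE
    } else {
      warning("joined feature with separation ", d,
              " (d mod 3 == 2) rejected", call. = FALSE)
    }
  }
  frag <- function(seg, tag) {
    cds_feature(matrix(seg, ncol = 2L), strand = feature$strand,
                product = paste0(feature$product, tag),
                source_order = feature$source_order)
  }
  list(
    upstream_fragment = frag(s1, " [fragment 1]"),
    downstream_fragment = frag(s2, " [fragment 2]"),
    separation_d = d,
    direction = direction,
    accepted = accepted
  )
}

# Locate the last base of gene_a's stop codon by an in-frame walk from its
# start. For ordinary genes this is the annotated end; for the upstream
# fragment of a split join the annotated end precedes the stop and the walk
# continues past it.
a_stop_end <- function(vseq, a_start) {
  st <- next_inframe_stop(vseq, a_start)
  if (is.na(st)) NA_integer_ else st + 2L
}

# Core geometry for one candidate pair, in view coordinates.
pair_geometry <- function(vseq, a_start, a_end, b_start, b_end) {
  if (b_start <= a_start) return(NULL)
  fo3 <- (b_start - a_start) %% 3L
  if (fo3 == 0L) return(NULL)               # same frame: no shift possible
  frame_offset <- if (fo3 == 1L) 1L else -1L
  stop_end <- a_stop_end(vseq, a_start)
  if (is.na(stop_end)) return(NULL)
  if (b_start > stop_end + 10L) return(NULL) # not adjacent / no overlap
  q <- prev_inframe_stop(vseq, b_start)
  w_start <- if (is.na(q)) ((b_start - 1L) %% 3L) + 1L else q + 3L
  w_start <- max(w_start, a_start)
  w_end <- stop_end
  if (w_start > w_end) return(NULL)
  list(window = c(w_start, w_end), frame_offset = frame_offset,
       a_stop_end = stop_end)
}

#' Overlap search window for a gene pair
#'
#' The window in which a frameshift out of `gene_a`'s frame into `gene_b`'s
#' frame is tenable: it ends at the last base of `gene_a`'s (in-frame) stop
#' codon and starts just after the nearest upstream stop codon in `gene_b`'s
#' frame, intersected with `gene_a`'s span. Both genes must be on the same
#' strand, in different frames, with `gene_b` starting no more than 10 nt
#' past `gene_a`'s stop codon.
#'
#' @param gene_a,gene_b single-segment [cds_feature()]s, `gene_a` 5' of
#'   `gene_b` in reading direction, same strand.
#' @param record the [genome_record()] containing them.
#' @return `NULL` when no window exists; otherwise an integer `c(start, end)`
#'   interval in coding-strand (view) coordinates with attributes `strand`,
#'   `frame_offset` and `genome` (the corresponding genome-coordinate
#'   interval, ascending).
#' @export
compute_overlap_window <- function(gene_a, gene_b, record) {
  if (gene_a$strand != gene_b$strand) return(NULL)
  strand <- gene_a$strand
  L <- nchar(record$sequence)
  vseq <- view_sequence(record, strand)
  a <- feature_view_span(gene_a, L)
  b <- feature_view_span(gene_b, L)
  g <- pair_geometry(vseq, a[1L], a[2L], b[1L], b[2L])
  if (is.null(g)) return(NULL)
  w <- as.integer(g$window)
  gen <- sort(view_to_genome(w, strand, L))
  structure(w, strand = strand, frame_offset = g$frame_offset, genome = gen)
}

#' Enumerate candidate gene pairs of a genome
#'
#' Walks consecutive genes in genome order and emits every same-strand pair
#' in different frames whose overlap window (see [compute_overlap_window()])
#' is non-empty. Pairs on opposite strands are skipped (ribosomal
#' frameshifting between them is untenable), as are joined features (split
#' them first with [split_joined()]).
#'
#' @param features list of [cds_feature()]s (any order; sorted internally).
#' @param record the [genome_record()].
#' @return list of `gene_pair` objects: `gene_a`, `gene_b`, `strand`, view
#'   coordinates of both genes, the `window`, `frame_offset`, `a_stop_end`
#'   and a stable `pair_id`.
#' @export
enumerate_pairs <- function(features, record) {
  features <- Filter(function(f) !f$joined, features)
  if (length(features) < 2L) return(list())
  L <- nchar(record$sequence)
  starts <- vapply(features, function(f) min(f$segments[, 1L]), integer(1))
  ends <- vapply(features, function(f) max(f$segments[, 2L]), integer(1))
  ord <- order(starts, ends)
  features <- features[ord]
  vcache <- list()
  pairs <- list()
  for (i in seq_len(length(features) - 1L)) {
    f1 <- features[[i]]
    f2 <- features[[i + 1L]]
    if (f1$strand != f2$strand) next
    strand <- f1$strand
    if (is.null(vcache[[strand]])) vcache[[strand]] <- view_sequence(record, strand)
    vseq <- vcache[[strand]]
    # gene_a is the 5'-most gene in reading direction
    if (strand == "+") { fa <- f1; fb <- f2 } else { fa <- f2; fb <- f1 }
    a <- feature_view_span(fa, L)
    b <- feature_view_span(fb, L)
    g <- pair_geometry(vseq, a[1L], a[2L], b[1L], b[2L])
    if (is.null(g)) next
    pairs[[length(pairs) + 1L]] <- structure(list(
      gene_a = fa, gene_b = fb, strand = strand,
      a_start = a[1L], a_end = a[2L], b_start = b[1L], b_end = b[2L],
      window = as.integer(g$window), frame_offset = g$frame_offset,
      a_stop_end = g$a_stop_end,
      pair_id = sprintf("%s:%d-%d%s", record$locus_id,
                        min(fa$segments, fb$segments),
                        max(fa$segments, fb$segments), strand)
    ), class = "gene_pair")
  }
  pairs
}
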