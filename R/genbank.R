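#' Construct a CDS feature
#'
#' A coding feature with one or more located segments. Coordinates are 1-based
#' inclusive genome positions (as in GenBank). Segments are stored in reading
#' order: 5' to 3' on the coding strand, so for minus-strand features the
#' first segment is the one with the highest genome coordinates.
#'
#' @param segments two-column integer matrix (start, end), one row per
#'   segment, each `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param joined logical; `TRUE` iff the location used the `join` keyword
#'   (more than one segment).
#' @param product free-text functional annotation.
#' @param source_order integer rank of the feature in its source file.
#' @return An object of class `cds_feature`.
#' @export
cds_feature <- function(segments, strand = "+", joined = NULL,
                        product = "", source_order = NA_integer_) {
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(segments) >= 1L, all(segments[, 1L] <= segments[, 2L]),
            strand %in% c("+", "-"))
  if (is.null(joined)) joined <- nrow(segments) > 1L
  if (joined != (nrow(segments) > 1L))
    stop("'joined' must be TRUE iff the feature has more than one segment")
  structure(list(segments = segments, strand = strand, joined = joined,
                 product = as.character(product),
                 source_order = as.integer(source_order)),
            class = "cds_feature")
}

#' Construct a genome record
#'
#' One GenBank locus: identifier, nucleotide sequence and CDS features.
#'
#' @param locus_id locus name.
#' @param sequence nucleotide string; canonicalized to uppercase DNA.
#' @param features list of [cds_feature()] objects.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(locus_id, sequence, features = list()) {
  sequence <- canonical_dna(sequence)
  stopifnot(nchar(sequence) > 0L)
  for (f in features) {
    if (any(f$segments < 1L) || any(f$segments > nchar(sequence)))
      stop("feature segment out of sequence bounds in locus ", locus_id)
  }
  structure(list(locus_id = locus_id, sequence = sequence,
                 features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d CDS feature(s)\n",
              x$locus_id, nchar(x$sequence), length(x$features)))
  invisible(x)
}

# ---- location grammar ------------------------------------------------------
# Supported: n..m, n, join(...), complement(...), complement(join(...)).
# Fuzzy qualifiers (< and >) are dropped with a warning.

parse_location <- function(loc, context = "CDS") {
  raw <- gsub("[[:space:]]", "", loc)
  loc <- raw
  if (grepl("[<>]", loc)) {
    warning("dropping fuzzy location qualifiers in ", context, ": ", raw,
            call. = FALSE)
    loc <- gsub("[<>]", "", loc)
  }
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!length(parts) || !all(grepl("^[0-9]+(\\.\\.[0-9]+)?$", parts)))
    stop("malformed location string in ", context, ": ", raw, call. = FALSE)
  segs <- t(vapply(parts, function(p) {
    nn <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(nn) == 1L) nn <- c(nn, nn)
    nn
  }, integer(2)))
  dimnames(segs) <- list(NULL, c("start", "end"))
  # GenBank lists segments in ascending genome order inside complement(join());
  # reading order on the minus strand is the reverse.
  if (strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  list(segments = segs, strand = strand)
}

format_location <- function(feature) {
  segs <- feature$segments
  if (feature$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  body <- paste(sprintf("%d..%d", segs[, 1L], segs[, 2L]), collapse = ",")
  if (nrow(segs) > 1L) body <- sprintf("join(%s)", body)
  if (feature$strand == "-") body <- sprintf("complement(%s)", body)
  body
}

# ---- flat-file reader ------------------------------------------------------

#' Parse GenBank flat-file text
#'
#' Reads one or more LOCUS...ORIGIN...// blocks and returns a
#' [genome_record()] per locus. `join` and `complement` location operators are
#' resolved into reading-ordered segments plus a strand; only CDS features and
#' their `/product` qualifiers are retained. Lowercase and RNA sequences are
#' canonicalized to uppercase DNA.
#'
#' @param text GenBank file content as a single string or character vector of
#'   lines.
#' @return list of `genome_record` objects.
#' @seealso [read_genbank()], [write_genbank()]
#' @export
parse_genbank <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  locus_at <- grep("^LOCUS", text)
  if (!length(locus_at)) stop("no LOCUS record found in GenBank input")
  end_at <- grep("^//\\s*$", text)
  records <- vector("list", length(locus_at))
  for (i in seq_along(locus_at)) {
    from <- locus_at[i]
    to <- end_at[end_at > from]
    to <- if (length(to)) to[1L] else length(text)
    records[[i]] <- parse_genbank_block(text[from:to])
  }
  records
}

parse_genbank_block <- function(lines) {
  locus_id <- strsplit(trimws(lines[1L]), "\\s+")[[1]][2L]
  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("record ", locus_id, " has no ORIGIN section")
  seq_lines <- lines[(origin_at[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- canonical_dna(paste(gsub("[0-9[:space:]/]", "", seq_lines),
                                  collapse = ""))

  feat_at <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_at)) {
    body <- lines[(feat_at[1L] + 1L):(origin_at[1L] - 1L)]
    # A new feature line has its key at column 6; continuations are indented
    # beyond that and qualifiers start with '/'.
    is_new <- grepl("^ {1,10}\\S", body) & !grepl("^ *\\/", body)
    idx <- which(is_new)
    rank <- 0L
    for (k in seq_along(idx)) {
      first <- body[idx[k]]
      last <- if (k < length(idx)) idx[k + 1L] - 1L else length(body)
      block <- body[idx[k]:last]
      key <- sub("^ *(\\S+).*$", "\\1", first)
      if (key != "CDS") next
      rank <- rank + 1L
      loc <- sub("^ *\\S+ +", "", first)
      j <- 2L
      while (j <= length(block) && !grepl("^ *\\/", block[j])) {
        loc <- paste0(loc, trimws(block[j]))
        j <- j + 1L
      }
      product <- ""
      prod_at <- grep("^ *\\/product=", block)
      if (length(prod_at)) {
        product <- sub("^ *\\/product=\"?", "", block[prod_at[1L]])
        product <- sub("\"\\s*$", "", product)
      }
      pl <- parse_location(loc, context = sprintf("CDS #%d of %s", rank, locus_id))
      if (any(pl$segments < 1L) || any(pl$segments > nchar(sequence)))
        stop("CDS #", rank, " of ", locus_id,
             " has a segment outside [1, ", nchar(sequence), "]")
      features[[length(features) + 1L]] <-
        cds_feature(pl$segments, pl$strand, product = product,
                    source_order = rank)
    }
  }
  genome_record(locus_id, sequence, features)
}

#' Read GenBank files
#'
#' @param path file path(s).
#' @return list of `genome_record` objects (across all files).
#' @export
read_genbank <- function(path) {
  out <- list()
  for (p in path) out <- c(out, parse_genbank(readLines(p, warn = FALSE)))
  out
}

# ---- flat-file writer ------------------------------------------------------

#' Write a genome record as GenBank flat-file text
#'
#' Emits LOCUS, FEATURES and ORIGIN sections. Multi-segment features are
#' written with `join(a..b,c..d)` locations (1-based inclusive); minus-strand
#' features are wrapped in `complement(...)`.
#'
#' @param record a [genome_record()].
#' @param path optional output file; when `NULL` the text is returned.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_genbank <- function(record, path = NULL) {
  L <- nchar(record$sequence)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   UNA", record$locus_id, L),
    sprintf("DEFINITION  %s.", record$locus_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L)
  )
  for (f in record$features) {
    loc <- format_location(f)
    out <- c(out, sprintf("     CDS             %s", loc))
    if (nzchar(f$product))
      out <- c(out, sprintf("                     /product=\"%s\"", f$product))
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(record$sequence, s, min(s + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))))
  }
  out <- c(out, "//")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Spliced nucleotide sequence of a feature
#'
#' Concatenates the feature's segments in reading order and
#' reverse-complements minus-strand features, giving the coding-strand mRNA
#' sense sequence.
#'
#' @param record a [genome_record()].
#' @param feature a [cds_feature()] of that record.
#' @return nucleotide string.
#' @export
feature_sequence <- function(record, feature) {
  segs <- feature$segments
  pieces <- substring(record$sequence, segs[, 1L], segs[, 2L])
  if (feature$strand == "-") pieces <- revcomp(pieces)
  paste(pieces, collapse = "")
}

#' Genome-wide codon usage
#'
#' Tabulates the relative frequency of all 64 codons over the in-frame,
#' non-overlapping codons of every annotated CDS (spliced, strand-resolved).
#' Stop codons are counted like any other codon. Codons containing N are
#' skipped; a trailing partial codon of a CDS whose spliced length is not a
#' multiple of three is dropped.
#'
#' @param record a [genome_record()] with at least one CDS of spliced length
#'   >= 3.
#' @return list with `freq` (named vector over all 64 codons, summing to 1)
#'   and `total_codons`.
#' @export
compute_codon_usage <- function(record) {
  codons <- all_codons()
  counts <- stats::setNames(numeric(64L), codons)
  usable <- FALSE
  partial <- 0L
  for (f in record$features) {
    s <- feature_sequence(record, f)
    if (nchar(s) < 3L) next
    usable <- TRUE
    if (nchar(s) %% 3L != 0L) partial <- partial + 1L
    cs <- codon_split(s)
    cs <- cs[!grepl("N", cs, fixed = TRUE)]
    if (length(cs)) {
      tab <- table(cs)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  if (!usable)
    stop("codon usage requires annotated genes: record '", record$locus_id,
         "' has no CDS feature of length >= 3")
  if (partial > 0L)
    message(partial, " CDS feature(s) with partial trailing codon (dropped)")
  total <- sum(counts)
  if (total == 0) stop("no countable codons in record ", record$locus_id)
  list(freq = counts / total, total_codons = as.integer(total))
}
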