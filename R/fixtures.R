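# Synthetic GenBank corpora with planted frameshift genes.
#
# The generator emulates the signal structure of real frameshift-bearing
# genomes: a slippery motif at a codon boundary near the end of the upstream
# gene fragment, an internal Shine-Dalgarno-like sequence at working spacer
# upstream of the E-site codon, a GC-rich hairpin starting just after the
# A-site codon, a short distance N to the in-frame stop, and a joined CDS
# annotation whose junction sits within the labeling tolerance of the
# motif. Negative signal comes from non-joined overlapping gene pairs whose
# overlap contains a motif but no hairpin or SD, and from spurious motif
# hits inside true overlap windows.
#
# Overlap regions are written over the T-free alphabet {A,C,G} wherever both
# reading frames must stay open: every stop codon contains a T, so T-free
# stretches can never terminate either frame.

#' Specification for a synthetic corpus
#'
#' @param n_genomes number of genomes.
#' @param genome_length genome length in nt.
#' @param gc background GC fraction.
#' @param genes_per_genome gene slots per genome (>= 2*prf_per_genome + 6).
#' @param prf_per_genome planted frameshift genes per genome (0, 1 or 2).
#' @param motif motif class to plant (must match `direction`).
#' @param direction -1 (backward) or +1 (forward).
#' @param stem_length hairpin stem length in bp.
#' @param stem_gc GC fraction of the hairpin stem.
#' @param plant_rbs plant an internal SD sequence upstream of the slippery
#'   site.
#' @param junction_n distance N (nt) from the P-site codon end to the
#'   in-frame stop; must be a multiple of 3 large enough to fit the hairpin.
#' @param n_families number of genome families (mutated copies of a founder).
#' @param mutation_rate per-base substitution rate within a family.
#' @param seed corpus seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genomes = 30L, genome_length = 20000L, gc = 0.60,
                         genes_per_genome = 10L, prf_per_genome = 1L,
                         motif = "threethree", direction = -1L,
                         stem_length = 12L, stem_gc = 1.0, plant_rbs = TRUE,
                         junction_n = 33L, n_families = 5L,
                         mutation_rate = 0.02, seed = 1L) {
  cls <- motif_classes()
  if (!motif %in% cls$name) stop("unknown motif class: ", motif)
  if (cls$direction[cls$name == motif] != direction)
    stop("motif ", motif, " does not match direction ", direction)
  if (junction_n %% 3L != 0L)
    stop("junction_n must be a multiple of 3")
  min_n <- 2L * stem_length + 7L + (direction == 1L)
  if (junction_n < min_n)
    stop("junction_n too small to fit the hairpin: need >= ", min_n)
  if (genes_per_genome < 2L * prf_per_genome + 6L)
    stop("too few gene slots for the requested layout")
  if (genome_length %/% genes_per_genome < 1200L)
    stop("gene slots shorter than 1200 nt; increase genome_length")
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = as.integer(genome_length), gc = gc,
                 genes_per_genome = as.integer(genes_per_genome),
                 prf_per_genome = as.integer(prf_per_genome),
                 motif = motif, direction = as.integer(direction),
                 stem_length = as.integer(stem_length), stem_gc = stem_gc,
                 plant_rbs = isTRUE(plant_rbs),
                 junction_n = as.integer(junction_n),
                 n_families = as.integer(n_families),
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

# T-free instantiation of a motif class (adjacent runs differ by cycling
# over G, A, C).
motif_instance <- function(name) {
  tpl <- .motif_defs[[name]]$template
  bases <- c("G", "A", "C")
  paste(mapply(function(len, i) strrep(bases[((i - 1L) %% 3L) + 1L], len),
               tpl, seq_along(tpl)), collapse = "")
}

tf_fill <- function(n) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G"), n, replace = TRUE)
}

#' Generate one synthetic genome with planted frameshift genes
#'
#' @param spec a [fixture_spec()].
#' @param seed genome seed.
#' @param id locus id.
#' @return list with `record` (a [genome_record()]) and `truth`
#'   (data.frame: genome, junction, direction, motif, p_site_end; genome
#'   coordinates, plus strand).
#' @export
make_genome <- function(spec, seed = spec$seed, id = "syn1") {
  set.seed(seed)
  L <- spec$genome_length
  n <- spec$genes_per_genome
  slot_w <- L %/% n
  pA <- (1 - spec$gc) / 2; pC <- spec$gc / 2
  sq <- sample(BASES, L, replace = TRUE, prob = c(pA, pC, pC, pA))

  put <- function(pos, s) {
    chars <- if (length(s) == 1L && nchar(s) > 1L) strsplit(s, "")[[1]] else s
    sq[pos:(pos + length(chars) - 1L)] <<- chars
    invisible(NULL)
  }

  sense_pool <- setdiff(all_codons(), c(STOP_CODONS, "CGG"))
  features <- list()
  truth <- list()

  stem_alpha <- function(k) {
    if (spec$stem_gc >= 0.99) sample(c("G", "C"), k, replace = TRUE)
    else sample(c("G", "C", "A"), k, replace = TRUE,
                prob = c(spec$stem_gc / 2, spec$stem_gc / 2, 1 - spec$stem_gc))
  }

  ordinary_gene <- function(gs, strand = "+") {
    ncod <- 220L + sample(0:40, 1L)
    cods <- c("GGG", "GGG", "GGG", sample(sense_pool, ncod, replace = TRUE))
    orf <- paste0("ATG", paste(cods, collapse = ""), "TAA")
    start <- gs + 33L
    if (strand == "+") {
      put(gs + 20L, "AGGAGG")
      put(start, orf)
    } else {
      put(start, revcomp(orf))
    }
    cds_feature(matrix(c(start, start + nchar(orf) - 1L), ncol = 2L),
                strand = strand, product = "hypothetical protein")
  }

  prf_gene <- function(gs) {
    s <- gs + 33L
    put(gs + 20L, "AGGAGG")                  # gene's own RBS
    m <- sample(20:30, 1L)
    p <- s + 3L * m - 1L                     # P-site codon end
    sl <- spec$stem_length
    N <- spec$junction_n
    put(s, "ATG")
    put(s + 3L, tf_fill(p - s - 2L))
    if (spec$plant_rbs) put(p - 17L, "AGGAGG")  # internal SD, spacer 6
    mi <- motif_instance(spec$motif)
    put(p - nchar(mi) + 1L, mi)
    stem <- paste(stem_alpha(sl), collapse = "")
    hairpin <- paste0(stem, "GAAA", revcomp(stem))
    if (spec$direction == -1L) {
      put(p + 1L, "CAA")                     # waiting A-site codon
      put(p + 4L, hairpin)
      he <- p + 3L + nchar(hairpin)
      put(he + 1L, tf_fill(p + N - he))
      put(p + N + 1L, "TAA")                 # frame-0 stop, distance N
      b_start <- p + 3L
      bq <- p + N + 3L + 180L                # downstream-frame stop
      put(p + N + 4L, tf_fill(bq - p - N - 4L))
      put(bq, "TAA")
      segs <- rbind(c(s, p + 2L), c(b_start, bq + 2L))
      junction <- p + 2L
    } else {
      put(p + 1L, "CGGG")  # A0 = CGG (kept rare), A1 = GGG (common)
      put(p + 5L, hairpin)
      he <- p + 4L + nchar(hairpin)
      put(he + 1L, tf_fill(p + N - he))
      put(p + N + 1L, "TAA")
      b_start <- p + 2L
      bq <- p + N + 5L + 180L
      put(p + N + 4L, tf_fill(bq - p - N - 4L))
      put(bq, "TAA")
      segs <- rbind(c(s, p), c(b_start, bq + 2L))
      junction <- p
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      genome = id, junction = junction, direction = spec$direction,
      motif = spec$motif, p_site_end = p, stringsAsFactors = FALSE)
    cds_feature(segs, strand = "+", product = "tail assembly chaperone")
  }

  decoy_pair <- function(gs) {
    xs <- gs + 33L
    m_x <- sample(40:60, 1L)
    t_d <- sample(4:10, 1L)
    x_stop <- xs + 3L * m_x
    p_d <- xs + 3L * (m_x - t_d) - 1L
    put(xs, "ATG")
    put(xs + 3L, paste(sample(sense_pool, m_x - 1L, replace = TRUE),
                       collapse = ""))
    put(p_d - 20L, tf_fill(x_stop - p_d + 20L))
    put(p_d - 5L, "GGGAAA")                  # motif with no hairpin / SD
    put(p_d + 1L, "CAA")
    put(x_stop, "TAA")
    ys <- p_d + 3L
    yq <- ys + 3L * 60L
    put(x_stop + 3L, tf_fill(yq - x_stop - 3L))
    put(yq, "TAA")
    list(cds_feature(matrix(c(xs, x_stop + 2L), ncol = 2L), strand = "+",
                     product = "hypothetical protein"),
         cds_feature(matrix(c(ys, yq + 2L), ncol = 2L), strand = "+",
                     product = "hypothetical protein"))
  }

  prf_slots <- if (spec$prf_per_genome > 0L)
    seq(2L, by = 2L, length.out = spec$prf_per_genome) else integer(0)
  decoy_slots <- (max(prf_slots, 2L) + c(2L, 4L))
  minus_slot <- n

  for (slot in seq_len(n)) {
    gs <- (slot - 1L) * slot_w + 1L
    if (slot %in% prf_slots) {
      features[[length(features) + 1L]] <- prf_gene(gs)
    } else if (slot %in% decoy_slots) {
      dp <- decoy_pair(gs)
      features[[length(features) + 1L]] <- dp[[1L]]
      features[[length(features) + 1L]] <- dp[[2L]]
    } else {
      strand <- if (slot == minus_slot) "-" else "+"
      features[[length(features) + 1L]] <- ordinary_gene(gs, strand)
    }
  }
  for (i in seq_along(features)) features[[i]]$source_order <- i
  rec <- genome_record(id, paste(sq, collapse = ""), features)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome = character(0), junction = integer(0),
               direction = integer(0), motif = character(0),
               p_site_end = integer(0), stringsAsFactors = FALSE)
  list(record = rec, truth = truth_df)
}

# Substitution mutations outside the protected (planted) regions.
mutate_record <- function(record, rate, seed, id) {
  set.seed(seed)
  sq <- strsplit(record$sequence, "")[[1]]
  L <- length(sq)
  protected <- rep(FALSE, L)
  for (f in record$features) {
    if (!f$joined) next
    lo <- max(1L, min(f$segments) - 45L)
    hi <- min(L, max(f$segments) + 10L)
    protected[lo:hi] <- TRUE
  }
  idx <- which(stats::runif(L) < rate & !protected)
  for (i in idx) sq[i] <- sample(setdiff(BASES, sq[i]), 1L)
  genome_record(id, paste(sq, collapse = ""), record$features)
}

#' Generate a corpus of related synthetic genomes
#'
#' Genomes are organized into families: each family has an independently
#' generated founder, and the other members are substitution-mutated copies
#' (planted frameshift regions protected), so that within-family MinHash
#' distances fall below the 0.05 clustering threshold and between-family
#' distances above it.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, one GenBank file per
#'   genome plus `truth.tsv` and `grouping.tsv` are written.
#' @return list with `genomes` (list of records), `truth` and `grouping`
#'   data.frames.
#' @export
make_corpus <- function(spec, dir = NULL) {
  n_fam <- spec$n_families
  sizes <- rep(spec$n_genomes %/% n_fam, n_fam)
  extra <- spec$n_genomes %% n_fam
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  genomes <- list()
  truth <- list()
  grouping <- list()
  for (fam in seq_len(n_fam)) {
    founder_seed <- spec$seed * 1000L + fam * 37L
    founder_id <- sprintf("synF%02dM01", fam)
    founder <- make_genome(spec, seed = founder_seed, id = founder_id)
    fam_members <- list(founder$record)
    fam_truth <- list(founder$truth)
    if (sizes[fam] > 1L) for (mm in 2:sizes[fam]) {
      mid <- sprintf("synF%02dM%02d", fam, mm)
      mrec <- mutate_record(founder$record, spec$mutation_rate,
                            seed = founder_seed + mm, id = mid)
      fam_members[[length(fam_members) + 1L]] <- mrec
      tt <- founder$truth
      if (nrow(tt)) tt$genome <- mid
      fam_truth[[length(fam_truth) + 1L]] <- tt
    }
    genomes <- c(genomes, fam_members)
    truth <- c(truth, fam_truth)
    grouping[[fam]] <- data.frame(
      genome_id = vapply(fam_members, `[[`, character(1), "locus_id"),
      cluster = sprintf("FAM%02d", fam),
      subcluster = sprintf("FAM%02da", fam),
      stringsAsFactors = FALSE)
  }
  truth_df <- do.call(rbind, truth)
  grouping_df <- do.call(rbind, grouping)
  rownames(truth_df) <- rownames(grouping_df) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (g in genomes)
      write_genbank(g, file.path(dir, paste0(g$locus_id, ".gbk")))
    utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(grouping_df, file.path(dir, "grouping.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genomes = genomes, truth = truth_df, grouping = grouping_df)
}
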