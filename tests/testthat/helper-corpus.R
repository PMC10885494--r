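# Shared fixtures built once per test run.

# Small two-family corpus with one planted backward frameshift per genome.
shared_spec <- fixture_spec(n_genomes = 6L, n_families = 2L, seed = 11L)
shared_corpus <- make_corpus(shared_spec)
shared_tables <- suppressMessages(
  lapply(shared_corpus$genomes, genome_candidate_table))
names(shared_tables) <- vapply(shared_corpus$genomes, `[[`, character(1),
                               "locus_id")
shared_sites <- do.call(rbind, lapply(shared_tables, `[[`, "sites"))
rownames(shared_sites) <- NULL

# Toy two-gene GenBank text in the style of the worked example: an ordinary
# gene at 1..100 and a frameshifted chaperone annotated as
# join(200..300,301..400).
toy_genbank_text <- local({
  set.seed(4L)
  sq <- sample(c("A", "C", "G", "T"), 600L, replace = TRUE)
  rec <- genome_record(
    "TOY", paste(sq, collapse = ""),
    list(cds_feature(matrix(c(1L, 100L), ncol = 2L), "+", product = "geneA"),
         cds_feature(matrix(c(200L, 300L, 301L, 400L), ncol = 2L,
                            byrow = TRUE), "+", product = "chaperone")))
  paste(write_genbank(rec), collapse = "\n")
})

# Independent run-length oracle for motif templates: a string matches a
# template iff its maximal-run decomposition equals the template lengths.
oracle_classify <- function(window, directions = c(-1L, 1L)) {
  defs <- list(
    six = c(6L), threethree = c(3L, 3L), fivetwo = c(5L, 2L),
    twofive = c(2L, 5L), twofour = c(2L, 4L), threetwotwo = c(3L, 2L, 2L),
    five = c(5L), twoonefour = c(2L, 1L, 4L), four = c(4L), three = c(3L))
  dirs <- c(rep(-1L, 8L), 1L, 1L)
  if (grepl("N", window, fixed = TRUE)) return(NA_character_)
  n <- nchar(window)
  best <- NA_character_
  best_key <- c(Inf, 0, Inf)
  for (i in seq_along(defs)) {
    if (!dirs[i] %in% directions) next
    tpl <- defs[[i]]
    sp <- sum(tpl)
    if (sp > n) next
    tail <- substr(window, n - sp + 1L, n)
    r <- rle(strsplit(tail, "")[[1]])
    if (!identical(r$lengths, tpl)) next
    prob <- 4 * 3^(length(tpl) - 1) / 4^sp
    key <- c(prob, -sp, i - 1L)
    better <- key[1] < best_key[1] ||
      (key[1] == best_key[1] && key[2] < best_key[2]) ||
      (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])
    if (better) { best <- names(defs)[i]; best_key <- key }
  }
  best
}

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
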