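test_that("the toy two-gene file parses with a joined second feature", {
  recs <- parse_genbank(toy_genbank_text)
  expect_length(recs, 1L)
  rec <- recs[[1]]
  expect_equal(rec$locus_id, "TOY")
  expect_length(rec$features, 2L)
  expect_false(rec$features[[1]]$joined)
  expect_equal(rec$features[[1]]$segments[1, ], c(start = 1L, end = 100L))
  f2 <- rec$features[[2]]
  expect_true(f2$joined)
  expect_equal(nrow(f2$segments), 2L)
  expect_equal(unname(f2$segments[1, ]), c(200L, 300L))
  expect_equal(unname(f2$segments[2, ]), c(301L, 400L))
  expect_equal(f2$product, "chaperone")
})

test_that("records with no CDS features parse to an empty feature list", {
  rec <- genome_record("EMPTY", random_dna(120, seed = 1))
  out <- parse_genbank(write_genbank(rec))[[1]]
  expect_length(out$features, 0L)
  expect_equal(out$sequence, rec$sequence)
})

test_that("a joined feature writes with the join( token and round-trips", {
  rec <- parse_genbank(toy_genbank_text)[[1]]
  txt <- write_genbank(rec)
  expect_true(any(grepl("join(", txt, fixed = TRUE)))
  again <- parse_genbank(txt)[[1]]
  expect_equal(again$features, rec$features)
})

test_that("parse/write round-trips preserve segments, strands and products", {
  set.seed(21)
  for (i in 1:25) {
    L <- sample(300:900, 1)
    sq <- random_dna(L)
    n_feat <- sample(0:4, 1)
    feats <- list()
    for (k in seq_len(n_feat)) {
      strand <- sample(c("+", "-"), 1)
      if (runif(1) < 0.4) {
        s1 <- sample(1:(L - 200), 1)
        e1 <- s1 + sample(30:80, 1)
        s2 <- e1 + sample(1:10, 1)
        e2 <- s2 + sample(30:80, 1)
        segs <- matrix(c(s1, e1, s2, e2), ncol = 2, byrow = TRUE)
        if (strand == "-") segs <- segs[2:1, , drop = FALSE]
      } else {
        s1 <- sample(1:(L - 100), 1)
        segs <- matrix(c(s1, s1 + sample(30:90, 1)), ncol = 2)
      }
      feats[[k]] <- cds_feature(segs, strand,
                                product = paste0("protein ", k))
    }
    rec <- genome_record(paste0("RT", i), sq, feats)
    out <- parse_genbank(write_genbank(rec))[[1]]
    expect_equal(out$sequence, rec$sequence)
    strip <- function(fs) lapply(fs, function(f) f[setdiff(names(f), "source_order")])
    expect_equal(strip(out$features), strip(rec$features))
  }
})

test_that("lowercase and RNA input canonicalize to uppercase DNA", {
  rec <- genome_record("RNA1", "augcnaugc")
  expect_equal(rec$sequence, "ATGCNATGC")
})

test_that("malformed locations and out-of-bounds segments are rejected", {
  txt <- strsplit(toy_genbank_text, "\n")[[1]]
  bad <- sub("join\\(200..300,301..400\\)", "join(200..300,abc)", txt)
  expect_error(parse_genbank(bad), "malformed location")
  oob <- sub("join\\(200..300,301..400\\)", "join(200..300,301..9000)", txt)
  expect_error(parse_genbank(oob), "outside")
})

test_that("fuzzy location qualifiers are dropped with a warning", {
  txt <- strsplit(toy_genbank_text, "\n")[[1]]
  fuzzy <- sub("CDS             1..100", "CDS             <1..100", txt)
  expect_warning(recs <- parse_genbank(fuzzy), "fuzzy")
  expect_equal(unname(recs[[1]]$features[[1]]$segments[1, ]), c(1L, 100L))
})

test_that("feature_sequence splices and strand-resolves correctly", {
  sq <- "ATGCATGCATGCATGCATGC"
  rec <- genome_record("FS", sq)
  plus <- cds_feature(matrix(c(3L, 8L), ncol = 2), "+")
  expect_equal(feature_sequence(rec, plus), substr(sq, 3, 8))
  minus <- cds_feature(matrix(c(1L, 4L), ncol = 2), "-")
  expect_equal(feature_sequence(rec, minus), "GCAT")   # revcomp of ATGC
  joined <- cds_feature(matrix(c(1L, 6L, 10L, 15L), ncol = 2, byrow = TRUE), "+")
  expect_equal(feature_sequence(rec, joined),
               paste0(substr(sq, 1, 6), substr(sq, 10, 15)))
  # minus-strand join: reading order is the high-coordinate segment first
  mj <- cds_feature(matrix(c(10L, 15L, 1L, 6L), ncol = 2, byrow = TRUE), "-")
  expect_equal(feature_sequence(rec, mj),
               paste0(revcomp(substr(sq, 10, 15)), revcomp(substr(sq, 1, 6))))
  expect_equal(nchar(feature_sequence(rec, joined)),
               sum(joined$segments[, 2] - joined$segments[, 1] + 1L))
})

test_that("codon usage counts in-frame codons and normalizes to 1", {
  rec <- genome_record("CU1", "ATGATGATGCCC",
                       list(cds_feature(matrix(c(1L, 9L), ncol = 2), "+")))
  u <- compute_codon_usage(rec)
  expect_equal(unname(u$freq[["ATG"]]), 1.0)
  expect_equal(sum(u$freq), 1.0)
  expect_equal(u$total_codons, 3L)

  # two genes with disjoint codons: hand-counted frequencies
  rec2 <- genome_record("CU2", "ATGATGGGGCCCTTT",
                        list(cds_feature(matrix(c(1L, 6L), ncol = 2), "+"),
                             cds_feature(matrix(c(7L, 15L), ncol = 2), "+")))
  u2 <- compute_codon_usage(rec2)
  expect_equal(unname(u2$freq[["ATG"]]), 2 / 5)
  expect_equal(unname(u2$freq[["GGG"]]), 1 / 5)
  expect_equal(unname(u2$freq[["CCC"]]), 1 / 5)
  expect_equal(unname(u2$freq[["TTT"]]), 1 / 5)
  expect_equal(sum(u2$freq), 1.0)
})

test_that("codons containing N are skipped and partial codons dropped", {
  rec <- genome_record("CU3", "ATGNNNATGCC",
                       list(cds_feature(matrix(c(1L, 11L), ncol = 2), "+")))
  u <- suppressMessages(compute_codon_usage(rec))
  expect_equal(u$total_codons, 2L)
  expect_equal(unname(u$freq[["ATG"]]), 1.0)
})

test_that("codon usage without usable CDS is an error", {
  rec <- genome_record("CU4", random_dna(50, seed = 2))
  expect_error(compute_codon_usage(rec), "annotated genes")
})

test_that("frequencies over fixture genomes sum to 1", {
  for (g in shared_corpus$genomes[1:2]) {
    u <- suppressMessages(compute_codon_usage(g))
    expect_equal(sum(u$freq), 1.0, tolerance = 1e-9)
    expect_true(all(u$freq >= 0))
    expect_length(u$freq, 64L)
  }
})
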