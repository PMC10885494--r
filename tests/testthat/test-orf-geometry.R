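join_feature <- function(e1, gap, len2 = 100L, start1 = 200L, strand = "+") {
  s2 <- e1 + gap + 1L
  segs <- matrix(c(start1, e1, s2, s2 + len2 - 1L), ncol = 2, byrow = TRUE)
  if (strand == "-") segs <- segs[2:1, , drop = FALSE]
  cds_feature(segs, strand, product = "chaperone")
}

test_that("splitting the toy chaperone join gives d = 0, backward", {
  f <- parse_genbank(toy_genbank_text)[[1]]$features[[2]]
  sj <- split_joined(f)
  expect_true(sj$accepted)
  expect_equal(sj$separation_d, 0L)
  expect_equal(sj$direction, -1L)
  expect_equal(unname(sj$upstream_fragment$segments[1, ]), c(200L, 300L))
  expect_equal(unname(sj$downstream_fragment$segments[1, ]), c(301L, 400L))
  expect_false(sj$upstream_fragment$joined)
})

test_that("a 1-nt separation is a forward shift", {
  sj <- split_joined(cds_feature(matrix(c(100L, 200L, 202L, 300L), ncol = 2,
                                        byrow = TRUE), "+"))
  expect_equal(sj$separation_d, 1L)
  expect_equal(sj$direction, 1L)
})

test_that("joins separated by more than 10 nt are rejected", {
  sj <- split_joined(cds_feature(matrix(c(1L, 50L, 500L, 600L), ncol = 2,
                                        byrow = TRUE), "+"))
  expect_equal(sj$separation_d, 449L)
  expect_false(sj$accepted)
  expect_true(is.na(sj$direction))
})

test_that("direction mapping is total on d in 0..10", {
  expected <- c(`0` = -1L, `1` = 1L, `2` = NA, `3` = -1L, `4` = 1L, `5` = NA,
                `6` = -1L, `7` = 1L, `8` = NA, `9` = -1L, `10` = 1L)
  for (d in 0:10) {
    f <- join_feature(300L, d)
    sj <- if (d %% 3L == 2L) {
      expect_warning(split_joined(f), "rejected")
      suppressWarnings(split_joined(f))
    } else split_joined(f)
    expect_equal(sj$separation_d, d)
    expect_equal(sj$direction, unname(expected[as.character(d)]))
  }
})

test_that("minus-strand separation is measured in reading direction", {
  # reading order: (500..600) then (397..496): gap 497..499 -> d = 3
  f <- cds_feature(matrix(c(500L, 600L, 397L, 496L), ncol = 2, byrow = TRUE),
                   "-")
  sj <- split_joined(f)
  expect_equal(sj$separation_d, 3L)
  expect_equal(sj$direction, -1L)
})

test_that("single-segment input is a contract error", {
  expect_error(split_joined(cds_feature(matrix(c(1L, 90L), ncol = 2), "+")),
               "joined feature")
})

# Build a plus-strand record with geneA (frame of a_start) and geneB
# overlapping near geneA's stop, controlling the nearest upstream stop in
# geneB's frame.
overlap_record <- function() {
  # geneA: ATG + 8 codons + TAA = 30 nt at 1..30. geneB starts at 23
  # (frame offset (23-1) %% 3 = 1 -> +1... choose 24: (24-1)%%3=2 -> -1).
  set.seed(5)
  sq <- rep("C", 120)
  orfA <- paste0("ATG", strrep("GCA", 7), "TAA")      # stop at 25..27
  sq[1:27] <- strsplit(orfA, "")[[1]]
  # geneB in frame starting 23: ensure no stop upstream in that frame
  sq[28:120] <- sample(c("A", "C", "G"), 93, replace = TRUE)
  rec <- genome_record("OV", paste(sq, collapse = ""))
  rec
}

test_that("overlap window ends at gene_a's stop and starts after the nearest
           upstream stop in gene_b's frame", {
  # Layout in the style of the worked overlap example: the window spans six
  # codons of gene_a's frame when the nearest gene_b-frame stop is six
  # codons upstream of gene_a's stop codon end.
  sq <- rep("C", 150)
  # gene_a: codons start at 1; stop TAA at 43..45
  sq[1:3] <- c("A", "T", "G")
  sq[43:45] <- c("T", "A", "A")
  # gene_b frame: starts at 47 -> (47-1) %% 3 = 1 -> frame offset +1...
  # use 48: (48-1) %% 3 = 2 -> -1 backward geometry
  # plant a gene_b-frame stop at 27..29 (27 = 48 - 21, in b frame)
  sq[27:29] <- c("T", "G", "A")
  rec <- genome_record("WIN", paste(sq, collapse = ""))
  ga <- cds_feature(matrix(c(1L, 45L), ncol = 2), "+")
  gb <- cds_feature(matrix(c(48L, 140L), ncol = 2), "+")
  w <- compute_overlap_window(ga, gb, rec)
  expect_equal(as.integer(w), c(30L, 45L))
  expect_equal(attr(w, "frame_offset"), -1L)
  # 16 nt window holds 5 full P-site codon ends of gene_a's frame; widening
  # the upstream stop distance widens the window codon-for-codon
  sq[27:29] <- "C"; sq[21:23] <- c("T", "G", "A")
  rec2 <- genome_record("WIN2", paste(sq, collapse = ""))
  w2 <- compute_overlap_window(ga, gb, rec2)
  expect_equal(as.integer(w2), c(24L, 45L))
})

test_that("adjacent genes on opposite strands yield no pair", {
  sq <- random_dna(400, seed = 8)
  rec <- genome_record("OPP", sq,
    list(cds_feature(matrix(c(1L, 90L), ncol = 2), "+"),
         cds_feature(matrix(c(80L, 200L), ncol = 2), "-")))
  expect_length(enumerate_pairs(rec$features, rec), 0L)
})

test_that("a gene_b-frame stop immediately before gene_b start empties the
           window when gene_b starts past gene_a's stop", {
  sq <- rep("C", 200)
  sq[1:3] <- c("A", "T", "G")
  sq[43:45] <- c("T", "A", "A")      # gene_a stop end at 45
  sq[50:52] <- c("T", "A", "A")      # gene_b-frame stop right before b start
  rec <- genome_record("EMP", paste(sq, collapse = ""))
  ga <- cds_feature(matrix(c(1L, 45L), ncol = 2), "+")
  gb <- cds_feature(matrix(c(53L, 150L), ncol = 2), "+")
  expect_null(compute_overlap_window(ga, gb, rec))
})

test_that("same-frame consecutive genes are not candidate pairs", {
  sq <- rep("C", 200)
  sq[1:3] <- c("A", "T", "G"); sq[43:45] <- c("T", "A", "A")
  rec <- genome_record("SF", paste(sq, collapse = ""))
  ga <- cds_feature(matrix(c(1L, 45L), ncol = 2), "+")
  gb <- cds_feature(matrix(c(40L, 150L), ncol = 2), "+")  # (40-1)%%3 == 0
  expect_null(compute_overlap_window(ga, gb, rec))
})

test_that("windows agree with a brute-force frame scan on random pairs", {
  set.seed(31)
  brute_window <- function(vseq, as, bs) {
    # forward walk for gene_a's stop
    stop_end <- NA
    for (q in seq(as, nchar(vseq) - 2, by = 3))
      if (substr(vseq, q, q + 2) %in% c("TAA", "TAG", "TGA")) {
        stop_end <- q + 2; break
      }
    if (is.na(stop_end) || bs > stop_end + 10) return(NULL)
    ws <- ((bs - 1) %% 3) + 1
    for (q in seq(bs - 3, 1, by = -3)) {
      if (q < 1) break
      if (substr(vseq, q, q + 2) %in% c("TAA", "TAG", "TGA")) {
        ws <- q + 3; break
      }
    }
    ws <- max(ws, as)
    if (ws > stop_end) NULL else c(ws, stop_end)
  }
  n_checked <- 0
  for (i in 1:60) {
    sq <- random_dna(400, gc = 0.4)
    as <- sample(1:60, 1)
    bs <- as + sample(c(1:80), 1)
    if ((bs - as) %% 3 == 0) next
    rec <- genome_record("RND", sq)
    ga <- cds_feature(matrix(c(as, as + 29L), ncol = 2), "+")
    gb <- cds_feature(matrix(c(bs, min(bs + 90L, 399L)), ncol = 2), "+")
    w <- compute_overlap_window(ga, gb, rec)
    bw <- brute_window(sq, as, bs)
    if (is.null(bw)) {
      expect_null(w)
    } else {
      expect_equal(as.integer(w), as.integer(bw))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("enumerate_pairs is invariant under feature permutation", {
  rec <- shared_corpus$genomes[[1]]
  feats <- Filter(function(f) !f$joined, rec$features)
  p1 <- enumerate_pairs(feats, rec)
  set.seed(9)
  p2 <- enumerate_pairs(sample(feats), rec)
  expect_equal(vapply(p1, `[[`, character(1), "pair_id"),
               vapply(p2, `[[`, character(1), "pair_id"))
})

test_that("emitted windows contain no gene_b-frame stop and end at gene_a's
           stop codon", {
  for (tab_name in names(shared_tables)[1:2]) {
    rec <- shared_corpus$genomes[[match(tab_name, names(shared_tables))]]
    feats <- prfscan:::split_record_features(rec)
    for (pr in enumerate_pairs(feats, rec)) {
      vseq <- prfscan:::view_sequence(rec, pr$strand)
      expect_equal(pr$window[2], pr$a_stop_end)
      expect_equal(substr(vseq, pr$a_stop_end - 2, pr$a_stop_end) %in%
                     c("TAA", "TAG", "TGA"), TRUE)
      # no gene_b-frame stop codon fully inside the window
      qs <- seq(pr$b_start, pr$window[1], by = -3)
      qs <- qs[qs >= pr$window[1] & qs + 2 <= pr$window[2] & qs < pr$b_start]
      if (length(qs)) {
        cods <- substring(vseq, qs, qs + 2)
        expect_false(any(cods %in% c("TAA", "TAG", "TGA")))
      }
    }
  }
})
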