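test_that("the full SD motif at ideal spacer scores the top bin", {
  up <- paste0(strrep("T", 9), "AGGAGG", strrep("T", 6))   # spacer 6
  expect_equal(score_rbs_prodigal(up), 27L)
  expect_equal(score_rbs_prodigal(strrep("T", 21)), 0L)
  # short submotif at ideal spacer: a mid-range bin, not the top
  up3 <- paste0(strrep("T", 12), "AGG", strrep("T", 6))
  expect_equal(score_rbs_prodigal(up3), 13L)
})

test_that("SD score never decreases when a motif is inserted", {
  set.seed(17)
  for (i in 1:40) {
    up <- random_dna(21)
    base <- score_rbs_prodigal(up)
    # inserting the full motif at ideal spacer reaches the top bin, so the
    # max-over-bins score cannot drop
    with_sd <- paste0(substr(up, 1, 9), "AGGAGG", substr(up, 16, 21))
    expect_gte(score_rbs_prodigal(with_sd), base)
    expect_equal(score_rbs_prodigal(with_sd), 27L)
  }
  # and a poorly spaced motif still lifts a scoreless window
  far <- paste0("AGGAGG", strrep("T", 15))
  expect_gt(score_rbs_prodigal(far), 0L)
})

test_that("RBS scores ignore bases 5' of the scanned spacer range", {
  set.seed(18)
  for (i in 1:20) {
    up <- random_dna(21)
    pre <- random_dna(15)
    expect_equal(score_rbs_prodigal(paste0(pre, up)), score_rbs_prodigal(up))
    expect_equal(score_rbs_rast(paste0(pre, up)), score_rbs_rast(up))
  }
})

test_that("the weighted RBS score is 0 without SD content and capped at 6.3", {
  expect_equal(score_rbs_rast(strrep("T", 21)), 0)
  up <- paste0(strrep("T", 9), "AGGAGG", strrep("T", 6))
  expect_equal(score_rbs_rast(up), 6.3)
  tab <- rbs2_weight_table()
  expect_true(all(tab$weight <= 6.3 & tab$weight >= 0))
  expect_setequal(names(tab), c("motif", "spacer_size", "weight"))
})

test_that("folding returns 0 for unpairable sequence and negative MFE for a
           hairpin, monotone in stem length", {
  expect_equal(fold_mfe("AAAAAAAAAA"), 0)
  mfes <- vapply(c(5, 7, 9, 11), function(k) {
    stem <- strrep("GC", k)
    fold_mfe(paste0(stem, "GAAA", revcomp(stem)))
  }, numeric(1))
  expect_true(all(mfes < 0))
  expect_true(all(diff(mfes) < 0))   # longer stems fold at least as strongly
  expect_error(fold_mfe("ACGTN"), "A/C/G/T")
  expect_error(fold_mfe(strrep("A", 150)), "120")
})

test_that("the pseudoknot engine currently duplicates the hairpin fold", {
  seqs <- c("GGGGCCCCGGGGAAAACCCC", random_dna(50, seed = 3))
  expect_equal(fold_mfe(seqs, "pseudoknot"), fold_mfe(seqs, "hairpin"))
})

test_that("normalized MFE is clamped to [0,1], antitone in GC, zero for
           empty or unfoldable windows", {
  expect_equal(normalized_mfe(0, "AAAAAAAAAA"), 0)
  expect_equal(normalized_mfe(-5, ""), 0)
  # same mfe, higher GC -> smaller normalized value
  lo_gc <- paste0(strrep("AT", 20), strrep("GC", 5))
  hi_gc <- paste0(strrep("AT", 5), strrep("GC", 20))
  expect_gt(normalized_mfe(-10, lo_gc), normalized_mfe(-10, hi_gc))
  gcs <- seq(0.1, 0.9, by = 0.2)
  vals <- vapply(gcs, function(g) {
    n_gc <- round(50 * g)
    w <- paste0(strrep("G", n_gc), strrep("A", 50 - n_gc))
    normalized_mfe(-8, w)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # antitone in mfe for fixed window
  w <- random_dna(50, seed = 5)
  expect_gt(normalized_mfe(-20, w), normalized_mfe(-5, w))
  # AT-only window: the GC floor keeps the value finite and clamped
  expect_equal(normalized_mfe(-100, strrep("AT", 25)), 1)
})

test_that("distance to stop matches a brute-force codon walk", {
  s <- shared_sites
  for (i in seq_len(nrow(s))) {
    rec <- shared_corpus$genomes[[match(s$genome[i], names(shared_tables))]]
    vseq <- prfscan:::view_sequence(rec, s$strand[i])
    p <- s$p_site_end[i]
    n_walk <- NA
    for (q in seq(p + 1, nchar(vseq) - 2, by = 3)) {
      if (substr(vseq, q, q + 2) %in% c("TAA", "TAG", "TGA")) {
        n_walk <- q - p - 1
        break
      }
    }
    expect_equal(s$N[i], n_walk)
  }
  expect_true(all(s$N >= 0))
})

test_that("a candidate whose A-site codon is the stop has N = 0", {
  pair <- list(a_stop_end = 103L)
  expect_equal(distance_to_stop(100L, pair), 0L)
  expect_error(distance_to_stop(104L, pair), "past gene_a's stop")
})

test_that("build_features maps candidate fields and stays in range", {
  rec <- shared_corpus$genomes[[1]]
  usage <- suppressMessages(compute_codon_usage(rec))
  feats <- prfscan:::split_record_features(rec)
  prs <- enumerate_pairs(feats, rec)
  checked <- 0
  for (pr in prs) {
    cands <- scan_overlap(pr, usage, rec)
    for (j in seq_len(nrow(cands))) {
      fv <- build_features(cands[j, ], pr, usage, rec)
      expect_named(fv, c("DIR", "RBS1", "RBS2", "MOTIF", "A0", "A1",
                         "LF50", "LF100", "HK50", "HK100", "N"))
      expect_equal(unname(fv["DIR"]), cands$direction[j])
      expect_equal(unname(fv["MOTIF"]), cands$motif_code[j])
      expect_true(fv["RBS1"] %in% 0:27)
      expect_true(fv["RBS2"] >= 0 && fv["RBS2"] <= 6.3)
      expect_true(all(fv[c("A0", "A1", "LF50", "LF100", "HK50", "HK100")] >= 0))
      expect_true(all(fv[c("A0", "A1", "LF50", "LF100", "HK50", "HK100")] <= 1))
      expect_gte(fv["N"], 0)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 3)
})

test_that("a planted site dominates decoy candidates in structure, RBS and
           proximity to the stop", {
  s <- shared_sites
  pos <- s[s$label != 0 & s$junction_dist <= 2, ]
  neg <- s[!s$from_join, ]
  expect_gt(nrow(pos), 0)
  expect_gt(nrow(neg), 0)
  expect_gt(min(pos$LF50), max(0.5, mean(neg$LF50)))
  expect_gte(min(pos$RBS1), 27)
})
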