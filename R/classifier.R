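# Training-set assembly, the 3-class gradient-boosted model, and prediction.
#
# Classes are the direction of the shift: -1 (backward), 0 (no frameshift),
# +1 (forward). Positive labels come from join-annotated genes: the joined
# gene is split into its two fragments, re-inserted as a pseudo gene pair,
# and scanned like any other pair; candidates whose P-site codon end lies
# within 10 nt of the annotated junction inherit the join's direction, all
# other candidates are labeled 0.

JUNCTION_TOL <- 10L

# Split every accepted joined feature of a record into tagged fragments;
# rejected joins are dropped with a warning.
split_record_features <- function(record) {
  out <- list()
  join_id <- 0L
  for (f in record$features) {
    if (!f$joined) {
      out[[length(out) + 1L]] <- f
      next
    }
    sj <- split_joined(f)
    if (!sj$accepted) {
      warning("dropping rejected joined feature in ", record$locus_id,
              call. = FALSE)
      next
    }
    join_id <- join_id + 1L
    jid <- sprintf("%s.j%d", record$locus_id, join_id)
    junction <- if (f$strand == "+") f$segments[1L, "end"] else f$segments[1L, "start"]
    f1 <- sj$upstream_fragment
    f2 <- sj$downstream_fragment
    attr(f1, "join_id") <- jid; attr(f2, "join_id") <- jid
    attr(f1, "frag_rank") <- 1L; attr(f2, "frag_rank") <- 2L
    attr(f1, "join_direction") <- sj$direction
    attr(f2, "join_direction") <- sj$direction
    attr(f1, "junction_genome") <- as.integer(junction)
    attr(f2, "junction_genome") <- as.integer(junction)
    out[[length(out) + 1L]] <- f1
    out[[length(out) + 1L]] <- f2
  }
  out
}

#' Candidate table of one genome
#'
#' Runs the full per-genome candidate pipeline: joined features are split
#' into pseudo gene pairs, candidate pairs are enumerated, overlap windows
#' scanned for slippery motifs, and the eleven signal features computed for
#' every candidate (RNA windows are folded in one batch). Candidates of
#' join-derived pairs within 10 nt of the annotated junction carry the
#' join's direction as `label`; everything else is labeled 0.
#'
#' @param record a [genome_record()] with CDS features.
#' @param usage optional precomputed codon usage (defaults to
#'   [compute_codon_usage()] on the record).
#' @return list with `sites` (one row per candidate: provenance, view and
#'   genome coordinates, motif, label, junction distance and the
#'   feature columns) and `pairs` (the candidate-pair universe with
#'   `pair_id`, `from_join`, `join_direction`).
#' @export
genome_candidate_table <- function(record, usage = NULL) {
  if (is.null(usage)) usage <- compute_codon_usage(record)
  feats <- split_record_features(record)
  pairs <- enumerate_pairs(feats, record)
  L <- nchar(record$sequence)

  pair_rows <- list()
  cand_rows <- list()
  vcache <- list()
  for (pr in pairs) {
    jid_a <- attr(pr$gene_a, "join_id")
    jid_b <- attr(pr$gene_b, "join_id")
    from_join <- !is.null(jid_a) && !is.null(jid_b) && identical(jid_a, jid_b) &&
      identical(attr(pr$gene_a, "frag_rank"), 1L)
    join_dir <- if (from_join) attr(pr$gene_a, "join_direction") else NA_integer_
    junction_v <- if (from_join) {
      genome_to_view(attr(pr$gene_a, "junction_genome"), pr$strand, L)
    } else NA_integer_
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      genome = record$locus_id, pair_id = pr$pair_id, strand = pr$strand,
      from_join = from_join, join_direction = join_dir,
      junction_view = junction_v, stringsAsFactors = FALSE)

    cands <- scan_overlap(pr, usage, record)
    if (!nrow(cands)) next
    if (is.null(vcache[[pr$strand]]))
      vcache[[pr$strand]] <- view_sequence(record, pr$strand)
    vseq <- vcache[[pr$strand]]
    cands$genome <- record$locus_id
    cands$pair_id <- pr$pair_id
    cands$strand <- pr$strand
    cands$gene_a <- format_location(pr$gene_a)
    cands$gene_b <- format_location(pr$gene_b)
    cands$position <- view_to_genome(cands$pos, pr$strand, L)
    cands$junction_dist <- if (from_join) {
      abs(cands$p_site_end - junction_v)
    } else NA_integer_
    cands$from_join <- from_join
    cands$label <- ifelse(from_join & cands$junction_dist <= JUNCTION_TOL,
                          join_dir, 0L)
    cands$upstream <- vapply(cands$p_site_end, function(p)
      rbs_upstream_seq(vseq, p), character(1))
    cands$w50 <- vapply(cands$p_site_end, function(p)
      fold_window_seq(vseq, p, 50L), character(1))
    cands$w100 <- vapply(cands$p_site_end, function(p)
      fold_window_seq(vseq, p, 100L), character(1))
    cands$N <- vapply(cands$p_site_end, function(p)
      distance_to_stop(p, pr), integer(1))
    cand_rows[[length(cand_rows) + 1L]] <- cands
  }

  pairs_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(genome = character(0), pair_id = character(0),
               strand = character(0), from_join = logical(0),
               join_direction = integer(0), junction_view = integer(0),
               stringsAsFactors = FALSE)
  if (!length(cand_rows)) {
    return(list(sites = empty_sites_df(), pairs = pairs_df, usage = usage))
  }
  sites <- do.call(rbind, cand_rows)

  # one folding batch per genome (both window sizes; cache dedupes)
  windows <- c(sites$w50, sites$w100)
  nonempty <- nzchar(windows)
  if (any(nonempty)) fold_mfe(windows[nonempty], "hairpin")
  norm_one <- function(w) {
    if (!nzchar(w)) return(0)
    normalized_mfe(fold_mfe(w, "hairpin"), w)
  }
  sites$LF50 <- vapply(sites$w50, norm_one, numeric(1), USE.NAMES = FALSE)
  sites$LF100 <- vapply(sites$w100, norm_one, numeric(1), USE.NAMES = FALSE)
  # no pseudoknot-capable backend: same thermodynamic fold (model metadata
  # records this)
  sites$HK50 <- sites$LF50
  sites$HK100 <- sites$LF100
  sites$DIR <- as.numeric(sites$direction)
  sites$MOTIF <- as.numeric(sites$motif_code)
  sites$RBS1 <- vapply(sites$upstream, function(u)
    as.numeric(score_rbs_prodigal(u)), numeric(1), USE.NAMES = FALSE)
  sites$RBS2 <- vapply(sites$upstream, score_rbs_rast, numeric(1),
                       USE.NAMES = FALSE)
  sites$upstream <- NULL; sites$w50 <- NULL; sites$w100 <- NULL
  rownames(sites) <- NULL
  list(sites = sites, pairs = pairs_df, usage = usage)
}

empty_sites_df <- function() {
  df <- data.frame(pos = integer(0), p_site_end = integer(0),
                   motif = character(0), motif_code = integer(0),
                   direction = integer(0), a0_codon = character(0),
                   a1_codon = character(0), A0 = numeric(0), A1 = numeric(0),
                   genome = character(0), pair_id = character(0),
                   strand = character(0), gene_a = character(0),
                   gene_b = character(0), position = integer(0),
                   junction_dist = integer(0), from_join = logical(0),
                   label = integer(0), stringsAsFactors = FALSE)
  for (col in c("N", "LF50", "LF100", "HK50", "HK100", "DIR", "MOTIF",
                "RBS1", "RBS2"))
    df[[col]] <- numeric(0)
  df
}

#' Assemble a labeled training set from join-annotated genomes
#'
#' @param genomes list of [genome_record()]s whose joined CDS features mark
#'   known frameshifted genes.
#' @return data.frame of labeled candidate sites (see
#'   [genome_candidate_table()]), rows from all genomes combined.
#' @export
assemble_training_set <- function(genomes) {
  tabs <- list()
  for (g in genomes) {
    if (!length(g$features)) {
      warning("genome ", g$locus_id, " has no CDS features; skipped",
              call. = FALSE)
      next
    }
    tabs[[length(tabs) + 1L]] <- genome_candidate_table(g)$sites
  }
  if (!length(tabs)) return(empty_sites_df())
  do.call(rbind, tabs)
}

# ---- model -----------------------------------------------------------------

PRF_CLASSES <- c(-1L, 0L, 1L)

#' Train the 3-class frameshift classifier
#'
#' Fits a histogram-based gradient-boosted tree ensemble (xgboost backend:
#' `tree_method = "hist"`, loss-guided growth with 31 leaves, learning rate
#' 0.1, 100 rounds) on the eleven signal features, predicting -1 (backward
#' shift), 0 (no shift) or +1 (forward shift). The L2 regularization
#' parameter is 1.0 and no early stopping is used, so training is
#' deterministic for a fixed dataset order and seed.
#'
#' @param sites labeled candidate table from [assemble_training_set()].
#' @param seed integer seed recorded in the model.
#' @return a `prf_model` object.
#' @export
train_prf_model <- function(sites, seed = 1L) {
  if (!nrow(sites)) stop("empty training set")
  if (length(unique(sites$label)) < 2L)
    stop("training requires at least two classes; got only label ",
         unique(sites$label))
  X <- as.matrix(sites[, FEATURE_COLS])
  y <- match(sites$label, PRF_CLASSES) - 1L
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(
    booster = "gbtree", objective = "multi:softprob", num_class = 3L,
    tree_method = "hist", grow_policy = "lossguide",
    max_depth = 0L, max_leaves = 31L, eta = 0.1, lambda = 1.0,
    nthread = 1L, seed = as.integer(seed))
  bst <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 100L,
                            verbose = 0L)
  structure(list(
    booster_raw = xgboost::xgb.save.raw(bst),
    feature_cols = FEATURE_COLS,
    feature_schema_version = FEATURE_SCHEMA_VERSION,
    motif_catalog_version = MOTIF_CATALOG_VERSION,
    classes = PRF_CLASSES,
    class_counts = table(factor(sites$label, levels = PRF_CLASSES)),
    seed = as.integer(seed),
    engines = c(hairpin = "viennarna",
                pseudoknot = "viennarna (no pseudoknot backend installed; "
                             %+% "duplicates the hairpin fold)")
  ), class = "prf_model")
}

`%+%` <- function(a, b) paste0(a, b)

#' @export
print.prf_model <- function(x, ...) {
  cat("<prf_model> 3-class gradient-boosted frameshift classifier\n")
  cat("  features:", paste(x$feature_cols, collapse = ", "), "\n")
  cat("  training class counts:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = " "), "\n")
  invisible(x)
}

model_booster <- function(model) {
  if (is.null(model$.booster)) xgboost::xgb.load.raw(model$booster_raw)
  else model$.booster
}

#' Save / load a trained model
#'
#' The model container embeds the feature-schema and motif-catalog versions
#' it was trained with; loading a model with a mismatched schema is an
#' error.
#'
#' @param model a `prf_model`.
#' @param path file path.
#' @return `load_prf_model` returns the `prf_model`.
#' @export
save_prf_model <- function(model, path) {
  model$.booster <- NULL
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_prf_model
#' @export
load_prf_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "prf_model")) stop("not a prf_model file: ", path)
  if (!identical(model$feature_schema_version, FEATURE_SCHEMA_VERSION) ||
      !identical(model$motif_catalog_version, MOTIF_CATALOG_VERSION))
    stop("model was trained with feature schema ",
         model$feature_schema_version, " / motif catalog ",
         model$motif_catalog_version, "; this build requires ",
         FEATURE_SCHEMA_VERSION, " / ", MOTIF_CATALOG_VERSION)
  model
}

#' Score candidate sites with a trained model
#'
#' @param model a `prf_model`.
#' @param sites candidate table with the model's feature columns.
#' @return `sites` with added columns `prob_back`, `prob_none`, `prob_fwd`,
#'   `pred_class` (-1/0/+1) and `score` (probability of the predicted
#'   non-zero class, NA for predicted class 0).
#' @export
predict_sites <- function(model, sites) {
  stopifnot(inherits(model, "prf_model"))
  if (!nrow(sites)) {
    sites$prob_back <- numeric(0); sites$prob_none <- numeric(0)
    sites$prob_fwd <- numeric(0); sites$pred_class <- integer(0)
    sites$score <- numeric(0)
    return(sites)
  }
  bst <- model_booster(model)
  X <- as.matrix(sites[, model$feature_cols])
  pr <- predict(bst, xgboost::xgb.DMatrix(X))
  if (!is.matrix(pr)) pr <- matrix(pr, ncol = 3L, byrow = TRUE)
  idx <- max.col(pr, ties.method = "first")
  sites$prob_back <- pr[, 1L]
  sites$prob_none <- pr[, 2L]
  sites$prob_fwd <- pr[, 3L]
  sites$pred_class <- PRF_CLASSES[idx]
  sites$score <- ifelse(sites$pred_class == 0L, NA_real_,
                        pr[cbind(seq_len(nrow(pr)), idx)])
  sites
}

#' Select at most one predicted site per gene pair
#'
#' Among a pair's candidates with a non-zero predicted class, returns the
#' one with the highest class probability; ties broken by smaller N
#' (closer to the in-frame stop), then by 5'-most position. `NULL` when no
#' candidate is predicted to shift.
#'
#' @param scored scored candidates of one pair (see [predict_sites()]).
#' @return one-row data.frame or `NULL`.
#' @export
predict_pair <- function(scored) {
  hits <- scored[!is.na(scored$score), , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(-hits$score, hits$N, hits$pos), , drop = FALSE]
  hits[1L, , drop = FALSE]
}

predictions_from_sites <- function(model, sites) {
  scored <- predict_sites(model, sites)
  out <- list()
  for (pid in unique(scored$pair_id)) {
    sel <- predict_pair(scored[scored$pair_id == pid, , drop = FALSE])
    if (!is.null(sel)) out[[length(out) + 1L]] <- sel
  }
  if (!length(out)) return(scored[0L, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict frameshift sites across a genome
#'
#' Runs the full pipeline of the method: enumerate candidate gene pairs,
#' scan overlap windows for slippery motifs, compute the eleven signal
#' features, score with the model, and keep at most the highest-scoring
#' site per pair. Predicted pairs are merged into joined CDS features in
#' the returned annotated copy of the record.
#'
#' @param model a `prf_model`.
#' @param record a [genome_record()] with CDS features.
#' @return list with `predictions` (data.frame, one row per predicted pair),
#'   `record` (annotated copy) and `sites` (all scored candidates).
#' @export
predict_genome <- function(model, record) {
  if (!length(record$features))
    stop("genome ", record$locus_id,
         " has no CDS features; the method requires gene calls")
  ct <- genome_candidate_table(record)
  preds <- predictions_from_sites(model, ct$sites)
  annotated <- annotate_predictions(record, preds)
  list(predictions = prediction_report(preds),
       record = annotated,
       sites = if (nrow(ct$sites)) predict_sites(model, ct$sites) else ct$sites)
}

prediction_report <- function(preds) {
  if (!nrow(preds)) {
    cols <- c("genome", "gene_a", "gene_b", "position", "direction",
              "motif_name", "score", "N", FEATURE_COLS)
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
    return(df)
  }
  data.frame(genome = preds$genome, gene_a = preds$gene_a,
             gene_b = preds$gene_b, position = preds$position,
             direction = preds$pred_class, motif_name = preds$motif,
             score = preds$score, N = preds$N,
             preds[, FEATURE_COLS], stringsAsFactors = FALSE)
}

# Merge each predicted pair's two genes into one joined CDS feature.
annotate_predictions <- function(record, preds) {
  if (!nrow(preds)) return(record)
  L <- nchar(record$sequence)
  feats <- split_record_features(record)
  keyed <- vapply(feats, format_location, character(1))
  for (i in seq_len(nrow(preds))) {
    p <- preds$p_site_end[i]          # view coordinate
    strand <- preds$strand[i]
    dirn <- preds$pred_class[i]
    ia <- match(preds$gene_a[i], keyed)
    ib <- match(preds$gene_b[i], keyed)
    if (is.na(ia) || is.na(ib)) next
    fa <- feats[[ia]]; fb <- feats[[ib]]
    j <- if (dirn == -1L) p + 2L else p
    gap <- if (dirn == -1L) 1L else 2L
    a_span <- feature_view_span(fa, L)
    b_span <- feature_view_span(fb, L)
    v1 <- c(a_span[1L], j)
    v2 <- c(j + gap, b_span[2L])
    # reading order is preserved: fragment 1 (5' in reading direction) first
    to_seg <- function(v) sort(view_to_genome(v, strand, L))
    segs <- rbind(to_seg(v1), to_seg(v2))
    joined <- cds_feature(segs, strand = strand,
                          product = paste0(fa$product,
                                           " [predicted ribosomal frameshift]"),
                          source_order = fa$source_order)
    feats[[ia]] <- joined
    feats[ib] <- NULL
    keyed <- vapply(feats, format_location, character(1))
  }
  genome_record(record$locus_id, record$sequence, feats)
}

#' Write a prediction report as TSV
#'
#' @param predictions data.frame from [predict_genome()].
#' @param path output file.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
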