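# Taxon-aware leave-one-out validation and TP/FP scoring.
#
# The training corpus a frameshift model is built from is typically highly
# redundant (near-identical genomes recur), so plain per-genome leave-one-out
# overstates recall. Validation is therefore run at a chosen grouping level:
# GENOME (each genome its own group), MASH95 (genomes clustered at ~95%
# identity, i.e. MinHash distance <= 0.05), or metadata-derived CLUSTER /
# SUBCLUSTER labels.

#' MinHash sketch of a genome
#'
#' Bottom-s sketch over canonical k-mers (lexicographic minimum of each
#' k-mer and its reverse complement), hashed with a fixed 64-bit mixer.
#' Defaults follow the standard genome-distance parameterization: sketch
#' size 400 and k = 16.
#'
#' @param x a [genome_record()] or nucleotide string.
#' @param k k-mer size.
#' @param s sketch size.
#' @param id sketch identifier (defaults to the record's locus id).
#' @return object of class `minhash_sketch` with sorted ascending `hashes`.
#' @export
minhash_sketch <- function(x, k = 16L, s = 400L, id = NULL) {
  if (inherits(x, "genome_record")) {
    if (is.null(id)) id <- x$locus_id
    x <- x$sequence
  }
  if (is.null(id)) id <- "seq"
  structure(list(id = id, k = as.integer(k), s = as.integer(s),
                 hashes = .minhash_hashes(x, as.integer(k), as.integer(s))),
            class = "minhash_sketch")
}

#' MinHash (Mash) distance between two sketches
#'
#' The Jaccard index `j` is estimated from the merged-sketch construction
#' (the s smallest hashes of the union; the fraction of those present in
#' both sketches), and converted to a distance
#' `d = -(1/k) * log(2j / (1+j))`. Identical sequences give d = 0; sketches
#' sharing no hashes give d = Inf.
#'
#' @param a,b `minhash_sketch` objects with the same `k` and `s`.
#' @return non-negative distance (possibly `Inf`).
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k || a$s != b$s)
    stop("sketches have mismatched k or sketch size")
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(length(u), a$s))]
  if (!length(u)) return(Inf)
  shared <- sum(u %in% a$hashes & u %in% b$hashes)
  j <- shared / length(u)
  if (j <= 0) return(Inf)
  if (j >= 1) return(0)
  -(1 / a$k) * log(2 * j / (1 + j))
}

#' Cluster genomes at ~95% identity by MinHash distance
#'
#' Single-linkage clustering of the pairwise MinHash distance graph
#' thresholded at `d <= threshold` (default 0.05, analogous to 95%
#' identity). Cluster labels are deterministic: each cluster is named after
#' its lexicographically smallest member id.
#'
#' @param genomes list of [genome_record()]s (or `minhash_sketch`es).
#' @param threshold distance threshold.
#' @param k,s sketch parameters.
#' @return named character vector: genome id -> cluster label.
#' @export
cluster_mash95 <- function(genomes, threshold = 0.05, k = 16L, s = 400L) {
  stopifnot(length(genomes) >= 1L)
  sketches <- lapply(genomes, function(g) {
    if (inherits(g, "minhash_sketch")) g else minhash_sketch(g, k = k, s = s)
  })
  ids <- vapply(sketches, `[[`, character(1), "id")
  n <- length(sketches)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (mash_distance(sketches[[i]], sketches[[j]]) <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- character(n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    labels[members] <- min(ids[members])
  }
  stats::setNames(labels, ids)
}

#' Score predictions against join-annotated truth
#'
#' A prediction is a True Positive when it belongs to a join-derived gene
#' pair and its P-site codon end lies within `tol` nt of the annotated
#' junction; predictions further away or on non-joined pairs are False
#' Positives. A joined gene with no TP prediction is a False Negative; a
#' non-joined candidate pair with no prediction is a True Negative.
#' Precision is reported as 1.0 (flagged) when there are no predictions.
#'
#' @param predictions data.frame of selected per-pair predictions (rows of
#'   the candidate table; needs `pair_id`, `from_join`, `junction_dist`).
#' @param pairs the candidate-pair universe (`pair_id`, `from_join`).
#' @param tol junction tolerance in nt.
#' @param level optional label stored in the summary.
#' @return object of class `eval_summary`: TP/FP/TN/FN counts and recall,
#'   precision, accuracy.
#' @export
score_predictions <- function(predictions, pairs, tol = 10L, level = NA) {
  n_joined <- sum(pairs$from_join)
  n_plain <- sum(!pairs$from_join)
  if (nrow(predictions)) {
    is_tp <- predictions$from_join & !is.na(predictions$junction_dist) &
      predictions$junction_dist <= tol
    tp_pairs <- unique(predictions$pair_id[is_tp])
    TP <- length(tp_pairs)
    FP <- nrow(predictions) - sum(is_tp)
    preds_on_plain <- sum(!predictions$from_join)
  } else {
    TP <- 0L; FP <- 0L; preds_on_plain <- 0L
  }
  FN <- n_joined - TP
  TN <- n_plain - preds_on_plain
  total <- TP + FP + TN + FN
  precision_defined <- (TP + FP) > 0L
  structure(list(
    level = level, TP = TP, FP = FP, TN = TN, FN = FN,
    recall = if (TP + FN > 0L) TP / (TP + FN) else NA_real_,
    precision = if (precision_defined) TP / (TP + FP) else 1.0,
    precision_defined = precision_defined,
    accuracy = if (total > 0L) (TP + TN) / total else 1.0
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary>%s TP=%d FP=%d TN=%d FN=%d\n",
              if (is.na(x$level)) "" else paste0(" [", x$level, "]"),
              x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  recall=%.3f precision=%.3f%s accuracy=%.3f\n",
              x$recall, x$precision,
              if (!x$precision_defined) " (no predictions)" else "",
              x$accuracy))
  invisible(x)
}

#' Leave-one-group-out validation
#'
#' For every group at the chosen level, a model is trained on all candidate
#' sites outside the group and predictions are made for the group's
#' genomes; the merged predictions are scored with [score_predictions()].
#'
#' @param genomes list of join-annotated [genome_record()]s.
#' @param level `"GENOME"`, `"MASH95"`, `"CLUSTER"` or `"SUBCLUSTER"`.
#' @param grouping data.frame with columns `genome_id`, `cluster`,
#'   `subcluster` (required for CLUSTER/SUBCLUSTER).
#' @param seed training seed.
#' @param tol junction tolerance in nt.
#' @param tables optional precomputed list of per-genome candidate tables
#'   (as returned by [genome_candidate_table()]), named by locus id.
#' @return `eval_summary` with extra fields `n_models` and `predictions`.
#' @export
loo_validate <- function(genomes, level = c("GENOME", "MASH95", "CLUSTER",
                                            "SUBCLUSTER"),
                         grouping = NULL, seed = 1L, tol = 10L,
                         tables = NULL) {
  level <- match.arg(level)
  ids <- vapply(genomes, `[[`, character(1), "locus_id")
  groups <- switch(level,
    GENOME = stats::setNames(ids, ids),
    MASH95 = cluster_mash95(genomes),
    CLUSTER = ,
    SUBCLUSTER = {
      if (is.null(grouping))
        stop(level, "-level validation requires grouping metadata")
      col <- if (level == "CLUSTER") "cluster" else "subcluster"
      g <- grouping[[col]][match(ids, grouping$genome_id)]
      if (anyNA(g)) stop("grouping metadata misses some genomes")
      stats::setNames(as.character(g), ids)
    })
  if (length(unique(groups)) < 2L)
    stop("level ", level, " yields a single group; no held-out complement")
  if (is.null(tables)) {
    tables <- lapply(genomes, genome_candidate_table)
    names(tables) <- ids
  }
  all_sites <- do.call(rbind, lapply(tables, `[[`, "sites"))
  all_pairs <- do.call(rbind, lapply(tables, `[[`, "pairs"))
  preds <- list()
  n_models <- 0L
  for (grp in sort(unique(groups))) {
    held <- ids[groups == grp]
    train_sites <- all_sites[!(all_sites$genome %in% held), , drop = FALSE]
    model <- train_prf_model(train_sites, seed = seed)
    n_models <- n_models + 1L
    test_sites <- all_sites[all_sites$genome %in% held, , drop = FALSE]
    if (nrow(test_sites))
      preds[[length(preds) + 1L]] <- predictions_from_sites(model, test_sites)
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    all_sites[0L, , drop = FALSE]
  out <- score_predictions(predictions, all_pairs, tol = tol, level = level)
  out$n_models <- n_models
  out$predictions <- predictions
  out
}
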