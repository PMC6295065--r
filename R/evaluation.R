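# Leave-one-out cross-validation, ranking AUC, and case-study rankings.

#' Mann-Whitney ROC AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counting one half; identical to the trapezoidal
#' area under the threshold-swept ROC curve. Computed from midranks, so tie
#' handling is exact.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length (at least one of each class).
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.8, 0.6, 0.4), c(1, 0, 1))  # one win, one loss: 0.5
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("need at least one positive and one negative label", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# rank of the test score among {test} + negatives, descending, ties averaged
heldout_rank <- function(test_score, neg_scores) {
  1 + sum(neg_scores > test_score) + sum(neg_scores == test_score) / 2
}

loocv_engine <- function(A, W_m, W_d, mode, config,
                         recompute_mirna_similarity = FALSE,
                         keep_scores = FALSE, verbose = FALSE) {
  check_fit_labels(A, W_m, W_d)
  known <- which(A == 1, arr.ind = TRUE)
  if (nrow(known) < 2L)
    stop("LOOCV needs at least 2 known associations", call. = FALSE)
  wins <- 0; comparisons <- 0
  per_fold <- vector("list", nrow(known))
  skipped <- character(0)
  dstat <- new.env(parent = emptyenv())
  score_pairs <- if (keep_scores) vector("list", nrow(known)) else NULL
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1L]; j <- known[f, 2L]
    A2 <- A
    A2[i, j] <- 0
    Wm2 <- if (recompute_mirna_similarity) mirna_functional_similarity(A2, W_d) else W_m
    fit <- l1graph(A2, Wm2, W_d, config = config)
    s <- fit$scores
    test <- s[i, j]
    neg <- if (mode == "global") s[A == 0] else s[A[, j] == 0, j]
    if (length(neg) == 0L) {
      skipped <- c(skipped, sprintf("%s/%s", rownames(A)[i], colnames(A)[j]))
      if (verbose)
        message(sprintf("fold %s/%s skipped: no negative candidates",
                        rownames(A)[i], colnames(A)[j]))
      next
    }
    w <- sum(neg < test) + sum(neg == test) / 2
    wins <- wins + w
    comparisons <- comparisons + length(neg)
    dis <- colnames(A)[j]
    st <- if (is.null(dstat[[dis]])) c(0, 0) else dstat[[dis]]
    dstat[[dis]] <- st + c(w, length(neg))
    per_fold[[f]] <- data.frame(
      mirna = rownames(A)[i], disease = dis,
      rank = heldout_rank(test, neg), candidate_count = length(neg) + 1L,
      stringsAsFactors = FALSE)
    if (keep_scores) score_pairs[[f]] <- list(test = test, neg = neg)
  }
  per_fold <- do.call(rbind, per_fold)
  if (is.null(per_fold) || nrow(per_fold) == 0L)
    stop("all LOOCV folds were skipped", call. = FALSE)
  pda <- vapply(ls(dstat), function(d) dstat[[d]][1] / dstat[[d]][2], numeric(1))
  structure(list(mode = mode,
                 per_fold_ranks = per_fold,
                 auc = wins / comparisons,
                 per_disease_auc = pda,
                 n_folds = nrow(per_fold),
                 skipped = skipped,
                 config = config,
                 score_pairs = if (keep_scores) Filter(Negate(is.null), score_pairs)),
            class = "l1mda_cv")
}

#' Global leave-one-out cross-validation
#'
#' Each known association is zeroed in turn, the model is refitted, and the
#' held-out pair's score is ranked against all unconfirmed pairs of the
#' whole matrix. The AUC is the pooled Mann-Whitney statistic: across folds,
#' the fraction of (held-out, unconfirmed) score comparisons won, ties
#' counting one half. Per-disease AUCs aggregate the same statistic within
#' each disease's folds.
#'
#' Similarity matrices are held fixed across folds by default (the matrices
#' are treated as precomputed inputs); set
#' `recompute_mirna_similarity = TRUE` to rebuild the association-derived
#' miRNA similarity from the fold's reduced matrix, which removes that
#' leakage path at a large computational cost.
#'
#' @param A,W_m,W_d As in [l1graph()].
#' @param config A [solver_config()].
#' @param recompute_mirna_similarity Rebuild `W_m` per fold from the
#'   fold-reduced `A` via [mirna_functional_similarity()].
#' @param keep_scores Retain each fold's held-out and candidate scores
#'   (needed for [roc_points()]).
#' @param verbose Log skipped folds.
#' @return Object of class `l1mda_cv`: `mode`, `per_fold_ranks` (data frame
#'   with columns mirna, disease, rank, candidate_count), `auc`,
#'   `per_disease_auc`, `n_folds`, `skipped`.
#' @export
global_loocv <- function(A, W_m, W_d, config = solver_config(),
                         recompute_mirna_similarity = FALSE,
                         keep_scores = FALSE, verbose = FALSE) {
  loocv_engine(A, W_m, W_d, "global", config, recompute_mirna_similarity,
               keep_scores, verbose)
}

#' Local leave-one-out cross-validation
#'
#' As [global_loocv()], but each fold's candidate set is restricted to the
#' unconfirmed miRNAs of the held-out association's disease. Folds whose
#' disease has no unconfirmed miRNA are skipped and logged.
#'
#' @inheritParams global_loocv
#' @export
local_loocv <- function(A, W_m, W_d, config = solver_config(),
                        recompute_mirna_similarity = FALSE,
                        keep_scores = FALSE, verbose = FALSE) {
  loocv_engine(A, W_m, W_d, "local", config, recompute_mirna_similarity,
               keep_scores, verbose)
}

#' @export
print.l1mda_cv <- function(x, ...) {
  cat(sprintf("%s LOOCV: AUC = %.4f over %d folds", x$mode, x$auc, x$n_folds))
  if (length(x$skipped)) cat(sprintf(" (%d skipped)", length(x$skipped)))
  cat("\n")
  cat(sprintf("  median held-out rank %.1f of median %d candidates; %d diseases with AUC\n",
              stats::median(x$per_fold_ranks$rank),
              as.integer(stats::median(x$per_fold_ranks$candidate_count)),
              length(x$per_disease_auc)))
  invisible(x)
}

#' ROC curve points from a cross-validation run
#'
#' Sweeps a score threshold over the pooled fold results (run the CV with
#' `keep_scores = TRUE`): TPR is the fraction of held-out positives at or
#' above the threshold, FPR the pooled fraction of candidate negatives at or
#' above it.
#'
#' @param cv An `l1mda_cv` object with retained scores.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(cv) {
  if (is.null(cv$score_pairs))
    stop("run the cross-validation with keep_scores = TRUE", call. = FALSE)
  pos <- vapply(cv$score_pairs, `[[`, numeric(1), "test")
  neg <- unlist(lapply(cv$score_pairs, `[[`, "neg"), use.names = FALSE)
  thr <- sort(unique(c(pos, neg, Inf)), decreasing = TRUE)
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
             tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)))
}

#' Ranked candidate miRNAs for a disease
#'
#' Sorts all miRNAs by their fused score for the query disease, descending;
#' ties break lexicographically by miRNA id so output is deterministic. With
#' `exclude_known = TRUE` the miRNAs already associated with the disease are
#' removed before ranking (first type of case study); keep them to score a
#' disease whose column has been ablated (second type, see
#' [ablate_disease()]).
#'
#' @param scores Fused score matrix (or an `l1graph` fit).
#' @param A The association matrix supplying the known flags.
#' @param disease_id Disease column to rank.
#' @param k Keep the top `k` candidates (the full list if fewer).
#' @param exclude_known Remove known positives from the candidate set.
#' @return Object of class `ranked_candidates`: data frame with columns
#'   `rank`, `mirna`, `score`, `known`, plus attributes `disease_id` and
#'   `known_excluded`.
#' @export
rank_candidates <- function(scores, A, disease_id, k = 50L,
                            exclude_known = FALSE) {
  if (inherits(scores, "l1graph")) scores <- scores$scores
  if (!disease_id %in% colnames(scores) || !disease_id %in% colnames(A))
    stop("unknown disease id '", disease_id, "'", call. = FALSE)
  s <- scores[, disease_id]
  known <- A[, disease_id][names(s)] == 1
  if (exclude_known) {
    s <- s[!known]
    known <- known[!known]
  }
  ord <- order(-s, names(s))
  s <- s[ord]; known <- known[ord]
  n <- min(as.integer(k), length(s))
  out <- data.frame(rank = seq_len(n), mirna = names(s)[seq_len(n)],
                    score = unname(s[seq_len(n)]),
                    known = unname(known[seq_len(n)]),
                    stringsAsFactors = FALSE)
  structure(out, disease_id = disease_id, known_excluded = exclude_known,
            class = c("ranked_candidates", "data.frame"))
}

#' Zero out a disease's known associations
#'
#' Returns a copy of the association matrix with the given disease's column
#' set to zero, simulating a disease with no known miRNAs (second type of
#' case study). The input matrix is untouched.
#'
#' @param A Association matrix.
#' @param disease_id Disease column to ablate.
#' @export
ablate_disease <- function(A, disease_id) {
  if (!disease_id %in% colnames(A))
    stop("unknown disease id '", disease_id, "'", call. = FALSE)
  A[, disease_id] <- 0
  A
}
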