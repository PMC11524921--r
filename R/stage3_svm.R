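#' Rank features by linear-SVM coefficient magnitude
#'
#' Fits a linear SVM (hinge loss, L2 penalty, regularization C) on each
#' training fold using the given features, standardized per fold on the
#' training subjects, and ranks features by the mean across folds of the
#' absolute coefficient. Ties break by schema order, keeping reports
#' byte-stable.
#'
#' @param table a [feature_table].
#' @param features character vector of candidate feature names (typically
#'   the stage-2 retained set).
#' @param cost linear-SVM C (default 10).
#' @param folds a `fold_plan`.
#' @return An object of class `ranked_features`: data.frame with
#'   `feature`, `rank`, `importance` (mean |coefficient|), rows ordered by
#'   rank.
#' @export
svm_rank_features <- function(table, features, cost = 10, folds) {
  if (!length(features)) stop("no features to rank")
  W <- matrix(NA_real_, folds$n_folds, length(features),
              dimnames = list(NULL, features))
  for (k in seq_len(folds$n_folds)) {
    tr <- folds$assignment != k
    if (length(unique(table$labels[tr])) < 2L)
      stop("fold ", k, " has one-class training data")
    st <- standardizer_fit(table$X[tr, features, drop = FALSE])
    Xtr <- standardizer_apply(st, table$X[tr, features, drop = FALSE])
    fit <- svm_linear_fit(Xtr, table$labels[tr], cost)
    W[k, ] <- fit$w
  }
  importance <- colMeans(abs(W))
  ord <- order(-importance, match(features, table$schema$names))
  structure(data.frame(feature = features[ord],
                       rank = seq_along(features),
                       importance = importance[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ranked_features", "data.frame"))
}

#' Cross-validated AUC of growing rank-ordered feature prefixes
#'
#' For each prefix size k of the ranking, retrains the linear SVM per fold
#' on the top-k features and scores the held-out subjects with the
#' decision function; records per-fold and mean AUC.
#'
#' @param table a [feature_table].
#' @param ranking a `ranked_features` from [svm_rank_features()].
#' @param cost linear-SVM C (default 10).
#' @param folds a `fold_plan`.
#' @return An `auc_curve` data.frame: `k`, `mean_auc`, then one
#'   `fold<j>_auc` column per fold.
#' @export
progressive_auc_curve <- function(table, ranking, cost = 10, folds) {
  if (!nrow(ranking)) stop("empty ranking")
  K <- nrow(ranking)
  per_fold <- matrix(NA_real_, K, folds$n_folds)
  for (k in seq_len(folds$n_folds)) {
    tr <- folds$assignment != k
    for (m in seq_len(K)) {
      feats <- ranking$feature[seq_len(m)]
      st <- standardizer_fit(table$X[tr, feats, drop = FALSE])
      Xtr <- standardizer_apply(st, table$X[tr, feats, drop = FALSE])
      Xte <- standardizer_apply(st, table$X[!tr, feats, drop = FALSE])
      fit <- svm_linear_fit(Xtr, table$labels[tr], cost)
      per_fold[m, k] <- auc_from_scores(svm_decision(fit, Xte),
                                        table$labels[!tr])
    }
  }
  out <- data.frame(k = seq_len(K), mean_auc = rowMeans(per_fold))
  colnames(per_fold) <- sprintf("fold%d_auc", seq_len(folds$n_folds))
  out <- cbind(out, per_fold)
  class(out) <- c("auc_curve", "data.frame")
  out
}

#' Plateau stopping rule on an AUC curve
#'
#' Chooses the smallest prefix size whose mean AUC is within
#' `plateau_tol` of the curve's maximum — the point past which adding
#' lower-ranked features no longer improves cross-validated performance.
#'
#' @param curve an `auc_curve`.
#' @param ranking the `ranked_features` the curve was computed from.
#' @param plateau_tol AUC tolerance (default 0.005).
#' @return List: `k_star` and `selected` (top-k* feature names).
#' @export
plateau_select <- function(curve, ranking, plateau_tol = 0.005) {
  if (!nrow(curve)) stop("empty AUC curve")
  stopifnot(plateau_tol >= 0)
  thr <- max(curve$mean_auc) - plateau_tol
  k_star <- min(curve$k[curve$mean_auc >= thr])
  list(k_star = k_star, selected = ranking$feature[seq_len(k_star)])
}

#' Final cross-validated performance of a feature set
#'
#' Retrains the linear SVM per fold on the selected features and averages
#' held-out AUC, accuracy, sensitivity (case recall) and specificity
#' (control recall) over folds; hard classification thresholds the
#' decision function at zero.
#'
#' @param table a [feature_table].
#' @param selected feature names.
#' @param cost linear-SVM C (default 10).
#' @param folds a `fold_plan`.
#' @return List: mean `auc`, `accuracy`, `sensitivity`, `specificity`,
#'   plus `per_fold` data.frame.
#' @export
evaluate_final <- function(table, selected, cost = 10, folds) {
  if (!length(selected)) stop("empty feature set")
  rows <- lapply(seq_len(folds$n_folds), function(k) {
    tr <- folds$assignment != k
    st <- standardizer_fit(table$X[tr, selected, drop = FALSE])
    Xtr <- standardizer_apply(st, table$X[tr, selected, drop = FALSE])
    Xte <- standardizer_apply(st, table$X[!tr, selected, drop = FALSE])
    fit <- svm_linear_fit(Xtr, table$labels[tr], cost)
    sc <- svm_decision(fit, Xte)
    cm <- confusion_metrics(as.integer(sc > 0), table$labels[!tr])
    data.frame(fold = k,
               auc = auc_from_scores(sc, table$labels[!tr]),
               accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity)
  })
  per_fold <- do.call(rbind, rows)
  list(auc = mean(per_fold$auc), accuracy = mean(per_fold$accuracy),
       sensitivity = mean(per_fold$sensitivity),
       specificity = mean(per_fold$specificity), per_fold = per_fold)
}
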