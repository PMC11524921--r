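#' Per-feature ANOVA F statistics for a binary outcome
#'
#' Scores every feature column by its one-way ANOVA F statistic against the
#' two class labels (between-group df = 1, within-group df = n - 2). For
#' two classes this equals the square of the pooled-variance two-sample t
#' statistic. Degenerate cases: a feature that separates the classes with
#' zero within-class variance scores `Inf` (ranked first); a feature
#' constant over all subjects scores 0 with a warning.
#'
#' @param X numeric matrix restricted to training subjects.
#' @param labels binary 0/1 vector for those subjects.
#' @return An object of class `score_vector`: `f` (named per-feature F),
#'   `df_between`, `df_within`.
#' @export
anova_f_scores <- function(X, labels) {
  labels <- as.integer(labels)
  n <- nrow(X)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L) stop("need >= 2 subjects in each class")
  m1 <- colMeans(X[labels == 1L, , drop = FALSE])
  m0 <- colMeans(X[labels == 0L, , drop = FALSE])
  mg <- colMeans(X)
  ss_between <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ss_within <- colSums(sweep(X[labels == 1L, , drop = FALSE], 2L, m1)^2) +
    colSums(sweep(X[labels == 0L, , drop = FALSE], 2L, m0)^2)
  dfw <- n - 2L
  f <- (ss_between / 1) / (ss_within / dfw)
  zero_w <- ss_within <= 0
  f[zero_w & ss_between > 0] <- Inf
  const <- zero_w & ss_between <= 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) scored F = 0: ",
            paste(utils::head(colnames(X)[const], 3L), collapse = ", "))
    f[const] <- 0
  }
  names(f) <- colnames(X)
  structure(list(f = f, df_between = 1L, df_within = dfw),
            class = "score_vector")
}

#' Retain the top fraction of features by F score
#'
#' Keeps `k = ceiling(fraction * p)` features with the largest F, ties
#' broken by original (schema) column order. With the 317-feature default
#' layout and fraction 0.20 this retains 64 features.
#'
#' @param scores a `score_vector` from [anova_f_scores()].
#' @param fraction proportion in (0, 1] of features to keep.
#' @return Character vector of selected feature names ordered by
#'   descending F.
#' @export
select_top_fraction <- function(scores, fraction) {
  stopifnot(inherits(scores, "score_vector"))
  f <- scores$f
  if (!length(f)) stop("empty score vector")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- as.integer(ceiling(fraction * length(f)))
  ord <- order(-f, seq_along(f))  # ties -> earlier schema position first
  names(f)[ord[seq_len(k)]]
}

#' Grid-search the filter retention fraction
#'
#' For each candidate fraction, runs the per-fold filter and scores the
#' fold-specific selections with a linear SVM on the held-out subjects;
#' returns the candidate with the highest mean cross-validated AUC, ties
#' broken toward the smallest fraction (the sparsest filter).
#'
#' @param table a [feature_table].
#' @param candidate_fractions numeric vector of fractions in (0, 1].
#'   Default `seq(0.05, 0.50, by = 0.05)`.
#' @param folds a `fold_plan` from [make_folds()].
#' @param cost linear-SVM regularization parameter C (default 10).
#' @return List: `best_fraction`, and `mean_auc` named by candidate.
#' @export
grid_search_fraction <- function(table,
                                 candidate_fractions = seq(0.05, 0.5, 0.05),
                                 folds, cost = 10) {
  if (!length(candidate_fractions)) stop("no candidate fractions")
  candidate_fractions <- sort(candidate_fractions)
  mean_auc <- vapply(candidate_fractions, function(fr) {
    aucs <- vapply(seq_len(folds$n_folds), function(k) {
      tr <- folds$assignment != k
      sel <- select_top_fraction(
        anova_f_scores(table$X[tr, , drop = FALSE], table$labels[tr]), fr)
      st <- standardizer_fit(table$X[tr, sel, drop = FALSE])
      Xtr <- standardizer_apply(st, table$X[tr, sel, drop = FALSE])
      Xte <- standardizer_apply(st, table$X[!tr, sel, drop = FALSE])
      fit <- svm_linear_fit(Xtr, table$labels[tr], cost)
      auc_from_scores(svm_decision(fit, Xte), table$labels[!tr])
    }, numeric(1L))
    mean(aucs)
  }, numeric(1L))
  names(mean_auc) <- format(candidate_fractions)
  best <- candidate_fractions[which.max(mean_auc)]  # ties -> smallest
  list(best_fraction = best, mean_auc = mean_auc)
}

# Stage-1 driver: per-fold F scores + top-fraction selection.
stage1_select <- function(table, folds, fraction) {
  lapply(seq_len(folds$n_folds), function(k) {
    tr <- folds$assignment != k
    sc <- anova_f_scores(table$X[tr, , drop = FALSE], table$labels[tr])
    sel <- select_top_fraction(sc, fraction)
    list(fold = k, selected = sel, f = sc$f[sel])
  })
}
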