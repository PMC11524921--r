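#' Build a cross-validation fold plan
#'
#' Assigns every subject to exactly one test fold. With `stratified = TRUE`
#' (the default) class proportions are preserved: per-fold class counts
#' differ from exact proportionality by at most one, and total fold sizes
#' differ by at most one.
#'
#' @param labels binary 0/1 vector.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param stratified preserve class balance across folds.
#' @return An object of class `fold_plan`: `assignment` (per-subject fold
#'   index in 1..n_folds), plus `n_folds`, `stratified`, `seed`.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L, stratified = TRUE) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n_folds > n) stop("more folds than subjects")
  assignment <- integer(n)
  with_local_seed(seed, {
    if (stratified) {
      counts <- integer(n_folds)  # running fold totals for balance
      for (cls in sort(unique(labels), decreasing = TRUE)) {
        idx <- which(labels == cls)
        if (length(idx) < n_folds)
          stop("class ", cls, " has fewer subjects (", length(idx),
               ") than folds (", n_folds, ")")
        idx <- sample(idx)
        base <- length(idx) %/% n_folds
        rem <- length(idx) %% n_folds
        per_fold <- rep(base, n_folds)
        if (rem > 0L) {
          # give the remainders to the currently smallest folds
          ord <- order(counts, sample(n_folds))
          per_fold[ord[seq_len(rem)]] <- base + 1L
        }
        assignment[idx] <- rep(seq_len(n_folds), times = per_fold)
        counts <- counts + per_fold
      }
    } else {
      sizes <- rep(n %/% n_folds, n_folds)
      rem <- n %% n_folds
      if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      assignment[sample(n)] <- rep(seq_len(n_folds), times = sizes)
    }
  })
  structure(list(assignment = assignment, n_folds = as.integer(n_folds),
                 stratified = stratified, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", x$n_folds, " folds, ",
      if (x$stratified) "stratified" else "unstratified",
      ", seed ", x$seed, "; sizes: ",
      paste(tabulate(x$assignment, x$n_folds), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a fold plan to JSON
#'
#' @param plan a `fold_plan`.
#' @param subject_ids per-subject identifiers aligned with the plan.
#' @param path output file.
#' @export
fold_plan_to_json <- function(plan, subject_ids, path) {
  jsonlite::write_json(
    list(n_folds = plan$n_folds, stratified = plan$stratified,
         seed = plan$seed,
         assignment = stats::setNames(as.list(plan$assignment),
                                      subject_ids)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Area under the ROC curve from continuous scores
#'
#' Computes AUC as the tie-corrected Mann-Whitney rank statistic:
#' the probability that a random case scores above a random control, with
#' half credit for ties. Identical to the trapezoidal ROC area for finite
#' samples.
#'
#' @param scores numeric decision scores, larger = more case-like.
#' @param labels binary 0/1 vector (1 = case).
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required to compute AUC")
  if (length(scores) != length(labels)) stop("length mismatch")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, sensitivity and specificity from binary predictions
#'
#' Sensitivity is recall on the case class (TP / (TP + FN)); specificity is
#' recall on the control class (TN / (TN + FP)). When a class is absent the
#' corresponding metric is `NA`, not zero.
#'
#' @param predicted binary 0/1 predictions.
#' @param labels binary 0/1 truth (1 = case).
#' @return Named list: `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predicted, labels) {
  predicted <- as.integer(predicted)
  labels <- as.integer(labels)
  if (length(predicted) != length(labels)) stop("length mismatch")
  tp <- sum(predicted == 1L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (n1 > 0L) tp / n1 else NA_real_,
       specificity = if (n0 > 0L) tn / n0 else NA_real_)
}
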