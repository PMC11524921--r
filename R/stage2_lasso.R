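#' Configuration of the LASSO frequency-selection stage
#'
#' @param alpha_grid strictly increasing positive penalty grid. Default:
#'   100 points log-spaced on \[1e-4, 1\], a range over which the
#'   regularization path of standardized 0/1-label data is non-trivial
#'   (the all-zero bound for such data sits below 1).
#' @param tol solver convergence tolerance (default 1e-4).
#' @param n_folds folds of the frequency-selection scheme (default 5).
#' @param min_count retain features selected in at least this many folds
#'   (default 3 of 5).
#' @return A `lasso_config` list.
#' @export
lasso_config <- function(alpha_grid = 10^seq(-4, 0, length.out = 100),
                         tol = 1e-4, n_folds = 5L, min_count = 3L) {
  alpha_grid <- as.numeric(alpha_grid)
  if (any(alpha_grid <= 0) || is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha_grid must be strictly increasing and positive")
  if (min_count < 1L || min_count > n_folds)
    stop("min_count must lie in [1, n_folds]")
  structure(list(alpha_grid = alpha_grid, tol = tol,
                 n_folds = as.integer(n_folds),
                 min_count = as.integer(min_count)),
            class = "lasso_config")
}

#' LASSO fit at a single penalty
#'
#' Minimizes `(1/2n) * ||y - b0 - X beta||^2 + alpha * ||beta||_1` with an
#' unpenalized intercept, for a column-standardized training matrix and
#' 0/1 labels treated as a quantitative response. Solved by coordinate
#' descent (glmnet) warm-started along a short ladder down to `alpha`;
#' penalties at or above the lambda-max bound return the exact all-zero
#' model.
#'
#' @param X standardized numeric training matrix.
#' @param y numeric 0/1 response.
#' @param alpha penalty, > 0.
#' @param tol solver tolerance.
#' @return List: `beta` (named coefficient vector), `intercept`.
#' @export
lasso_fit <- function(X, y, alpha, tol = 1e-4) {
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite input")
  stopifnot(alpha > 0, nrow(X) == length(y))
  n <- nrow(X)
  p <- ncol(X)
  zero <- stats::setNames(numeric(p), colnames(X))
  if (stats::var(y) == 0) return(list(beta = zero, intercept = mean(y)))
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (alpha >= lam_max) return(list(beta = zero, intercept = mean(y)))
  if (p == 1L) {
    # univariate soft-threshold closed form
    xc <- X[, 1L] - mean(X[, 1L])
    yc <- y - mean(y)
    c1 <- sum(xc * yc) / n
    b <- sign(c1) * max(abs(c1) - alpha, 0) / (sum(xc^2) / n)
    beta <- stats::setNames(b, colnames(X))
    return(list(beta = beta, intercept = mean(y) - b * mean(X[, 1L])))
  }
  ladder <- exp(seq(log(lam_max), log(alpha), length.out = 30L))
  ladder[30L] <- alpha  # guard against log/exp round-off at the target
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = ladder, standardize = FALSE,
                        intercept = TRUE, thresh = tol * 1e-3)
  last <- ncol(fit$beta)  # warm-started solution at exactly alpha
  beta <- stats::setNames(as.numeric(fit$beta[, last]), colnames(X))
  list(beta = beta, intercept = as.numeric(fit$a0[last]))
}

#' Choose the LASSO penalty by cross-validated held-out loss
#'
#' For each grid penalty, fits on every training fold (restricted to that
#' fold's stage-1 feature set, standardized on the training subjects) and
#' measures mean squared loss on the held-out subjects; returns the
#' penalty with the lowest mean loss, ties broken toward the largest
#' (sparsest) penalty.
#'
#' @param table a [feature_table].
#' @param stage1_selections list of per-fold feature-name vectors.
#' @param cfg a [lasso_config()].
#' @param folds a `fold_plan`.
#' @return List: `alpha` (chosen penalty), `mean_loss` (per grid point).
#' @export
select_alpha <- function(table, stage1_selections, cfg, folds) {
  grid <- cfg$alpha_grid
  dec <- rev(grid)  # glmnet wants decreasing lambda
  loss <- matrix(NA_real_, folds$n_folds, length(grid))
  for (k in seq_len(folds$n_folds)) {
    tr <- folds$assignment != k
    sel <- stage1_selections[[k]]$selected
    st <- standardizer_fit(table$X[tr, sel, drop = FALSE])
    Xtr <- standardizer_apply(st, table$X[tr, sel, drop = FALSE])
    Xte <- standardizer_apply(st, table$X[!tr, sel, drop = FALSE])
    ytr <- as.numeric(table$labels[tr])
    fit <- glmnet::glmnet(Xtr, ytr, family = "gaussian", alpha = 1,
                          lambda = dec, standardize = FALSE,
                          intercept = TRUE, thresh = cfg$tol * 1e-3)
    pred <- stats::predict(fit, newx = Xte)  # one column per grid penalty,
    stopifnot(ncol(pred) == length(dec))     # in the supplied (decreasing)
    mse <- colMeans((as.numeric(table$labels[!tr]) - pred)^2)  # order
    loss[k, ] <- rev(mse)  # back to increasing grid order
  }
  mean_loss <- colMeans(loss)
  # ties (within numerical noise) break toward the largest alpha
  best <- max(grid[mean_loss <= min(mean_loss) + 1e-12])
  list(alpha = best,
       mean_loss = stats::setNames(mean_loss, format(grid, digits = 6)))
}

#' Per-fold LASSO feature subsets at a fixed penalty
#'
#' Fits the LASSO at `alpha` on each fold's training subjects (restricted
#' to that fold's stage-1 features) and records the nonzero-coefficient
#' set.
#'
#' @param table a [feature_table].
#' @param stage1_selections list of per-fold feature-name vectors.
#' @param alpha penalty at which to fit.
#' @param folds a `fold_plan`.
#' @param cfg a [lasso_config()].
#' @return List of per-fold records: `fold`, `selected`, `coefficients`,
#'   `train_ids`.
#' @export
fold_feature_subsets <- function(table, stage1_selections, alpha, folds,
                                 cfg = lasso_config()) {
  stopifnot(alpha > 0)
  lapply(seq_len(folds$n_folds), function(k) {
    tr <- folds$assignment != k
    sel <- stage1_selections[[k]]$selected
    st <- standardizer_fit(table$X[tr, sel, drop = FALSE])
    Xtr <- standardizer_apply(st, table$X[tr, sel, drop = FALSE])
    fit <- lasso_fit(Xtr, as.numeric(table$labels[tr]), alpha, cfg$tol)
    nz <- fit$beta[abs(fit$beta) > 0]
    list(fold = k, selected = names(nz), coefficients = nz,
         train_ids = table$subject_ids[tr])
  })
}

#' Frequency voting over per-fold LASSO selections
#'
#' Retains features selected in at least `min_count` folds, ordered by
#' (selection count descending, mean absolute coefficient over selecting
#' folds descending, schema order).
#'
#' @param records output of [fold_feature_subsets()].
#' @param min_count minimum number of folds a feature must appear in.
#' @param schema_order character vector defining the tie-break order
#'   (defaults to first-appearance order).
#' @return List: `retained` (ordered feature names) and `table` (a
#'   data.frame with feature, count, mean_abs_coefficient, folds).
#' @export
frequency_filter <- function(records, min_count = 3L,
                             schema_order = NULL) {
  if (min_count < 1L || min_count > length(records))
    stop("min_count must lie in [1, number of records]")
  all_feats <- unique(unlist(lapply(records, `[[`, "selected")))
  if (is.null(schema_order)) schema_order <- all_feats
  if (!length(all_feats)) {
    return(list(retained = character(),
                table = data.frame(feature = character(),
                                   count = integer(),
                                   mean_abs_coefficient = numeric(),
                                   folds = character())))
  }
  count <- vapply(all_feats, function(f)
    sum(vapply(records, function(r) f %in% r$selected, logical(1L))),
    integer(1L))
  mean_abs <- vapply(all_feats, function(f) {
    v <- unlist(lapply(records, function(r) abs(r$coefficients[f])))
    mean(v[!is.na(v)])
  }, numeric(1L))
  in_folds <- vapply(all_feats, function(f)
    paste(which(vapply(records, function(r) f %in% r$selected,
                       logical(1L))), collapse = ","), character(1L))
  ord <- order(-count, -mean_abs, match(all_feats, schema_order))
  tab <- data.frame(feature = all_feats[ord], count = count[ord],
                    mean_abs_coefficient = mean_abs[ord],
                    folds = in_folds[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(retained = tab$feature[tab$count >= min_count], table = tab)
}
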