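#' Empirical-Bayes batch harmonization (ComBat)
#'
#' Fits the standard parametric empirical-Bayes location/scale batch-effect
#' model: each feature is standardized against a batch-weighted grand mean
#' (plus optional covariate effects) and pooled variance; per-batch
#' location (gamma) and scale (delta) effects are estimated and shrunk
#' toward their across-feature priors (normal for gamma, inverse-gamma for
#' delta, both moment-matched); shrunken effects are then removed and the
#' data restored to the original scale. Group labels are never used, so
#' harmonization cannot leak outcome information.
#'
#' @param table a [feature_table] with a `batch` field (or see
#'   `batch`).
#' @param batch optional explicit per-subject batch vector overriding
#'   `table$batch`.
#' @param covariate_names names of columns of `table$covariates` to protect
#'   (biological signal retained during standardization). Default none.
#' @param eb_conv convergence tolerance of the empirical-Bayes
#'   fixed-point iteration.
#' @return A `combat_model` with per-feature pooled mean/variance,
#'   covariate coefficients, and per-batch shrunken `gamma_star` /
#'   `delta_star`; or an identity-flagged model when only one batch is
#'   present.
#' @seealso [combat_apply()]
#' @export
combat_fit <- function(table, batch = table$batch,
                       covariate_names = character(), eb_conv = 1e-4) {
  if (is.null(batch)) stop("no batch information on table")
  batch <- as.character(batch)
  X <- table$X
  n <- nrow(X)
  stopifnot(length(batch) == n)
  batches <- sort(unique(batch))
  if (length(batches) < 2L) {
    return(structure(list(identity = TRUE, batches = batches,
                          schema = table$schema), class = "combat_model"))
  }
  n_i <- table(factor(batch, levels = batches))
  if (any(n_i < 2L))
    stop("every batch needs >= 2 subjects; too small: ",
         paste(batches[n_i < 2L], collapse = ", "))

  batchmod <- stats::model.matrix(~ 0 + factor(batch, levels = batches))
  colnames(batchmod) <- batches
  covmod <- NULL
  if (length(covariate_names)) {
    covs <- table$covariates[covariate_names]
    covmod <- stats::model.matrix(~ ., data = covs)[, -1L, drop = FALSE]
  }
  design <- cbind(batchmod, covmod)
  if (qr(design)$rank < ncol(design))
    stop("covariates are collinear with the batch design")

  # per-feature least squares on the batch + covariate design
  B <- solve(crossprod(design), crossprod(design, X))
  nb <- length(batches)
  grand_mean <- drop(as.numeric(n_i / n) %*% B[seq_len(nb), , drop = FALSE])
  resid <- X - design %*% B
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled == 0))
    stop("zero pooled variance for feature(s): ",
         paste(table$schema$names[var_pooled == 0], collapse = ", "))
  beta_cov <- if (!is.null(covmod))
    B[-seq_len(nb), , drop = FALSE] else NULL

  stand_mean <- matrix(grand_mean, n, ncol(X), byrow = TRUE)
  if (!is.null(beta_cov)) stand_mean <- stand_mean + covmod %*% beta_cov
  Z <- sweep(X - stand_mean, 2L, sqrt(var_pooled), "/")

  gamma_hat <- t(vapply(batches, function(b)
    colMeans(Z[batch == b, , drop = FALSE]), numeric(ncol(X))))
  delta_hat <- t(vapply(batches, function(b)
    apply(Z[batch == b, , drop = FALSE], 2L, stats::var), numeric(ncol(X))))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, stats::var)
  # inverse-gamma prior on delta^2, moment-matched per batch
  m <- rowMeans(delta_hat)
  s2 <- apply(delta_hat, 1L, stats::var)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    ni <- as.numeric(n_i[i])
    Zi <- Z[batch == batches[i], , drop = FALSE]
    g_old <- gamma_hat[i, ]
    d_old <- delta_hat[i, ]
    change <- 1
    while (change > eb_conv) {
      g_new <- (t2[i] * ni * gamma_hat[i, ] + d_old * gamma_bar[i]) /
        (t2[i] * ni + d_old)
      sum2 <- colSums(sweep(Zi, 2L, g_new, "-")^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }
  stopifnot(all(delta_star > 0))

  structure(list(identity = FALSE, batches = batches,
                 grand_mean = grand_mean, var_pooled = var_pooled,
                 beta_cov = beta_cov, covariate_names = covariate_names,
                 gamma_star = gamma_star, delta_star = delta_star,
                 schema = table$schema), class = "combat_model")
}

#' Apply a fitted ComBat model to a feature table
#'
#' Removes the model's shrunken per-batch location/scale effects from the
#' table's matrix. Only the matrix changes; ids, labels, batch and
#' covariates pass through. Tables whose batches were not seen at fit time
#' are rejected.
#'
#' @param model a `combat_model` from [combat_fit()].
#' @param table a [feature_table] with the same schema.
#' @return A harmonized [feature_table].
#' @export
combat_apply <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  if (!identical(model$schema$names, table$schema$names))
    stop("schema mismatch between model and table")
  if (isTRUE(model$identity)) return(table)
  batch <- as.character(table$batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen))
    stop("batch(es) not seen at fit time: ", paste(unseen, collapse = ", "))

  X <- table$X
  stand_mean <- matrix(model$grand_mean, nrow(X), ncol(X), byrow = TRUE)
  if (!is.null(model$beta_cov)) {
    covs <- table$covariates[model$covariate_names]
    covmod <- stats::model.matrix(~ ., data = covs)[, -1L, drop = FALSE]
    stand_mean <- stand_mean + covmod %*% model$beta_cov
  }
  sdp <- sqrt(model$var_pooled)
  Z <- sweep(X - stand_mean, 2L, sdp, "/")
  for (b in unique(batch)) {
    i <- match(b, model$batches)
    rows <- batch == b
    Z[rows, ] <- sweep(sweep(Z[rows, , drop = FALSE], 2L,
                             model$gamma_star[i, ], "-"),
                       2L, sqrt(model$delta_star[i, ]), "/")
  }
  Xadj <- sweep(Z, 2L, sdp, "*") + stand_mean
  out <- table
  out$X <- Xadj
  colnames(out$X) <- table$schema$names
  out
}

#' Serialize a ComBat model to JSON for audit
#'
#' @param model a `combat_model`.
#' @param path output file.
#' @export
combat_model_to_json <- function(model, path) {
  keep <- model[setdiff(names(model), "schema")]
  keep$features <- model$schema$names
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
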