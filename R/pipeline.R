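#' Pipeline configuration
#'
#' Gathers every tunable of the three refinement stages. Defaults follow
#' the study protocol: filter fraction 0.20, LASSO penalty chosen by
#' 5-fold held-out loss with a frequency threshold of 3/5 folds, linear
#' SVM with C = 10, plateau tolerance 0.005 AUC, stratified 5-fold CV, and
#' harmonization fit on the full cohort before selection when batch
#' information is present.
#'
#' @param filter_fraction stage-1 retention fraction (default 0.20).
#' @param lasso a [lasso_config()].
#' @param cost linear-SVM C (default 10).
#' @param plateau_tol AUC plateau tolerance (default 0.005).
#' @param n_folds cross-validation folds (default 5).
#' @param stratified stratify folds by class (default TRUE).
#' @param seed integer seed governing fold construction.
#' @param harmonize apply ComBat before selection when the table carries
#'   batch labels (default TRUE).
#' @param combat_covariates covariate names protected during
#'   harmonization (default none).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(filter_fraction = 0.20,
                            lasso = lasso_config(),
                            cost = 10, plateau_tol = 0.005,
                            n_folds = 5L, stratified = TRUE, seed = 1L,
                            harmonize = TRUE,
                            combat_covariates = character()) {
  stopifnot(filter_fraction > 0, filter_fraction <= 1,
            cost > 0, plateau_tol >= 0, n_folds >= 2L)
  structure(list(filter_fraction = filter_fraction, lasso = lasso,
                 cost = cost, plateau_tol = plateau_tol,
                 n_folds = as.integer(n_folds), stratified = stratified,
                 seed = as.integer(seed), harmonize = harmonize,
                 combat_covariates = combat_covariates),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trip identity: `load_config(save_config(cfg, f))` reproduces the
#' configuration, so a run is fully reconstructible from its config echo.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path.
#' @return `save_config` the path, invisibly; `load_config` a
#'   `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$lasso <- unclass(cfg$lasso)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(
    filter_fraction = x$filter_fraction,
    lasso = lasso_config(alpha_grid = as.numeric(x$lasso$alpha_grid),
                         tol = x$lasso$tol, n_folds = x$lasso$n_folds,
                         min_count = x$lasso$min_count),
    cost = x$cost, plateau_tol = x$plateau_tol, n_folds = x$n_folds,
    stratified = x$stratified, seed = x$seed, harmonize = x$harmonize,
    combat_covariates = as.character(unlist(x$combat_covariates)))
}

#' Run the full multi-stage refinement pipeline
#'
#' Executes, on one shared cross-validation fold plan derived from
#' `cfg$seed`: optional ComBat harmonization (fit on the full cohort) →
#' per-fold ANOVA-F filtering at `filter_fraction` → LASSO penalty
#' selection and K-fold selection-frequency voting → linear-SVM
#' coefficient ranking, progressive feature addition, plateau stopping,
#' and final cross-validated metrics.
#'
#' @param table a [feature_table] with both classes present.
#' @param cfg a [pipeline_config()].
#' @return A `refinement_report`: `folds`, `stage1` (per-fold
#'   selections), `stage2` (`alpha`, fold records, frequency table,
#'   `retained`), `stage3` (`ranking`, `auc_curve`, `k_star`, `selected`,
#'   `metrics`), `config`, `version`.
#' @export
run_pipeline <- function(table, cfg = pipeline_config()) {
  viol <- validate_table(table)
  if (length(viol)) stop("invalid input table: ",
                         paste(viol, collapse = "; "))
  if (length(unique(table$labels)) < 2L)
    stop("both classes required")

  if (isTRUE(cfg$harmonize) && !is.null(table$batch) &&
      length(unique(table$batch)) > 1L) {
    model <- combat_fit(table, covariate_names = cfg$combat_covariates)
    table <- combat_apply(model, table)
  }

  folds <- make_folds(table$labels, cfg$n_folds, cfg$seed, cfg$stratified)

  stage1 <- stage1_select(table, folds, cfg$filter_fraction)

  sel_alpha <- select_alpha(table, stage1, cfg$lasso, folds)
  records <- fold_feature_subsets(table, stage1, sel_alpha$alpha, folds,
                                  cfg$lasso)
  freq <- frequency_filter(records, cfg$lasso$min_count,
                           schema_order = table$schema$names)

  if (length(freq$retained)) {
    ranking <- svm_rank_features(table, freq$retained, cfg$cost, folds)
    curve <- progressive_auc_curve(table, ranking, cfg$cost, folds)
    sel <- plateau_select(curve, ranking, cfg$plateau_tol)
    metrics <- evaluate_final(table, sel$selected, cfg$cost, folds)
  } else {
    # no stable signal: the final model is the trivial constant score,
    # i.e. AUC 1/2 by tie half-credit and all-control predictions
    ranking <- structure(data.frame(feature = character(),
                                    rank = integer(),
                                    importance = numeric()),
                         class = c("ranked_features", "data.frame"))
    curve <- structure(data.frame(k = integer(), mean_auc = numeric()),
                       class = c("auc_curve", "data.frame"))
    sel <- list(k_star = 0L, selected = character())
    per_fold <- do.call(rbind, lapply(seq_len(folds$n_folds), function(k) {
      yte <- table$labels[folds$assignment == k]
      cm <- confusion_metrics(rep(0L, length(yte)), yte)
      data.frame(fold = k, auc = 0.5, accuracy = cm$accuracy,
                 sensitivity = cm$sensitivity,
                 specificity = cm$specificity)
    }))
    metrics <- list(auc = 0.5, accuracy = mean(per_fold$accuracy),
                    sensitivity = mean(per_fold$sensitivity),
                    specificity = mean(per_fold$specificity),
                    per_fold = per_fold)
  }

  structure(list(
    folds = folds,
    stage1 = stage1,
    stage2 = list(alpha = sel_alpha$alpha,
                  mean_loss = sel_alpha$mean_loss,
                  records = records, frequency = freq$table,
                  retained = freq$retained),
    stage3 = list(ranking = ranking, auc_curve = curve,
                  k_star = sel$k_star, selected = sel$selected,
                  metrics = metrics),
    config = cfg,
    version = as.character(utils::packageVersion("msrefine"))
  ), class = "refinement_report")
}

#' @export
print.refinement_report <- function(x, ...) {
  s1 <- lengths(lapply(x$stage1, `[[`, "selected"))
  cat("<refinement_report>\n",
      "  stage 1: ", paste(s1, collapse = "/"),
      " features per fold (fraction ", x$config$filter_fraction, ")\n",
      "  stage 2: alpha = ", signif(x$stage2$alpha, 4), "; per-fold ",
      paste(lengths(lapply(x$stage2$records, `[[`, "selected")),
            collapse = "/"),
      "; retained (>=", x$config$lasso$min_count, " folds): ",
      length(x$stage2$retained), "\n",
      "  stage 3: k* = ", x$stage3$k_star, " of ",
      nrow(x$stage3$ranking), "; mean AUC ",
      round(x$stage3$metrics$auc, 3), ", accuracy ",
      round(x$stage3$metrics$accuracy, 3), ", sensitivity ",
      round(x$stage3$metrics$sensitivity, 3), ", specificity ",
      round(x$stage3$metrics$specificity, 3), "\n", sep = "")
  invisible(x)
}

#' Write a refinement report to disk
#'
#' Emits, under `outdir`: `ranking.tsv` (feature, rank), `frequency.tsv`,
#' `auc_curve.tsv` (prefix size, mean and per-fold AUC), `metrics.json`,
#' `selected_features.txt`, `config.yaml`, `fold_plan.json`, and a
#' one-line-per-stage `log.txt`. Refuses to overwrite an existing
#' directory unless `force = TRUE`.
#'
#' @param report a `refinement_report`.
#' @param outdir output directory.
#' @param subject_ids subject identifiers for the fold-plan echo
#'   (optional).
#' @param force overwrite an existing directory.
#' @export
write_report <- function(report, outdir, subject_ids = NULL,
                         force = FALSE) {
  if (dir.exists(outdir) && !force)
    stop("output directory exists: ", outdir, " (use force = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  tsv(report$stage3$ranking[c("feature", "rank")], "ranking.tsv")
  tsv(report$stage2$frequency, "frequency.tsv")
  tsv(as.data.frame(report$stage3$auc_curve), "auc_curve.tsv")
  m <- report$stage3$metrics
  jsonlite::write_json(list(auc = m$auc, accuracy = m$accuracy,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            per_fold = m$per_fold,
                            k_star = report$stage3$k_star),
                       file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$stage3$selected,
             file.path(outdir, "selected_features.txt"))
  save_config(report$config, file.path(outdir, "config.yaml"))
  if (!is.null(subject_ids))
    fold_plan_to_json(report$folds, subject_ids,
                      file.path(outdir, "fold_plan.json"))
  s1 <- lengths(lapply(report$stage1, `[[`, "selected"))
  s2 <- lengths(lapply(report$stage2$records, `[[`, "selected"))
  writeLines(c(
    sprintf("stage1 fraction=%g per_fold=%s", report$config$filter_fraction,
            paste(s1, collapse = ",")),
    sprintf("stage2 alpha=%.6g per_fold=%s retained=%d",
            report$stage2$alpha, paste(s2, collapse = ","),
            length(report$stage2$retained)),
    sprintf("stage3 k_star=%d auc=%.4f seed=%d", report$stage3$k_star,
            m$auc, report$config$seed)),
    file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' Group-comparison statistics for cohort demographics
#'
#' Compares two groups on numeric variables with two-sample t tests
#' (pooled and Welch variants) and on a 2x2 categorical table with the
#' Pearson chi-square test (uncorrected by default; the
#' continuity-corrected value is reported alongside). A variable with
#' zero variance in both groups yields `NA` statistics rather than an
#' error.
#'
#' @param numeric_vars named list, each element a list of two numeric
#'   vectors `case` and `control`.
#' @param count_tables named list of 2x2 matrices (rows = categories,
#'   columns = groups).
#' @return data.frame: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
cohort_stats <- function(numeric_vars = list(), count_tables = list()) {
  rows <- list()
  for (v in names(numeric_vars)) {
    a <- numeric_vars[[v]]$case
    b <- numeric_vars[[v]]$control
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 subjects per group for '", v, "'")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = c("t_pooled", "t_welch"),
        statistic = NA_real_, df = NA_real_, p = NA_real_)
      next
    }
    tp <- stats::t.test(a, b, var.equal = TRUE)
    tw <- stats::t.test(a, b, var.equal = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = c("t_pooled", "t_welch"),
      statistic = c(unname(tp$statistic), unname(tw$statistic)),
      df = c(unname(tp$parameter), unname(tw$parameter)),
      p = c(tp$p.value, tw$p.value))
  }
  for (v in names(count_tables)) {
    tab <- count_tables[[v]]
    stopifnot(all(dim(tab) == 2L), all(tab >= 0))
    cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    cc <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = c("chisq_pearson", "chisq_yates"),
      statistic = c(unname(cs$statistic), unname(cc$statistic)),
      df = c(unname(cs$parameter), unname(cc$parameter)),
      p = c(cs$p.value, cc$p.value))
  }
  do.call(rbind, rows)
}
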