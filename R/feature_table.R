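#' Case-control feature table
#'
#' Container for a subjects x features numeric matrix with per-subject
#' group labels (case = 1, control = 0), an optional batch identifier, and
#' optional covariates. The column layout is carried by a [feature_schema].
#'
#' @param X numeric matrix, subjects x features.
#' @param subject_ids character vector of unique subject identifiers.
#' @param labels integer/numeric vector of 0 (control) and 1 (case).
#' @param schema a [feature_schema] whose size matches `ncol(X)`; if
#'   `NULL`, an anonymous single-block schema is built from `colnames(X)`.
#' @param batch optional per-subject batch identifier (character/factor).
#' @param covariates optional data.frame of per-subject covariates.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, subject_ids, labels, schema = NULL,
                          batch = NULL, covariates = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(schema)) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- sprintf("f%03d", seq_len(ncol(X)))
    schema <- feature_schema(list(features = nm))
  }
  colnames(X) <- schema$names
  tab <- structure(list(
    X = X,
    subject_ids = as.character(subject_ids),
    labels = as.integer(labels),
    batch = if (!is.null(batch)) as.character(batch) else NULL,
    covariates = covariates,
    schema = schema
  ), class = "feature_table")
  viol <- validate_table(tab, schema)
  if (length(viol)) stop("invalid feature table: ",
                         paste(viol, collapse = "; "))
  tab
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$X), " subjects x ", ncol(x$X),
      " features; ", sum(x$labels == 1L), " cases / ",
      sum(x$labels == 0L), " controls", sep = "")
  if (!is.null(x$batch)) {
    cat("; batches: ", paste(names(table(x$batch)), table(x$batch),
                             sep = "=", collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Validate a feature table against a schema
#'
#' Checks the table invariants (matching lengths, unique ids, binary
#' labels, finite matrix entries, column names and count matching the
#' schema) and reports violations instead of throwing.
#'
#' @param table a [feature_table] (or a bare list with the same fields).
#' @param schema a [feature_schema] to check the column layout against.
#' @return Character vector of human-readable violations; empty when the
#'   table conforms.
#' @export
validate_table <- function(table, schema = table$schema) {
  v <- character()
  X <- table$X
  n <- nrow(X)
  if (length(table$subject_ids) != n)
    v <- c(v, sprintf("subject_ids length %d != %d rows",
                      length(table$subject_ids), n))
  if (anyDuplicated(table$subject_ids))
    v <- c(v, paste0("duplicate subject ids: ",
                     paste(unique(table$subject_ids[
                       duplicated(table$subject_ids)]), collapse = ", ")))
  if (length(table$labels) != n)
    v <- c(v, sprintf("labels length %d != %d rows",
                      length(table$labels), n))
  if (!all(table$labels %in% c(0L, 1L)))
    v <- c(v, "labels must be 0 (control) or 1 (case)")
  if (!is.null(table$batch) && length(table$batch) != n)
    v <- c(v, sprintf("batch length %d != %d rows",
                      length(table$batch), n))
  if (ncol(X) != length(schema$names))
    v <- c(v, sprintf("column count %d != schema size %d",
                      ncol(X), length(schema$names)))
  else if (!is.null(colnames(X)) && !identical(colnames(X), schema$names))
    v <- c(v, "column names do not match schema order")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(bad[seq_len(min(5L, nrow(bad))), , drop = FALSE], 1L,
                   function(rc) sprintf("(%s, %s)",
                                        table$subject_ids[rc[1L]],
                                        colnames(X)[rc[2L]]))
    v <- c(v, sprintf("%d non-finite entries, e.g. %s", nrow(bad),
                      paste(cells, collapse = " ")))
  }
  v
}

#' Read a feature table from delimited text
#'
#' Parses a TSV/CSV file with a header row: a subject-id column, a group
#' label column, optionally a batch column and covariate columns, then the
#' numeric feature columns in schema order.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"csv"`.
#' @param id_column,label_column,batch_column column names; `batch_column`
#'   may be `NULL`.
#' @param case_level value of the label column mapped to case = 1; the
#'   single remaining level is mapped to control = 0. Defaults to `"1"`.
#' @param covariate_columns character vector of covariate column names.
#' @param schema optional [feature_schema]; defaults to one built from the
#'   feature columns found in the file.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, format = c("tsv", "csv"),
                               id_column = "subject_id",
                               label_column = "group",
                               batch_column = NULL,
                               case_level = "1",
                               covariate_columns = character(),
                               schema = NULL) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  need <- c(id_column, label_column, batch_column, covariate_columns)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ids <- df[[id_column]]
  if (anyDuplicated(ids))
    stop("duplicate subject id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lab_raw <- df[[label_column]]
  lv <- unique(lab_raw)
  if (length(lv) != 2L)
    stop("label column '", label_column, "' must have exactly two levels, found: ",
         paste(lv, collapse = ", "))
  if (!case_level %in% lv)
    stop("case level '", case_level, "' not present in label column")
  labels <- as.integer(lab_raw == case_level)
  feat_cols <- setdiff(names(df), need)
  if (!length(feat_cols)) stop("no feature columns found")
  Xc <- as.matrix(df[feat_cols])
  suppressWarnings(X <- matrix(as.numeric(Xc), nrow = nrow(Xc),
                               dimnames = list(NULL, feat_cols)))
  bad <- which(!is.finite(X) | Xc == "", arr.ind = TRUE)
  if (nrow(bad)) {
    rc <- bad[1L, ]
    stop(sprintf("non-numeric or missing feature value at row '%s', column '%s'",
                 ids[rc[1L]], feat_cols[rc[2L]]))
  }
  covs <- if (length(covariate_columns)) {
    cdf <- df[covariate_columns]
    for (cc in covariate_columns) {
      num <- suppressWarnings(as.numeric(cdf[[cc]]))
      if (!anyNA(num)) cdf[[cc]] <- num
    }
    cdf
  } else NULL
  feature_table(X, ids, labels, schema = schema,
                batch = if (!is.null(batch_column)) df[[batch_column]],
                covariates = covs)
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: emits `subject_id`, `group`
#' (1 = case, 0 = control), the batch and covariate columns when present,
#' then the features in schema order. Values round-trip at full `%.17g`
#' precision.
#'
#' @param table a [feature_table].
#' @param path output file.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_feature_table <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(subject_id = table$subject_ids,
                   group = table$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(table$batch)) df$batch <- table$batch
  if (!is.null(table$covariates)) df <- cbind(df, table$covariates)
  Xchr <- apply(table$X, 2L, function(col) sprintf("%.17g", col))
  df <- cbind(df, as.data.frame(Xchr, check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Subset helper: rows (subjects) and/or feature columns by name.
subset_table <- function(table, rows = NULL, features = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(table$X))
  cols <- if (is.null(features)) seq_len(ncol(table$X)) else
    match(features, table$schema$names)
  if (anyNA(cols)) stop("unknown feature(s): ",
                        paste(features[is.na(cols)], collapse = ", "))
  keep_names <- table$schema$names[cols]
  list(X = table$X[rows, cols, drop = FALSE],
       labels = table$labels[rows],
       subject_ids = table$subject_ids[rows],
       features = keep_names)
}
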