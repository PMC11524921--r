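# Small in-code fixtures shared across test files.

# a tiny anonymous schema of p features
tiny_schema <- function(p) feature_schema(list(features = sprintf("f%02d", seq_len(p))))

# small balanced cohort with the first m features informative
tiny_cohort <- function(n_per_group = 50, p = 20, m = 1, d = 1.5,
                        seed = 1, n_batches = 1L, ...) {
  generate_cohort(synthetic_config(
    n_case = n_per_group, n_control = n_per_group, schema = tiny_schema(p),
    informative = sprintf("f%02d", seq_len(m)), d = d,
    n_batches = n_batches, seed = seed, ...))
}

# independent O(n^2) AUC oracle: explicit pair counting with tie half-credit
auc_bruteforce <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# independent pooled-variance two-sample t, coded without the F machinery
pooled_t <- function(x, y01) {
  a <- x[y01 == 1]; b <- x[y01 == 0]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# write a small feature table file by hand
write_tiny_tsv <- function(path, ids, groups, X, sep = "\t") {
  hdr <- paste(c("subject_id", "group", colnames(X)), collapse = sep)
  rows <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], groups[i], format(X[i, ], digits = 17)),
          collapse = sep), character(1))
  writeLines(c(hdr, rows), path)
}
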