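test_that("default cohort matches the study dimensions", {
  cc <- generate_cohort(synthetic_config(seed = 5))
  expect_equal(dim(cc$table$X), c(244L, 317L))
  expect_equal(sum(cc$table$labels == 1L), 175L)
  expect_equal(sum(cc$table$labels == 0L), 69L)
  expect_length(cc$truth$informative, 9L)
  expect_length(validate_table(cc$table), 0L)
  # two balanced batches within each group
  expect_setequal(unique(cc$table$batch), c("scanner1", "scanner2"))
  bt <- table(cc$table$batch, cc$table$labels)
  expect_true(all(abs(bt[1, ] - bt[2, ]) <= 1))
})

test_that("generation is bit-reproducible from the seed", {
  a <- generate_cohort(synthetic_config(seed = 33))
  b <- generate_cohort(synthetic_config(seed = 33))
  expect_identical(a$table$X, b$table$X)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(synthetic_config(seed = 34))
  expect_false(identical(a$table$X, c$table$X))
})

test_that("unscaled features have unit within-group variance", {
  cc <- generate_cohort(synthetic_config(n_batches = 1L, seed = 12))
  v <- apply(cc$table$X[cc$table$labels == 0L, 1:50], 2, var)
  expect_true(all(v > 0.6 & v < 1.5))   # sampling band at n = 69
})

test_that("planted effects materialize at their configured size", {
  cc <- generate_cohort(synthetic_config(n_batches = 1L, seed = 13))
  aud <- effect_size_audit(cc$table, cc$truth)
  inf <- aud$empirical_d[aud$informative]
  # SE(d) ~ sqrt(1/175 + 1/69) ~ 0.14: each within 3 SE, mean within 3
  # SE/sqrt(9) of the planted value
  expect_true(all(abs(inf - 1.2) < 0.45))
  expect_lt(abs(mean(inf) - 1.2), 0.15)
  nulls <- aud$empirical_d[!aud$informative][1:300]
  # null |d| has expectation sqrt(2/pi)*SE ~ 0.11 at n = 175/69
  expect_lt(mean(abs(nulls)), 0.2)
  expect_lt(abs(mean(nulls)), 0.05)         # centered at zero
  # audit is invariant to subject row order
  perm <- cc$table
  set.seed(1)
  ord <- sample(nrow(perm$X))
  perm$X <- perm$X[ord, ]
  perm$subject_ids <- perm$subject_ids[ord]
  perm$labels <- perm$labels[ord]
  perm$batch <- perm$batch[ord]
  expect_equal(effect_size_audit(perm, cc$truth), aud)
})

test_that("a d = 1 feature shows the binormal marginal AUC", {
  cc <- generate_cohort(synthetic_config(
    informative = "left_accumbens_area", d = 1.0, n_batches = 1L, seed = 1))
  auc <- auc_from_scores(cc$table$X[, "left_accumbens_area"],
                         cc$table$labels)
  expect_lt(abs(auc - pnorm(1 / sqrt(2))), 0.04)   # Phi(d/sqrt(2)) ~ 0.760
})

test_that("correlation blocks produce the requested equicorrelation", {
  blk <- sprintf("f%02d", 1:6)
  cc <- generate_cohort(synthetic_config(
    n_case = 400, n_control = 400, schema = tiny_schema(10),
    informative = "f09", d = 0, n_batches = 1L,
    cor_blocks = list(list(features = blk, rho = 0.5)), seed = 14))
  C <- cor(cc$table$X[, blk])
  off <- C[upper.tri(C)]
  expect_true(all(abs(off - 0.5) < 0.12))
  out <- cor(cc$table$X[, "f01"], cc$table$X[, "f08"])
  expect_lt(abs(out), 0.12)
  expect_error(synthetic_config(schema = tiny_schema(4),
                                informative = "f01",
                                cor_blocks = list(list(features = "f02",
                                                       rho = 1.0))),
               "positive-definite")
})

test_that("batch structure is applied after group effects", {
  cfg <- synthetic_config(schema = tiny_schema(6), informative = "f01",
                          d = 1.0, n_batches = 2L,
                          batch_offset = c(0, 3), batch_scale = c(1, 2),
                          n_case = 200, n_control = 200, seed = 15)
  cc <- generate_cohort(cfg)
  b2 <- cc$table$batch == "scanner2"
  gap <- mean(cc$table$X[b2, "f03"]) - mean(cc$table$X[!b2, "f03"])
  expect_lt(abs(gap - 3), 0.5)
  expect_gt(sd(cc$table$X[b2, "f03"]) / sd(cc$table$X[!b2, "f03"]), 1.5)
  # the planted group effect exists inside each batch
  for (b in c(TRUE, FALSE)) {
    x <- cc$table$X[b2 == b, "f01"]
    y <- cc$table$labels[b2 == b]
    expect_gt(mean(x[y == 1]) - mean(x[y == 0]), 0.5)
  }
})
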