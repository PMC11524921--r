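# balanced two-batch cohort with configurable batch offset/scale
two_batch_table <- function(n_per_batch = 100, p = 30, offset = 5,
                            scale = 1, d = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_batch
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  labels <- rep(c(1L, 0L), n_per_batch)      # groups balanced across batches
  if (d != 0) X[labels == 1L, 1:3] <- X[labels == 1L, 1:3] + d
  batch <- rep(c("A", "B"), each = n_per_batch)
  X[batch == "B", ] <- X[batch == "B", ] * scale + offset
  feature_table(X, sprintf("s%03d", 1:n), labels, batch = batch)
}

test_that("single batch fits an identity model", {
  tab <- two_batch_table(20, 10, offset = 0)
  tab$batch <- rep("A", 40)
  model <- combat_fit(tab)
  expect_true(model$identity)
  expect_equal(combat_apply(model, tab)$X, tab$X, tolerance = 1e-8)
})

test_that("additive batch offsets are removed", {
  tab <- two_batch_table(100, 30, offset = 5, seed = 2)
  adj <- combat_apply(combat_fit(tab), tab)
  a <- tab$batch == "A"
  # the systematic (across-feature) offset is essentially eliminated;
  # per-feature residuals keep an EB-shrinkage noise floor of order
  # 0.5 * sqrt(2/n) per batch that does not scale with the offset
  signed_before <- colMeans(tab$X[!a, ]) - colMeans(tab$X[a, ])
  signed_after <- colMeans(adj$X[!a, ]) - colMeans(adj$X[a, ])
  expect_lt(abs(mean(signed_after)), 0.02 * abs(mean(signed_before)))
  pooled_sd <- sqrt((apply(adj$X[a, ], 2, var) +
                     apply(adj$X[!a, ], 2, var)) / 2)
  expect_lt(mean(abs(signed_after) / pooled_sd), 0.1)
  expect_true(all(abs(signed_after) / pooled_sd < 0.35))
})

test_that("multiplicative batch scale effects are removed", {
  tab <- two_batch_table(100, 30, offset = 0, scale = 2, seed = 3)
  adj <- combat_apply(combat_fit(tab), tab)
  a <- tab$batch == "A"
  ratio <- apply(adj$X[!a, ], 2, sd) / apply(adj$X[a, ], 2, sd)
  expect_true(all(ratio > 0.8 & ratio < 1.25))
})

test_that("harmonization ignores group labels and preserves group effects", {
  tab <- two_batch_table(100, 30, offset = 0.5, d = 1.0, seed = 4)
  adj <- combat_apply(combat_fit(tab), tab)
  perm <- tab
  perm$labels <- rev(tab$labels)
  expect_identical(combat_apply(combat_fit(perm), perm)$X, adj$X)
  cohens_d <- function(x, y) {
    (mean(x[y == 1]) - mean(x[y == 0])) /
      sqrt(((sum(y == 1) - 1) * var(x[y == 1]) +
            (sum(y == 0) - 1) * var(x[y == 0])) / (length(y) - 2))
  }
  for (j in 1:3) {
    before <- cohens_d(tab$X[, j], tab$labels)
    after <- cohens_d(adj$X[, j], tab$labels)
    expect_lt(abs(after - before) / abs(before), 0.10)
  }
})

test_that("re-harmonizing already corrected data is a near no-op", {
  tab <- two_batch_table(100, 20, offset = 2, seed = 5)
  adj1 <- combat_apply(combat_fit(tab), tab)
  adj2 <- combat_apply(combat_fit(adj1), adj1)
  first <- mean(abs(adj1$X - tab$X))
  second <- mean(abs(adj2$X - adj1$X))
  expect_lt(second, 0.01 * first)
})

test_that("model agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  tab <- two_batch_table(30, 25, offset = 0.8, scale = 1.4, seed = 6)
  mine <- combat_apply(combat_fit(tab), tab)$X
  ref <- t(suppressMessages(sva::ComBat(dat = t(tab$X), batch = tab$batch)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-4)
  # covariate-protected variant
  tab$covariates <- data.frame(age = runif(60, 7, 18))
  mine2 <- combat_apply(combat_fit(tab, covariate_names = "age"), tab)$X
  ref2 <- t(suppressMessages(sva::ComBat(
    dat = t(tab$X), batch = tab$batch,
    mod = model.matrix(~ age, tab$covariates))))
  expect_equal(unname(mine2), unname(ref2), tolerance = 1e-4)
})

test_that("degenerate inputs are rejected with named errors", {
  tab <- two_batch_table(20, 10)
  model <- combat_fit(tab)
  unseen <- tab
  unseen$batch[1] <- "C"
  expect_error(combat_apply(model, unseen), "not seen at fit time")
  flat <- tab
  flat$X[, 2] <- 7
  expect_error(combat_fit(flat), "zero pooled variance.*f02")
  tiny <- two_batch_table(20, 10)
  tiny$batch <- c("A", rep("B", 39))
  expect_error(combat_fit(tiny), ">= 2 subjects")
  coll <- tab
  coll$covariates <- data.frame(b2 = as.integer(tab$batch == "B"))
  expect_error(combat_fit(coll, covariate_names = "b2"), "collinear")
})
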