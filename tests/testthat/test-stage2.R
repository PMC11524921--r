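std <- function(X) scale(X)[, , drop = FALSE]

test_that("penalties above lambda-max give the exact all-zero model", {
  # 5 x 3 hand matrix
  X <- std(matrix(c(1, 2, 3, 4, 5,
                    2, 1, 4, 3, 5,
                    5, 4, 3, 2, 1), 5, 3,
                  dimnames = list(NULL, c("a", "b", "c"))))
  y <- c(0, 0, 1, 1, 1)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / 5
  fit <- lasso_fit(X, y, lam_max * 1.0001)
  expect_identical(unname(fit$beta), c(0, 0, 0))
  expect_equal(fit$intercept, mean(y))
  fit2 <- lasso_fit(X, y, lam_max * 0.9)
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("the small-penalty limit approaches least squares", {
  set.seed(21)
  X <- std(matrix(rnorm(200 * 4), 200, 4,
                  dimnames = list(NULL, letters[1:4])))
  beta_true <- c(1, -0.5, 0.25, 0)
  y <- drop(X %*% beta_true) + rnorm(200, sd = 0.3)
  ols <- unname(coef(lm(y ~ X))[-1])
  fit <- lasso_fit(X, y, 1e-7, tol = 1e-8)
  expect_equal(unname(fit$beta), ols, tolerance = 1e-4)
})

test_that("constant response yields the null model", {
  X <- std(matrix(rnorm(30), 10, 3, dimnames = list(NULL, letters[1:3])))
  fit <- lasso_fit(X, rep(0.4, 10), 0.1)
  expect_identical(unname(fit$beta), c(0, 0, 0))
  expect_equal(fit$intercept, 0.4)
})

test_that("solutions satisfy the KKT conditions", {
  set.seed(31)
  n <- 80
  X <- std(matrix(rnorm(n * 12), n, 12,
                  dimnames = list(NULL, sprintf("f%02d", 1:12))))
  y <- as.numeric(rbinom(n, 1, plogis(X[, 1] - X[, 2])))
  tol <- 1e-4
  for (alpha in c(0.005, 0.02, 0.08)) {
    fit <- lasso_fit(X, y, alpha, tol)
    r <- y - fit$intercept - drop(X %*% fit$beta)
    g <- drop(crossprod(X, r)) / n       # subgradient of the smooth part
    active <- fit$beta != 0
    expect_true(all(abs(g[active] - alpha * sign(fit$beta[active]))
                    < 10 * tol))
    expect_true(all(abs(g[!active]) < alpha + 10 * tol))
  }
})

test_that("selected sets shrink weakly as the penalty grows", {
  cc <- tiny_cohort(n_per_group = 50, p = 20, m = 4, d = 1.0, seed = 41)
  folds <- make_folds(cc$table$labels, 5, seed = 41)
  s1 <- msrefine:::stage1_select(cc$table, folds, 1.0)
  grid <- 10^seq(-3, -0.5, length.out = 8)
  sizes <- sapply(grid, function(a) {
    recs <- fold_feature_subsets(cc$table, s1, a, folds)
    sapply(recs, function(r) length(r$selected))
  })
  for (k in 1:5) expect_true(all(diff(sizes[k, ]) <= 0))
})

test_that("penalty selection minimizes held-out loss with sparse ties", {
  cc <- tiny_cohort(n_per_group = 40, p = 10, m = 2, seed = 51)
  folds <- make_folds(cc$table$labels, 5, seed = 51)
  s1 <- msrefine:::stage1_select(cc$table, folds, 1.0)
  one <- select_alpha(cc$table, s1, lasso_config(alpha_grid = 0.03), folds)
  expect_equal(one$alpha, 0.03)
  # pure noise: every fold's best model is empty, ties resolve to the
  # largest (sparsest) penalty on the grid
  null_cc <- tiny_cohort(n_per_group = 40, p = 30, m = 1, d = 0, seed = 52)
  nfolds <- make_folds(null_cc$table$labels, 5, seed = 52)
  ns1 <- msrefine:::stage1_select(null_cc$table, nfolds, 1.0)
  cfg <- lasso_config()
  pick <- select_alpha(null_cc$table, ns1, cfg, nfolds)
  expect_equal(pick$alpha, max(cfg$alpha_grid))
  recs <- fold_feature_subsets(null_cc$table, ns1, pick$alpha, nfolds, cfg)
  expect_true(all(lengths(lapply(recs, `[[`, "selected")) == 0))
})

test_that("strong planted features survive in every fold at alpha*", {
  cc <- generate_cohort(synthetic_config(
    informative = 5L, d = 1.5, n_batches = 1L, seed = 61))
  folds <- make_folds(cc$table$labels, 5, seed = 61)
  s1 <- msrefine:::stage1_select(cc$table, folds, 0.2)
  cfg <- lasso_config()
  astar <- select_alpha(cc$table, s1, cfg, folds)$alpha
  recs <- fold_feature_subsets(cc$table, s1, astar, folds, cfg)
  for (r in recs)
    expect_true(all(cc$truth$informative %in% r$selected))
  expect_identical(recs,
                   fold_feature_subsets(cc$table, s1, astar, folds, cfg))
})

test_that("frequency voting respects counts, ordering and nestedness", {
  rec <- function(fold, feats, coefs)
    list(fold = fold, selected = feats,
         coefficients = setNames(coefs, feats), train_ids = character())
  records <- list(rec(1, c("a", "b"), c(1, 0.5)),
                  rec(2, c("a", "c"), c(0.9, 0.2)),
                  rec(3, c("a", "b"), c(1.1, 0.4)),
                  rec(4, c("b"), 0.6),
                  rec(5, c("a"), 1.0))
  out <- frequency_filter(records, 3, schema_order = c("a", "b", "c"))
  expect_identical(out$retained, c("a", "b"))   # counts 4 and 3; c has 1
  expect_identical(out$table$feature, c("a", "b", "c"))
  expect_identical(frequency_filter(records, 1)$retained, c("a", "b", "c"))
  expect_identical(frequency_filter(records, 4)$retained, "a")
  expect_length(frequency_filter(records, 5)$retained, 0L)
  # raising min_count never adds features
  for (m in 1:4)
    expect_true(all(frequency_filter(records, m + 1)$retained %in%
                      frequency_filter(records, m)$retained))
  expect_error(frequency_filter(records, 6), "min_count")
})
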