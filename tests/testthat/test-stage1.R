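test_that("ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(10)
  for (rep_i in 1:5) {
    n <- sample(10:40, 1)
    X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, letters[1:8]))
    y <- c(rep(1L, n %/% 2), rep(0L, n - n %/% 2))
    f <- anova_f_scores(X, y)$f
    t2 <- apply(X, 2, function(x) pooled_t(x, y)^2)
    expect_equal(unname(f), unname(t2), tolerance = 1e-10)
  }
})

test_that("degenerate features get the documented conventions", {
  y <- rep(c(1L, 0L), each = 10)
  X <- cbind(sep = as.numeric(y),       # zero within-class variance
             flat = rep(3, 20),         # constant everywhere
             noise = rnorm(20))
  expect_warning(sc <- anova_f_scores(X, y), "constant feature")
  expect_true(is.infinite(sc$f["sep"]))
  expect_equal(unname(sc$f["flat"]), 0)
  expect_equal(select_top_fraction(sc, 1 / 3), "sep")  # Inf ranks first
  expect_error(anova_f_scores(X, rep(1L, 20)), "class")
})

test_that("null features score F near its expectation", {
  set.seed(99)
  n <- 244
  X <- matrix(rnorm(n * 2000), n, 2000,
              dimnames = list(NULL, sprintf("n%04d", 1:2000)))
  y <- sample(rep(c(1L, 0L), c(175, 69)))
  f <- anova_f_scores(X, y)$f
  expect_gt(mean(f), 0.9)   # E[F] = dfw/(dfw-2) ~ 1.008 under the null
  expect_lt(mean(f), 1.1)
})

test_that("top-fraction selection uses the ceiling rule", {
  mk <- function(p) structure(list(f = setNames(rev(seq_len(p)),
                                                sprintf("f%03d", 1:p)),
                                   df_between = 1L, df_within = 10L),
                              class = "score_vector")
  expect_length(select_top_fraction(mk(317), 0.20), 64L)
  expect_length(select_top_fraction(mk(10), 0.5), 5L)
  expect_length(select_top_fraction(mk(10), 0.25), 3L)   # ceil(2.5)
  expect_length(select_top_fraction(mk(10), 1.0), 10L)
  expect_identical(select_top_fraction(mk(5), 0.4), c("f001", "f002"))
  expect_error(select_top_fraction(mk(5), 0), "fraction")
  # ties break by schema position
  sc <- structure(list(f = setNames(c(1, 2, 2, 0), letters[1:4]),
                       df_between = 1L, df_within = 10L),
                  class = "score_vector")
  expect_identical(select_top_fraction(sc, 0.5), c("b", "c"))
})

test_that("fold selections never depend on held-out subjects", {
  cc <- tiny_cohort(n_per_group = 30, p = 15, m = 2, seed = 8)
  folds <- make_folds(cc$table$labels, 5, seed = 8)
  base <- msrefine:::stage1_select(cc$table, folds, 0.3)
  poked <- cc$table
  held <- folds$assignment == 2
  poked$X[held, ] <- poked$X[held, ] + 100
  after <- msrefine:::stage1_select(poked, folds, 0.3)
  expect_identical(after[[2]]$selected, base[[2]]$selected)
  expect_identical(after[[2]]$f, base[[2]]$f)
})

test_that("grid search returns the fraction capturing the signal band", {
  # six informative features sit exactly in the top 15% of F ranks (p = 40),
  # so 0.2 is the smallest candidate that captures them all
  sch <- tiny_schema(40)
  cc <- generate_cohort(synthetic_config(
    n_case = 80, n_control = 80, schema = sch,
    informative = sprintf("f%02d", 1:6), d = 0.9, n_batches = 1L, seed = 1))
  folds <- make_folds(cc$table$labels, 5, seed = 1)
  g <- grid_search_fraction(cc$table, c(0.1, 0.2, 0.3), folds)
  expect_equal(g$best_fraction, 0.2)
  # single candidate is returned untouched
  expect_equal(grid_search_fraction(cc$table, 0.2, folds)$best_fraction, 0.2)
  # exact AUC ties break toward the smallest fraction: both candidates
  # select all features of a tiny table, so the scores coincide
  cc2 <- tiny_cohort(n_per_group = 20, p = 5, m = 1, seed = 2)
  folds2 <- make_folds(cc2$table$labels, 5, seed = 2)
  g2 <- grid_search_fraction(cc2$table, c(0.85, 1.0), folds2)
  expect_equal(unname(diff(g2$mean_auc)), 0)
  expect_equal(g2$best_fraction, 0.85)
})
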