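# Internal helpers shared across stages.

# Run code under a temporary RNG state; restores the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column standardization fit on training rows only (leakage control).
# Constant columns get sd = 1 so they standardize to zero, not NaN.
standardizer_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

standardizer_apply <- function(st, X) {
  sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
}

# Linear SVM (hinge loss, L2 penalty) returning a weight vector and
# intercept oriented so that score > 0 predicts the case class (label 1).
# libsvm's internal sign convention depends on training-row order, so the
# orientation is fixed against the model's own predicted labels.
svm_linear_fit <- function(X, y, cost) {
  if (length(unique(y)) < 2L) stop("one-class training fold: cannot fit SVM")
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  pred <- predict(fit, X)
  score <- drop(X %*% w) + b
  # orient: the fitted model's own hard predictions define the sign
  agree <- mean((score > 0) == (pred == "1"))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

svm_decision <- function(model, X) drop(X %*% model$w) + model$b
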