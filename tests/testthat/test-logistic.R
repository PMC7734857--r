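test_that("logistic fit recovers symmetric and planted structure", {
  # symmetric toy data: intercept must vanish
  x <- matrix(c(-1, -1, 1, 1), ncol = 1, dimnames = list(NULL, "v"))
  y <- c(0, 0, 1, 1)
  m <- fit_logistic(x, y)
  expect_lt(abs(m$intercept), 1e-6)
  expect_gt(m$coefficients[["v"]], 0)

  # parameter recovery: planted log-odds slope 2.0
  set.seed(41)
  errs <- vapply(1:10, function(i) {
    x <- matrix(stats::rnorm(5000), ncol = 1, dimnames = list(NULL, "v"))
    y <- rbinom(5000, 1, stats::plogis(2 * x[, 1]))
    fit_logistic(x, y)$coefficients[["v"]] - 2
  }, numeric(1))
  expect_true(all(abs(errs) < 0.15))
})

test_that("logistic fit matches glm on well-conditioned data", {
  set.seed(42)
  x <- cbind(a = stats::rnorm(200), b = stats::runif(200, -2, 2))
  y <- rbinom(200, 1, stats::plogis(0.5 + 0.8 * x[, 1] - 1.2 * x[, 2]))
  m <- fit_logistic(x, y, lambda = 1e-8, maxit = 100, tol = 1e-12)
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(m$intercept, unname(stats::coef(g)[1]), tolerance = 1e-4)
  expect_equal(unname(m$coefficients), unname(stats::coef(g)[-1]),
               tolerance = 1e-4)
})

test_that("fitted coefficients match a brute-force penalized grid search", {
  set.seed(43)
  x <- matrix(stats::rnorm(20), ncol = 1, dimnames = list(NULL, "v"))
  y <- rbinom(20, 1, stats::plogis(1.2 * x[, 1] - 0.3))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  lam <- 0.05  # appreciable penalty so the oracle tests the ridge term too
  m <- fit_logistic(x, y, lambda = lam, maxit = 200, tol = 1e-12)
  obj <- function(b0, b1) {
    eta <- b0 + b1 * x[, 1]
    -sum(y * eta - log1p(exp(eta))) + 0.5 * lam * b1^2
  }
  # coarse-to-fine grid search, independent of the IRLS path
  ctr <- c(0, 0); width <- 8
  for (pass in 1:6) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(obj))
    k <- arrayInd(which.min(vals), dim(vals))
    ctr <- c(b0s[k[1]], b1s[k[2]])
    width <- width / 10
  }
  expect_equal(m$intercept, ctr[1], tolerance = 5e-3)
  expect_equal(unname(m$coefficients), ctr[2], tolerance = 5e-3)
})

test_that("degenerate inputs are handled deterministically", {
  x <- matrix(rep(3, 20), ncol = 1, dimnames = list(NULL, "const"))
  y <- rep(c(0, 1), 10)
  m <- fit_logistic(x, y)  # constant column: penalty keeps it finite
  expect_true(is.finite(m$coefficients[["const"]]))

  expect_error(fit_logistic(x, rep(1, 20)), "degenerate fold")
  expect_error(fit_logistic(x[1, , drop = FALSE], 1), "at least 2 rows")

  # determinism: same inputs, same coefficients
  set.seed(44)
  x2 <- cbind(a = stats::rnorm(50))
  y2 <- rbinom(50, 1, 0.4)
  if (length(unique(y2)) < 2) y2[1] <- 1 - y2[1]
  expect_identical(fit_logistic(x2, y2), fit_logistic(x2, y2))
})

test_that("predictions respect the logistic link and column matching", {
  null_model <- structure(
    list(intercept = 0,
         coefficients = c(a = 0, b = 0),
         feature_names = c("a", "b"), lambda = 0, converged = TRUE),
    class = "hrv_logit"
  )
  x <- cbind(a = c(-5, 0, 5), b = c(1, 2, 3))
  expect_equal(predict_prob(null_model, x), rep(0.5, 3))

  set.seed(45)
  xt <- cbind(a = stats::rnorm(30), b = stats::rnorm(30))
  yt <- rbinom(30, 1, stats::plogis(xt[, 1]))
  if (length(unique(yt)) < 2) yt[1] <- 1 - yt[1]
  m <- fit_logistic(xt, yt)
  p <- predict_prob(m, xt)
  expect_true(all(p > 0 & p < 1))
  # probabilities increase monotonically along the fitted direction
  grid <- cbind(a = seq(-50, 50, length.out = 11), b = 0)
  pg <- predict_prob(m, grid)
  if (m$coefficients[["a"]] > 0) expect_true(all(diff(pg) >= 0))

  # column order must not matter when names are present
  expect_equal(predict_prob(m, xt[, c("b", "a")]), p)
  expect_error(predict_prob(m, cbind(a = 1:3)), "missing")

  # refitting with shuffled columns gives identical predictions
  m2 <- fit_logistic(xt[, c("b", "a")], yt)
  expect_equal(predict_prob(m2, xt), p, tolerance = 1e-6)
})
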