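test_that("model term sets have the frozen structure and column counts", {
  m1 <- model_terms("model1")
  expect_length(m1$terms, 13)
  expect_identical(model_terms("null")$terms, m1$terms)
  expect_length(model_terms("model2")$terms, 19)
  expect_length(model_terms("model3")$terms, 21)

  d <- tibble::tibble(suitability = rnorm(10), access = rnorm(10),
                      steepness = rnorm(10), pop_density = rnorm(10),
                      gdp = rnorm(10), cropland_start = rnorm(10),
                      frontierness = rnorm(10))
  expect_equal(ncol(build_design(d, m1)), 14)
  expect_equal(ncol(build_design(d, model_terms("model2"))), 20)
  expect_equal(ncol(build_design(d, model_terms("model3"))), 22)
  expect_error(build_design(d[, 1:4], m1), "missing variable")
})

test_that("re-centering subtracts sub-sample means from mains before products", {
  set.seed(3)
  d <- tibble::tibble(suitability = rnorm(50, 2), access = rnorm(50, -1),
                      steepness = rnorm(50), pop_density = rnorm(50),
                      gdp = rnorm(50))
  X <- build_design(d, model_terms("model1"), recenter = TRUE)
  expect_equal(unname(colMeans(X)[2:6]), rep(0, 5), tolerance = 1e-12)
  cen <- function(v) v - mean(v)
  expect_equal(X[, "suitability:access"],
               cen(d$suitability) * cen(d$access))
  # without re-centering, raw products are used
  X0 <- build_design(d, model_terms("model1"), recenter = FALSE)
  expect_equal(X0[, "suitability:access"], d$suitability * d$access)
})

test_that("standardize_predictors gives mean 0 / SD 1 over the domain and keeps stats", {
  d <- tibble::tibble(a = rep(c(0, 2), 500), b = rnorm(1000, 5, 3))
  out <- standardize_predictors(d, c("a", "b"))
  expect_equal(sort(unique(round(out$data$a, 3))), c(-0.999, 0.999))
  expect_equal(mean(out$data$b), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out$data$b), 1, tolerance = 1e-12)
  # idempotent on already-standardized input
  out2 <- standardize_predictors(out$data, c("a", "b"))
  expect_equal(out2$data$b, out$data$b, tolerance = 1e-12)
  expect_error(standardize_predictors(tibble::tibble(x = rep(1, 10)), "x"),
               "degenerate variable")
  # domain restriction: stats computed over the domain only
  dom <- d$b > 5
  out3 <- standardize_predictors(d, "b", domain = dom)
  expect_equal(mean(out3$data$b[dom]), 0, tolerance = 1e-12)
})

test_that("fit_logistic reproduces the closed-form 2x2 log-odds", {
  x <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  fit <- fit_logistic(cbind(1, x), y)
  expect_equal(unname(fit$beta[2]), log(16), tolerance = 1e-8)
  expect_equal(unname(fit$beta[1]), log(1 / 4), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("fit_logistic agrees with an independent Newton-Raphson oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(100:400, 1)
    p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    beta <- runif(p + 1, -1, 1)
    y <- rbinom(n, 1, plogis(X %*% beta))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(X, y)
    expect_equal(unname(fit$beta), newton_logistic(X, y), tolerance = 1e-6)
  }
})

test_that("likelihood quantities are invariant to row duplication", {
  x <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  f1 <- fit_logistic(cbind(1, x), y)
  f2 <- fit_logistic(cbind(1, c(x, x)), c(y, y))
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-9)
  expect_equal(mcfadden(f1), mcfadden(f2), tolerance = 1e-9)
})

test_that("a null predictor yields a near-zero slope on simulated data", {
  set.seed(21)
  n <- 1e4
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic(cbind(1, x), y)
  expect_lt(abs(fit$beta[2]), 0.07)
  expect_lt(mcfadden(fit), 0.02)
})

test_that("mcfadden satisfies its defining identities", {
  # intercept-only: fitted probabilities equal the sample mean -> 0
  y <- rep(c(0, 1), c(30, 20))
  fit <- fit_logistic(matrix(1, 50, 1), y)
  expect_equal(mcfadden(fit), 0, tolerance = 1e-12)

  # six-row worked sample, hand-computed 1 - l/l0
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fit_logistic(cbind(1, x), y)
  p <- plogis(fit$beta[1] + fit$beta[2] * x)
  ll_hand <- sum(log(ifelse(y == 1, p, 1 - p)))
  ll0_hand <- sum(log(ifelse(y == 1, 0.5, 0.5)))
  expect_equal(mcfadden(fit), 1 - ll_hand / ll0_hand, tolerance = 1e-12)

  # near-perfect classifier on balanced toy data
  set.seed(5)
  x <- c(rnorm(200, -4), rnorm(200, 4))
  y <- rep(c(0, 1), each = 200)
  fit <- suppressWarnings(fit_logistic(cbind(1, x), y))
  expect_gt(mcfadden(fit), 0.95)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_logistic(cbind(1, rnorm(20)), rep(1, 20)), "one class")
  expect_error(fit_logistic(cbind(1, rnorm(20)), c(rep(0.5, 20))), "binary")
  expect_error(mcfadden(list(loglik = -1, loglik_null = 0)), "degenerate")
})

test_that("tidy and glance expose coefficients and fit statistics", {
  x <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  fit <- fit_logistic(cbind("(Intercept)" = 1, slope = x), y)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$mcfadden, mcfadden(fit))
  expect_equal(gl$nobs, 100)
})
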