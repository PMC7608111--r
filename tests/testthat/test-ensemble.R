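test_that("balanced_sample draws exact class counts without replacement, reproducibly", {
  y <- rep(c(1, 0), c(1000, 1000))
  cfg <- ensemble_config(n_replicates = 5, n_presence = 500, n_absence = 500,
                         seed = 1)
  idx <- balanced_sample(y, cfg, 1)
  expect_length(idx, 1000)
  expect_false(any(duplicated(idx)))
  expect_equal(sum(y[idx] == 1), 500)
  expect_equal(sum(y[idx] == 0), 500)
  expect_identical(idx, balanced_sample(y, cfg, 1))
  expect_false(identical(idx, balanced_sample(y, cfg, 2)))

  y_short <- rep(c(1, 0), c(499, 1000))
  expect_error(balanced_sample(y_short, cfg, 1), "pool error.*499")
})

test_that("a one-replicate ensemble reduces to a single fit", {
  set.seed(8)
  n <- 1500
  d <- tibble::tibble(
    suitability = rnorm(n), access = rnorm(n), steepness = rnorm(n),
    pop_density = rnorm(n), gdp = rnorm(n))
  d$y <- rbinom(n, 1, plogis(d$suitability - d$access))
  cfg <- ensemble_config(n_replicates = 1, n_presence = 300, n_absence = 300,
                         seed = 4)
  ens <- run_ensemble(d, model_terms("model1"), cfg)
  idx <- balanced_sample(d$y, cfg, 1)
  X <- build_design(d[idx, ], model_terms("model1"), recenter = TRUE)
  fit <- fit_logistic(X, d$y[idx])
  expect_equal(unname(ens$beta[1, ]), unname(fit$beta))
  expect_equal(ens$r2[1], mcfadden(fit))
  expect_equal(tidy(ens)$estimate, unname(fit$beta))
})

test_that("ensembles are bitwise reproducible and summaries match a sort oracle", {
  set.seed(9)
  n <- 2000
  d <- tibble::tibble(
    suitability = rnorm(n), access = rnorm(n), steepness = rnorm(n),
    pop_density = rnorm(n), gdp = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.8 * d$suitability))
  cfg <- ensemble_config(n_replicates = 30, n_presence = 250, n_absence = 250,
                         seed = 12)
  e1 <- run_ensemble(d, model_terms("model1"), cfg)
  e2 <- run_ensemble(d, model_terms("model1"), cfg)
  expect_identical(e1$beta, e2$beta)
  expect_identical(e1$r2, e2$r2)

  td <- tidy(e1)
  for (j in c(1, 5)) {
    v <- sort(e1$beta[e1$converged, j])
    k <- length(v)
    lo <- stats::quantile(v, 0.025, names = FALSE)
    expect_equal(unname(td$conf.low[j]), lo)
    expect_equal(unname(td$estimate[j]), mean(v))
  }
  expect_equal(summarize_ensemble(e1)$mean_mcfadden, mean(e1$r2[e1$converged]))
})

test_that("an uninformative response gives near-zero mean pseudo-R2", {
  set.seed(10)
  n <- 3000
  d <- tibble::tibble(
    suitability = rnorm(n), access = rnorm(n), steepness = rnorm(n),
    pop_density = rnorm(n), gdp = rnorm(n))
  d$y <- rbinom(n, 1, 0.3)
  cfg <- ensemble_config(n_replicates = 50, n_presence = 300, n_absence = 300,
                         seed = 2)
  ens <- run_ensemble(d, model_terms("model1"), cfg)
  expect_lt(mean(ens$r2[ens$converged]), 0.02)
})

test_that("glance reports replicate accounting", {
  set.seed(13)
  n <- 1200
  d <- tibble::tibble(
    suitability = rnorm(n), access = rnorm(n), steepness = rnorm(n),
    pop_density = rnorm(n), gdp = rnorm(n))
  d$y <- rbinom(n, 1, 0.5)
  cfg <- ensemble_config(10, 200, 200, seed = 3)
  ens <- run_ensemble(d, model_terms("model1"), cfg)
  gl <- glance(ens)
  expect_equal(gl$n_replicates, 10L)
  expect_equal(gl$model, "model1")
  expect_lte(gl$n_converged, 10L)
})
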