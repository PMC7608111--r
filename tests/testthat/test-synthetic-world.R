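test_that("random fields are standardized, seeded, and track corr_length", {
  f1 <- grid_values(random_field(c(200, 200), corr_length = 1, seed = 5))
  f10 <- grid_values(random_field(c(200, 200), corr_length = 10, seed = 5))
  lag1 <- function(m) stats::cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  expect_lt(abs(lag1(f1)), 0.05)
  expect_gt(lag1(f10), 0.5)
  expect_equal(mean(f10), 0, tolerance = 1e-12)
  expect_equal(stats::sd(f10), 1, tolerance = 1e-12)
  expect_identical(f10, grid_values(random_field(c(200, 200), 10, seed = 5)))
  expect_error(random_field(c(10, 10), corr_length = 0.5), "corr_length")
})

test_that("generate_world is reproducible and respects fraction invariants", {
  cfg <- world_config(shape = c(60, 60), seed = 7, corr_length = 5,
                      n_clusters = 3, cluster_radius = 4)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(grid_values(w1$cropland$frac_start),
                   grid_values(w2$cropland$frac_start))
  px <- world_pixels(w1)
  ok <- !is.na(px$frac_start)
  expect_true(all(px$frac_start[ok] >= 0 & px$frac_start[ok] <= 1))
  expect_true(all(px$frac_expansion[ok] >= 0))
  expect_true(all(px$frac_expansion[ok] <= 1 - px$frac_start[ok] + 1e-9))
  expect_true(all(px$frac_expansion[ok] <= px$available[ok] + 1e-9))
  expect_true(all(px$frontier >= 0))
  # per-cell fraction bookkeeping stays consistent
  tot <- px$frac_start + px$protected_frac + px$nonconvertible_frac
  expect_true(all(tot[ok] <= 1 + 1e-9))
})

test_that("frontier field is confined to cluster neighbourhoods", {
  cfg <- world_config(shape = c(80, 80), seed = 3, n_clusters = 1,
                      cluster_radius = 4)
  w <- generate_world(cfg)
  f <- grid_values(w$frontier_field)
  centre <- which(f == max(f), arr.ind = TRUE)[1, ]
  rows <- matrix(seq_len(80), 80, 80)
  cols <- matrix(seq_len(80), 80, 80, byrow = TRUE)
  dist <- sqrt((rows - centre[1])^2 + (cols - centre[2])^2)
  expect_true(all(f[dist > 4 * 4] == 0))
  expect_true(all(f[dist < 2] > 0))
})

test_that("a frontier-free world leaves residual cropland uncorrelated with the cluster field", {
  # plant clusters but give them zero effect on extent and expansion
  cfg <- world_config(shape = c(120, 120), seed = 5, gamma_frontier = 0,
                      lambda_frontier = 0, beta_true = recovery_beta())
  w <- generate_world(cfg)
  px <- world_pixels(w)
  td <- suppressWarnings(prepare_analysis(w, 0.10))
  f_truth <- px$frontier[as.vector(td$domains$extent_domain)]
  rho <- stats::cor(td$frontierness$z, f_truth, method = "spearman")
  expect_lt(abs(rho), 0.05)
})

test_that("protected_share = 0 removes protection from the availability budget", {
  cfg <- world_config(shape = c(60, 60), seed = 7, protected_share = 0)
  w <- generate_world(cfg)
  expect_true(all(grid_values(w$masks$protected_frac) == 0))
  px <- world_pixels(w)
  ok <- !is.na(px$available)
  expect_equal(px$available[ok],
               pmax(1 - px$frac_start[ok] - px$nonconvertible_frac[ok], 0))
})

test_that("fine-scale sampling reproduces coarse fractions by counting", {
  w <- small_world()
  k <- 4
  fine <- fine_scale_sample(w, k)
  agg <- aggregate_fraction(fine, k)
  fs <- grid_values(w$cropland$frac_start)
  wf <- grid_values(w$masks$water_frac)
  n_land <- k^2 - round(wf * k^2)
  ok <- !is.na(fs) & n_land > 0
  # block cropland share matches frac_start to within one fine cell
  expect_true(all(abs(grid_values(agg)[ok] - fs[ok]) <= 1 / n_land[ok] + 1e-12))
  # end-year grid adds expansion cells on top of the same start layout
  fine_end <- fine_scale_sample(w, k, year = "end")
  expf <- expansion_fraction(fine, fine_end, k)
  fe <- grid_values(w$cropland$frac_expansion)
  expect_true(all(abs(grid_values(expf)[ok] - fe[ok]) <= 1 / n_land[ok] + 1e-12))
  expect_error(fine_scale_sample(w, 1), "pixels_per_side")
})
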