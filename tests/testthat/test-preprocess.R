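block4 <- function(labels) matrix(labels, 4, 4)

test_that("aggregate_fraction matches counting oracles on hand-built blocks", {
  b <- block4(rep(c("cropland", "other"), each = 8))
  expect_equal(grid_values(aggregate_fraction(b, 4))[1, 1], 0.5)

  b <- block4(c(rep("cropland", 4), rep("water", 8), rep("other", 4)))
  expect_equal(grid_values(aggregate_fraction(b, 4))[1, 1], 4 / 8)

  b <- block4(rep("water", 16))
  expect_true(is.na(grid_values(aggregate_fraction(b, 4))[1, 1]))

  # mosaic excluded by default, counted in sensitivity mode
  b <- block4(c(rep("cropland", 4), rep("mosaic", 4), rep("other", 8)))
  expect_equal(grid_values(aggregate_fraction(b, 4))[1, 1], 0.25)
  expect_equal(grid_values(aggregate_fraction(b, 4, mosaic_as_cropland = TRUE))[1, 1], 0.5)

  expect_error(aggregate_fraction(matrix("other", 5, 5), 4), "divisible")
})

test_that("aggregate_fraction equals an explicit double-loop mean of the indicator", {
  set.seed(2)
  fine <- matrix(sample(c("cropland", "other", "water"), 24 * 24, TRUE,
                        prob = c(0.4, 0.4, 0.2)), 24, 24)
  got <- grid_values(aggregate_fraction(fine, 8))
  for (bi in 1:3) for (bj in 1:3) {
    n_crop <- 0; n_land <- 0
    for (i in ((bi - 1) * 8 + 1):(bi * 8)) for (j in ((bj - 1) * 8 + 1):(bj * 8)) {
      if (fine[i, j] != "water") {
        n_land <- n_land + 1
        if (fine[i, j] == "cropland") n_crop <- n_crop + 1
      }
    }
    expect_identical(got[bi, bj], n_crop / n_land)
  }
})

test_that("expansion_fraction counts only gained cropland over non-water cells", {
  start <- block4(rep("other", 16))
  end <- block4(rep(c("cropland", "other"), each = 8))
  expect_equal(grid_values(expansion_fraction(start, end, 4))[1, 1], 0.5)

  expect_equal(grid_values(expansion_fraction(start, start, 4))[1, 1], 0)

  # 4 cells lost, 4 different cells gained -> expansion 4/16, losses ignored
  start <- block4(c(rep("cropland", 4), rep("other", 12)))
  end <- block4(c(rep("other", 4), rep("cropland", 4), rep("other", 8)))
  expect_equal(grid_values(expansion_fraction(start, end, 4))[1, 1], 0.25)

  expect_error(expansion_fraction(start, matrix("other", 4, 5), 4), "alignment")
})

test_that("binarize applies a strict threshold by default and propagates nodata", {
  expect_false(binarize(0.004, 0.005))
  expect_true(binarize(0.60, 0.50))
  expect_false(binarize(0.10, 0.10))
  expect_true(binarize(0.10, 0.10, boundary = "inclusive"))
  g <- land_grid(matrix(c(0.2, NA, 0.05, 0.9), 2, 2))
  b <- grid_values(binarize(g, 0.10))
  expect_identical(as.vector(b), c(1, NA, 0, 1))
})

test_that("suitable_mask keeps strictly positive suitability only", {
  g <- land_grid(matrix(c(0, 0.01, NA, 2), 2, 2))
  expect_identical(as.vector(grid_values(suitable_mask(g))), c(0, 1, 0, 1))
})

test_that("expansion_domain applies the availability arithmetic", {
  mk <- function(fs, prot, nonc, suit = 1) {
    list(frac_start = land_grid(matrix(fs, 2, 2)),
         masks = list(suitable = land_grid(matrix(suit, 2, 2)),
                      protected_frac = land_grid(matrix(prot, 2, 2)),
                      nonconvertible_frac = land_grid(matrix(nonc, 2, 2))))
  }
  w <- mk(0.95, 0, 0)
  d <- expansion_domain(w$frac_start, w$masks, 0.10)
  expect_false(any(d$expansion_domain))
  expect_equal(d$available[1, 1], 0.05)

  w <- mk(0.2, 0.3, 0.1)
  d <- expansion_domain(w$frac_start, w$masks, 0.10)
  expect_true(all(d$expansion_domain))
  expect_equal(d$available[1, 1], 0.4)

  w <- mk(0.1, 0, 0, suit = 0)
  d <- expansion_domain(w$frac_start, w$masks, 0.10)
  expect_false(any(d$expansion_domain))

  # inconsistent overlapping fractions are clipped with a warning
  w <- mk(0.8, 0.5, 0)
  expect_warning(d <- expansion_domain(w$frac_start, w$masks, 0.10), "clipping")
  expect_equal(d$available[1, 1], 0)
})

test_that("raising tau never adds pixels to binarized layers or domains", {
  w <- small_world()
  taus <- c(0.005, 0.10, 0.50)
  fs <- w$cropland$frac_start
  prev_bin <- NULL
  prev_dom <- NULL
  for (tau in taus) {
    b <- grid_values(binarize(fs, tau))
    d <- expansion_domain(fs, w$masks, tau)$expansion_domain
    if (!is.null(prev_bin)) {
      expect_true(all(b[!is.na(b)] <= prev_bin[!is.na(b)]))
      expect_true(all(d <= prev_dom))
    }
    prev_bin <- b
    prev_dom <- d
  }
})
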