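#' Stationary Gaussian random field on a grid
#'
#' Simulates a zero-mean, unit-variance spatially autocorrelated field by
#' circular convolution of white noise with an isotropic Gaussian kernel
#' (computed via FFT, so the field is stationary on the torus). The kernel
#' standard deviation is `(corr_length - 1) / 2` cells, so `corr_length = 1`
#' yields spatially independent noise and larger values give progressively
#' smoother fields (lag-1 autocorrelation increasing towards 1).
#'
#' @param shape Integer vector `c(nrows, ncols)`.
#' @param corr_length Autocorrelation scale in cells; must be >= 1.
#' @param seed Integer seed; the field is fully reproducible from it.
#' @return A `land_grid` with empirical mean 0 and standard deviation 1.
#' @export
random_field <- function(shape, corr_length = 1, seed = 1) {
  if (corr_length < 1) stop("corr_length must be >= 1")
  stopifnot(length(shape) == 2, all(shape >= 2))
  set.seed(as.integer(seed))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  sigma <- (corr_length - 1) / 2
  if (sigma > 0) {
    # toroidal distances along each axis -> separable Gaussian kernel
    dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    kern <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
  }
  z <- (z - mean(z)) / stats::sd(z)
  land_grid(z)
}

#' Configuration of a synthetic gridded world
#'
#' Collects every knob of the synthetic-landscape generator. The defaults
#' describe the reference study conditions used throughout the package's
#' validation suite: a 200 x 200 lattice, five autocorrelated predictor
#' fields, a cropland-extent process driven by classical land-rent /
#' market-access predictors (`beta_true`, logit scale), and planted frontier
#' clusters that boost both 1992 extent (`gamma_frontier`) and 1992-2015
#' expansion (`lambda_frontier`) beyond what those predictors explain.
#'
#' @param shape `c(nrows, ncols)` of the coarse lattice.
#' @param seed Master integer seed for the world.
#' @param corr_length Autocorrelation scale (cells) of the predictor fields.
#' @param beta_true Named 14-vector: intercept + the 13 classical-theory
#'   terms (5 main effects, 8 interactions), logit scale, applied to
#'   globally standardized predictors.
#' @param gamma_frontier Logit-scale boost of the frontier field on extent.
#' @param n_clusters Number of planted frontier clusters.
#' @param cluster_radius Gaussian kernel scale of each cluster, in cells.
#' @param delta_expansion Named 14-vector of expansion-process coefficients
#'   over the same term set (logit scale).
#' @param lambda_frontier Logit-scale boost of the frontier field on expansion.
#' @param protected_share Fraction of the land surface placed under
#'   protection (contiguous patches).
#' @param expansion_noise_scale Scale of the latent logistic disturbance of
#'   the expansion process (the extent disturbance is fixed at scale 1 so
#'   binarized extent is an exact logistic GLM in `beta_true`).
#' @return A list of class `world_config`.
#' @seealso [generate_world()]
#' @export
world_config <- function(shape = c(200, 200),
                         seed = 1,
                         corr_length = 10,
                         beta_true = NULL,
                         gamma_frontier = 9,
                         n_clusters = 25,
                         cluster_radius = 10,
                         delta_expansion = NULL,
                         lambda_frontier = 8,
                         protected_share = 0.05,
                         expansion_noise_scale = 0.3) {
  if (is.null(beta_true)) beta_true <- default_beta_true()
  if (is.null(delta_expansion)) delta_expansion <- default_delta_expansion()
  beta_true <- check_term_vector(beta_true, "beta_true")
  delta_expansion <- check_term_vector(delta_expansion, "delta_expansion")
  stopifnot(length(shape) == 2, all(shape >= 2),
            corr_length >= 1, cluster_radius > 0, n_clusters >= 0,
            gamma_frontier >= 0, lambda_frontier >= 0,
            protected_share >= 0, protected_share <= 1,
            expansion_noise_scale > 0)
  structure(
    list(shape = as.integer(shape), seed = as.integer(seed),
         corr_length = corr_length, beta_true = beta_true,
         gamma_frontier = gamma_frontier, n_clusters = as.integer(n_clusters),
         cluster_radius = cluster_radius, delta_expansion = delta_expansion,
         lambda_frontier = lambda_frontier, protected_share = protected_share,
         expansion_noise_scale = expansion_noise_scale),
    class = "world_config"
  )
}

# intercept + 13 classical-theory terms, logit scale. Strong main effects so
# the classical signal dominates extent; interaction effects deliberately an
# order of magnitude weaker (with sub-sample re-centering, true interaction
# coefficients leak into fitted mains in proportion to the balanced-sample
# mean shift, so weak planted interactions keep main effects identifiable)
default_beta_true <- function() {
  c("(Intercept)" = -7.0,
    suitability = 3.0, access = -2.4, steepness = -1.8,
    pop_density = 1.8, gdp = 1.2,
    "suitability:access" = -0.02, "steepness:access" = -0.02,
    "suitability:pop_density" = 0.02, "steepness:pop_density" = -0.02,
    "gdp:access" = -0.02, "gdp:steepness" = -0.02,
    "gdp:suitability" = -0.02, "gdp:pop_density" = -0.02)
}

# expansion only weakly follows the classical predictors: the planted
# frontier field is meant to carry most of the signal
default_delta_expansion <- function() {
  c("(Intercept)" = -8.5,
    suitability = 0.3, access = -0.2, steepness = -0.3,
    pop_density = 0.2, gdp = -0.2,
    "suitability:access" = 0, "steepness:access" = 0,
    "suitability:pop_density" = 0, "steepness:pop_density" = 0,
    "gdp:access" = 0, "gdp:steepness" = 0,
    "gdp:suitability" = 0, "gdp:pop_density" = 0)
}

check_term_vector <- function(b, what) {
  tmpl <- names(default_beta_true())
  if (is.null(names(b))) {
    if (length(b) != length(tmpl)) {
      stop(what, " must have ", length(tmpl), " entries (intercept + 13 terms)")
    }
    names(b) <- tmpl
  }
  if (!setequal(names(b), tmpl)) {
    stop(what, " must be named with intercept + the 13 classical-theory terms")
  }
  b[tmpl]
}

#' Generate a synthetic gridded world with planted frontier clusters
#'
#' Builds a full synthetic study system: five spatially autocorrelated
#' predictor layers (bioclimatic suitability, steepness, market access,
#' population density, GDP) on plausible skewed supports; a latent frontier
#' intensity field made of Gaussian cluster kernels seeded preferentially at
#' moderate-suitability, remote (high access-distance) cells; a start-year
#' cropland fraction from a logistic link on the classical-theory design plus
#' the frontier boost; an expansion fraction concentrated near the frontier
#' clusters and clipped to the land still available; and water / protected /
#' non-convertible masks. Both fraction processes include a latent
#' standard-logistic disturbance, so the binarized responses follow exact
#' logistic regressions in the planted coefficients.
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`: a list with elements
#'   `predictors` (list of 5 `land_grid`s), `cropland` (`frac_start`,
#'   `frac_end`, `frac_expansion`), `masks` (`suitable`, `water_frac`,
#'   `protected_frac`, `nonconvertible_frac`), `frontier_field`, `available`,
#'   and `config`.
#' @examples
#' w <- generate_world(world_config(shape = c(60, 60), seed = 7))
#' w
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  if (all(cfg$beta_true == 0) && cfg$gamma_frontier == 0) {
    warning("degenerate config: beta_true and gamma_frontier all zero; ",
            "extent is pure noise")
  }
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  # independent sub-seeds per field, all derived from the master seed
  set.seed(cfg$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 12)

  f_suit <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[1]))
  f_steep <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[2]))
  f_acc <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[3]))
  f_pop <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[4]))
  f_gdp <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[5]))
  f_water <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[6]))
  f_prot <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[7]))
  f_nonc <- grid_values(random_field(cfg$shape, cfg$corr_length, sub[8]))

  # plausible supports: suitability truncated at 0 (defines suitable mask),
  # steepness a share in [0,1], the socio-economic layers right-skewed >= 0
  suitability <- pmax(f_suit + 1, 0)
  steepness <- stats::plogis(1.5 * f_steep - 1.5)
  access <- exp(0.5 * f_acc)
  pop_density <- exp(0.6 * f_pop)
  gdp <- exp(0.6 * f_gdp)

  water_frac <- pmin(pmax(f_water - 1.8, 0), 1)
  nonconvertible_frac <- pmin(pmax(0.5 * (f_nonc - 1.5), 0), 1)
  prot_cut <- stats::quantile(f_prot, 1 - cfg$protected_share, names = FALSE)
  protected_frac <- ifelse(cfg$protected_share > 0 & f_prot > prot_cut, 1, 0)
  protected_frac <- matrix(protected_frac, nr, nc)

  all_water <- water_frac >= 1
  suitable <- suitability > 0 & !all_water

  # frontier intensity: Gaussian cluster kernels, zero beyond 4 x radius
  frontier <- plant_frontier_clusters(cfg, suitability, access, suitable, sub[9])

  # classical-theory linear predictor on globally standardized variables
  std <- function(v) as.vector((v - mean(v[suitable])) / stats::sd(v[suitable]))
  s_su <- std(suitability); s_st <- std(steepness); s_ac <- std(access)
  s_po <- std(pop_density); s_gd <- std(gdp)
  X <- cbind(
    1, s_su, s_ac, s_st, s_po, s_gd,
    s_su * s_ac, s_st * s_ac, s_su * s_po, s_st * s_po,
    s_gd * s_ac, s_gd * s_st, s_gd * s_su, s_gd * s_po
  )
  eta_extent <- matrix(X %*% cfg$beta_true, nr, nc)
  eta_expn <- matrix(X %*% cfg$delta_expansion, nr, nc)

  set.seed(sub[10])
  eps_extent <- matrix(stats::rlogis(nr * nc), nr, nc)
  # expansion noise is tighter than the extent noise: the planted frontier
  # process, not chance, should dominate where expansion lands
  set.seed(sub[11])
  eps_expn <- matrix(stats::rlogis(nr * nc, scale = cfg$expansion_noise_scale), nr, nc)

  frac_start <- 0.95 * stats::plogis(eta_extent + cfg$gamma_frontier * frontier +
                                       eps_extent)
  # urban/barren cannot overlap cropland, and protection applies to the land
  # left after both: per-cell fractions always sum to <= 1
  nonconvertible_frac <- pmin(nonconvertible_frac, 1 - frac_start)
  protected_frac <- pmin(protected_frac,
                         pmax(1 - frac_start - nonconvertible_frac, 0))
  available <- pmax(1 - frac_start - nonconvertible_frac - protected_frac, 0)
  frac_expansion <- pmin(
    0.95 * stats::plogis(eta_expn + cfg$lambda_frontier * frontier + eps_expn),
    available
  )
  frac_start[all_water] <- NA_real_
  frac_expansion[all_water] <- NA_real_
  available[all_water] <- NA_real_
  frac_end <- frac_start + frac_expansion

  g <- function(m) land_grid(m)
  structure(
    list(
      predictors = list(
        suitability = g(suitability), steepness = g(steepness),
        access = g(access), pop_density = g(pop_density), gdp = g(gdp)
      ),
      cropland = list(frac_start = g(frac_start), frac_end = g(frac_end),
                      frac_expansion = g(frac_expansion)),
      masks = list(suitable = g(suitable * 1), water_frac = g(water_frac),
                   protected_frac = g(protected_frac),
                   nonconvertible_frac = g(nonconvertible_frac)),
      frontier_field = g(frontier),
      available = g(available),
      config = cfg
    ),
    class = "synthetic_world"
  )
}

plant_frontier_clusters <- function(cfg, suitability, access, suitable, seed) {
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  frontier <- matrix(0, nr, nc)
  if (cfg$n_clusters == 0) return(frontier)
  set.seed(seed)
  cand <- which(suitable)
  # remote frontiers: weight by rank of access distance times rank of
  # closeness to median suitability
  w_suit <- rank(-abs(suitability[cand] - stats::median(suitability[cand])))
  w_acc <- rank(access[cand])
  w <- w_suit * w_acc
  centers <- cand[sample.int(length(cand), min(cfg$n_clusters, length(cand)),
                             prob = w)]
  r <- cfg$cluster_radius
  lim <- ceiling(4 * r)
  off <- -lim:lim
  kern <- exp(-outer(off^2, off^2, "+") / (2 * r^2))
  kern[sqrt(outer(off^2, off^2, "+")) > 4 * r] <- 0
  for (idx in centers) {
    ci <- (idx - 1) %% nr + 1
    cj <- (idx - 1) %/% nr + 1
    ri <- max(1, ci - lim):min(nr, ci + lim)
    rj <- max(1, cj - lim):min(nc, cj + lim)
    frontier[ri, rj] <- frontier[ri, rj] +
      kern[ri - ci + lim + 1, rj - cj + lim + 1]
  }
  frontier
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synthetic_world> %d x %d cells (seed %d)\n",
              cfg$shape[1], cfg$shape[2], cfg$seed))
  sv <- grid_values(x$masks$suitable) > 0
  cat(sprintf("  suitable: %d cells (%.1f%%)   frontier clusters: %d\n",
              sum(sv), 100 * mean(sv), cfg$n_clusters))
  fs <- grid_values(x$cropland$frac_start)
  cat(sprintf("  mean cropland fraction (start): %.3f   mean expansion: %.3f\n",
              mean(fs, na.rm = TRUE),
              mean(grid_values(x$cropland$frac_expansion), na.rm = TRUE)))
  invisible(x)
}

#' Flatten a synthetic world into a pixel table
#'
#' One row per coarse cell with every predictor, cropland fraction, mask and
#' ground-truth column, ready for the modelling functions.
#'
#' @param world A `synthetic_world`.
#' @return A tibble with columns `row`, `col`, the five predictors,
#'   `frac_start`, `frac_end`, `frac_expansion`, `available`, the mask
#'   fractions, logical `suitable`, and the latent `frontier` truth.
#' @export
world_pixels <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  d <- dim(grid_values(world$frontier_field))
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    suitability = as.vector(grid_values(world$predictors$suitability)),
    steepness = as.vector(grid_values(world$predictors$steepness)),
    access = as.vector(grid_values(world$predictors$access)),
    pop_density = as.vector(grid_values(world$predictors$pop_density)),
    gdp = as.vector(grid_values(world$predictors$gdp)),
    frac_start = as.vector(grid_values(world$cropland$frac_start)),
    frac_end = as.vector(grid_values(world$cropland$frac_end)),
    frac_expansion = as.vector(grid_values(world$cropland$frac_expansion)),
    available = as.vector(grid_values(world$available)),
    water_frac = as.vector(grid_values(world$masks$water_frac)),
    protected_frac = as.vector(grid_values(world$masks$protected_frac)),
    nonconvertible_frac = as.vector(grid_values(world$masks$nonconvertible_frac)),
    suitable = as.vector(grid_values(world$masks$suitable)) > 0,
    frontier = as.vector(grid_values(world$frontier_field))
  )
}

#' Downscale a world to a fine classified grid
#'
#' Expands each coarse cell into a `pixels_per_side` x `pixels_per_side`
#' block of land-cover class labels (`"cropland"`, `"other"`, `"water"`,
#' `"urban"`), allocating counts so the block reproduces the coarse water
#' fraction and — over its non-water cells — the coarse cropland fraction to
#' within one fine cell. With `year = "end"` the block additionally converts
#' `frac_expansion` worth of `"other"` cells to cropland, so aggregating the
#' start/end pair recovers the coarse expansion fraction.
#'
#' @param world A `synthetic_world`.
#' @param pixels_per_side Fine cells per coarse-cell edge (>= 2).
#' @param year `"start"` or `"end"`.
#' @return A character matrix of fine class labels with
#'   `nrow(world) * pixels_per_side` rows.
#' @export
fine_scale_sample <- function(world, pixels_per_side = 4,
                              year = c("start", "end")) {
  stopifnot(inherits(world, "synthetic_world"), pixels_per_side >= 2)
  year <- match.arg(year)
  k <- as.integer(pixels_per_side)
  fs <- grid_values(world$cropland$frac_start)
  fe <- grid_values(world$cropland$frac_expansion)
  wf <- grid_values(world$masks$water_frac)
  uf <- grid_values(world$masks$nonconvertible_frac)
  nr <- nrow(fs); nc <- ncol(fs)
  fine <- matrix("other", nr * k, nc * k)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cells <- rep("other", k * k)
      n_water <- if (is.na(fs[i, j])) k * k else round(wf[i, j] * k * k)
      n_land <- k * k - n_water
      n_crop <- if (n_land > 0) round(fs[i, j] * n_land) else 0
      n_new <- if (year == "end" && n_land > 0) round(fe[i, j] * n_land) else 0
      n_urban <- if (n_land > 0) {
        min(round(uf[i, j] * n_land), n_land - n_crop - n_new)
      } else 0
      pos <- 1L
      fill <- function(lab, n) {
        if (n > 0) cells[pos:(pos + n - 1)] <<- lab
        pos <<- pos + n
      }
      fill("water", n_water)
      fill("cropland", n_crop + n_new)
      fill("urban", max(0, n_urban))
      fine[(i - 1) * k + seq_len(k), (j - 1) * k + seq_len(k)] <-
        matrix(cells, k, k)
    }
  }
  fine
}
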