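model_variables <- c("suitability", "access", "steepness", "pop_density",
                     "gdp", "cropland_start")

#' Assemble the analysis datasets for one cropland threshold
#'
#' Runs the full data-preparation chain for a threshold `tau`: derive the
#' extent and expansion domains, globally standardize every model variable
#' over the suitable-pixel set, binarize extent and expansion, fit the
#' global null model, attach the frontierness score (standardized over the
#' extent domain, like every other predictor), and return modelling-ready
#' tibbles. Frontierness is computed once here and reused downstream as a
#' fixed covariate — never recomputed inside sub-samples.
#'
#' @param world A `synthetic_world` (or any object accepted by
#'   [world_pixels()] plus `cropland`/`masks` layers).
#' @param tau Cropland threshold in (0, 1).
#' @param boundary Binarization boundary rule, see [binarize()].
#' @return A list of class `threshold_data`: `tau`; `extent` (tibble over
#'   the extent domain: standardized predictors, `y`); `expansion` (tibble
#'   over the expansion domain: standardized predictors, `cropland_start`,
#'   `frontierness`, `y`); `null_fit`; `frontierness` (the
#'   `frontierness_grid` over the extent domain); `domains`
#'   (`analysis_domain`); `std_stats`.
#' @export
prepare_analysis <- function(world, tau, boundary = "strict") {
  stopifnot(inherits(world, "synthetic_world"))
  px <- world_pixels(world)
  px$cropland_start <- px$frac_start
  dom <- expansion_domain(world$cropland$frac_start, world$masks, tau)
  ext_dom <- as.vector(dom$extent_domain)
  exp_dom <- as.vector(dom$expansion_domain)

  std <- standardize_predictors(px, model_variables, domain = ext_dom)
  dat <- std$data

  extent <- dat[ext_dom, ]
  extent$y <- as.numeric(binarize(extent$frac_start, tau, boundary))

  nf <- fit_null(extent, response = "y")
  fg <- frontierness_score(nf)

  # frontierness standardized over the extent domain like the other predictors
  fz <- (fg$z - mean(fg$z)) / stats::sd(fg$z)
  extent$frontierness <- fz

  expansion <- extent[exp_dom[ext_dom], ]
  expansion$y <- as.numeric(binarize(expansion$frac_expansion, tau, boundary))

  structure(
    list(tau = tau, extent = extent, expansion = expansion,
         null_fit = nf, frontierness = fg, domains = dom,
         std_stats = std$stats),
    class = "threshold_data"
  )
}

#' @export
print.threshold_data <- function(x, ...) {
  cat(sprintf(
    "<threshold_data> tau = %g: %d extent pixels (%d presence), %d expansion pixels (%d presence)\n",
    x$tau, nrow(x$extent), sum(x$extent$y), nrow(x$expansion),
    sum(x$expansion$y)))
  invisible(x)
}
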