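#' Aggregate a fine classified grid to coarse cropland fractions
#'
#' For each `block_size` x `block_size` block of fine cells, computes the
#' share of non-water cells classified as cropland. Blocks that are entirely
#' water become nodata. Optionally a separate fine water mask overrides the
#' `"water"` labels in the class grid.
#'
#' @param fine_class Character matrix of fine class labels (as produced by
#'   [fine_scale_sample()]), or any matrix whose cells equal `"cropland"` /
#'   `"water"` / other labels.
#' @param block_size Fine cells per coarse-cell edge; must divide both
#'   dimensions of `fine_class`.
#' @param water_mask_fine Optional logical matrix, `TRUE` = water.
#' @param mosaic_as_cropland If `TRUE`, cells labelled `"mosaic"` also count
#'   as cropland (sensitivity mode); default excludes them.
#' @return A `land_grid` of cropland fractions in `[0, 1]`.
#' @export
aggregate_fraction <- function(fine_class, block_size, water_mask_fine = NULL,
                               mosaic_as_cropland = FALSE) {
  check_blocks(dim(fine_class), block_size)
  if (is.null(water_mask_fine)) {
    water_mask_fine <- fine_class == "water"
  } else if (!all(dim(water_mask_fine) == dim(fine_class))) {
    stop("alignment error: water_mask_fine shape differs from fine_class")
  }
  crop_labels <- if (mosaic_as_cropland) c("cropland", "mosaic") else "cropland"
  is_crop <- matrix(fine_class %in% crop_labels, nrow(fine_class)) &
    !water_mask_fine
  n_crop <- block_sum(is_crop, block_size)
  n_land <- block_sum(!water_mask_fine, block_size)
  frac <- ifelse(n_land > 0, n_crop / n_land, NA_real_)
  land_grid(frac)
}

#' Coarse expansion fraction from fine start/end class grids
#'
#' Expansion counts fine cells classified as cropland at the end date but not
#' at the start date; cells leaving cropland do not offset it. The fraction
#' is taken over non-water fine cells per block.
#'
#' @inheritParams aggregate_fraction
#' @param fine_start,fine_end Aligned fine class matrices for the two dates.
#' @return A `land_grid` of expansion fractions in `[0, 1]`.
#' @export
expansion_fraction <- function(fine_start, fine_end, block_size,
                               water_mask_fine = NULL,
                               mosaic_as_cropland = FALSE) {
  if (!all(dim(fine_start) == dim(fine_end))) {
    stop("alignment error: fine_start and fine_end have different shapes")
  }
  check_blocks(dim(fine_start), block_size)
  if (is.null(water_mask_fine)) {
    water_mask_fine <- fine_start == "water" | fine_end == "water"
  }
  crop_labels <- if (mosaic_as_cropland) c("cropland", "mosaic") else "cropland"
  gained <- matrix(fine_end %in% crop_labels & !(fine_start %in% crop_labels),
                   nrow(fine_start)) & !water_mask_fine
  n_new <- block_sum(gained, block_size)
  n_land <- block_sum(!water_mask_fine, block_size)
  frac <- ifelse(n_land > 0, n_new / n_land, NA_real_)
  land_grid(frac)
}

check_blocks <- function(d, block_size) {
  if (block_size < 1 || any(d %% block_size != 0)) {
    stop(sprintf("alignment error: %dx%d fine grid not divisible by block size %d",
                 d[1], d[2], block_size))
  }
}

block_sum <- function(m, k) {
  nr <- nrow(m) %/% k
  nc <- ncol(m) %/% k
  storage.mode(m) <- "double"
  # sum k x k blocks via two grouped row sums
  byrow <- rowsum(m, rep(seq_len(nr), each = k))
  t(rowsum(t(byrow), rep(seq_len(nc), each = k)))
}

#' Binarize a fraction layer at a cropland threshold
#'
#' @param frac A `land_grid` or numeric vector of fractions in `[0, 1]`.
#' @param tau Threshold in (0, 1); the study's defaults are 0.005, 0.10, 0.50.
#' @param boundary `"strict"` (`> tau`, the default) or `"inclusive"`
#'   (`>= tau`).
#' @return Same container as `frac`, logical values; nodata propagates as `NA`.
#' @export
binarize <- function(frac, tau, boundary = c("strict", "inclusive")) {
  boundary <- match.arg(boundary)
  stopifnot(tau > 0, tau < 1)
  f <- if (inherits(frac, "land_grid")) grid_values(frac) else frac
  b <- if (boundary == "strict") f > tau else f >= tau
  if (inherits(frac, "land_grid")) grid_like(frac, b) else b
}

#' Bioclimatic suitability mask
#'
#' Cells are retained when minimally bioclimatically suitable, i.e. strictly
#' positive suitability; nodata cells are excluded.
#'
#' @param suitability A `land_grid` or numeric vector of suitability values.
#' @return Logical values in the same container (`NA` treated as unsuitable).
#' @export
suitable_mask <- function(suitability) {
  s <- if (inherits(suitability, "land_grid")) grid_values(suitability) else suitability
  m <- !is.na(s) & s > 0
  if (inherits(suitability, "land_grid")) grid_like(suitability, m) else m
}

#' Analysis domains for extent and expansion models
#'
#' The extent domain is the set of bioclimatically suitable cells. The
#' expansion domain additionally requires enough land left for conversion:
#' available fraction = 1 - cropland(start) - non-convertible - protected
#' (clipped at zero; water is already outside the fraction denominators),
#' and the cell is kept when available >= `tau`.
#'
#' @param frac_start `land_grid` of start-year cropland fractions.
#' @param masks List with `land_grid`s `suitable` (or a suitability layer),
#'   `protected_frac`, `nonconvertible_frac` — e.g. `world$masks`.
#' @param tau Expansion threshold in (0, 1).
#' @return List of class `analysis_domain` with logical matrices
#'   `extent_domain`, `expansion_domain`, and the numeric `available` matrix.
#' @export
expansion_domain <- function(frac_start, masks, tau) {
  stopifnot(tau > 0, tau < 1)
  assert_aligned(list(frac_start = frac_start,
                      protected = masks$protected_frac,
                      nonconvertible = masks$nonconvertible_frac))
  fs <- grid_values(frac_start)
  pf <- grid_values(masks$protected_frac)
  nf <- grid_values(masks$nonconvertible_frac)
  suit <- grid_values(masks$suitable) > 0 & !is.na(grid_values(masks$suitable))
  avail <- 1 - fs - nf - pf
  n_neg <- sum(avail < -1e-6, na.rm = TRUE)
  if (n_neg > 0) {
    warning(sprintf(
      "clipping %d cell(s) where cropland + protected + non-convertible exceed the cell",
      n_neg))
  }
  avail <- pmax(avail, 0)
  ext <- suit & !is.na(fs)
  exp_dom <- ext & !is.na(avail) & avail >= tau
  structure(list(extent_domain = ext, expansion_domain = exp_dom,
                 available = avail),
            class = "analysis_domain")
}
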