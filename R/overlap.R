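#' Proportional overlap ratio
#'
#' The share of a nonnegative value raster's total that falls inside a
#' selection, divided by the selection's share of the domain area:
#' \deqn{r = \frac{\sum_{sel} v / \sum_{dom} v}{|sel| / |dom|}.}
#' Ratios above 1 indicate over-representation of the value inside the
#' selection, below 1 under-representation; a value uniform over the domain
#' gives exactly 1 for any selection.
#'
#' @param value Nonnegative numeric vector (or `land_grid`) of pixel values.
#' @param selection Logical vector/grid, `TRUE` inside the selection; must
#'   lie within the domain.
#' @param domain Logical vector/grid delimiting the analysis domain.
#' @return A single ratio >= 0; an empty selection or an all-zero value
#'   raster is an error (render as `NA` in tables upstream).
#' @export
overlap_ratio <- function(value, selection, domain) {
  v <- if (inherits(value, "land_grid")) as.vector(grid_values(value)) else as.numeric(value)
  s <- as.logical(if (inherits(selection, "land_grid")) grid_values(selection) else selection)
  d <- as.logical(if (inherits(domain, "land_grid")) grid_values(domain) else domain)
  stopifnot(length(v) == length(s), length(s) == length(d))
  s[is.na(s)] <- FALSE; d[is.na(d)] <- FALSE
  if (any(s & !d)) stop("selection extends outside the domain")
  if (any(v[d] < 0, na.rm = TRUE)) stop("value raster must be nonnegative on the domain")
  n_dom <- sum(d)
  n_sel <- sum(s)
  tot <- sum(v[d], na.rm = TRUE)
  if (n_sel == 0) stop("undefined ratio: empty selection")
  if (!is.finite(tot) || tot <= 0) stop("undefined ratio: zero total value over domain")
  (sum(v[s], na.rm = TRUE) / tot) / (n_sel / n_dom)
}

#' Table of deviance-class / expansion overlap ratios
#'
#' For each deviance class (`pos2`, `pos1`, `neg2`, `neg1`) and each
#' expansion threshold, computes the proportional overlap of the class with
#' the binarized expansion map. In the default `"magnitude"` mode the class
#' value raster is `|z|` restricted to the class (so stronger deviations
#' weigh more, matching a summed-total-value reading); `"area"` mode uses a
#' 0/1 indicator instead. Pairs are matched by threshold: the class layer at
#' a given tau is only compared with expansion binarized at that same tau.
#'
#' @param fg_by_tau Named list (names = thresholds as character) of
#'   `frontierness_grid` tibbles, each with `row`/`col`.
#' @param expansion_by_tau Named list (same names) of binarized expansion
#'   selections: logical vectors aligned with the matching domain vector.
#' @param domain_by_tau Named list (same names) of logical domain vectors
#'   (the extent domain of the matched null model), aligned row-for-row with
#'   the corresponding `frontierness_grid`.
#' @param mode `"magnitude"` (default) or `"area"`.
#' @return A tibble of class `overlap_table`: `class`, one column per
#'   threshold; undefined cells are `NA`.
#' @export
overlap_table <- function(fg_by_tau, expansion_by_tau, domain_by_tau,
                          mode = c("magnitude", "area")) {
  mode <- match.arg(mode)
  taus <- names(fg_by_tau)
  stopifnot(!is.null(taus), setequal(taus, names(expansion_by_tau)),
            setequal(taus, names(domain_by_tau)))
  classes <- c("pos2", "pos1", "neg2", "neg1")
  out <- tibble::tibble(class = classes)
  for (tau in taus) {
    fg <- fg_by_tau[[tau]]
    sel <- as.logical(expansion_by_tau[[tau]])
    dom <- as.logical(domain_by_tau[[tau]])
    stopifnot(nrow(fg) == length(dom), length(sel) == length(dom))
    col <- vapply(classes, function(cl) {
      inside <- fg$class == cl
      value <- if (mode == "magnitude") abs(fg$z) * inside else as.numeric(inside)
      tryCatch(overlap_ratio(value, sel & dom, dom), error = function(e) NA_real_)
    }, numeric(1))
    out[[tau]] <- unname(col)
  }
  class(out) <- c("overlap_table", class(out))
  out
}

#' Post-hoc overlay enrichment
#'
#' Generic enrichment of an arbitrary nonnegative overlay raster (e.g. field
#' size, soil constraints, development indicators) against one or more
#' selections (deviance classes, expansion maps).
#'
#' @param overlay Nonnegative numeric vector/`land_grid` aligned with the
#'   domain.
#' @param selections Named list of logical selections.
#' @param domain Logical domain vector/grid.
#' @return A tibble: `selection`, `ratio` (`NA` where undefined).
#' @export
posthoc_overlay <- function(overlay, selections, domain) {
  stopifnot(is.list(selections), !is.null(names(selections)))
  ratios <- vapply(selections, function(sel) {
    tryCatch(overlap_ratio(overlay, sel, domain), error = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(selection = names(selections), ratio = unname(ratios))
}
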