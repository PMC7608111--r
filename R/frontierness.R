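#' Fit the global null model of cropland extent
#'
#' A single logistic regression of binarized start-year cropland extent on
#' the classical-theory term set (X1), fit on *all* suitable pixels — no
#' sub-sampling, no re-centering beyond the global standardization. Its
#' response-scale residuals are the raw material of the frontierness score.
#'
#' @param data Data frame over the extent domain with globally standardized
#'   predictors and the binary response.
#' @param response Name of the binary extent column (default `"y"`).
#' @return Object of class `null_fit`: the `logit_fit`, plus `p_hat`,
#'   `residual` (`y - p_hat`), `residual_sd`, and any `row`/`col` columns
#'   carried through from `data`.
#' @export
fit_null <- function(data, response = "y") {
  if (!response %in% names(data)) stop("response column '", response, "' not found")
  y <- as.numeric(data[[response]])
  if (length(unique(y)) < 2) stop("degenerate response: only one class in domain")
  spec <- model_terms("null")
  X <- build_design(data, spec, recenter = FALSE)
  fit <- fit_logistic(X, y)
  resid <- y - fit$fitted
  structure(
    list(fit = fit, p_hat = fit$fitted, residual = resid,
         residual_sd = stats::sd(resid),
         row = data[["row"]], col = data[["col"]]),
    class = "null_fit"
  )
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit> %d pixels, McFadden R2 %.3f, residual SD %.3f\n",
              x$fit$n_obs, mcfadden(x$fit), x$residual_sd))
  invisible(x)
}

#' Frontierness score and deviance classes
#'
#' Standardizes the null model's response residuals by their domain standard
#' deviation (`z = (y - p_hat) / sd`) and classifies each pixel into
#' positive/negative deviance classes: `pos2` (`z >= 2`), `pos1`
#' (`1 <= z < 2`), `neg1` (`-2 < z <= -1`), `neg2` (`z <= -2`), otherwise
#' `neutral`. Positive classes are "bright spots" — more cropland than the
#' classical predictors explain; negative classes the converse.
#'
#' @param null_fit A [fit_null()] result.
#' @return A tibble of class `frontierness_grid` with columns `row`, `col`
#'   (if available), `z`, and `class` (factor, levels
#'   `neg2 < neg1 < neutral < pos1 < pos2`).
#' @export
frontierness_score <- function(null_fit) {
  stopifnot(inherits(null_fit, "null_fit"))
  if (!is.finite(null_fit$residual_sd) || null_fit$residual_sd <= 0) {
    stop("degenerate model: residual SD is zero")
  }
  z <- null_fit$residual / null_fit$residual_sd
  cls <- dplyr::case_when(
    z >= 2 ~ "pos2",
    z >= 1 ~ "pos1",
    z <= -2 ~ "neg2",
    z <= -1 ~ "neg1",
    TRUE ~ "neutral"
  )
  out <- tibble::tibble(
    z = z,
    class = factor(cls, levels = c("neg2", "neg1", "neutral", "pos1", "pos2"))
  )
  if (!is.null(null_fit$row)) out <- tibble::add_column(
    out, row = null_fit$row, col = null_fit$col, .before = 1)
  class(out) <- c("frontierness_grid", class(out))
  out
}

#' Export frontierness rasters and class summary
#'
#' Writes the z score and the deviance classes as plain-text ASCII grids
#' (classes coded -2, -1, 0, 1, 2) plus a CSV of class pixel counts.
#'
#' @param fg A `frontierness_grid` with `row`/`col` columns.
#' @param shape `c(nrows, ncols)` of the full lattice.
#' @param prefix Output path prefix; writes `<prefix>_z.asc`,
#'   `<prefix>_classes.asc`, `<prefix>_classes.csv`.
#' @return Invisibly, the three paths written.
#' @export
export_frontierness <- function(fg, shape, prefix) {
  stopifnot(inherits(fg, "frontierness_grid"),
            all(c("row", "col") %in% names(fg)))
  zm <- matrix(NA_real_, shape[1], shape[2])
  cm <- matrix(NA_real_, shape[1], shape[2])
  idx <- cbind(fg$row, fg$col)
  zm[idx] <- fg$z
  code <- c(neg2 = -2, neg1 = -1, neutral = 0, pos1 = 1, pos2 = 2)
  cm[idx] <- code[as.character(fg$class)]
  paths <- paste0(prefix, c("_z.asc", "_classes.asc", "_classes.csv"))
  write_grid(land_grid(zm), paths[1])
  write_grid(land_grid(cm), paths[2])
  counts <- dplyr::count(tibble::as_tibble(fg), .data$class, name = "n_pixels")
  utils::write.csv(counts, paths[3], row.names = FALSE)
  invisible(paths)
}
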