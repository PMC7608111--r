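#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient distributions of a balanced-subsample ensemble
#'
#' Boxplots of per-replicate coefficient estimates across terms, the
#' standard way to eyeball which predictors carry signal and how stable they
#' are across sub-samples.
#'
#' @param object A `logit_ensemble`.
#' @param intercept Include the intercept column.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.logit_ensemble <- function(object, intercept = FALSE, ...) {
  b <- object$beta[object$converged, , drop = FALSE]
  df <- tidyr::pivot_longer(tibble::as_tibble(b), dplyr::everything(),
                            names_to = "term", values_to = "estimate")
  if (!intercept) df <- dplyr::filter(df, .data$term != "(Intercept)")
  df$term <- factor(df$term, levels = colnames(object$beta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "coefficient (logit scale)",
                  title = sprintf("%s: %d balanced sub-samples",
                                  object$spec$name, sum(object$converged))) +
    ggplot2::theme_minimal()
}

#' Map of the frontierness score
#'
#' @param object A `frontierness_grid` with `row`/`col` columns.
#' @param what `"z"` for the continuous score, `"class"` for deviance
#'   classes.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.frontierness_grid <- function(object, what = c("z", "class"), ...) {
  what <- match.arg(what)
  stopifnot(all(c("row", "col") %in% names(object)))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (what == "z") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
      ggplot2::scale_fill_gradient2(low = "#313695", mid = "grey95",
                                    high = "#a50026", name = "frontierness z")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
      ggplot2::scale_fill_manual(
        values = c(neg2 = "#313695", neg1 = "#74add1", neutral = "grey92",
                   pos1 = "#f46d43", pos2 = "#a50026"),
        name = "deviance class")
  }
}

#' Pseudo-R2 comparison of expansion models with and without frontierness
#'
#' @param object An `expansion_comparison` table.
#' @param ... Ignored.
#' @return A ggplot object (dodged bars per threshold).
#' @export
autoplot.expansion_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "tau", "model2_mean_r2",
                  "model3_mean_r2"),
    -"tau", names_to = "model", values_to = "mean_r2")
  df$model <- ifelse(df$model == "model2_mean_r2",
                     "existing predictors", "+ frontierness")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$tau), y = .data$mean_r2,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cropland threshold", y = "mean McFadden pseudo-R2",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
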