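x1_mains <- c("suitability", "access", "steepness", "pop_density", "gdp")
x1_interactions <- list(
  c("suitability", "access"), c("steepness", "access"),
  c("suitability", "pop_density"), c("steepness", "pop_density"),
  c("gdp", "access"), c("gdp", "steepness"),
  c("gdp", "suitability"), c("gdp", "pop_density")
)
x2_mains <- "cropland_start"
x2_interactions <- list(
  c("cropland_start", "suitability"), c("cropland_start", "access"),
  c("cropland_start", "steepness"), c("cropland_start", "pop_density"),
  c("cropland_start", "gdp")
)
x3_mains <- "frontierness"
x3_interactions <- list(c("frontierness", "cropland_start"))

#' Declarative model term sets
#'
#' Returns the ordered term list of one of the four study models, built from
#' three theory-driven blocks:
#' \describe{
#'   \item{X1}{the five classical land-rent / location-theory predictors
#'     (bioclimatic suitability, market access, steepness, population
#'     density, GDP) plus eight pairwise interactions — 13 terms;}
#'   \item{X2}{start-year cropland fraction and its interactions with the
#'     five X1 mains — 6 terms;}
#'   \item{X3}{frontierness and its interaction with start-year cropland —
#'     2 terms.}
#' }
#' `model1` and `null` use X1 (the null model is fit globally, model 1 on
#' balanced sub-samples); `model2` = X1 + X2; `model3` = X1 + X2 + X3. An
#' intercept is always prepended by [build_design()].
#'
#' @param name One of `"model1"`, `"null"`, `"model2"`, `"model3"`.
#' @return An object of class `model_spec` with elements `name`, `mains`
#'   (character), `interactions` (list of character pairs), and `terms`
#'   (the full ordered term labels, `a:b` for products).
#' @export
model_terms <- function(name = c("model1", "null", "model2", "model3")) {
  name <- match.arg(name)
  mains <- x1_mains
  inters <- x1_interactions
  if (name %in% c("model2", "model3")) {
    mains <- c(mains, x2_mains)
    inters <- c(inters, x2_interactions)
  }
  if (name == "model3") {
    mains <- c(mains, x3_mains)
    inters <- c(inters, x3_interactions)
  }
  structure(
    list(name = name, mains = mains, interactions = inters,
         terms = c(mains, vapply(inters, paste, "", collapse = ":"))),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d terms (+ intercept)\n", x$name,
              length(x$terms)))
  cat(" ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Globally standardize model variables over a domain
#'
#' Centers and scales each variable to mean 0, SD 1 computed over the rows
#' flagged by `domain` (the suitable-pixel set); rows outside the domain are
#' transformed with the same statistics so any subset remains comparable.
#'
#' @param data A data frame of pixel rows.
#' @param vars Character vector of columns to standardize.
#' @param domain Logical vector over rows (default: all rows).
#' @return A list with `data` (tibble, standardized columns) and `stats`
#'   (tibble: `variable`, `mean`, `sd`).
#' @export
standardize_predictors <- function(data, vars, domain = NULL) {
  if (is.null(domain)) domain <- rep(TRUE, nrow(data))
  stopifnot(length(domain) == nrow(data))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variables not in data: ", paste(missing_vars, collapse = ", "))
  }
  out <- tibble::as_tibble(data)
  stats_tbl <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]][domain]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate variable '", v, "': zero variance over the domain")
    }
    tibble::tibble(variable = v, mean = m, sd = s)
  })
  for (i in seq_len(nrow(stats_tbl))) {
    v <- stats_tbl$variable[i]
    out[[v]] <- (data[[v]] - stats_tbl$mean[i]) / stats_tbl$sd[i]
  }
  list(data = out, stats = stats_tbl)
}

#' Build a design matrix for a model spec
#'
#' Column 0 is the intercept; then the main effects, then interaction
#' columns formed as products of the mains. With `recenter = TRUE`
#' (recommended for interaction models fit on sub-samples) every main-effect
#' column has its within-sample mean subtracted *before* the products are
#' formed; columns are never re-scaled.
#'
#' @param data Data frame containing every variable the spec references.
#' @param spec A [model_terms()] object.
#' @param recenter Subtract sub-sample means from mains before products.
#' @return Numeric matrix, `1 + length(spec$terms)` columns, named
#'   `(Intercept)` plus the term labels.
#' @export
build_design <- function(data, spec, recenter = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  missing_vars <- setdiff(spec$mains, names(data))
  if (length(missing_vars)) {
    stop("model spec '", spec$name, "' needs missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  mains <- lapply(spec$mains, function(v) as.numeric(data[[v]]))
  names(mains) <- spec$mains
  if (recenter) mains <- lapply(mains, function(x) x - mean(x))
  inter_cols <- lapply(spec$interactions, function(pr) {
    mains[[pr[1]]] * mains[[pr[2]]]
  })
  X <- cbind(1, do.call(cbind, mains), do.call(cbind, inter_cols))
  colnames(X) <- c("(Intercept)", spec$terms)
  X
}

#' Fit a logistic regression by maximum likelihood
#'
#' Fits a Bernoulli GLM with logit link via iteratively reweighted least
#' squares and reports the fitted log-likelihood alongside the intercept-only
#' log-likelihood, the pair behind McFadden's pseudo-R². Complete or
#' quasi-complete separation is flagged (`converged = FALSE`) when fitted
#' coefficients diverge.
#'
#' @param X Design matrix including its intercept column.
#' @param y Binary response (0/1 or logical), both classes present.
#' @return Object of class `logit_fit`: `beta` (named), `loglik`,
#'   `loglik_null`, `fitted`, `converged`, `n_obs`.
#' @examples
#' x <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
#' y <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
#' fit <- fit_logistic(cbind(1, x), y)
#' fit$beta  # slope log(16), intercept log(1/4)
#' @export
fit_logistic <- function(X, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2) {
    stop("degenerate response: only one class present")
  }
  if (nrow(X) <= ncol(X)) stop("need more observations than design columns")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  names(beta) <- colnames(X)
  # aliased (rank-deficient) columns contribute nothing; report them as 0
  beta[is.na(beta)] <- 0
  p <- fit$fitted.values
  ll <- sum(stats::dbinom(y, 1, p, log = TRUE))
  pbar <- mean(y)
  ll0 <- sum(y) * log(pbar) + sum(1 - y) * log1p(-pbar)
  separated <- any(!is.finite(beta)) || max(abs(beta)) > 25
  converged <- isTRUE(fit$converged) && !separated
  if (separated) {
    warning("possible complete separation: coefficient estimates diverging")
  }
  structure(
    list(beta = beta, loglik = ll, loglik_null = ll0, fitted = p,
         converged = converged, n_obs = length(y)),
    class = "logit_fit"
  )
}

#' McFadden pseudo-R-squared
#'
#' `1 - loglik / loglik_null` for a fitted binary-response likelihood; 0 for
#' an intercept-only fit, approaching 1 for a near-perfect classifier.
#'
#' @param fit A `logit_fit` (or any list with `loglik` and `loglik_null`).
#' @return A scalar in `[0, 1)`.
#' @export
mcfadden <- function(fit) {
  if (!is.finite(fit$loglik_null) || fit$loglik_null >= 0) {
    stop("degenerate response: null log-likelihood must be negative")
  }
  1 - fit$loglik / fit$loglik_null
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, %d terms, logLik %.2f, McFadden R2 %.3f%s\n",
              x$n_obs, length(x$beta) - 1, x$loglik, mcfadden(x),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.logit_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @export
glance.logit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, logLik_null = x$loglik_null,
    mcfadden = mcfadden(x), nobs = x$n_obs, converged = x$converged
  )
}
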