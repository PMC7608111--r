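#' Configuration of a balanced-subsample ensemble
#'
#' @param n_replicates Number of balanced sub-samples to fit (the study
#'   design uses 10,000 for the extent/expansion comparison and 1,000 for the
#'   with/without-frontierness comparison; the package default of 200 keeps
#'   synthetic-world runs fast and is configurable up to those counts).
#' @param n_presence,n_absence Presences / absences per sub-sample (500/500
#'   in the study design).
#' @param seed Integer master seed; each replicate's RNG stream is derived
#'   from `(seed, replicate_index)`, so replicates are order-independent.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_replicates = 200, n_presence = 500,
                            n_absence = 500, seed = 1) {
  stopifnot(n_replicates >= 1, n_presence >= 1, n_absence >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 n_presence = as.integer(n_presence),
                 n_absence = as.integer(n_absence),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# deterministic stream seed from (master seed, replicate); keeps the value
# inside 32-bit range for set.seed()
replicate_seed <- function(seed, replicate_index) {
  as.integer((as.double(seed) * 48271 + as.double(replicate_index) * 69621) %%
               2147483563) + 1L
}

#' Draw one balanced presence/absence sub-sample
#'
#' Samples exactly `n_presence` indices with `y == 1` and `n_absence` with
#' `y == 0`, without replacement within the replicate, deterministically from
#' `(cfg$seed, replicate_index)` and independently across replicates.
#'
#' @param y Binary vector over the analysis domain.
#' @param cfg An [ensemble_config()].
#' @param replicate_index 1-based replicate number.
#' @return Integer vector of row indices (presences first).
#' @export
balanced_sample <- function(y, cfg, replicate_index = 1) {
  stopifnot(inherits(cfg, "ensemble_config"))
  pres <- which(y == 1)
  abs_ <- which(y == 0)
  if (length(pres) < cfg$n_presence || length(abs_) < cfg$n_absence) {
    stop(sprintf(
      "pool error: need %d presences and %d absences, pool has %d and %d",
      cfg$n_presence, cfg$n_absence, length(pres), length(abs_)))
  }
  set.seed(replicate_seed(cfg$seed, replicate_index))
  c(pres[sample.int(length(pres), cfg$n_presence)],
    abs_[sample.int(length(abs_), cfg$n_absence)])
}

#' Fit a balanced-subsample logistic ensemble
#'
#' Repeats, for each replicate: draw a balanced presence/absence sub-sample,
#' re-center the main-effect columns within the sub-sample, rebuild the
#' interaction columns, fit the logistic regression, and record coefficients
#' and McFadden pseudo-R². Non-converged replicates are kept in the raw
#' store but excluded from summaries.
#'
#' @param data Data frame over the analysis domain with globally
#'   standardized model variables and the binary response.
#' @param spec A [model_terms()] object.
#' @param cfg An [ensemble_config()].
#' @param response Name of the binary response column (default `"y"`).
#' @return Object of class `logit_ensemble`: `beta` (replicates x columns
#'   matrix), `r2`, `loglik`, `converged`, `spec`, `cfg`, `response`.
#' @export
run_ensemble <- function(data, spec, cfg, response = "y") {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "ensemble_config"))
  if (!response %in% names(data)) stop("response column '", response, "' not found")
  y <- as.numeric(data[[response]])
  n_col <- 1 + length(spec$terms)
  betas <- matrix(NA_real_, cfg$n_replicates, n_col)
  r2 <- ll <- rep(NA_real_, cfg$n_replicates)
  conv <- rep(FALSE, cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    idx <- balanced_sample(y, cfg, r)
    sub <- data[idx, , drop = FALSE]
    X <- build_design(sub, spec, recenter = TRUE)
    fit <- withCallingHandlers(
      fit_logistic(X, y[idx]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    betas[r, ] <- fit$beta
    r2[r] <- mcfadden(fit)
    ll[r] <- fit$loglik
    conv[r] <- fit$converged
  }
  colnames(betas) <- c("(Intercept)", spec$terms)
  if (mean(conv) < 0.9) {
    warning(sprintf("ensemble warning: %d of %d replicates failed to converge",
                    sum(!conv), cfg$n_replicates))
  }
  structure(list(beta = betas, r2 = r2, loglik = ll, converged = conv,
                 spec = spec, cfg = cfg, response = response),
            class = "logit_ensemble")
}

#' @export
print.logit_ensemble <- function(x, ...) {
  cat(sprintf(
    "<logit_ensemble> %s, %d replicates (%d converged), mean McFadden R2 %.3f\n",
    x$spec$name, x$cfg$n_replicates, sum(x$converged),
    mean(x$r2[x$converged])))
  invisible(x)
}

#' @export
tidy.logit_ensemble <- function(x, ...) {
  keep <- x$converged
  if (!any(keep)) stop("ensemble error: no converged replicates to summarize")
  b <- x$beta[keep, , drop = FALSE]
  tibble::tibble(
    term = colnames(b),
    estimate = unname(colMeans(b)),
    conf.low = unname(apply(b, 2, stats::quantile, 0.025, names = FALSE)),
    conf.high = unname(apply(b, 2, stats::quantile, 0.975, names = FALSE))
  )
}

#' @export
glance.logit_ensemble <- function(x, ...) {
  keep <- x$converged
  tibble::tibble(
    model = x$spec$name,
    mean_mcfadden = mean(x$r2[keep]),
    n_replicates = x$cfg$n_replicates,
    n_converged = sum(keep),
    n_presence = x$cfg$n_presence,
    n_absence = x$cfg$n_absence,
    seed = x$cfg$seed
  )
}

#' Summarize an ensemble: coefficient table plus mean pseudo-R-squared
#'
#' @param result A `logit_ensemble`.
#' @return A list with `coefficients` (the [tidy()] table: mean and empirical
#'   2.5/97.5 percentile interval per term over converged replicates) and
#'   `mean_mcfadden`.
#' @export
summarize_ensemble <- function(result) {
  stopifnot(inherits(result, "logit_ensemble"))
  list(coefficients = tidy(result),
       mean_mcfadden = mean(result$r2[result$converged]))
}
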