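#' Compare expansion models with and without frontierness
#'
#' For each expansion threshold, fits two balanced-subsample ensembles on the
#' same expansion response over the same domain: the state-of-the-art model
#' (X1 + X2: classical predictors plus start-year cropland and its
#' interactions) and the augmented model (X1 + X2 + X3: adding frontierness
#' and its cropland interaction). The design is paired — both models see
#' identical replicate sub-samples, derived from `(seed, replicate)` — so the
#' pseudo-R² difference is not inflated by sampling noise.
#'
#' @param data_by_tau Named list (names = thresholds as character) of data
#'   frames over the matching expansion domain, each with globally
#'   standardized model variables including `frontierness`, and the binary
#'   expansion response.
#' @param cfg An [ensemble_config()] applied to every threshold and model.
#' @param response Name of the binary response column (default `"y"`).
#' @return A tibble of class `expansion_comparison`: `tau`,
#'   `model2_mean_r2`, `model3_mean_r2`, `delta` (`model3 - model2`), with
#'   the two `logit_ensemble` lists attached as attribute `"ensembles"`.
#'   Thresholds whose pool cannot supply the sub-sample sizes yield `NA`
#'   rows.
#' @export
compare_models <- function(data_by_tau, cfg, response = "y") {
  stopifnot(is.list(data_by_tau), !is.null(names(data_by_tau)),
            inherits(cfg, "ensemble_config"))
  spec2 <- model_terms("model2")
  spec3 <- model_terms("model3")
  rows <- list()
  ensembles <- list()
  for (tau in names(data_by_tau)) {
    dat <- data_by_tau[[tau]]
    res <- tryCatch({
      e2 <- run_ensemble(dat, spec2, cfg, response)
      e3 <- run_ensemble(dat, spec3, cfg, response)
      list(e2 = e2, e3 = e3,
           r2_2 = mean(e2$r2[e2$converged]), r2_3 = mean(e3$r2[e3$converged]))
    }, error = function(e) {
      warning("threshold ", tau, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      rows[[tau]] <- tibble::tibble(tau = as.numeric(tau),
                                    model2_mean_r2 = NA_real_,
                                    model3_mean_r2 = NA_real_,
                                    delta = NA_real_)
    } else {
      rows[[tau]] <- tibble::tibble(tau = as.numeric(tau),
                                    model2_mean_r2 = res$r2_2,
                                    model3_mean_r2 = res$r2_3,
                                    delta = res$r2_3 - res$r2_2)
      ensembles[[tau]] <- res[c("e2", "e3")]
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ensembles") <- ensembles
  attr(out, "config") <- cfg
  class(out) <- c("expansion_comparison", class(out))
  out
}

#' @export
glance.expansion_comparison <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_thresholds = nrow(x),
    mean_delta = mean(x$delta, na.rm = TRUE),
    n_replicates = cfg$n_replicates,
    seed = cfg$seed
  )
}
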