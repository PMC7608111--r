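# Shared fixtures: small synthetic worlds and an independent logistic-MLE
# oracle. Worlds are generated once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, config) {
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(config)
  }
  .world_cache[[key]]
}

small_world <- function(seed = 7) {
  # rougher predictor fields than the 200x200 default: on a small lattice a
  # long correlation length leaves too few independent patches, so realized
  # class balance would swing wildly from seed to seed
  # cluster count and radius scaled down with the lattice so the frontier
  # footprint stays a minority of the map
  cached_world(paste0("small", seed),
               world_config(shape = c(60, 60), seed = seed, corr_length = 5,
                            n_clusters = 3, cluster_radius = 4))
}

default_world <- function(seed = 42) {
  cached_world(paste0("default", seed), world_config(seed = seed))
}

# moderate, well-identified planted coefficients for recovery checks
recovery_beta <- function() {
  c("(Intercept)" = -2,
    suitability = 1, access = -0.8, steepness = -0.6,
    pop_density = 0.6, gdp = 0.4,
    "suitability:access" = -0.02, "steepness:access" = -0.02,
    "suitability:pop_density" = 0.02, "steepness:pop_density" = -0.02,
    "gdp:access" = -0.02, "gdp:steepness" = -0.02,
    "gdp:suitability" = -0.02, "gdp:pop_density" = -0.02)
}

no_frontier_world <- function(seed = 42) {
  cached_world(paste0("nofrontier", seed),
               world_config(seed = seed, beta_true = recovery_beta(),
                            gamma_frontier = 0))
}

# independent oracle: Newton-Raphson on the Bernoulli log-likelihood,
# written without reference to glm machinery
newton_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- crossprod(X, y - p)
    W <- p * (1 - p)
    H <- crossprod(X, X * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < tol) break
  }
  as.vector(beta)
}

# brute-force proportional overlap, straight from the definition
overlap_bruteforce <- function(value, selection, domain) {
  num <- 0; den <- 0; nsel <- 0; ndom <- 0
  for (i in seq_along(value)) {
    if (isTRUE(domain[i])) {
      ndom <- ndom + 1
      den <- den + value[i]
      if (isTRUE(selection[i])) {
        nsel <- nsel + 1
        num <- num + value[i]
      }
    }
  }
  (num / den) / (nsel / ndom)
}

mean_r2 <- function(ens) mean(ens$r2[ens$converged])
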