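# Shared fixtures and independent oracles for the test suite.

# small two-country cohort used by most fitting tests
small_cohort <- function(seed = 7) make_cohort(default_cohorts(seed = seed))

# a moderately heritable ADE truth with stable genetics
ade_truth <- function(cors = c(0.9, 0.8, 0.2), k = c(0.9, 0.88)) {
  paths_from_components(c(0.30, 0.20, 0.50), c(0.25, 0.20, 0.55), cors,
                        variant = "ADE", k = k,
                        beta = c(t1 = 1, t2 = 1.2, age = 0.01, sex = 0.1,
                                 country = -0.1))
}

# independent dense multivariate-normal log-density: solve()/determinant()
# route, deliberately distinct from the package's Cholesky-based kernel
dense_mvn_logdens <- function(y, mu, sigma) {
  obs <- which(!is.na(y))
  S <- sigma[obs, obs, drop = FALSE]
  r <- y[obs] - mu[obs]
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (length(obs) * log(2 * pi) + ld +
            drop(t(r) %*% solve(S) %*% r))
}

# fabricate a minimal twinchol-like object with given paths/means, for
# tests that probe downstream rules without running the optimizer
fake_fit <- function(params, sex = c(0, 1), converged = TRUE,
                     loglik = -100, n_free = 16) {
  structure(list(variant = params$variant, params = params,
                 loglik = loglik, n_free = n_free,
                 aic = -2 * loglik + 2 * n_free, converged = converged,
                 n_pairs_used = length(sex),
                 constrain_cross = FALSE, occasion_specific = FALSE,
                 data = list(sex = sex)),
            class = "twinchol")
}
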