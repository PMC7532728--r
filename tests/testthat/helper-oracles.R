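# Independent oracles and shared fixtures for the test suite.

# Brute-force maximum of the NB Beverton-Holt likelihood over a parameter
# grid; deliberately independent of the optimizer path in fit_competition().
grid_oracle <- function(table, lambda_grid, alpha_grid, theta_grid) {
  best <- -Inf; at <- NULL
  for (lam in lambda_grid) for (a1 in alpha_grid)
    for (a2 in alpha_grid) for (th in theta_grid) {
      ll <- tryCatch(
        nb_loglik(c(lambda = lam, alpha_intra = a1,
                    alpha_inter = a2, theta = th), table),
        error = function(e) -Inf)
      if (ll > best) { best <- ll; at <- c(lam, a1, a2, th) }
    }
  list(loglik = best, par = at)
}

# Small deterministic single-slice fixture: exact rounded Beverton-Holt
# means, no noise, for near-deterministic fitting checks.
noise_free_slice <- function(lambda = 200, a_ii = 0.3, a_ij = 0.2) {
  cells <- data.frame(
    neighbour = c("none", "none", "conspecific", "heterospecific",
                  "conspecific", "heterospecific",
                  "conspecific", "heterospecific"),
    density = c(0, 0, 4, 4, 10, 10, 20, 20))
  cells <- cells[rep(seq_len(nrow(cells)), each = 4), ]
  mu <- lambda / (1 + a_ii * ifelse(cells$neighbour == "conspecific",
                                    cells$density, 0) +
                    a_ij * ifelse(cells$neighbour == "heterospecific",
                                  cells$density, 0))
  data.frame(pot = seq_len(nrow(cells)), treatment = "dry", focal = "i",
             neighbour = cells$neighbour, density = cells$density,
             seeds = round(mu))
}

# A random admissible parameter set for the classification sweeps.
random_pair_params <- function() {
  c(lambda_i = exp(runif(1, log(5), log(800))),
    lambda_j = exp(runif(1, log(5), log(800))),
    alpha_ii = exp(runif(1, log(0.02), log(2))),
    alpha_ij = exp(runif(1, log(0.02), log(2))),
    alpha_jj = exp(runif(1, log(0.02), log(2))),
    alpha_ji = exp(runif(1, log(0.02), log(2))))
}

dry_params <- function() published_estimates()$dry$params
wet_params <- function() published_estimates()$wet$params
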