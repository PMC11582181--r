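# Shared fixture builders (everything generated in code).

# Random stationary 2x2 or 3x3 transition matrix that is also feasible
# under the unit-variance identification constraint.
random_feasible_A <- function(p = 2, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    A <- matrix(stats::runif(p^2, -0.9, 0.9), p, p) / p
    if (is_stationary(A) && is_feasible(A)) return(A)
  }
  stop("no feasible matrix found")
}

# A stationary matrix incompatible with unit marginal variances
# (complex eigenvalues with modulus ~0.80, implied innovation variance < 0).
infeasible_A <- function() matrix(c(0.2, -0.93, 0.44, 1.18), 2, 2)

# Small two-state linear measurement model, three items per state.
toy_linear_model <- function(items_per_state = 3, loading = 1, error_var = 0.5,
                             p = 2) {
  items <- list()
  for (s in seq_len(p)) {
    for (k in seq_len(items_per_state)) {
      items[[length(items) + 1L]] <- linear_item(
        sprintf("y%d_%d", s, k), s, loading = loading, error_var = error_var
      )
    }
  }
  measurement_model(items, p = p)
}

# Two-state GRM model with common alpha and a shared threshold set.
toy_grm_model <- function(items_per_state = 3, beta = c(-1, 0, 1), alpha = 1,
                          p = 2) {
  items <- list()
  for (s in seq_len(p)) {
    for (k in seq_len(items_per_state)) {
      items[[length(items) + 1L]] <- grm_item(
        sprintf("y%d_%d", s, k), s, beta = beta, alpha = alpha
      )
    }
  }
  measurement_model(items, p = p)
}

# Brute-force fixed-point iteration for the stationary covariance
# (independent oracle for the Lyapunov solve).
lyapunov_fixed_point <- function(A, Sigma, iters = 10000, tol = 1e-12) {
  G <- diag(nrow(A))
  for (i in seq_len(iters)) {
    G2 <- A %*% G %*% t(A) + Sigma
    if (max(abs(G2 - G)) < tol) return(G2)
    G <- G2
  }
  G
}

# Direct dense multivariate normal log-density (oracle for likelihoods).
dmvnorm_log <- function(x, mu, V) {
  ch <- chol(V)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}
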