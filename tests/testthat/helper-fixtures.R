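# Shared fixtures: small node/reservoir configurations used across tests.

sin2_node <- function(beta = 0.7, phi = -pi / 4, tau = 10) {
  node_params("ikeda_sin2", beta = beta, phi = phi, tau = tau)
}

linear_node <- function(eta = 0.9, tau = 20) {
  node_params("linear", beta = eta, tau = tau)
}

small_sin2_config <- function(N = 20, beta = 0.7, phi = -pi / 4, theta = 0.5,
                              seed = 1, gamma = 0.5, ...) {
  node <- node_params("ikeda_sin2", beta = beta, phi = phi, tau = N * theta)
  reservoir_config(node, N = N, seed = seed, gamma = gamma, ...)
}

small_linear_config <- function(N = 10, eta = 0.9, theta = 1, seed = 1, ...) {
  node <- node_params("linear", beta = eta, tau = N * theta)
  reservoir_config(node, N = N, seed = seed, ...)
}

# Independent scalar root finding by plain bisection (test oracle; kept
# deliberately separate from solve_fixed_point).
bisect_root <- function(g, lo, hi, tol = 1e-12) {
  stopifnot(sign(g(lo)) != sign(g(hi)))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(g(lo))) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
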