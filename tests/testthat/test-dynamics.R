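# Node nonlinearity, DDE integration, fixed points, local derivatives.

test_that("node_response evaluates the feedback nonlinearity", {
  p <- sin2_node()
  expect_equal(node_response(p, 0, 0), 0.7 * sin(-pi / 4)^2) # = 0.35
  expect_equal(node_response(p, 0, 0), 0.35)

  # zero gain kills every family
  for (fam in c("ikeda_sin2", "mackey_glass", "linear")) {
    p0 <- node_params(fam, beta = 0, tau = 1)
    expect_equal(node_response(p0, 0.3, -0.2), 0)
  }

  # sin^2 maximum: argument pi/2 gives exactly beta
  p1 <- node_params("ikeda_sin2", beta = 1.3, phi = 0, tau = 1)
  expect_equal(node_response(p1, pi / 4, pi / 4), 1.3)

  # bounded in [0, beta] for beta >= 0
  xs <- seq(-5, 5, length.out = 101)
  vals <- node_response(p, xs, 0.3)
  expect_true(all(vals >= 0 & vals <= p$beta))

  expect_error(node_response(p, NaN, 0), "finite")
  expect_error(node_response(p, 0, Inf), "finite")
})

test_that("integrator reproduces the exponential-decay closed form", {
  p <- node_params("ikeda_sin2", beta = 0, tau = 1)
  tr <- integrate_node(p, constant_drive(0, 5, theta = 0.1), history = 1,
                       oversampling = 100)
  expect_lt(max(abs(tr$x - exp(-tr$time))), 1e-3)
})

test_that("driven sin^2 node converges to the bisection fixed point", {
  p <- node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 1)
  xstar_oracle <- bisect_root(function(x) x - 0.7 * sin(x - pi / 4)^2,
                              0, 0.7 + 1e-3)
  tr <- integrate_node(p, constant_drive(0, 50, theta = 0.1),
                       oversampling = 20)
  expect_lt(abs(tr$x[length(tr$x)] - xstar_oracle), 1e-4)
  # and the package's own fixed-point solver agrees with the oracle
  expect_lt(abs(solve_fixed_point(p, 0) - xstar_oracle), 1e-10)
})

test_that("transient response to the masked periodic demo input is bounded and repeatable", {
  demo <- demo_transient()
  S <- demo$response$values
  expect_equal(dim(S), c(50, 10))
  expect_true(all(is.finite(S)))
  expect_true(all(abs(S) <= 0.7 + 0.1))
  # non-stationary transient: columns differ
  expect_gt(max(apply(S, 1, stats::sd)), 0)
  demo2 <- demo_transient()
  expect_identical(S, demo2$response$values)
})

test_that("solve_fixed_point handles linear and degenerate cases", {
  expect_equal(solve_fixed_point(node_params("linear", beta = 0.5, tau = 1)), 0)
  expect_equal(solve_fixed_point(node_params("ikeda_sin2", beta = 0, tau = 1),
                                 5), 0)
  # residual bound
  p <- sin2_node()
  xs <- solve_fixed_point(p, 0.2)
  expect_lt(abs(xs - node_response(p, xs, 0.2)), 1e-10)
  # no root in a bracket without sign change
  expect_error(solve_fixed_point(p, 0, bracket = c(2, 3)), "sign change")
})

test_that("local slope and curvature match analytic and finite-difference values", {
  p <- sin2_node()
  sc <- local_slope_curvature(p, 0)
  expect_equal(unname(sc["slope"]), -0.7)
  expect_equal(unname(sc["curvature"]), 0, tolerance = 1e-12)

  p0 <- node_params("ikeda_sin2", beta = 0.7, phi = 0, tau = 1)
  sc0 <- local_slope_curvature(p0, 0)
  expect_equal(unname(sc0["slope"]), 0)
  expect_equal(unname(sc0["curvature"]), 1.4)

  # central finite differences of node_response as an independent check
  h <- 1e-5
  for (a in c(-0.8, 0.1, 0.6)) {
    sc <- local_slope_curvature(p, a)
    f <- function(x) node_response(p, x, 0)
    slope_fd <- (f(a + h) - f(a - h)) / (2 * h)
    curv_fd <- (f(a + h) - 2 * f(a) + f(a - h)) / h^2
    expect_equal(unname(sc["slope"]), slope_fd, tolerance = 1e-6)
    expect_equal(unname(sc["curvature"]), curv_fd, tolerance = 1e-4)
  }

  expect_equal(local_slope_curvature(linear_node(0.8), 2),
               c(slope = 0.8, curvature = 0))
  expect_error(local_slope_curvature(node_params("mackey_glass", beta = 1,
                                                 tau = 1), 0),
               "no analytic derivatives")
})

test_that("Euler scheme shows first-order step-size convergence", {
  p <- sin2_node(tau = 2)
  u <- sin(2 * pi * (1:10) / 5)
  mask <- generate_mask(4, "binary_random", seed = 7)
  drive <- multiplex(u, mask, theta = 0.5, gamma = 1)
  sol <- function(rho) {
    integrate_grid(p, drive$values, 0.5, rho, keep = "full")$x
  }
  # sup-norm difference between successive step halvings, compared on the
  # coarse grid; first order: halving the step roughly halves the change
  x10 <- sol(10)
  x20 <- sol(20)
  x40 <- sol(40)
  d1 <- max(abs(x20[seq(2, length(x20), 2)] - x10))
  d2 <- max(abs(x40[seq(4, length(x40), 4)] - x20[seq(2, length(x20), 2)]))
  expect_gt(d1 / d2, 1.5)
  expect_lt(d1 / d2, 2.5)
})

test_that("autonomous decay stays below the discrete-Euler envelope", {
  p <- node_params("linear", beta = 0, tau = 1)
  h <- 0.1 / 20
  tr <- integrate_node(p, constant_drive(0, 4, theta = 0.1), history = 0.8,
                       oversampling = 20)
  expect_true(all(diff(abs(tr$x)) < 0))
  expect_true(all(abs(tr$x) <= 0.8 * exp(-tr$time) * (1 + 5 * h)))
})

test_that("sin^2 trajectories stay within the absorbing set", {
  p <- node_params("ikeda_sin2", beta = 1.5, phi = 0.3, tau = 5)
  u <- runif(20, -1, 1)
  mask <- generate_mask(10, "binary_random", seed = 3)
  drive <- multiplex(u, mask, theta = 0.5, gamma = 1)
  tr <- integrate_node(p, drive, history = 4, oversampling = 20)
  tail_x <- tr$x[tr$time > 5]
  expect_true(all(abs(tail_x) <= 1.5 + 0.1))
})

test_that("identical inputs give bit-identical trajectories (both schemes)", {
  p <- sin2_node(tau = 2)
  u <- runif(8)
  mask <- generate_mask(4, "binary_random", seed = 2)
  drive <- multiplex(u, mask, theta = 0.5, gamma = 0.5)
  for (scheme in c("euler", "heun")) {
    t1 <- integrate_node(p, drive, oversampling = 20, scheme = scheme)
    t2 <- integrate_node(p, drive, oversampling = 20, scheme = scheme)
    expect_identical(t1$x, t2$x)
  }
})

test_that("Heun is more accurate than Euler on the linear decay", {
  p <- node_params("ikeda_sin2", beta = 0, tau = 1)
  dr <- constant_drive(0, 3, theta = 0.1)
  eu <- integrate_node(p, dr, history = 1, oversampling = 10)
  he <- integrate_node(p, dr, history = 1, oversampling = 10,
                       scheme = "heun")
  expect_lt(max(abs(he$x - exp(-he$time))),
            max(abs(eu$x - exp(-eu$time))) / 5)
})

test_that("history validation and grid mismatch are caught", {
  p <- sin2_node(tau = 2)
  dr <- constant_drive(0, 3, theta = 0.5)
  expect_error(integrate_node(p, dr, history = c(1, 2, 3), oversampling = 20),
               "history")
  p_bad <- sin2_node(tau = 2.013) # not divisible by h = theta/rho
  expect_error(integrate_node(p_bad, dr, oversampling = 20),
               "grid mismatch")
})
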