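# Dynamics of a single nonlinear node with delayed self-feedback:
#   T x'(t) = -x(t) + f(x(t - tau), J(t)),   T = 1 (all times in units of T)
# where J(t) is the time-multiplexed drive and f is the node nonlinearity.

#' Parameters of the nonlinear delay node
#'
#' Defines the node driving a delay-based reservoir: its nonlinearity family,
#' gain, offset phase and delay. The node evolves as
#' `x'(t) = -x(t) + f(x(t - tau), J(t))` with the characteristic time scale
#' fixed to 1, so `tau` and all other times are dimensionless.
#'
#' Families:
#' * `ikeda_sin2`: `f(x, J) = beta * sin^2(x + J + phi)` — the Ikeda-type
#'   interference nonlinearity of opto-electronic implementations. `beta` is
#'   the nonlinearity gain, `phi` the offset phase setting the operating
#'   point (slope vs. curvature of the response).
#' * `mackey_glass`: `f(x, J) = beta * (x + J) / (1 + (x + J)^p)` with
#'   `p = mg_exponent`, a saturating nonlinearity of the kind used in
#'   electronic implementations.
#' * `linear`: `f(x, J) = beta * (x + J)`; `beta` doubles as the linear
#'   feedback gain. Useful as a purely linear (maximal-memory) reference.
#'
#' @param family One of `"ikeda_sin2"`, `"mackey_glass"`, `"linear"`.
#' @param beta Nonlinearity gain (dimensionless, finite).
#' @param phi Offset phase in radians (ignored outside `ikeda_sin2`).
#' @param tau Delay time in units of the node time scale; must be positive.
#' @param mg_exponent Exponent of the Mackey-Glass family (default 1).
#' @return An object of class `node_params`.
#' @examples
#' node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 10)
#' @export
node_params <- function(family = c("ikeda_sin2", "mackey_glass", "linear"),
                        beta, phi = 0, tau = 10, mg_exponent = 1) {
  family <- match.arg(family)
  stopifnot(length(beta) == 1L, is.finite(beta),
            length(phi) == 1L, is.finite(phi),
            length(tau) == 1L, is.finite(tau), tau > 0,
            length(mg_exponent) == 1L, is.finite(mg_exponent))
  structure(
    list(family = family, beta = beta, phi = phi, T = 1, tau = tau,
         mg_exponent = mg_exponent),
    class = "node_params"
  )
}

#' @export
print.node_params <- function(x, ...) {
  cat(sprintf("<node_params> family=%s beta=%g phi=%g tau=%g (T=1)\n",
              x$family, x$beta, x$phi, x$tau))
  invisible(x)
}

# Fast vectorized nonlinearity f(x_delayed, J) for the integrator hot loop.
node_fun <- function(params) {
  beta <- params$beta
  phi <- params$phi
  p <- params$mg_exponent
  switch(params$family,
    ikeda_sin2 = function(xd, J) beta * sin(xd + J + phi)^2,
    linear = function(xd, J) beta * (xd + J),
    mackey_glass = function(xd, J) {
      z <- xd + J
      beta * z / (1 + z^p)
    }
  )
}

#' Node response function f
#'
#' Evaluates the feedback nonlinearity `f(x(t - tau), J(t))` of the node,
#' i.e. the forcing term of the delay differential equation. Vectorized over
#' `x_delayed` and `drive`.
#'
#' @param params A [node_params()] object.
#' @param x_delayed Delayed state value(s) `x(t - tau)`.
#' @param drive Injected drive value(s) `J(t)`.
#' @return Numeric vector of forcing values; for `ikeda_sin2` bounded in
#'   `[0, beta]` when `beta >= 0`.
#' @examples
#' p <- node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 10)
#' node_response(p, 0, 0) # 0.7 * sin(-pi/4)^2 = 0.35
#' @export
node_response <- function(params, x_delayed, drive) {
  stopifnot(inherits(params, "node_params"))
  stop_if_not_finite(x_delayed, "x_delayed")
  stop_if_not_finite(drive, "drive")
  node_fun(params)(x_delayed, drive)
}

#' Constant drive segment
#'
#' A minimal piecewise-constant drive for direct use with [integrate_node()]
#' (e.g. autonomous runs with `value = 0`). For masked input streams use
#' [multiplex()] instead.
#'
#' @param value Drive value held over the whole duration.
#' @param duration Total duration in units of the node time scale.
#' @param theta Slot width of the underlying grid (default 0.1).
#' @return A `multiplexed_drive` object with a single repeated value.
#' @export
constant_drive <- function(value, duration, theta = 0.1) {
  stopifnot(is.finite(value), duration > 0, theta > 0)
  n_slots <- ceiling(duration / theta - 1e-9)
  new_multiplexed_drive(rep(value, n_slots), theta = theta, gamma = 1,
                        timing = "matched", mask_span = duration,
                        N = n_slots, K = 1L)
}

# Core grid integrator. Jslots: one drive value per theta-slot. Processes the
# trajectory in blocks of one delay interval; within a block the delayed term
# is known, so the remaining linear recurrence x_i = a*x_{i-1} + forcing_i
# runs through stats::filter (C speed).
#
# keep = "full":  return the whole trajectory at resolution h = theta/rho.
# keep = "slots": return only the state at the end of every theta-slot
#                 (the virtual-node sampling instants), saving memory.
integrate_grid <- function(params, Jslots, theta, rho, history = NULL,
                           scheme = c("euler", "heun"), keep = c("full", "slots"),
                           divergence_limit = Inf) {
  scheme <- match.arg(scheme)
  keep <- match.arg(keep)
  stopifnot(rho >= 1, rho == round(rho), theta > 0)
  h <- theta / rho
  tau <- params$tau
  D <- round(tau / h)
  if (abs(D * h - tau) > 1e-8 * max(1, tau)) {
    stop(sprintf(paste0("integration grid mismatch: step h = theta/rho = %g ",
                        "does not divide the delay tau = %g"), h, tau),
         call. = FALSE)
  }
  n_slots <- length(Jslots)
  if (n_slots < 1L) stop("empty drive", call. = FALSE)
  stop_if_not_finite(Jslots, "drive")
  n_grid <- n_slots * rho

  # history covers [-tau, 0): D samples; state at t = 0 is its last value.
  if (is.null(history)) history <- 0
  if (length(history) == 1L) history <- rep(history, D)
  if (length(history) != D) {
    stop(sprintf("history must have length tau/h = %d (got %d)",
                 D, length(history)), call. = FALSE)
  }
  stop_if_not_finite(history, "history")
  x0 <- history[D]

  f <- node_fun(params)
  if (scheme == "euler") {
    a <- 1 - h
  } else {
    a <- 1 - h + h^2 / 2
  }

  full <- keep == "full"
  if (full) {
    # zfull[j] = x((j - D - 1) * h); indices 1..D+1 hold history + x(0).
    zfull <- c(history, x0, numeric(n_grid))
  } else {
    zprev <- c(history, x0) # rolling window x((-D..0) * h), length D + 1
    slot_states <- numeric(n_slots)
  }
  x_last <- x0
  n_blocks <- ceiling(n_grid / D)
  for (b in seq_len(n_blocks)) {
    s <- (b - 1L) * D
    idx <- (s + 1L):min(s + D, n_grid) # global grid indices of this block
    slot_of <- ((idx - 1L) %/% rho) + 1L
    Jb <- Jslots[slot_of]
    if (full) {
      zd1 <- zfull[idx] # x(t_{i-1} - tau)
    } else {
      zd1 <- zprev[idx - s]
    }
    if (scheme == "euler") {
      forcing <- h * f(zd1, Jb)
    } else {
      # Heun with the delayed term explicit: right-endpoint delayed state
      # x(t_i - tau) is still outside the current block, hence known.
      if (full) {
        zd2 <- zfull[idx + 1L]
      } else {
        zd2 <- zprev[idx - s + 1L]
      }
      forcing <- (h / 2) * ((1 - h) * f(zd1, Jb) + f(zd2, Jb))
    }
    xb <- as.numeric(stats::filter(forcing, a, method = "recursive",
                                   init = x_last))
    if (!all(is.finite(xb)) || max(abs(xb)) > divergence_limit) {
      bad <- idx[which(!is.finite(xb) | abs(xb) > divergence_limit)[1L]]
      stop(sprintf("trajectory diverged at t = %g (input span %d)",
                   bad * h, ((bad - 1L) %/% rho) + 1L), call. = FALSE)
    }
    x_last <- xb[length(xb)]
    if (full) {
      zfull[idx + D + 1L] <- xb
    } else {
      ends <- which(idx %% rho == 0L)
      if (length(ends)) slot_states[idx[ends] %/% rho] <- xb[ends]
      nb <- length(xb)
      if (nb == D) {
        zprev <- c(zprev[D + 1L], xb)
      } else {
        zprev <- utils::tail(c(zprev, xb), D + 1L)
      }
    }
  }
  if (full) {
    list(x = zfull[(D + 2L):(D + 1L + n_grid)], h = h, time = h * seq_len(n_grid))
  } else {
    list(slot_states = slot_states, h = h, theta = theta)
  }
}

#' Integrate the delay differential equation of the node
#'
#' Numerically integrates `x'(t) = -x(t) + f(x(t - tau), J(t))` driven by a
#' piecewise-constant multiplexed input, from a supplied history function on
#' `[-tau, 0)`. The integration step is `h = theta / oversampling`; the
#' delayed term is treated explicitly, so each delay interval reduces to a
#' linear recurrence that is evaluated at C speed.
#'
#' @param params A [node_params()] object.
#' @param drive A `multiplexed_drive` (from [multiplex()] or
#'   [constant_drive()]).
#' @param history Initial history on `[-tau, 0)`: `NULL` (zeros), a scalar
#'   (constant history), or a vector of length `tau / h`. The state at
#'   `t = 0` is the last history value.
#' @param oversampling Integration points per theta-slot (`rho >= 1`).
#' @param scheme `"euler"` (default, first order) or `"heun"` (trapezoidal
#'   predictor-corrector with the delayed term explicit).
#' @return A `node_trajectory`: list with `x` (state at each grid point),
#'   `time`, `h`, and the inputs used. Deterministic: identical inputs give
#'   bit-identical trajectories.
#' @examples
#' p <- node_params("ikeda_sin2", beta = 0, tau = 1)
#' tr <- integrate_node(p, constant_drive(0, 5, theta = 0.1),
#'                      history = 1, oversampling = 10)
#' tr$x[tr$time == 1] # close to exp(-1)
#' @export
integrate_node <- function(params, drive, history = NULL, oversampling = 20,
                           scheme = c("euler", "heun")) {
  stopifnot(inherits(params, "node_params"),
            inherits(drive, "multiplexed_drive"))
  res <- integrate_grid(params, drive$values, drive$theta, oversampling,
                        history = history, scheme = match.arg(scheme),
                        keep = "full")
  structure(
    list(x = res$x, time = res$time, h = res$h, params = params,
         theta = drive$theta, oversampling = oversampling),
    class = "node_trajectory"
  )
}

#' @export
print.node_trajectory <- function(x, ...) {
  cat(sprintf("<node_trajectory> %d points, h=%g, t in (0, %g]\n",
              length(x$x), x$h, max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.node_trajectory <- function(x, ...) {
  data.frame(time = x$time, state = x$x)
}

#' Write a trajectory as two-column CSV
#'
#' @param trajectory A `node_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "node_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Fixed point of the autonomous node
#'
#' Solves `x* = f(x*, J)` for a constant drive `J` by bracketed root finding
#' on `g(x) = x - f(x, J)`. Serves as an independent check of where the
#' integrated trajectory settles under constant drive.
#'
#' @param params A [node_params()] object.
#' @param constant_drive Constant drive value (default 0).
#' @param bracket Search interval; defaults to the range of `f` padded by 1.
#' @return The fixed point `x*` with `|x* - f(x*, J)| <= 1e-10`.
#' @export
solve_fixed_point <- function(params, constant_drive = 0, bracket = NULL) {
  stopifnot(inherits(params, "node_params"), is.finite(constant_drive))
  f <- node_fun(params)
  g <- function(x) x - f(x, constant_drive)
  if (params$beta == 0) return(0)
  if (is.null(bracket)) {
    b <- abs(params$beta) + abs(constant_drive) + 1
    bracket <- c(-b, b)
  }
  if (g(bracket[1]) == 0) return(bracket[1])
  if (g(bracket[2]) == 0) return(bracket[2])
  if (sign(g(bracket[1])) == sign(g(bracket[2]))) {
    stop("no sign change of x - f(x, drive) in the search bracket",
         call. = FALSE)
  }
  stats::uniroot(g, bracket, tol = 1e-12)$root
}

#' Local slope and curvature of the node response
#'
#' First and second derivative of `f` with respect to its total argument
#' `a = x + J` at an operating point. For the `ikeda_sin2` family with
#' `f = beta * sin^2(a + phi)`: slope `beta * sin(2 (a + phi))`, curvature
#' `2 beta * cos(2 (a + phi))`. The slope measures the linear response (and
#' hence the memory) of the node around the operating point, the curvature
#' its nonlinearity (dimensional expansion).
#'
#' @param params A [node_params()] object (`ikeda_sin2` or `linear`).
#' @param operating_point The argument value `a` at which to evaluate.
#' @return Named numeric vector `c(slope = ..., curvature = ...)`.
#' @examples
#' p <- node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 10)
#' local_slope_curvature(p, 0) # slope -0.7, curvature 0
#' @export
local_slope_curvature <- function(params, operating_point = 0) {
  stopifnot(inherits(params, "node_params"), is.finite(operating_point))
  a <- operating_point
  switch(params$family,
    ikeda_sin2 = c(slope = params$beta * sin(2 * (a + params$phi)),
                   curvature = 2 * params$beta * cos(2 * (a + params$phi))),
    linear = c(slope = params$beta, curvature = 0),
    stop(sprintf("no analytic derivatives implemented for family '%s'",
                 params$family), call. = FALSE)
  )
}
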