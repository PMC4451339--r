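# Driven delay reservoir: run the node on the multiplexed input and collect
# the virtual-node state matrix S_M (N nodes x K input steps).

#' Reservoir configuration
#'
#' Bundles the node, the virtual-node layout and the input layer into one
#' reproducible configuration. With matched timing the node separation is
#' `theta = tau / N` exactly; with desynchronized timing the mask span is one
#' slot shorter than the delay, i.e. `theta = tau / (N + 1)`. A warning is
#' emitted when `theta` falls outside `[0.1, 1]` (in units of the node time
#' scale): shorter slots give the node no time to react, longer ones let it
#' reach steady state, and both degrade the virtual-node coupling.
#'
#' @param node A [node_params()] object.
#' @param N Number of virtual nodes.
#' @param oversampling Integration points per slot (`rho`).
#' @param mask An `rc_mask` of length `N`, or `NULL` to generate a
#'   `binary_random` mask from `seed`.
#' @param gamma Input scaling factor.
#' @param timing `"matched"` or `"desynchronized"`.
#' @param noise_snr_db Detection signal-to-noise ratio in dB applied to the
#'   state matrix (`Inf` disables noise).
#' @param seed Integer seed used for the default mask and detection noise.
#' @param warmup Number of delay intervals discarded as warmup (default 3),
#'   removing any dependence on the arbitrary initial history.
#' @param scheme Integration scheme, `"euler"` or `"heun"`.
#' @param theta Optional explicit node separation; must agree with the value
#'   implied by `tau`, `N` and `timing`.
#' @return A `reservoir_config` object.
#' @examples
#' p <- node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 10)
#' cfg <- reservoir_config(p, N = 50, seed = 1)
#' cfg$theta # 0.2
#' @export
reservoir_config <- function(node, N, oversampling = 20, mask = NULL,
                             gamma = 0.5, timing = c("matched", "desynchronized"),
                             noise_snr_db = Inf, seed = NULL, warmup = 3,
                             scheme = c("euler", "heun"), theta = NULL) {
  timing <- match.arg(timing)
  scheme <- match.arg(scheme)
  stopifnot(inherits(node, "node_params"), N >= 1, N == round(N),
            oversampling >= 1, is.finite(gamma), warmup >= 0)
  N <- as.integer(N)
  theta_implied <- if (timing == "matched") node$tau / N else node$tau / (N + 1)
  if (!is.null(theta)) {
    if (abs(theta - theta_implied) > 1e-9 * max(1, theta_implied)) {
      stop(sprintf(paste0("theta = %g inconsistent with tau = %g, N = %d, ",
                          "timing = %s (implies theta = %g)"),
                   theta, node$tau, N, timing, theta_implied), call. = FALSE)
    }
  }
  theta <- theta_implied
  if (theta < 0.1 - 1e-12 || theta > 1 + 1e-12) {
    warning(sprintf(paste0("node separation theta = %g is outside the ",
                           "recommended range [0.1, 1] (units of the node ",
                           "time scale)"), theta))
  }
  if (is.null(mask)) {
    mask <- generate_mask(N, "binary_random", seed = seed %||% 1L)
  }
  stopifnot(inherits(mask, "rc_mask"))
  if (length(mask$weights) != N) {
    stop(sprintf("mask length %d does not match N = %d",
                 length(mask$weights), N), call. = FALSE)
  }
  cfg <- structure(
    list(node = node, N = N, theta = theta, oversampling = as.integer(oversampling),
         mask = mask, gamma = gamma, timing = timing,
         noise_snr_db = noise_snr_db, seed = seed, warmup = warmup,
         scheme = scheme),
    class = "reservoir_config"
  )
  cfg
}

#' @export
print.reservoir_config <- function(x, ...) {
  cat(sprintf(paste0("<reservoir_config> %s node, N=%d, theta=%g, rho=%d, ",
                     "gamma=%g, timing=%s, warmup=%g delay intervals\n"),
              x$node$family, x$N, x$theta, x$oversampling, x$gamma, x$timing,
              x$warmup))
  invisible(x)
}

# Warmup expressed in state-matrix columns (mask spans).
warmup_columns <- function(config) {
  span <- config$N * config$theta
  as.integer(ceiling(config$warmup * config$node$tau / span - 1e-9))
}

new_state_matrix <- function(values, warmup_discarded, config) {
  structure(list(values = values, warmup_discarded = warmup_discarded,
                 meta = list(digest = config_digest(config[c(
                   "N", "theta", "oversampling", "gamma", "timing", "scheme"
                 )]), N = nrow(values), K = ncol(values))),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix> N=%d nodes x K=%d steps (%d warmup columns discarded)\n",
              nrow(x$values), ncol(x$values), x$warmup_discarded))
  invisible(x)
}

#' @export
as.matrix.state_matrix <- function(x, ...) x$values

# Coerce a state_matrix or plain matrix to the N x K numeric matrix.
state_values <- function(states) {
  if (inherits(states, "state_matrix")) states$values else as.matrix(states)
}

#' Run the reservoir on an input sequence
#'
#' Multiplexes the input through the configured mask, integrates the delay
#' equation and samples the trajectory at the end of every `theta`-slot: the
#' state of virtual node `j` at input step `k`. The first `warmup` delay
#' intervals are discarded so the result does not depend on the (arbitrary)
#' initial history. If `noise_snr_db` is finite, detection noise is added to
#' the returned matrix (see [add_detection_noise()]).
#'
#' @param config A [reservoir_config()].
#' @param input_sequence Numeric vector of input samples `u(k)`, or a
#'   `channels x K` matrix of vector-valued samples (channels are
#'   concatenated across the mask span, see [multiplex()]).
#' @param history Initial history passed to the integrator (default zeros).
#' @param keep_warmup Keep the warmup columns (used by diagnostics and the
#'   rank protocols, which manage their own warmup).
#' @return A `state_matrix` with `values` (`N x K` matrix, `K` = number of
#'   retained input steps) and `warmup_discarded`.
#' @examples
#' p <- node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 10)
#' cfg <- reservoir_config(p, N = 50, seed = 1)
#' sm <- reservoir_run(cfg, sin(2 * pi * (1:13) / 10))
#' dim(sm$values) # 50 x 10
#' @export
reservoir_run <- function(config, input_sequence, history = NULL,
                          keep_warmup = FALSE) {
  stopifnot(inherits(config, "reservoir_config"))
  u <- input_sequence
  n_steps <- if (is.matrix(u)) ncol(u) else length(u)
  wcols <- if (keep_warmup) 0L else warmup_columns(config)
  if (n_steps < wcols + 1L) {
    stop(sprintf("input too short: need at least %d samples (%d warmup + 1)",
                 wcols + 1L, wcols), call. = FALSE)
  }
  drive <- multiplex(u, config$mask, theta = config$theta,
                     gamma = config$gamma, timing = config$timing)
  res <- integrate_grid(config$node, drive$values, config$theta,
                        config$oversampling, history = history,
                        scheme = config$scheme, keep = "slots",
                        divergence_limit = 1e6)
  S <- matrix(res$slot_states, nrow = config$N)
  if (wcols > 0L) S <- S[, -seq_len(wcols), drop = FALSE]
  sm <- new_state_matrix(S, wcols, config)
  if (is.finite(config$noise_snr_db)) {
    sm <- add_detection_noise(sm, config$noise_snr_db,
                              seed = config$seed %||% 1L)
  }
  sm
}

#' Add detection noise to a state matrix
#'
#' Emulates the dominant noise source of analog hardware readouts: additive
#' zero-mean Gaussian noise on the measured node states, scaled so the
#' signal-to-noise power ratio equals `snr_db` (signal power taken as the
#' mean square of the states).
#'
#' @param states A `state_matrix` or plain matrix.
#' @param snr_db Target SNR in dB; `Inf` returns the input unchanged.
#' @param seed Integer seed for reproducible noise.
#' @return A `state_matrix` (or matrix) of the same shape.
#' @export
add_detection_noise <- function(states, snr_db, seed = NULL) {
  stopifnot(length(snr_db) == 1L, !is.na(snr_db))
  S <- state_values(states)
  if (is.infinite(snr_db) && snr_db > 0) return(states)
  stopifnot(is.finite(snr_db))
  p_sig <- mean(S^2)
  if (p_sig == 0) {
    stop("SNR undefined for an all-zero state matrix", call. = FALSE)
  }
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- with_seed(seed, stats::rnorm(length(S), sd = sd_noise))
  Sn <- S + matrix(noise, nrow = nrow(S))
  if (inherits(states, "state_matrix")) {
    states$values <- Sn
    states
  } else {
    Sn
  }
}

#' Consistency (reliability) of the reservoir response
#'
#' Runs the reservoir twice on the same input from different initial
#' histories (zeros vs. a seeded random history of scale
#' `perturbation_scale`) and returns the Pearson correlation of the two
#' post-warmup state matrices. In the echo-state (consistent) regime the
#' influence of the history fades and the correlation is close to 1; values
#' below ~0.99 flag an inconsistent operating regime.
#'
#' @param config A [reservoir_config()] (detection noise is disabled for the
#'   check).
#' @param input_sequence Input samples.
#' @param perturbation_scale Standard deviation of the random second history;
#'   0 reproduces the identical run (correlation exactly 1).
#' @param seed Seed for the perturbed history.
#' @return Pearson correlation of the two state matrices.
#' @export
consistency_check <- function(config, input_sequence, perturbation_scale = 0.1,
                              seed = 1) {
  stopifnot(inherits(config, "reservoir_config"), perturbation_scale >= 0)
  cfg <- config
  cfg$noise_snr_db <- Inf
  s1 <- reservoir_run(cfg, input_sequence, history = NULL)
  if (perturbation_scale == 0) return(1)
  D <- round(cfg$node$tau * cfg$oversampling / cfg$theta)
  hist2 <- with_seed(seed, stats::rnorm(D, sd = perturbation_scale))
  s2 <- reservoir_run(cfg, input_sequence, history = hist2)
  r <- stats::cor(as.vector(s1$values), as.vector(s2$values))
  if (is.na(r) || r < 0.99) {
    warning(sprintf(paste0("consistency %.4f below 0.99: the reservoir is ",
                           "operating in an inconsistent regime"), r))
  }
  r
}

#' Write a state matrix as CSV (nodes x steps)
#'
#' @param states A `state_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_matrix_csv <- function(states, path) {
  S <- state_values(states)
  utils::write.csv(as.data.frame(S), path, row.names = FALSE)
  invisible(path)
}
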