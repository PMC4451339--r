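# Task-independent reservoir quality measures:
#   - linear memory capacity mu_c = sum_i m_i, m_i the squared Pearson
#     correlation between a lag-i-trained readout and u(k - i);
#   - kernel quality rank r_kq and generalization rank r_g from concatenated
#     final-state columns of random probe inputs;
#   - computational ability r_c = r_kq - r_g.

#' Numerical rank by singular-value threshold
#'
#' Counts singular values at least `tol` times the largest one. The states
#' of an analog reservoir are never exactly dependent, so the rank protocols
#' need an explicit tolerance; it is the single most sensitive choice in the
#' rank measures and is exposed everywhere they are used.
#'
#' @param M Numeric matrix.
#' @param tol Relative singular-value threshold (default `1e-6`).
#' @return Integer rank in `0..min(dim(M))`; an (effectively) all-zero
#'   matrix returns 0 with a warning.
#' @export
rank_by_svd <- function(M, tol = 1e-6) {
  M <- as.matrix(M)
  d <- svd(M, nu = 0, nv = 0)$d
  if (!length(d) || d[1] <= .Machine$double.xmin) {
    warning("degenerate (all-zero) matrix: rank 0")
    return(0L)
  }
  sum(d >= tol * d[1])
}

# Shared ridge/pinv trainer over a fixed design matrix for many targets:
# returns test-set predictions for each target column, reusing one SVD.
lagged_readout_predictions <- function(X_train, X_test, Y_train, lambda) {
  mu <- colMeans(X_train)
  Xc <- sweep(X_train, 2, mu)
  sv <- svd(Xc)
  d <- sv$d
  if (lambda == 0) {
    di <- ifelse(d > 1e-10 * max(d), 1 / d, 0)
  } else {
    di <- d / (d^2 + lambda)
  }
  ym <- colMeans(Y_train)
  Yc <- sweep(Y_train, 2, ym)
  W <- sv$v %*% (di * (t(sv$u) %*% Yc))
  sweep(sweep(X_test, 2, mu) %*% W, 2, ym, `+`)
}

# Capacity computation shared by the reservoir wrapper and direct-state
# callers (e.g. an ideal shift-register control).
#
# states: N x K matrix; input: full input vector; offset: column k of states
# corresponds to input[offset + k], so lag-i targets input[offset + k - i].
memory_capacity_core <- function(states, input, offset, horizon,
                                 train_frac = 0.8, ridge_lambda = 0,
                                 early_stop = TRUE) {
  S <- state_values(states)
  K <- ncol(S)
  stopifnot(horizon >= 1, offset >= 0, length(input) >= offset + K)
  kmin <- max(1L, horizon + 1L - offset) # ensure u(k - i) exists for all lags
  ks <- kmin:K
  if (length(ks) < 20L) {
    stop("too few usable steps for the requested horizon", call. = FALSE)
  }
  n_train <- floor(train_frac * length(ks))
  if (n_train < 2L || n_train >= length(ks)) {
    stop("train fraction leaves no train or no test data", call. = FALSE)
  }
  tr <- ks[seq_len(n_train)]
  te <- ks[(n_train + 1L):length(ks)]
  X_train <- t(S[, tr, drop = FALSE])
  X_test <- t(S[, te, drop = FALSE])
  lags <- seq_len(horizon)
  Y_train <- vapply(lags, function(i) input[offset + tr - i], numeric(length(tr)))
  Y_test <- vapply(lags, function(i) input[offset + te - i], numeric(length(te)))
  P <- lagged_readout_predictions(X_train, X_test, Y_train, ridge_lambda)
  m <- numeric(horizon)
  for (i in lags) {
    sp <- stats::sd(P[, i])
    m[i] <- if (is.na(sp) || sp == 0) 0 else stats::cor(P[, i], Y_test[, i])^2
  }
  if (early_stop) {
    below <- m < 1e-3
    run <- 0L
    cut <- horizon
    for (i in lags) {
      run <- if (below[i]) run + 1L else 0L
      if (run >= 5L) {
        cut <- i
        break
      }
    }
    if (cut < horizon) m[(cut + 1L):horizon] <- 0
  }
  structure(
    list(m = m, mu_c = sum(m), horizon = horizon,
         split = c(train = length(tr), test = length(te)),
         ridge_lambda = ridge_lambda),
    class = "memory_capacity_report"
  )
}

#' @export
print.memory_capacity_report <- function(x, ...) {
  cat(sprintf("<memory_capacity_report> mu_c = %.3f over %d lags (train %d / test %d)\n",
              x$mu_c, x$horizon, x$split["train"], x$split["test"]))
  invisible(x)
}

#' Linear memory capacity of a reservoir
#'
#' Drives the reservoir with an i.i.d. uniform input on `[-1, 1]` and, for
#' every lag `i = 1..horizon`, trains a separate linear readout to reproduce
#' `u(k - i)`. The per-lag capacity `m_i` is the squared Pearson correlation
#' between the readout and the delayed input on a held-out test split, and
#' the memory capacity is `mu_c = sum_i m_i`. For a reservoir of `N` nodes
#' `mu_c <= N`, with equality approached only by purely linear reservoirs;
#' nonlinearity trades this linear memory for dimensional expansion.
#'
#' The squared correlation is used (rather than the raw coefficient) so that
#' each `m_i` lies in `[0, 1]` and the `N` ceiling holds; the sum is
#' truncated at `horizon` with an early stop once five consecutive lags fall
#' below `1e-3`.
#'
#' @param config A [reservoir_config()].
#' @param n_samples Input length (should be much larger than
#'   `N + horizon`).
#' @param horizon Maximum lag evaluated (default `2 N`).
#' @param seed Seed for the input sequence.
#' @param train_frac Fraction of usable steps used for training (the rest
#'   is the held-out evaluation split).
#' @param ridge_lambda Ridge strength for the lag readouts (default 0:
#'   pseudoinverse least squares).
#' @param early_stop Truncate the lag sum once contributions vanish.
#' @return A `memory_capacity_report`: per-lag `m`, their sum `mu_c`,
#'   `horizon` and the train/test `split`.
#' @export
memory_capacity <- function(config, n_samples = 10000, horizon = NULL,
                            seed = 1, train_frac = 0.8, ridge_lambda = 0,
                            early_stop = TRUE) {
  stopifnot(inherits(config, "reservoir_config"))
  horizon <- as.integer(horizon %||% (2L * config$N))
  if (horizon >= n_samples) {
    stop("horizon must be smaller than n_samples", call. = FALSE)
  }
  u <- with_seed(seed, stats::runif(n_samples, -1, 1))
  sm <- reservoir_run(config, u)
  offset <- sm$warmup_discarded
  memory_capacity_core(sm, u, offset, horizon, train_frac = train_frac,
                       ridge_lambda = ridge_lambda, early_stop = early_stop)
}

#' Memory capacity from a precomputed state matrix
#'
#' Same estimator as [memory_capacity()] but for externally supplied states,
#' e.g. an ideal shift-register control with `x_j(k) = u(k - j)` whose
#' capacity equals `N` exactly.
#'
#' @param states `N x K` matrix (or `state_matrix`) of node states.
#' @param input Full input vector; column `k` of `states` corresponds to
#'   `input[offset + k]`.
#' @param offset Alignment offset (see above).
#' @param horizon Maximum lag evaluated.
#' @param ... Passed to the shared estimator (`train_frac`, `ridge_lambda`,
#'   `early_stop`).
#' @return A `memory_capacity_report`.
#' @export
memory_capacity_states <- function(states, input, offset, horizon, ...) {
  memory_capacity_core(states, input, offset, horizon, ...)
}

# Run one probe input through the reservoir with k-1 warmup steps and return
# the (noiseless) state column of the final step. Detection noise, if
# configured, is applied once to the concatenated probe matrix.
probe_final_column <- function(config, probe) {
  cfg <- config
  cfg$noise_snr_db <- Inf
  sm <- reservoir_run(cfg, probe, keep_warmup = TRUE)
  sm$values[, ncol(sm$values)]
}

probe_matrix_noise <- function(config, M) {
  if (is.finite(config$noise_snr_db)) {
    M <- add_detection_noise(M, config$noise_snr_db,
                             seed = config$seed %||% 1L)
  }
  M
}

#' Kernel quality rank
#'
#' Runs `N` different random probe inputs (length `k_steps`, i.i.d. uniform
#' on `[-1, 1]`) through the reservoir, using the first `k_steps - 1` steps
#' as warmup, and concatenates the final state column of each probe into an
#' `N x N` matrix. The kernel quality `r_kq` is the numerical rank of that
#' matrix: it counts the linearly independent directions the reservoir
#' offers a linear readout, and a well-suited reservoir approaches
#' `r_kq -> N`.
#'
#' @param config A [reservoir_config()].
#' @param k_steps Probe length (default 20; the last step is measured).
#' @param seed Seed for the probe inputs.
#' @param sv_tolerance Relative singular-value threshold for the rank.
#' @return A `rank_report` with `rank`, `singular_values`, `N`, `k`,
#'   `sv_tolerance` and `kind = "kernel_quality"`.
#' @export
kernel_quality <- function(config, k_steps = 20, seed = 1,
                           sv_tolerance = 1e-6) {
  stopifnot(inherits(config, "reservoir_config"), k_steps >= 2)
  N <- config$N
  probes <- with_seed(seed, matrix(stats::runif(N * k_steps, -1, 1),
                                   nrow = k_steps))
  M <- vapply(seq_len(N), function(i) probe_final_column(config, probes[, i]),
              numeric(N))
  M <- probe_matrix_noise(config, M)
  rank_report(M, sv_tolerance, k = k_steps, l = NULL, kind = "kernel_quality")
}

#' Generalization rank
#'
#' Same protocol as [kernel_quality()], except that the final `l_shared`
#' elements of every probe are replaced by one common random suffix: the
#' differing prefixes emulate noise, and a reservoir that generalizes well
#' responds (almost) identically to all probes, giving a low rank `r_g`.
#'
#' @param config A [reservoir_config()].
#' @param k_steps Probe length.
#' @param l_shared Length of the shared suffix, `1 <= l_shared < k_steps`.
#' @param seed Seed for probes and shared suffix.
#' @param sv_tolerance Relative singular-value threshold.
#' @return A `rank_report` with `kind = "generalization"`.
#' @export
generalization_rank <- function(config, k_steps = 20, l_shared = NULL,
                                seed = 1, sv_tolerance = 1e-6) {
  stopifnot(inherits(config, "reservoir_config"), k_steps >= 2)
  l_shared <- as.integer(l_shared %||% (k_steps - 1L))
  if (l_shared < 1L || l_shared >= k_steps) {
    stop("l_shared must satisfy 1 <= l_shared < k_steps", call. = FALSE)
  }
  N <- config$N
  probes <- with_seed(seed, {
    P <- matrix(stats::runif(N * k_steps, -1, 1), nrow = k_steps)
    shared <- stats::runif(l_shared, -1, 1)
    P[(k_steps - l_shared + 1L):k_steps, ] <- shared
    P
  })
  M <- vapply(seq_len(N), function(i) probe_final_column(config, probes[, i]),
              numeric(N))
  M <- probe_matrix_noise(config, M)
  rank_report(M, sv_tolerance, k = k_steps, l = l_shared,
              kind = "generalization")
}

rank_report <- function(M, sv_tolerance, k, l, kind) {
  d <- svd(M, nu = 0, nv = 0)$d
  r <- if (d[1] <= .Machine$double.xmin) {
    warning("degenerate (all-zero) probe matrix: rank 0")
    0L
  } else {
    sum(d >= sv_tolerance * d[1])
  }
  structure(list(rank = as.integer(r), singular_values = d, N = nrow(M),
                 k = k, l = l, sv_tolerance = sv_tolerance, kind = kind),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("<rank_report> %s rank = %d of N = %d (tol %.1e, k = %s%s)\n",
              x$kind, x$rank, x$N, x$sv_tolerance, x$k,
              if (is.null(x$l)) "" else sprintf(", l = %d", x$l)))
  invisible(x)
}

#' Computational ability
#'
#' The difference `r_c = r_kq - r_g` between the kernel quality rank and
#' the generalization rank: high when the reservoir separates genuinely
#' different inputs while still responding identically to inputs that share
#' their recent past. Both ranks must come from the same reservoir dimension
#' and tolerance.
#'
#' @param r_kq A `rank_report` from [kernel_quality()] (or a plain number).
#' @param r_g A `rank_report` from [generalization_rank()] (or a number).
#' @return List with `r_kq`, `r_g`, `r_c`.
#' @examples
#' computational_ability(40, 10)$r_c # 30
#' @export
computational_ability <- function(r_kq, r_g) {
  get_rank <- function(x) if (inherits(x, "rank_report")) x$rank else x
  if (inherits(r_kq, "rank_report") && inherits(r_g, "rank_report")) {
    if (r_kq$N != r_g$N || r_kq$sv_tolerance != r_g$sv_tolerance) {
      stop("rank reports come from different N or tolerance", call. = FALSE)
    }
  }
  a <- get_rank(r_kq)
  b <- get_rank(r_g)
  stopifnot(is.finite(a), is.finite(b))
  if (b > a) {
    warning("generalization rank exceeds kernel quality rank on this seed")
  }
  list(r_kq = a, r_g = b, r_c = a - b)
}
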