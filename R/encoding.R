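# Input layer: sample-and-hold, mask construction and time multiplexing.
#
# Each input sample u(k) is held constant over one mask span and multiplied,
# slot by slot, with a length-N mask. The resulting piecewise-constant signal
# J(t) addresses the N virtual nodes of the delay line in sequence.

#' Sample-and-hold of a discrete input stream
#'
#' Turns discrete samples `u(k)` into a right-continuous step function that
#' holds each sample constant over one `hold_span` (normally the mask span,
#' i.e. one delay interval for matched timing).
#'
#' @param input_sequence Numeric vector of samples `u(k)`.
#' @param hold_span Duration each sample is held, in units of the node time
#'   scale.
#' @return A function `s(t)` defined on `[0, length(u) * hold_span)`, with
#'   attributes `samples` and `hold_span`.
#' @examples
#' s <- sample_and_hold(c(1, 2), hold_span = 10)
#' s(c(0, 9.99, 10)) # 1 1 2
#' @export
sample_and_hold <- function(input_sequence, hold_span) {
  if (length(input_sequence) == 0L) {
    stop("input_sequence must be non-empty", call. = FALSE)
  }
  stop_if_not_finite(input_sequence, "input_sequence")
  stopifnot(is.finite(hold_span), hold_span > 0)
  u <- as.numeric(input_sequence)
  span <- hold_span
  f <- function(t) {
    k <- pmin(length(u), pmax(1L, floor(t / span) + 1L))
    u[k]
  }
  structure(f, samples = u, hold_span = span, class = c("held_signal", "function"))
}

# Primitive polynomial taps (Fibonacci LFSR) for maximum length sequences.
mls_taps <- list(
  `2` = c(2L, 1L), `3` = c(3L, 2L), `4` = c(4L, 3L), `5` = c(5L, 3L),
  `6` = c(6L, 5L), `7` = c(7L, 6L), `8` = c(8L, 6L, 5L, 4L), `9` = c(9L, 5L),
  `10` = c(10L, 7L), `11` = c(11L, 9L), `12` = c(12L, 11L, 10L, 4L)
)

# One period (2^m - 1 bits) of a maximum length sequence from a Fibonacci
# LFSR with the given taps, starting from register 00...01.
mls_bits <- function(m, taps = mls_taps[[as.character(m)]]) {
  if (is.null(taps)) {
    stop(sprintf("no primitive taps tabulated for m = %d", m), call. = FALSE)
  }
  reg <- c(rep(0L, m - 1L), 1L)
  n <- 2L^m - 1L
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- reg[m]
    fb <- Reduce(bitwXor, reg[taps])
    reg <- c(fb, reg[-m])
  }
  out
}

#' Generate an input mask
#'
#' Builds the length-`N` weight sequence that scales the held input sample
#' for each virtual node. The mask sequentializes the input, diversifies the
#' node responses and (with the feedback) defines the effective reservoir
#' connectivity.
#'
#' Kinds:
#' * `binary_random`: i.i.d. weights in `{-1, +1}`.
#' * `binary_mls`: one period of a maximum length sequence (from a primitive
#'   linear feedback shift register), mapped `{0,1} -> {-1,+1}`; requires
#'   `N = 2^m - 1`. MLS masks have nearly ideal (flat) circular
#'   autocorrelation, which maximizes the diversity of node responses for
#'   small `N`.
#' * `multivalued`: i.i.d. weights drawn from the amplitude set `levels`.
#' * `analog`: a smooth seeded random waveform (low-pass filtered Gaussian
#'   noise, rescaled to `[-1, 1]`).
#'
#' @param N Number of virtual nodes (mask length).
#' @param kind Mask kind, see Details.
#' @param seed Integer seed; the mask is deterministic given `(N, kind,
#'   seed, levels)`.
#' @param levels Amplitude set for `multivalued` masks.
#' @return An `rc_mask` object: list with `weights`, `kind`, `seed`,
#'   `levels`.
#' @examples
#' generate_mask(7, "binary_mls")$weights
#' @export
generate_mask <- function(N, kind = c("binary_random", "binary_mls",
                                      "multivalued", "analog"),
                          seed = NULL, levels = c(-1, -1 / 3, 1 / 3, 1)) {
  kind <- match.arg(kind)
  stopifnot(N >= 1, N == round(N))
  N <- as.integer(N)
  weights <- switch(kind,
    binary_random = with_seed(seed, sample(c(-1, 1), N, replace = TRUE)),
    binary_mls = {
      m <- round(log2(N + 1))
      if (2L^m - 1L != N) {
        stop(sprintf("binary_mls requires N = 2^m - 1 (got N = %d)", N),
             call. = FALSE)
      }
      2 * mls_bits(m) - 1
    },
    multivalued = {
      stop_if_not_finite(levels, "levels")
      with_seed(seed, sample(levels, N, replace = TRUE))
    },
    analog = {
      raw <- with_seed(seed, stats::rnorm(N + 8))
      sm <- stats::filter(raw, rep(1 / 5, 5), sides = 2)
      sm <- sm[!is.na(sm)][seq_len(N)]
      as.numeric(sm / max(abs(sm)))
    }
  )
  structure(list(weights = as.numeric(weights), kind = kind, seed = seed,
                 levels = if (kind == "multivalued") levels else NULL),
            class = "rc_mask")
}

#' @export
print.rc_mask <- function(x, ...) {
  cat(sprintf("<rc_mask> kind=%s N=%d\n", x$kind, length(x$weights)))
  invisible(x)
}

#' Serialize / read a mask as JSON
#'
#' @param mask An `rc_mask`.
#' @param path File path.
#' @return `path` (write) or an `rc_mask` (read).
#' @export
write_mask_json <- function(mask, path) {
  stopifnot(inherits(mask, "rc_mask"))
  jsonlite::write_json(unclass(mask), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = as.numeric(x$weights), kind = x$kind,
                 seed = x$seed, levels = x$levels), class = "rc_mask")
}

new_multiplexed_drive <- function(values, theta, gamma, timing, mask_span,
                                  N, K) {
  structure(list(values = as.numeric(values), theta = theta, gamma = gamma,
                 timing = timing, mask_span = mask_span, N = as.integer(N),
                 K = as.integer(K)),
            class = "multiplexed_drive")
}

#' Time-multiplex a held input through a mask
#'
#' Builds the injected signal `J(t)`: every held sample `u(k)` is expanded
#' over the `N` virtual-node slots of width `theta`, the `j`-th slot carrying
#' `gamma * mask_j * u(k)`. With `timing = "matched"` the mask span equals
#' the delay (`tau = N * theta`): neighbouring virtual nodes couple through
#' the inertia of the node. With `timing = "desynchronized"` the mask span is
#' one slot shorter than the delay (`tau = (N + 1) * theta`), so the mask
#' start drifts by one `theta` per delay interval and the mismatch itself
#' provides the coupling.
#'
#' For a vector-valued input (a `channels x K` matrix), the channels of each
#' time step are concatenated across the mask span: slot `j` carries channel
#' `ceiling(j * C / N)` of the current sample, scaled by `gamma * mask_j`,
#' so the mask length stays `N` regardless of the input dimension.
#'
#' @param held_input A numeric vector of samples `u(k)`, a `channels x K`
#'   matrix of vector samples, or a [sample_and_hold()] signal (its samples
#'   are used).
#' @param mask An `rc_mask` of length `N`.
#' @param theta Virtual-node separation (slot width), units of the node time
#'   scale.
#' @param gamma Input scaling factor applied to every weight.
#' @param timing `"matched"` or `"desynchronized"`.
#' @return A `multiplexed_drive`: piecewise-constant values, one per
#'   `theta`-slot, in input order (`N * K` slots for `K` samples).
#' @examples
#' m <- structure(list(weights = c(1, -1, 1), kind = "binary_random",
#'                     seed = NULL, levels = NULL), class = "rc_mask")
#' multiplex(2, m, theta = 1, gamma = 1)$values # 2 -2 2
#' @export
multiplex <- function(held_input, mask, theta, gamma = 0.5,
                      timing = c("matched", "desynchronized")) {
  timing <- match.arg(timing)
  stopifnot(inherits(mask, "rc_mask"), is.finite(theta), theta > 0,
            is.finite(gamma))
  u <- if (inherits(held_input, "held_signal")) {
    attr(held_input, "samples")
  } else {
    held_input
  }
  if (length(u) == 0L) stop("empty input", call. = FALSE)
  stop_if_not_finite(u, "held_input")
  w <- mask$weights
  N <- length(w)
  if (is.matrix(u)) {
    C <- nrow(u)
    K <- ncol(u)
    chan <- pmin(C, ((seq_len(N) - 1L) * C) %/% N + 1L) # channel of slot j
    values <- gamma * as.vector(w * u[chan, , drop = FALSE])
  } else {
    u <- as.numeric(u)
    K <- length(u)
    values <- gamma * as.vector(outer(w, u)) # column k = w * u[k]
  }
  new_multiplexed_drive(values, theta = theta, gamma = gamma, timing = timing,
                        mask_span = N * theta, N = N, K = K)
}

#' @export
print.multiplexed_drive <- function(x, ...) {
  cat(sprintf("<multiplexed_drive> N=%d K=%d theta=%g timing=%s\n",
              x$N, x$K, x$theta, x$timing))
  invisible(x)
}

#' Pseudo-space matrix view of a multiplexed drive
#'
#' Reshapes the injected signal into an `N x K` matrix: row `j` is virtual
#' node `j` (the pseudo-space direction), column `k` is input sample `k`.
#' Flattening the matrix column-major recovers the drive sequence.
#'
#' @param drive A `multiplexed_drive`.
#' @return An `N x K` numeric matrix.
#' @export
pseudo_space_matrix <- function(drive) {
  stopifnot(inherits(drive, "multiplexed_drive"))
  v <- drive$values
  N <- drive$N
  K <- length(v) %/% N
  if (length(v) %% N != 0L) {
    warning("drive does not span an integer number of mask applications; ",
            "dropping the partial final span")
    v <- v[seq_len(N * K)]
  }
  matrix(v, nrow = N, ncol = K)
}
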