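# Synthetic benchmark generators: NARMA-10 system identification, chaotic
# one-step prediction (a generated stand-in for laser-intensity series), and
# multiclass temporal pattern classification (a generated stand-in for
# isolated spoken-digit recognition). All are produced in code from a seed;
# an optional loader accepts a user-supplied single-column series file.

new_task_dataset <- function(inputs, targets, split, task_kind, seed,
                             labels = NULL, extras = list()) {
  structure(list(inputs = inputs, targets = targets, labels = labels,
                 split = split, task_kind = task_kind, seed = seed,
                 extras = extras),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  dm <- dim(x$inputs)
  n <- if (is.null(dm)) length(x$inputs) else dm[length(dm)]
  cat(sprintf("<task_dataset> %s, %d %s (train %d / test %d)\n",
              x$task_kind, n, if (is.null(dm)) "steps" else "items",
              length(x$split$train), length(x$split$test)))
  invisible(x)
}

default_series_split <- function(n, train_frac = 0.8) {
  n_train <- floor(train_frac * n)
  list(train = seq_len(n_train), test = (n_train + 1L):n)
}

#' NARMA-10 benchmark dataset
#'
#' The tenth-order nonlinear autoregressive moving-average system: with
#' i.i.d. input `u(k) ~ U[0, 0.5]`,
#' `y(k+1) = 0.3 y(k) + 0.05 y(k) * sum_{i=0..9} y(k-i)
#'           + 1.5 u(k-9) u(k) + 0.1`.
#' Reproducing `y` from `u` needs both ten steps of memory and a nonlinear
#' combination of past inputs, which is why the task probes the
#' memory/nonlinearity compromise of a reservoir.
#'
#' @param length Sequence length (> 200).
#' @param seed Integer seed.
#' @param train_frac Fraction of steps in the training split.
#' @return A `task_dataset` with step-aligned `inputs` `u(k)` and `targets`
#'   `y(k)`. If the recurrence diverges (|y| > 10) the sequence is
#'   regenerated with a shifted seed and a warning.
#' @export
make_narma10 <- function(length = 2000, seed = 1, train_frac = 0.8) {
  stopifnot(length > 200)
  for (attempt in 0:4) {
    u <- with_seed(seed + attempt, stats::runif(length, 0, 0.5))
    y <- narma10_recurrence(u)
    if (all(is.finite(y)) && max(abs(y)) <= 10) {
      if (attempt > 0) {
        warning(sprintf("NARMA-10 diverged; regenerated with seed %d",
                        seed + attempt))
      }
      return(new_task_dataset(u, y, default_series_split(length, train_frac),
                              "narma10", seed + attempt))
    }
  }
  stop("NARMA-10 recurrence diverged for 5 consecutive seeds", call. = FALSE)
}

# Direct recurrence; exported for use as an explicit reference.
narma10_recurrence <- function(u) {
  n <- length(u)
  y <- numeric(n)
  for (k in 10:(n - 1)) {
    y[k + 1] <- 0.3 * y[k] +
      0.05 * y[k] * sum(y[(k - 9):k]) +
      1.5 * u[k - 9] * u[k] + 0.1
    if (!is.finite(y[k + 1]) || abs(y[k + 1]) > 1e6) {
      y[k + 1] <- Inf
      break
    }
  }
  y
}

#' Chaotic time series for one-step prediction
#'
#' Generates a chaotic scalar series from the Mackey-Glass delay equation
#' `x'(t) = a x(t - d) / (1 + x(t - d)^10) - b x(t)` in its chaotic regime
#' (`a = 0.2`, `b = 0.1`, `d = 17`), integrated by Euler steps of 0.1 and
#' subsampled, then standardized to zero mean and unit variance. It serves
#' as a generated stand-in for recorded chaotic laser-intensity series used
#' in one-step-prediction benchmarks. The target at each step is the next
#' value of the series.
#'
#' @param length Number of samples (> 1000 recommended; enforced > 200).
#' @param seed Integer seed (perturbs the initial history).
#' @param a,b,d Mackey-Glass parameters (defaults are the classic chaotic
#'   point).
#' @param stride Subsampling stride in integration steps.
#' @param train_frac Fraction of steps in the training split.
#' @return A `task_dataset`: `inputs` = series values, `targets` = series
#'   shifted one step ahead. A warning is issued if the generated series is
#'   suspiciously close to periodic.
#' @export
make_chaotic_series <- function(length = 4000, seed = 1, a = 0.2, b = 0.1,
                                d = 17, stride = 10, train_frac = 0.8) {
  stopifnot(length > 200)
  dt <- 0.1
  dsteps <- round(d / dt)
  discard <- 500L # settle onto the attractor
  n_steps <- (length + discard) * stride
  hist0 <- 1.2 + with_seed(seed, stats::rnorm(dsteps, sd = 0.01))
  x <- c(hist0, numeric(n_steps))
  for (i in seq_len(n_steps)) {
    xd <- x[i]
    xc <- x[i + dsteps - 1L]
    x[i + dsteps] <- xc + dt * (a * xd / (1 + xd^10) - b * xc)
  }
  s <- x[dsteps + seq(discard * stride + stride, n_steps, by = stride)]
  s <- s[seq_len(length)]
  s <- (s - mean(s)) / stats::sd(s)
  # crude near-periodicity check on the autocorrelation tail
  ac <- stats::acf(s, lag.max = min(200L, length %/% 4L), plot = FALSE)$acf[-1]
  if (max(abs(ac[-seq_len(9)])) > 0.995) {
    warning("generated series looks near-periodic; check parameters")
  }
  inputs <- s[-length(s)]
  targets <- s[-1]
  new_task_dataset(inputs, targets,
                   default_series_split(length(inputs), train_frac),
                   "one_step_prediction", seed)
}

#' Multiclass temporal-pattern classification dataset
#'
#' A generated stand-in for isolated spoken-digit recognition. Each class is
#' a fixed smooth positive envelope pattern over `n_channels` frequency-like
#' channels and `item_length` time steps (a miniature cochleagram); each
#' item is its class envelope modulating an item-specific random binary
#' carrier per channel and step, under random amplitude jitter (emulating
#' speaker variability) plus i.i.d. Gaussian noise of standard deviation
#' `noise_sd`:
#' `item(c, t) = amp * envelope_class(c, t) * carrier(c, t) + noise(c, t)`.
#' Because the carrier is zero-mean and independent of the class, every
#' linear functional of the input has identical class means: classification
#' requires a nonlinear (energy-detecting) transformation of the per-step
#' channel profile, as spectral-energy features of speech do, while
#' demanding little memory. The default shape mirrors a 500-digit set:
#' 10 classes x 50 items. Items are ordered by interleaving classes so
#' consecutive cross-validation folds stay class-balanced.
#'
#' @param n_items Total items (must be divisible by `n_classes`).
#' @param n_classes Number of classes.
#' @param item_length Time steps per item.
#' @param n_channels Input channels per step (concatenated over the mask
#'   span when multiplexed, see [multiplex()]).
#' @param noise_sd Additive noise standard deviation (>= 0); task difficulty
#'   is monotone in it.
#' @param amp_jitter_sd Standard deviation of the multiplicative amplitude
#'   jitter.
#' @param seed Integer seed.
#' @param test_frac Fraction of items in the test split (stratified by the
#'   interleaved ordering).
#' @return A `task_dataset` with `inputs`
#'   (`n_channels x item_length x n_items` array), integer `labels` in
#'   `1..n_classes`, and item-level `split`. Class envelope templates are
#'   kept in `extras$templates` (`n_channels x item_length x n_classes`).
#' @export
make_pattern_classification <- function(n_items = 500, n_classes = 10,
                                        item_length = 30, n_channels = 8,
                                        noise_sd = 0.3, amp_jitter_sd = 0.1,
                                        seed = 1, test_frac = 0.2) {
  stopifnot(n_items >= n_classes, n_classes >= 2, item_length >= 2,
            n_channels >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_items %% n_classes != 0) {
    stop("n_items must be divisible by n_classes for a balanced set",
         call. = FALSE)
  }
  per_class <- n_items %/% n_classes
  smooth_env <- function(len) {
    raw <- stats::rnorm(len + 8)
    sm <- stats::filter(raw, rep(1 / 5, 5), sides = 2)
    sm <- sm[!is.na(sm)][seq_len(len)]
    env <- abs(as.numeric(sm)) + 0.2 # smooth positive envelope
    env / max(env)
  }
  dat <- with_seed(seed, {
    templates <- array(0, c(n_channels, item_length, n_classes))
    for (cl in seq_len(n_classes)) {
      for (ch in seq_len(n_channels)) {
        templates[ch, , cl] <- smooth_env(item_length)
      }
    }
    labels <- rep(seq_len(n_classes), times = per_class) # interleaved
    items <- array(0, c(n_channels, item_length, n_items))
    for (i in seq_len(n_items)) {
      cl <- labels[i]
      amp <- 1 + stats::rnorm(1, sd = amp_jitter_sd)
      carrier <- matrix(sample(c(-1, 1), n_channels * item_length,
                               replace = TRUE), n_channels)
      items[, , i] <- amp * templates[, , cl] * carrier +
        stats::rnorm(n_channels * item_length, sd = noise_sd)
    }
    list(templates = templates, labels = labels, items = items)
  })
  n_test <- max(1L, round(test_frac * n_items))
  split <- list(train = seq_len(n_items - n_test),
                test = (n_items - n_test + 1L):n_items)
  new_task_dataset(dat$items, NULL, split, "pattern_classification", seed,
                   labels = dat$labels,
                   extras = list(templates = dat$templates,
                                 noise_sd = noise_sd,
                                 amp_jitter_sd = amp_jitter_sd,
                                 n_channels = n_channels))
}

#' Persist / restore a task dataset as a CSV bundle
#'
#' Writes `inputs.csv`, `targets.csv` (or `labels.csv` for classification),
#' `split.csv` and a JSON manifest (`manifest.json` with kind, seed and
#' shape) into a directory, and reads such a bundle back.
#'
#' @param dataset A `task_dataset`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (write) or a `task_dataset` (read). Multi-channel item
#'   arrays are stored flattened with their shape in the manifest.
#' @export
write_task_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "task_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(dataset$inputs)
  utils::write.csv(data.frame(value = as.vector(dataset$inputs)),
                   file.path(dir, "inputs.csv"), row.names = FALSE)
  if (!is.null(dataset$targets)) {
    utils::write.csv(data.frame(value = dataset$targets),
                     file.path(dir, "targets.csv"), row.names = FALSE)
  }
  if (!is.null(dataset$labels)) {
    utils::write.csv(data.frame(label = dataset$labels),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(index = c(dataset$split$train, dataset$split$test),
               role = rep(c("train", "test"),
                          c(length(dataset$split$train),
                            length(dataset$split$test)))),
    file.path(dir, "split.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(task_kind = dataset$task_kind, seed = dataset$seed,
         shape = as.list(dm %||% length(dataset$inputs))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname write_task_dataset
#' @export
read_task_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  inputs <- utils::read.csv(file.path(dir, "inputs.csv"))$value
  shape <- unlist(man$shape)
  if (length(shape) > 1) dim(inputs) <- shape
  targets <- if (file.exists(file.path(dir, "targets.csv"))) {
    utils::read.csv(file.path(dir, "targets.csv"))$value
  }
  labels <- if (file.exists(file.path(dir, "labels.csv"))) {
    utils::read.csv(file.path(dir, "labels.csv"))$label
  }
  sp <- utils::read.csv(file.path(dir, "split.csv"))
  new_task_dataset(inputs, targets,
                   list(train = sp$index[sp$role == "train"],
                        test = sp$index[sp$role == "test"]),
                   man$task_kind, man$seed, labels = labels)
}

#' Load a single-column series file as a prediction dataset
#'
#' Reads a plain-text file with one numeric value per line (e.g. a recorded
#' laser-intensity series), optionally standardizes it, and builds the
#' one-step-prediction dataset (`targets` = next value).
#'
#' @param path File path.
#' @param standardize Center and scale to unit variance (default `TRUE`).
#' @param train_frac Fraction of steps in the training split.
#' @return A `task_dataset` of kind `one_step_prediction`.
#' @export
load_series_file <- function(path, standardize = TRUE, train_frac = 0.8) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) < 2L) {
    stop(sprintf("'%s': need at least two numeric rows", path), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("'%s': non-numeric value on line %d", path, bad),
         call. = FALSE)
  }
  s <- vals
  if (standardize) s <- (s - mean(s)) / stats::sd(s)
  inputs <- s[-length(s)]
  targets <- s[-1]
  new_task_dataset(inputs, targets,
                   default_series_split(length(inputs), train_frac),
                   "one_step_prediction", seed = NULL,
                   extras = list(path = path, standardized = standardize,
                                 raw = vals))
}
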