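# Linear output layer: y_k = sum_j w_jk x_j (+ intercept), trained by ridge
# regression on the state matrix, plus the evaluation measures used
# throughout (NMSE for prediction, winner-take-all error for classification).

# Minimum-norm least squares via SVD pseudoinverse (lambda = 0 path).
lstsq_pinv <- function(X, Y, tol = 1e-10) {
  sv <- svd(X)
  d <- sv$d
  keep <- d > tol * d[1]
  di <- ifelse(keep, 1 / d, 0)
  sv$v %*% (di * (t(sv$u) %*% Y))
}

#' Train the linear readout
#'
#' Fits readout weights minimizing `||Y - X w||^2 + lambda ||w||^2`, where
#' `X` is the state matrix transposed to `K x N` (optionally augmented with a
#' constant node for the intercept, which is never penalized). `lambda = 0`
#' uses the minimum-norm least-squares solution (SVD pseudoinverse), so
#' rank-deficient and interpolation regimes are handled.
#'
#' @param states A `state_matrix` or `N x K` matrix.
#' @param targets Length-`K` vector or `K x C` matrix of target outputs (one
#'   column per output/class).
#' @param ridge_lambda Ridge strength. `NULL` (default) uses the scale-aware
#'   value `1e-6 * mean(diag(S S^T))`.
#' @param intercept Include a constant node (default `TRUE`). Disable for a
#'   strict weighted-sum readout.
#' @param classes Optional class labels attached to the model (one per
#'   target column).
#' @return A `readout_model`: `weights` (`N x C`), `intercepts` (length
#'   `C`), `ridge_lambda`, `classes`.
#' @examples
#' S <- diag(4)
#' m <- readout_train(S, c(1, 2, 3, 4), ridge_lambda = 0, intercept = FALSE)
#' drop(m$weights) # 1 2 3 4
#' @export
readout_train <- function(states, targets, ridge_lambda = NULL,
                          intercept = TRUE, classes = NULL) {
  S <- state_values(states) # N x K
  X <- t(S)                 # K x N
  Y <- as.matrix(targets)
  if (!all(is.finite(Y))) stop("targets must be finite", call. = FALSE)
  if (nrow(Y) != nrow(X)) {
    stop(sprintf("targets have %d rows but the state matrix has %d steps",
                 nrow(Y), nrow(X)), call. = FALSE)
  }
  N <- ncol(X)
  K <- nrow(X)
  if (K <= N) {
    warning(sprintf("K = %d training steps for N = %d nodes: ", K, N),
            "interpolation regime, consider more data or larger lambda")
  }
  if (is.null(ridge_lambda)) {
    ridge_lambda <- 1e-6 * mean(colSums(X^2))
  }
  stopifnot(ridge_lambda >= 0)
  if (intercept) {
    A <- cbind(1, X)
    pen <- c(0, rep(ridge_lambda, N))
  } else {
    A <- X
    pen <- rep(ridge_lambda, N)
  }
  if (ridge_lambda == 0) {
    W <- lstsq_pinv(A, Y)
  } else {
    G <- crossprod(A)
    diag(G) <- diag(G) + pen
    W <- solve(G, crossprod(A, Y))
  }
  if (intercept) {
    intercepts <- W[1, ]
    weights <- W[-1, , drop = FALSE]
  } else {
    intercepts <- rep(0, ncol(Y))
    weights <- W
  }
  structure(list(weights = weights, intercepts = as.numeric(intercepts),
                 ridge_lambda = ridge_lambda, classes = classes,
                 intercept = intercept),
            class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model> N=%d nodes -> C=%d outputs, lambda=%.3g%s\n",
              nrow(x$weights), ncol(x$weights), x$ridge_lambda,
              if (x$intercept) ", intercept" else ""))
  invisible(x)
}

#' Predict readout outputs
#'
#' Applies the trained weighted sum to a state matrix.
#'
#' @param model A `readout_model`.
#' @param states A `state_matrix` or `N x K` matrix with the same `N` as the
#'   model.
#' @return `K x C` matrix of outputs `y_k`.
#' @export
readout_predict <- function(model, states) {
  stopifnot(inherits(model, "readout_model"))
  S <- state_values(states)
  if (nrow(S) != nrow(model$weights)) {
    stop(sprintf("model expects %d nodes but the state matrix has %d",
                 nrow(model$weights), nrow(S)), call. = FALSE)
  }
  sweep(crossprod(S, model$weights), 2, model$intercepts, `+`)
}

#' Winner-take-all classification
#'
#' Assigns each item the class with the largest time-averaged output over
#' the item's steps. Ties break toward the lowest class index, and adding a
#' common constant to all class outputs never changes the labels.
#'
#' @param outputs `K x C` output matrix (one row per step).
#' @param segments Item membership of each step: a factor/vector of length
#'   `K`, or a list of index vectors (one per item).
#' @return Integer vector of class indices (1-based; use `classes` labels of
#'   the model to map back), one per item, in segment order.
#' @export
wta_classify <- function(outputs, segments) {
  Y <- as.matrix(outputs)
  if (is.list(segments)) {
    idx_list <- segments
  } else {
    stopifnot(length(segments) == nrow(Y))
    idx_list <- split(seq_len(nrow(Y)), factor(segments, levels = unique(segments)))
  }
  if (any(lengths(idx_list) == 0L)) {
    stop("empty segment in winner-take-all grouping", call. = FALSE)
  }
  vapply(idx_list, function(ix) {
    which.max(colMeans(Y[ix, , drop = FALSE]))
  }, integer(1))
}

#' Normalized mean square error
#'
#' Mean squared prediction error divided by the target variance (population
#' form): 0 for a perfect prediction, 1 for constantly predicting the target
#' mean.
#'
#' @param predicted,target Equal-length numeric vectors.
#' @return The NMSE (dimensionless). Its square root (`sqrt(nmse(...))`) is
#'   the normalized root-mean-square error sometimes reported instead.
#' @examples
#' nmse(c(1, 0, 1, 0), c(0, 1, 0, 1)) # 4
#' @export
nmse <- function(predicted, target) {
  stopifnot(length(predicted) == length(target))
  stop_if_not_finite(predicted, "predicted")
  stop_if_not_finite(target, "target")
  v <- mean((target - mean(target))^2)
  if (v == 0) {
    stop("NMSE undefined for a zero-variance target", call. = FALSE)
  }
  mean((predicted - target)^2) / v
}

#' Misclassification rate
#'
#' @param labels_pred,labels_true Equal-length label vectors.
#' @return Fraction of mismatching labels, in `[0, 1]`.
#' @export
error_rate <- function(labels_pred, labels_true) {
  if (length(labels_pred) == 0L) {
    stop("empty label vectors", call. = FALSE)
  }
  stopifnot(length(labels_pred) == length(labels_true))
  mean(labels_pred != labels_true)
}

#' Rotation cross-validation folds
#'
#' Partitions `n_items` into consecutive folds of size `fold_size` (the last
#' fold absorbs any remainder), the default shape being leave-25-out over
#' 500 items. Every item appears in exactly one fold.
#'
#' @param n_items Number of items.
#' @param fold_size Items per held-out fold.
#' @return List of integer index vectors (the held-out items of each fold).
#' @export
cv_folds <- function(n_items, fold_size = 25) {
  stopifnot(n_items >= 2, fold_size >= 1, fold_size < n_items)
  n_folds <- floor(n_items / fold_size)
  fold_of <- pmin(((seq_len(n_items) - 1L) %/% fold_size) + 1L, n_folds)
  unname(split(seq_len(n_items), fold_of))
}

#' Serialize / read a readout model as JSON
#'
#' @param model A `readout_model`.
#' @param path File path.
#' @return `path` (write) or a `readout_model` (read).
#' @export
write_readout_json <- function(model, path) {
  stopifnot(inherits(model, "readout_model"))
  x <- list(weights = model$weights, intercepts = model$intercepts,
            ridge_lambda = model$ridge_lambda, classes = model$classes,
            intercept = model$intercept)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_readout_json
#' @export
read_readout_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(x$weights)
  storage.mode(W) <- "double"
  structure(list(weights = W,
                 intercepts = as.numeric(x$intercepts),
                 ridge_lambda = x$ridge_lambda,
                 classes = x$classes, intercept = isTRUE(x$intercept)),
            class = "readout_model")
}
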