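# Experiment layer: task evaluation pipelines, operating-point (phi) sweeps,
# reservoir-size (N) sweeps, config handling and result export. The
# command-line runner in inst/cli/delayrc is a thin wrapper over these
# functions.

#' Run a batch of items through one reservoir
#'
#' Concatenates the item sequences (each preceded by `pad` zero-input
#' samples that let the previous item's activity fade) into one input
#' stream, runs the reservoir once, and splits the resulting state matrix
#' back into per-item blocks. Far cheaper than one reservoir run per item.
#'
#' @param config A [reservoir_config()].
#' @param items `item_length x n_items` matrix of scalar input sequences,
#'   or a `channels x item_length x n_items` array of vector-valued ones.
#' @param pad Zero-input samples inserted before each item.
#' @return List with `states` (`N x (item_length * n_items)` matrix of the
#'   non-pad columns) and `item_of` (item index of each column).
#' @export
run_items <- function(config, items, pad = 3) {
  stopifnot(pad >= 0)
  if (is.array(items) && length(dim(items)) == 3L) {
    C <- dim(items)[1]
    len <- dim(items)[2]
    n_items <- dim(items)[3]
    blocks <- lapply(seq_len(n_items), function(i) {
      cbind(matrix(0, C, pad), items[, , i])
    })
    stream <- do.call(cbind, blocks) # C x (n_items * (len + pad))
  } else {
    stopifnot(is.matrix(items))
    len <- nrow(items)
    n_items <- ncol(items)
    stream <- as.vector(rbind(matrix(0, pad, n_items), items))
  }
  cfg <- config
  cfg$warmup <- 0
  sm <- reservoir_run(cfg, stream, keep_warmup = TRUE)
  keep <- rep(c(rep(FALSE, pad), rep(TRUE, len)), n_items)
  S <- sm$values[, keep, drop = FALSE]
  if (is.finite(config$noise_snr_db)) {
    S <- add_detection_noise(S, config$noise_snr_db,
                             seed = config$seed %||% 1L)
  }
  list(states = S, item_of = rep(seq_len(n_items), each = len))
}

#' Evaluate a reservoir on a one-step-prediction dataset
#'
#' Runs the reservoir over the input series, trains the readout on the
#' training split of the targets and reports the test-set NMSE.
#'
#' @param config A [reservoir_config()].
#' @param dataset A `task_dataset` with step-aligned `inputs`/`targets`
#'   (from [make_chaotic_series()], [make_narma10()] or
#'   [load_series_file()]).
#' @param ridge_lambda Ridge strength (`NULL` = scale-aware default).
#' @return List with `nmse`, `nmse_train`, `model`, `n_train`, `n_test`.
#' @export
evaluate_prediction <- function(config, dataset, ridge_lambda = NULL) {
  stopifnot(inherits(dataset, "task_dataset"), !is.matrix(dataset$inputs))
  sm <- reservoir_run(config, dataset$inputs)
  off <- sm$warmup_discarded
  K <- ncol(sm$values)
  targ <- dataset$targets[off + seq_len(K)]
  tr <- dataset$split$train
  te <- dataset$split$test
  tr <- tr[tr > off] - off
  te <- te[te > off] - off
  S <- sm$values
  model <- readout_train(S[, tr, drop = FALSE], targ[tr],
                         ridge_lambda = ridge_lambda)
  pred_te <- drop(readout_predict(model, S[, te, drop = FALSE]))
  pred_tr <- drop(readout_predict(model, S[, tr, drop = FALSE]))
  list(nmse = nmse(pred_te, targ[te]),
       nmse_train = nmse(pred_tr, targ[tr]),
       model = model, n_train = length(tr), n_test = length(te))
}

#' Evaluate a reservoir on a pattern-classification dataset
#'
#' Runs all items through the reservoir ([run_items()]), trains a one-hot
#' ridge readout on the per-step states of the training items and classifies
#' each test item by winner-take-all over its time-averaged class outputs.
#' With `cv = TRUE` the dataset split is ignored and a rotation
#' cross-validation over folds of `fold_size` items is performed instead
#' (the reservoir states are computed once; only the readout is retrained
#' per fold).
#'
#' @param config A [reservoir_config()].
#' @param dataset A `task_dataset` from [make_pattern_classification()].
#' @param ridge_lambda Ridge strength (`NULL` = scale-aware default).
#' @param cv Use rotation cross-validation over all items.
#' @param fold_size Held-out items per fold when `cv = TRUE` (default 25).
#' @param node_subset Optional integer vector of node indices exposed to the
#'   readout (emulates partial readout access to a larger reservoir).
#' @param pad Zero-input padding between items (see [run_items()]).
#' @return List with `error` (misclassification fraction), `n_eval`,
#'   `labels_pred`, `labels_true`.
#' @export
evaluate_classification <- function(config, dataset, ridge_lambda = NULL,
                                    cv = FALSE, fold_size = 25,
                                    node_subset = NULL, pad = 3) {
  stopifnot(inherits(dataset, "task_dataset"))
  dm <- dim(dataset$inputs)
  n_items <- dm[length(dm)]
  n_classes <- max(dataset$labels)
  res <- run_items(config, dataset$inputs, pad = pad)
  S <- res$states
  if (!is.null(node_subset)) {
    if (any(node_subset > nrow(S)) || any(node_subset < 1)) {
      stop("node_subset indices outside the reservoir", call. = FALSE)
    }
    S <- S[node_subset, , drop = FALSE]
  }
  onehot <- function(items) {
    steps <- which(res$item_of %in% items)
    Y <- matrix(0, length(steps), n_classes)
    Y[cbind(seq_along(steps), dataset$labels[res$item_of[steps]])] <- 1
    list(steps = steps, Y = Y)
  }
  eval_split <- function(train_items, test_items) {
    tr <- onehot(train_items)
    Str <- S[, tr$steps, drop = FALSE]
    # one-hot targets on carrier-noise-dominated states: shrink harder than
    # the generic default (only the output ranking matters for WTA)
    lam <- ridge_lambda %||% (1e-3 * mean(rowSums(Str^2)))
    model <- readout_train(Str, tr$Y, ridge_lambda = lam)
    te_steps <- which(res$item_of %in% test_items)
    out <- readout_predict(model, S[, te_steps, drop = FALSE])
    pred <- wta_classify(out, res$item_of[te_steps])
    list(pred = unname(pred), true = dataset$labels[test_items])
  }
  if (cv) {
    folds <- cv_folds(n_items, fold_size)
    preds <- lapply(folds, function(te_items) {
      eval_split(setdiff(seq_len(n_items), te_items), te_items)
    })
    labels_pred <- unlist(lapply(preds, `[[`, "pred"))
    labels_true <- unlist(lapply(preds, `[[`, "true"))
  } else {
    r <- eval_split(dataset$split$train, dataset$split$test)
    labels_pred <- r$pred
    labels_true <- r$true
  }
  list(error = error_rate(labels_pred, labels_true),
       n_eval = length(labels_true),
       labels_pred = labels_pred, labels_true = labels_true)
}

# Build a node + reservoir config from a flat option list (used by sweeps,
# run_experiment and the CLI).
build_config <- function(opts, seed = NULL) {
  N <- opts$N %||% 50
  timing <- opts$timing %||% "matched"
  tau <- opts$tau %||% 10
  if (!is.null(opts$theta)) {
    # fixed node separation: the delay line grows with N
    tau <- opts$theta * (if (timing == "matched") N else N + 1)
  }
  node <- node_params(opts$family %||% "ikeda_sin2",
                      beta = opts$beta %||% 0.7,
                      phi = opts$phi %||% (-pi / 4),
                      tau = tau,
                      mg_exponent = opts$mg_exponent %||% 1)
  mask <- generate_mask(N, opts$mask_kind %||% "binary_random",
                        seed = seed %||% opts$seed %||% 1)
  reservoir_config(node,
                   mask = mask,
                   N = N,
                   oversampling = opts$oversampling %||% 20,
                   gamma = opts$gamma %||% 0.5,
                   timing = timing,
                   noise_snr_db = opts$noise_snr_db %||% Inf,
                   seed = seed %||% opts$seed %||% 1,
                   warmup = opts$warmup %||% 3,
                   scheme = opts$scheme %||% "euler")
}

#' Default experiment configuration
#'
#' The full set of tunable options with their defaults, as a nested list
#' (reservoir, task, readout, sweep). [load_config()] merges a YAML file
#' over these values.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    version = 1,
    seed = 1,
    reservoir = list(family = "ikeda_sin2", beta = 0.9, phi = -pi / 4,
                     tau = 25, N = 50, oversampling = 20, gamma = 1,
                     timing = "matched", noise_snr_db = Inf, warmup = 3,
                     scheme = "euler", mg_exponent = 1,
                     mask_kind = "multivalued", theta = NULL),
    task = list(kind = "one_step_prediction", length = 2000, n_items = 300,
                n_classes = 10, item_length = 20, n_channels = 16,
                noise_sd = 0.3),
    readout = list(ridge_lambda = NULL, cv = FALSE, fold_size = 25),
    metrics = list(sv_tolerance = 1e-6, k_steps = 20, horizon = NULL,
                   mc_samples = 4000),
    sweep = list(parameter = NULL, grid = NULL, repeats = 5)
  )
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load an experiment configuration file
#'
#' Reads a YAML config and merges it over [default_config()]. Unknown keys
#' are kept (and ignored by the runners).
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    if (!is.list(over)) stop("config file is not a YAML mapping", call. = FALSE)
    # YAML 1.1 reads a bare `N:` key as the boolean FALSE; map it back
    if (is.list(over$reservoir)) {
      names(over$reservoir)[names(over$reservoir) %in% c("FALSE", "n_nodes")] <- "N"
    }
    cfg <- merge_lists(cfg, over)
  }
  cfg
}

make_task_dataset <- function(task, seed) {
  switch(task$kind %||% "one_step_prediction",
    narma10 = make_narma10(task$length %||% 2000, seed = seed),
    one_step_prediction = make_chaotic_series(task$length %||% 2000,
                                              seed = seed),
    pattern_classification = make_pattern_classification(
      n_items = task$n_items %||% 300, n_classes = task$n_classes %||% 10,
      item_length = task$item_length %||% 20,
      n_channels = task$n_channels %||% 16,
      noise_sd = task$noise_sd %||% 0.3, seed = seed),
    stop(sprintf("unknown task kind '%s'", task$kind), call. = FALSE)
  )
}

#' Run a configured experiment
#'
#' Builds the reservoir and the task from a config (see
#' [default_config()]), evaluates it, and optionally writes a JSON report
#' and a one-row CSV into `out_dir`. Every report carries the seed and a
#' config digest, so the run can be reproduced bit-identically.
#'
#' @param config Nested config list (from [load_config()]) or a YAML path.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `score` (NMSE or error rate), `task_kind`, `seed`,
#'   `digest`, and the per-task details.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  seed <- config$seed %||% 1
  rc <- build_config(config$reservoir, seed = seed)
  ds <- make_task_dataset(config$task, seed = seed)
  lam <- config$readout$ridge_lambda
  if (ds$task_kind == "pattern_classification") {
    ev <- evaluate_classification(rc, ds, ridge_lambda = lam,
                                  cv = isTRUE(config$readout$cv),
                                  fold_size = config$readout$fold_size %||% 25)
    score <- ev$error
    metric <- "wta_error"
  } else {
    ev <- evaluate_prediction(rc, ds, ridge_lambda = lam)
    score <- ev$nmse
    metric <- "nmse"
  }
  out <- list(task_kind = ds$task_kind, metric = metric, score = score,
              seed = seed, digest = config_digest(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(
      data.frame(task_kind = out$task_kind, metric = metric, score = score,
                 seed = seed, digest = out$digest),
      file.path(out_dir, "run.csv"), row.names = FALSE)
  }
  c(out, list(details = ev))
}

#' Sweep the operating point phi
#'
#' Evaluates a prediction task and a classification task over a grid of
#' offset phases of the sin^2 node, attaching the analytic slope and
#' curvature of the response at each operating point (the autonomous fixed
#' point). Moving `phi` trades the linear response (slope, hence memory)
#' against the nonlinearity (curvature, hence dimensional expansion):
#' prediction favours slope, classification favours curvature.
#'
#' @param config Nested config list; `config$reservoir$family` must be
#'   `"ikeda_sin2"`.
#' @param grid Numeric vector of phi values (radians).
#' @param repeats Independent repeats per grid point (fresh mask, input and
#'   noise seeds derived from `config$seed`).
#' @return A data.frame with one row per grid point: `phi`, `slope`,
#'   `curvature`, `nmse_mean`, `nmse_se`, `class_err_mean`, `class_err_se`,
#'   `repeats`; per-run results in `attr(, "runs")`.
#' @export
sweep_phi <- function(config = default_config(), grid, repeats = 5) {
  stopifnot(length(grid) >= 1, repeats >= 1)
  if ((config$reservoir$family %||% "ikeda_sin2") != "ikeda_sin2") {
    stop("phi sweep requires the ikeda_sin2 family", call. = FALSE)
  }
  seeds <- derive_seeds(config$seed %||% 1, repeats)
  runs <- list()
  for (gi in seq_along(grid)) {
    phi <- grid[gi]
    ropts <- config$reservoir
    ropts$phi <- phi
    for (r in seq_len(repeats)) {
      rc <- build_config(ropts, seed = seeds[r])
      xstar <- solve_fixed_point(rc$node, 0)
      sc <- local_slope_curvature(rc$node, xstar)
      pred_ds <- make_chaotic_series(config$task$length %||% 2000,
                                     seed = seeds[r])
      cls_ds <- make_pattern_classification(
        n_items = config$task$n_items %||% 300,
        n_classes = config$task$n_classes %||% 10,
        item_length = config$task$item_length %||% 20,
        n_channels = config$task$n_channels %||% 16,
        noise_sd = config$task$noise_sd %||% 0.3, seed = seeds[r])
      nm <- tryCatch(
        evaluate_prediction(rc, pred_ds,
                            ridge_lambda = config$readout$ridge_lambda)$nmse,
        error = function(e) NA_real_)
      er <- tryCatch(
        evaluate_classification(rc, cls_ds,
                                ridge_lambda = config$readout$ridge_lambda)$error,
        error = function(e) NA_real_)
      runs[[length(runs) + 1L]] <- data.frame(
        phi = phi, repeat_ = r, seed = seeds[r],
        slope = unname(sc["slope"]), curvature = unname(sc["curvature"]),
        nmse = nm, class_err = er, failed = is.na(nm) || is.na(er))
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$phi), function(d) {
    data.frame(phi = d$phi[1], slope = d$slope[1], curvature = d$curvature[1],
               nmse_mean = mean(d$nmse, na.rm = TRUE),
               nmse_se = stats::sd(d$nmse, na.rm = TRUE) / sqrt(sum(!is.na(d$nmse))),
               class_err_mean = mean(d$class_err, na.rm = TRUE),
               class_err_se = stats::sd(d$class_err, na.rm = TRUE) /
                 sqrt(sum(!is.na(d$class_err))),
               repeats = nrow(d))
  }))
  agg <- agg[order(agg$phi), ]
  rownames(agg) <- NULL
  attr(agg, "runs") <- runs
  agg
}

#' Trend summary of a phi sweep
#'
#' Spearman rank correlations between the magnitude of the local response
#' derivatives and task performance (negated error, so positive values mean
#' "more of this property helps"): `slope_vs_prediction` between `|slope|`
#' and prediction performance, `curvature_vs_classification` between
#' `|curvature|` and classification performance.
#'
#' @param sweep A data.frame from [sweep_phi()].
#' @return Named numeric vector of the two rank correlations.
#' @export
sweep_phi_trends <- function(sweep) {
  c(slope_vs_prediction =
      stats::cor(abs(sweep$slope), -sweep$nmse_mean, method = "spearman"),
    curvature_vs_classification =
      stats::cor(abs(sweep$curvature), -sweep$class_err_mean,
                 method = "spearman"))
}

#' Sweep the reservoir size N
#'
#' Classification error as a function of the number of virtual nodes, in
#' two modes: `"resize"` builds a reservoir of `N` nodes and reads all of
#' them out; `"subset"` builds one reservoir of `total_N` nodes and exposes
#' only `N` randomly chosen nodes to the readout. Comparing the modes shows
#' whether a large reservoir with partial readout access beats a small
#' reservoir. Means and standard errors are taken over `repeats`
#' realizations (fresh mask/input seeds).
#'
#' @param config Nested config list.
#' @param N_grid Integer vector of reservoir (or readout-subset) sizes.
#' @param repeats Realizations per grid point.
#' @param modes Subset of `c("resize", "subset")`.
#' @param total_N Full reservoir size for `"subset"` mode (default 400).
#' @return A data.frame with one row per `(N, mode)`: `err_mean`, `err_se`,
#'   `repeats`; per-run results in `attr(, "runs")`.
#' @export
sweep_N <- function(config = default_config(), N_grid = c(10, 25, 50, 100, 200, 400),
                    repeats = 10, modes = c("resize", "subset"),
                    total_N = 400) {
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(all(N_grid >= 1), repeats >= 1)
  if (any(N_grid > total_N) && "subset" %in% modes) {
    stop("subset sizes cannot exceed the full reservoir size", call. = FALSE)
  }
  seeds <- derive_seeds(config$seed %||% 1, repeats)
  runs <- list()
  for (r in seq_len(repeats)) {
    cls_ds <- make_pattern_classification(
      n_items = config$task$n_items %||% 300,
      n_classes = config$task$n_classes %||% 10,
      item_length = config$task$item_length %||% 20,
      n_channels = config$task$n_channels %||% 16,
      noise_sd = config$task$noise_sd %||% 0.3, seed = seeds[r])
    if ("subset" %in% modes) {
      ropts <- config$reservoir
      ropts$N <- total_N
      rc_full <- build_config(ropts, seed = seeds[r])
      res_full <- run_items(rc_full, cls_ds$inputs)
    }
    for (N in N_grid) {
      if ("resize" %in% modes) {
        ropts <- config$reservoir
        ropts$N <- N
        rc <- build_config(ropts, seed = seeds[r])
        err <- tryCatch(
          evaluate_classification(rc, cls_ds,
                                  ridge_lambda = config$readout$ridge_lambda)$error,
          error = function(e) NA_real_)
        runs[[length(runs) + 1L]] <- data.frame(
          N = N, mode = "resize", repeat_ = r, seed = seeds[r], err = err)
      }
      if ("subset" %in% modes) {
        subset_idx <- with_seed(seeds[r] + N, sample.int(total_N, N))
        err <- tryCatch(
          classification_error_from_states(res_full, cls_ds,
                                           node_subset = subset_idx,
                                           ridge_lambda = config$readout$ridge_lambda),
          error = function(e) NA_real_)
        runs[[length(runs) + 1L]] <- data.frame(
          N = N, mode = "subset", repeat_ = r, seed = seeds[r], err = err)
      }
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, list(runs$N, runs$mode), drop = TRUE),
                               function(d) {
    data.frame(N = d$N[1], mode = d$mode[1],
               err_mean = mean(d$err, na.rm = TRUE),
               err_se = stats::sd(d$err, na.rm = TRUE) / sqrt(sum(!is.na(d$err))),
               repeats = nrow(d))
  }))
  agg <- agg[order(agg$mode, agg$N), ]
  rownames(agg) <- NULL
  attr(agg, "runs") <- runs
  agg
}

# Classification evaluation from precomputed item states (used by the
# subset mode of sweep_N to avoid re-running the full reservoir per N).
classification_error_from_states <- function(res, dataset, node_subset = NULL,
                                             ridge_lambda = NULL) {
  S <- res$states
  if (!is.null(node_subset)) S <- S[node_subset, , drop = FALSE]
  n_classes <- max(dataset$labels)
  tr_items <- dataset$split$train
  te_items <- dataset$split$test
  tr_steps <- which(res$item_of %in% tr_items)
  Y <- matrix(0, length(tr_steps), n_classes)
  Y[cbind(seq_along(tr_steps), dataset$labels[res$item_of[tr_steps]])] <- 1
  Str <- S[, tr_steps, drop = FALSE]
  lam <- ridge_lambda %||% (1e-3 * mean(rowSums(Str^2)))
  model <- readout_train(Str, Y, ridge_lambda = lam)
  te_steps <- which(res$item_of %in% te_items)
  out <- readout_predict(model, S[, te_steps, drop = FALSE])
  pred <- wta_classify(out, res$item_of[te_steps])
  error_rate(unname(pred), dataset$labels[te_items])
}

#' Write a sweep table as CSV and JSON
#'
#' @param table A data.frame from [sweep_phi()] or [sweep_N()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return The directory, invisibly.
#' @export
write_results <- function(table, dir, name = "sweep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
  runs <- attr(table, "runs")
  if (!is.null(runs)) {
    utils::write.csv(runs, file.path(dir, paste0(name, "_runs.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(table, file.path(dir, paste0(name, ".json")),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Transient-response demonstration
#'
#' Reproduces the textbook demonstration of the masked input and the
#' nonlinear transient response: a sin^2 node (`tau = 10`, `beta = 0.7`,
#' `phi = -pi/4`), 50 virtual nodes at `theta = 0.2`, driven by 10 samples
#' of a periodic input expanded through a random binary mask. Writes the
#' pseudo-space input matrix and the response state matrix as CSV when
#' `out_dir` is given.
#'
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param keep_warmup Also return/write the response including warmup spans.
#' @param seed Mask seed.
#' @return List with `input_matrix` (50 x 10), `response` (`state_matrix`),
#'   and optionally `response_with_warmup`.
#' @export
demo_transient <- function(out_dir = NULL, keep_warmup = FALSE, seed = 1) {
  node <- node_params("ikeda_sin2", beta = 0.7, phi = -pi / 4, tau = 10)
  cfg <- reservoir_config(node, N = 50, seed = seed, gamma = 1)
  u <- sin(2 * pi * (0:9) / 10)
  u_run <- c(rep(0, 3), u) # 3 warmup spans ahead of the 10 shown samples
  drive <- multiplex(u, cfg$mask, theta = cfg$theta, gamma = cfg$gamma)
  inp <- pseudo_space_matrix(drive)
  resp <- reservoir_run(cfg, u_run)
  out <- list(input_matrix = inp, response = resp)
  if (keep_warmup) {
    out$response_with_warmup <- reservoir_run(cfg, u_run, keep_warmup = TRUE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(inp),
                     file.path(out_dir, "input_pseudo_space.csv"),
                     row.names = FALSE)
    write_state_matrix_csv(resp, file.path(out_dir, "response_matrix.csv"))
    if (keep_warmup) {
      write_state_matrix_csv(out$response_with_warmup,
                             file.path(out_dir, "response_matrix_warmup.csv"))
    }
  }
  out
}
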