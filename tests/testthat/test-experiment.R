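# Config handling, experiment runner, phi and N sweeps, seed management.

small_sweep_config <- function(seed = 9) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$reservoir$N <- 20
  cfg$reservoir$tau <- 10
  cfg$task$length <- 500
  cfg$task$n_items <- 60
  cfg$task$n_classes <- 6
  cfg$task$item_length <- 10
  cfg$task$n_channels <- 8
  cfg
}

test_that("config files merge over the defaults", {
  base <- default_config()
  expect_equal(load_config(NULL), base)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 7", "reservoir:", "  N: 31", "task:", "  kind: narma10"),
             path)
  cfg <- load_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$reservoir$N, 31)
  expect_equal(cfg$task$kind, "narma10")
  # untouched defaults survive
  expect_equal(cfg$reservoir$gamma, base$reservoir$gamma)
})

test_that("derived seeds are deterministic, distinct and below 2^31", {
  s1 <- delayrc:::derive_seeds(5, 10)
  s2 <- delayrc:::derive_seeds(5, 10)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0L)
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_false(identical(delayrc:::derive_seeds(6, 10), s1))
})

test_that("run_experiment writes reproducible reports", {
  cfg <- small_sweep_config()
  cfg$task <- list(kind = "one_step_prediction", length = 400)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_experiment(cfg, out_dir = d1)
  r2 <- run_experiment(cfg, out_dir = d2)
  expect_equal(r1$score, r2$score)
  expect_true(file.exists(file.path(d1, "run.json")))
  expect_identical(readLines(file.path(d1, "run.json")),
                   readLines(file.path(d2, "run.json")))
  expect_identical(readLines(file.path(d1, "run.csv")),
                   readLines(file.path(d2, "run.csv")))
  rep_ <- jsonlite::read_json(file.path(d1, "run.json"))
  expect_equal(rep_$metric, "nmse")
  expect_true(is.numeric(rep_$score))
  expect_match(rep_$digest, "^[0-9a-f]{8}$")
})

test_that("phi sweep reports per-point derivatives and aggregated scores", {
  cfg <- small_sweep_config()
  grid <- c(-pi / 4, 0)
  sw <- suppressWarnings(sweep_phi(cfg, grid, repeats = 2))
  expect_equal(nrow(sw), 2)
  expect_equal(sw$phi, sort(grid))
  runs <- attr(sw, "runs")
  expect_equal(nrow(runs), 2 * 2)
  expect_true(all(c("seed", "nmse", "class_err") %in% names(runs)))

  # slope/curvature columns agree with the analytic derivatives at the
  # autonomous operating point
  for (i in 1:2) {
    node <- node_params("ikeda_sin2", beta = cfg$reservoir$beta,
                        phi = sw$phi[i], tau = cfg$reservoir$tau)
    sc <- local_slope_curvature(node, solve_fixed_point(node, 0))
    expect_equal(sw$slope[i], unname(sc["slope"]))
    expect_equal(sw$curvature[i], unname(sc["curvature"]))
  }

  # grid {-pi/4, 0} for phi applied at a = 0: slope magnitudes (beta, 0),
  # curvatures (0, 2 beta) by the sin^2 derivatives
  b <- cfg$reservoir$beta
  sc0 <- local_slope_curvature(node_params("ikeda_sin2", beta = b,
                                           phi = -pi / 4, tau = 10), 0)
  expect_equal(unname(abs(sc0["slope"])), b)
  expect_equal(unname(sc0["curvature"]), 0, tolerance = 1e-12)
  sc1 <- local_slope_curvature(node_params("ikeda_sin2", beta = b, phi = 0,
                                           tau = 10), 0)
  expect_equal(unname(sc1["slope"]), 0)
  expect_equal(unname(sc1["curvature"]), 2 * b)
})

test_that("N sweep covers both readout modes and matches at full readout", {
  cfg <- small_sweep_config()
  cfg$reservoir$theta <- 0.5
  sw <- suppressWarnings(sweep_N(cfg, N_grid = c(5, 40), repeats = 2,
                                 total_N = 40))
  expect_equal(nrow(sw), 4) # one row per (N, mode)
  expect_setequal(unique(sw$mode), c("resize", "subset"))
  # at N = total_N the two modes are the same configuration
  full <- sw[sw$N == 40, ]
  expect_equal(full$err_mean[1], full$err_mean[2], tolerance = 0.3)
  expect_error(suppressWarnings(
    sweep_N(cfg, N_grid = c(10, 80), repeats = 1, total_N = 40)),
    "cannot exceed")
})

test_that("single-node subset of a 10-class reservoir is near chance", {
  cfg <- small_sweep_config()
  cfg$reservoir$theta <- 0.5
  cfg$task$n_items <- 100
  cfg$task$n_classes <- 10
  sw <- suppressWarnings(sweep_N(cfg, N_grid = c(1), repeats = 3,
                                 total_N = 40, modes = "subset"))
  # chance level for 10 balanced classes is 0.9
  expect_gt(sw$err_mean, 0.7)
})

test_that("sweep results serialize to CSV and JSON", {
  cfg <- small_sweep_config()
  sw <- suppressWarnings(sweep_phi(cfg, c(0, 0.3), repeats = 1))
  dir <- withr::local_tempdir()
  write_results(sw, dir, name = "phi")
  expect_true(all(file.exists(file.path(dir, c("phi.csv", "phi_runs.csv",
                                               "phi.json")))))
  back <- utils::read.csv(file.path(dir, "phi.csv"))
  expect_equal(back$phi, sw$phi)
})

test_that("demo emits the pseudo-space input and response matrices", {
  dir <- withr::local_tempdir()
  demo <- demo_transient(out_dir = dir, keep_warmup = TRUE)
  expect_equal(dim(demo$input_matrix), c(50, 10))
  expect_equal(dim(demo$response$values), c(50, 10))
  expect_equal(dim(demo$response_with_warmup$values), c(50, 13))
  expect_true(all(file.exists(file.path(dir, c(
    "input_pseudo_space.csv", "response_matrix.csv",
    "response_matrix_warmup.csv")))))
  # the warmup view ends in the same columns as the trimmed view
  expect_equal(demo$response_with_warmup$values[, 4:13],
               demo$response$values)
})
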