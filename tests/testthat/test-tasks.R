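# Synthetic benchmark generators and the series-file loader.

test_that("NARMA-10 under zero input settles at the analytic fixed point", {
  # independent oracle: fixed-point iteration of
  # y = 0.3 y + 0.05 y (10 y) + 0.1
  y <- 0
  for (i in 1:500) y <- 0.3 * y + 0.5 * y^2 + 0.1
  # which is the smaller root of 0.5 y^2 - 0.7 y + 0.1 = 0
  expect_equal(y, 0.7 - sqrt(0.49 - 0.2), tolerance = 1e-12)

  traj <- delayrc:::narma10_recurrence(rep(0, 500))
  expect_equal(traj[500], y, tolerance = 1e-6)
})

test_that("NARMA-10 targets match a direct recurrence oracle", {
  ds <- make_narma10(300, seed = 8)
  u <- ds$inputs
  y <- ds$targets
  # independent re-implementation of the step for a few positions
  for (k in c(10, 57, 150)) {
    y_next <- 0.3 * y[k] + 0.05 * y[k] * sum(y[(k - 9):k]) +
      1.5 * u[k - 9] * u[k] + 0.1
    expect_equal(y[k + 1], y_next)
  }
  expect_true(max(abs(y)) <= 10)
  expect_identical(make_narma10(300, seed = 8)$targets, y)
  expect_false(identical(make_narma10(300, seed = 9)$targets, y))
})

test_that("NARMA-10 depends on inputs only up to lag 9", {
  set.seed(41)
  u <- runif(60, 0, 0.5)
  y <- delayrc:::narma10_recurrence(u)
  k <- 40
  # permute early inputs but keep the y-history and the lag-0/lag-9 inputs
  u2 <- u
  u2[1:(k - 10)] <- sample(u2[1:(k - 10)])
  y_next <- 0.3 * y[k] + 0.05 * y[k] * sum(y[(k - 9):k]) +
    1.5 * u2[k - 9] * u2[k] + 0.1
  expect_equal(y[k + 1], y_next)
})

test_that("chaotic series is standardized, aperiodic-looking and reproducible", {
  ds <- make_chaotic_series(1500, seed = 5)
  s <- c(ds$inputs, ds$targets[length(ds$targets)])
  expect_equal(mean(s), 0, tolerance = 1e-6)
  expect_equal(stats::sd(s), 1, tolerance = 1e-6)
  expect_equal(ds$inputs[-1], ds$targets[-length(ds$targets)]) # shift by one
  expect_identical(make_chaotic_series(1500, seed = 5)$inputs, ds$inputs)
  # bounded and not constant
  expect_true(all(abs(s) < 10))
})

test_that("reservoir prediction beats the persistence baseline on the chaotic series", {
  ds <- make_chaotic_series(1200, seed = 6)
  te <- ds$split$test
  nmse_persistence <- nmse(ds$inputs[te], ds$targets[te])
  expect_gt(nmse_persistence, 0)
  expect_lt(nmse_persistence, 2)
  node <- node_params("ikeda_sin2", beta = 0.9, phi = pi / 4 - 0.45, tau = 25)
  cfg <- reservoir_config(node, N = 50, seed = 6, gamma = 0.5)
  ev <- evaluate_prediction(cfg, ds)
  expect_lt(ev$nmse, nmse_persistence)
})

test_that("pattern classification set is balanced, reproducible and separable when clean", {
  ds <- make_pattern_classification(n_items = 100, n_classes = 10,
                                    item_length = 12, n_channels = 8,
                                    noise_sd = 0.3, seed = 2)
  expect_equal(dim(ds$inputs), c(8, 12, 100))
  expect_equal(as.integer(table(ds$labels)), rep(10L, 10))
  expect_length(intersect(ds$split$train, ds$split$test), 0)
  expect_equal(sort(c(ds$split$train, ds$split$test)), 1:100)
  ds2 <- make_pattern_classification(n_items = 100, n_classes = 10,
                                     item_length = 12, n_channels = 8,
                                     noise_sd = 0.3, seed = 2)
  expect_identical(ds$inputs, ds2$inputs)

  # noiseless items are their class envelope up to carrier sign and amplitude
  ds0 <- make_pattern_classification(n_items = 40, n_classes = 4,
                                     item_length = 10, n_channels = 6,
                                     noise_sd = 0, amp_jitter_sd = 0, seed = 3)
  tpl <- ds0$extras$templates
  for (i in c(1, 17, 40)) {
    expect_equal(abs(ds0$inputs[, , i]), tpl[, , ds0$labels[i]])
  }
  # and a nonlinear reservoir separates them perfectly
  node <- node_params("ikeda_sin2", beta = 1, phi = 0, tau = 25)
  cfg <- reservoir_config(node, N = 50, seed = 3, gamma = 1,
                          mask = generate_mask(50, "multivalued", seed = 3))
  ev <- evaluate_classification(cfg, ds0)
  expect_equal(ev$error, 0)

  expect_error(make_pattern_classification(n_items = 101, n_classes = 10),
               "divisible")
  expect_error(make_pattern_classification(noise_sd = -1), ">= 0")
})

test_that("classification difficulty is monotone in the noise level", {
  node <- node_params("ikeda_sin2", beta = 1, phi = 0, tau = 10)
  cfg <- reservoir_config(node, N = 20, seed = 1, gamma = 1,
                          mask = generate_mask(20, "multivalued", seed = 1))
  errs <- sapply(c(0.1, 0.5, 1.5), function(ns) {
    mean(sapply(1:5, function(s) {
      ds <- make_pattern_classification(n_items = 60, n_classes = 6,
                                        item_length = 10, n_channels = 8,
                                        noise_sd = ns, seed = 50 + s)
      evaluate_classification(cfg, ds)$error
    }))
  })
  expect_true(all(diff(errs) >= 0))
})

test_that("task datasets round-trip through their CSV bundle", {
  ds <- make_narma10(300, seed = 8)
  dir <- withr::local_tempdir()
  write_task_dataset(ds, dir)
  back <- read_task_dataset(dir)
  expect_equal(back$inputs, ds$inputs)
  expect_equal(back$targets, ds$targets)
  expect_equal(back$split, ds$split)
  expect_equal(back$task_kind, ds$task_kind)

  dc <- make_pattern_classification(n_items = 20, n_classes = 4,
                                    item_length = 6, n_channels = 3,
                                    noise_sd = 0.2, seed = 5)
  dir2 <- withr::local_tempdir()
  write_task_dataset(dc, dir2)
  back2 <- read_task_dataset(dir2)
  expect_equal(back2$inputs, dc$inputs)
  expect_equal(back2$labels, dc$labels)
})

test_that("series files load with exact alignment and clear errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "2", "3"), path)
  ds <- load_series_file(path, standardize = FALSE)
  expect_equal(ds$inputs, c(1, 2))
  expect_equal(ds$targets, c(2, 3))

  # round trip through a written series
  ds0 <- make_chaotic_series(300, seed = 1)
  s <- c(ds0$inputs, ds0$targets[length(ds0$targets)])
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(s, digits = 17), path2)
  back <- load_series_file(path2, standardize = FALSE)
  expect_equal(back$inputs, ds0$inputs, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.5", "oops", "2"), bad)
  expect_error(load_series_file(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(load_series_file(empty), "at least two")
})
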