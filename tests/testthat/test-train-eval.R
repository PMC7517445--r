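# training loop, schedule, evaluation runner and the CLI

test_that("poly schedule hits its endpoints and midpoint", {
  cfg <- train_config(base_lr = 2e-4, max_iter = 1000L)
  expect_identical(poly_lr(0, cfg), 2e-4)
  expect_identical(poly_lr(1000, cfg), 0)
  expect_equal(poly_lr(500, cfg), 2e-4 * 0.5^0.9, tolerance = 1e-12)
  lrs <- vapply(0:1000, poly_lr, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_warning(z <- poly_lr(1001, cfg), "clamped")
  expect_identical(z, 0)
  expect_error(poly_lr(0, train_config()), "max_iter")
})

test_that("a zero learning-rate Adam step leaves parameters unchanged", {
  net <- build_network(network_config_test(), seed = 1)
  for (p in net$params) p$grad[] <- 1          # pretend gradients arrived
  st <- acaunet:::adam_state(net$params)
  before <- get_network_weights(net)
  acaunet:::adam_step(net$params, st, lr = 0, t = 1, cfg = train_config())
  expect_identical(get_network_weights(net), before)
})

test_that("loss decreases over the first iterations of the tiny fixture", {
  ds <- desk_dataset(4, 64, seed = 7)
  net <- build_network(network_config_test(), seed = 1)
  fit <- train(net, ds, train_config_desk(iterations = 10, n_samples = 4))
  expect_identical(nrow(fit$history), 10L)
  expect_lt(fit$history$loss[10], fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("two seeded runs produce identical loss traces", {
  ds <- desk_dataset(4, 64, seed = 7)
  cfg <- train_config_desk(iterations = 6, n_samples = 4)
  f1 <- train(build_network(network_config_test(), seed = 1), ds, cfg)
  f2 <- train(build_network(network_config_test(), seed = 1), ds, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
})

test_that("the validation split records per-epoch overlapping error", {
  ds <- desk_dataset(5, 64, seed = 8)
  cfg <- train_config(base_lr = 1e-3, epochs = 2, batch_size = 2,
                      val_fraction = 0.2, seed = 1)
  fit <- train(build_network(network_config_test(), seed = 1), ds, cfg)
  expect_identical(nrow(fit$val_history), 2L)
  expect_true(all(fit$val_history$mean_E >= 0 & fit$val_history$mean_E <= 1))
})

test_that("evaluate scores oracle and degenerate predictors correctly", {
  ds <- desk_dataset(3, 32, seed = 9)
  oracle <- function(pair) pair$mask
  ev <- evaluate(oracle, ds)
  expect_equal(ev$summary$mean_E, 0)
  zeros <- function(pair) array(0, dim(pair$mask))
  ev0 <- evaluate(zeros, ds)
  expect_true(all(ev0$metrics$E == 1))
  expect_error(evaluate(oracle, list()), "empty")
})

test_that("evaluate reproduces a confusion-count example and writes CSV", {
  truth <- matrix(0, 4, 4); truth[1:3, 1:3] <- 1; truth[4, 1:2] <- 1
  pred <- matrix(0, 4, 4); pred[1:3, 1:3] <- 0.9; pred[4, 4] <- 0.9
  pair <- structure(list(image = array(0, c(4, 4, 3)), mask = truth,
                         id = "hand"), class = "sample_pair")
  csv <- withr::local_tempfile(fileext = ".csv")
  ev <- evaluate(function(p) pred, list(pair), csv = csv)
  expect_equal(ev$metrics$E, 0.25)
  got <- read.csv(csv)
  expect_equal(got$E, 0.25)
  expect_identical(got$image_id, "hand")
})

test_that("the sweep emits one row per grid point with pure-loss endpoints", {
  ds <- desk_dataset(3, 32, seed = 10)
  res <- sweep_hyper(ds, pks = c(1, 5), alphas = c(0, 1),
                     make_config = function(pk)
                       network_config_test(input_size = 32, pk = pk),
                     train_cfg = train_config(base_lr = 1e-3, epochs = 2,
                                              batch_size = 3, val_fraction = 0,
                                              seed = 2))
  expect_identical(nrow(res), 4L)
  expect_setequal(res$pk, c(1, 5))
  expect_true(all(res$mean_E >= 0 & res$mean_E <= 1))
})

test_that("alpha endpoints of the training loss equal the pure losses", {
  ds <- desk_dataset(2, 32, seed = 11)
  batch <- acaunet:::stack_batch(ds)
  net <- build_network(network_config_test(input_size = 32), seed = 3)
  p <- net_forward(net, batch$x)
  ce <- mean(vapply(1:2, function(n)
    cross_entropy(p[, , , n], batch$t[, , , n]), numeric(1)))
  dd <- mean(vapply(1:2, function(n)
    1 - dice_coefficient(p[, , , n], batch$t[, , , n], S = 1), numeric(1)))
  ag <- asNamespace("acaunet")
  l1 <- ag$ag_combined_loss(ag$ag_input(p), batch$t, alpha = 1)$value
  l0 <- ag$ag_combined_loss(ag$ag_input(p), batch$t, alpha = 0)$value
  expect_equal(as.numeric(l1), ce, tolerance = 1e-12)
  expect_equal(as.numeric(l0), dd, tolerance = 1e-12)
})

test_that("the CLI generates, trains, evaluates and sweeps end to end", {
  root <- withr::local_tempdir()
  data_dir <- file.path(root, "d")
  out_dir <- file.path(root, "run")
  expect_identical(acau_cli(c("generate", "--n", "4", "--size", "64",
                              "--seed", "7", "--out", data_dir)), 0L)
  expect_length(list.files(file.path(data_dir, "images")), 4L)
  suppressMessages(expect_identical(
    acau_cli(c("train", "--data", data_dir, "--test-profile",
               "--epochs", "2", "--seed", "1", "--out", out_dir)), 0L))
  expect_true(file.exists(file.path(out_dir, "weights.rds")))
  expect_true(file.exists(file.path(out_dir, "history.csv")))
  expect_identical(
    acau_cli(c("evaluate", "--data", data_dir, "--test-profile",
               "--weights", file.path(out_dir, "weights.rds"),
               "--out", out_dir)), 0L)
  expect_true(file.exists(file.path(out_dir, "metrics.csv")))
  expect_identical(
    acau_cli(c("predict", "--data", data_dir, "--test-profile",
               "--weights", file.path(out_dir, "weights.rds"),
               "--out", out_dir)), 0L)
  expect_length(list.files(out_dir, pattern = "_pred\\.png$"), 4L)
  # unknown subcommand fails with usage
  expect_identical(suppressMessages(acau_cli(c("frobnicate"))), 1L)
})

test_that("a NaN-poisoned run aborts naming the iteration", {
  ds <- desk_dataset(2, 32, seed = 12)
  net <- build_network(network_config_test(input_size = 32), seed = 1)
  net$params[[1]]$value[] <- NaN
  expect_error(train(net, ds, train_config_desk(iterations = 2, n_samples = 2)),
               "non-finite loss at iteration")
})
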