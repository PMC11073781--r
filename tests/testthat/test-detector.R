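fp <- asNamespace("fetalpeaks")

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(42)
  B <- 3; T_ <- 4; D <- 2
  params <- fp$init_bilstm_params(D, c(3, 2), 2)
  X <- array(rnorm(B * T_ * D), c(B, T_, D))
  y <- c(0L, 1L, 0L)
  w <- c(w0 = 0.7, w1 = 2.1)
  loss_fn <- function(p) {
    fwd <- fp$bilstm_forward(X, p, training = FALSE)
    fp$weighted_ce(fwd$p, y, w)$loss
  }
  fwd <- fp$bilstm_forward(X, params, training = FALSE)
  lo <- fp$weighted_ce(fwd$p, y, w)
  analytic <- fp$flatten_params(fp$bilstm_backward(fwd, lo$dlogits, params))
  flat <- fp$flatten_params(params)
  eps <- 1e-6
  for (nm in names(flat)) {
    for (i in sample(length(flat[[nm]]), min(4, length(flat[[nm]])))) {
      up <- flat; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- flat; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_fn(fp$unflatten_params(up, params)) -
                loss_fn(fp$unflatten_params(dn, params))) / (2 * eps)
      expect_lt(abs(num - analytic[[nm]][i]) /
                  max(1e-8, abs(num) + abs(analytic[[nm]][i])), 1e-4)
    }
  }
})

test_that("network description has dimensionally consistent weight shapes", {
  tiny <- build_network(detector_config(hidden_sizes = c(1, 1, 1)))
  first <- tiny[tiny$layer == "bilstm_1" & tiny$parameter == "input_weights", ]
  expect_equal(c(first$rows, first$cols), c(8, 12))
  # every recurrent layer: input weights 8H x D_in, recurrent 8H x H
  cfg <- detector_config(hidden_sizes = c(7, 5, 3))
  net <- build_network(cfg)
  d <- 12
  for (l in 1:3) {
    h <- cfg$hidden_sizes[l]
    iw <- net[net$layer == sprintf("bilstm_%d", l) & net$parameter == "input_weights", ]
    rw <- net[net$layer == sprintf("bilstm_%d", l) & net$parameter == "recurrent_weights", ]
    expect_equal(c(iw$rows, iw$cols), c(8 * h, d))
    expect_equal(c(rw$rows, rw$cols), c(8 * h, h))
    d <- 2 * h
  }
  fc <- net[net$layer == "fully_connected" & net$parameter == "weights", ]
  expect_equal(c(fc$rows, fc$cols), c(2, 2 * 3))
  expect_error(detector_config(hidden_sizes = c(0, 4)), class = "fetalpeaks_config_error")
})

test_that("untrained loss sits at the weighted-coin-flip value", {
  set.seed(10)
  n <- 200
  labels <- rbinom(n, 1, 0.2)
  if (sum(labels) == 0) labels[1] <- 1
  frames <- make_frames(array(rnorm(n * 65 * 12), c(n, 65, 12)), labels)
  w <- class_weights(labels)
  expected <- mean(w[labels + 1]) * log(2)
  got <- initial_loss(frames, detector_config(hidden_sizes = c(8, 4, 2)),
                      train_schedule(seed = 3))
  expect_lt(abs(got - expected) / expected, 0.10)
})

test_that("a planted separable signal is learned almost perfectly", {
  set.seed(11)
  n <- 240
  labels <- rbinom(n, 1, 0.25)
  x <- array(rnorm(n * 65 * 12, sd = 0.5), c(n, 65, 12))
  x[, , 1] <- labels # channel 1 broadcasts the label
  frames <- make_frames(x, labels)
  train_idx <- 1:180
  test_idx <- 181:240
  fit <- fit_detector(make_frames(x[train_idx, , ], labels[train_idx]),
                      detector_config(hidden_sizes = c(8, 4, 2)),
                      train_schedule(epochs = 20, batch_size = 16, seed = 5,
                                     initial_lr = 2e-3))
  expect_gte(tail(fit$history$accuracy, 1), 0.99)
  pred <- predict(fit, make_frames(x[test_idx, , ], labels[test_idx]))
  expect_gte(mean(pred$pred == labels[test_idx]), 0.99)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(2)
  n <- 60
  labels <- rep(c(0L, 1L), 30)
  x <- array(rnorm(n * 65 * 12), c(n, 65, 12))
  f <- make_frames(x, labels)
  cfg <- detector_config(hidden_sizes = c(4, 3, 2))
  sch <- train_schedule(epochs = 2, batch_size = 16, seed = 99)
  fit1 <- fit_detector(f, cfg, sch)
  fit2 <- fit_detector(f, cfg, sch)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$params, fit2$params)
})

test_that("posteriors are normalized and predictions match input arity", {
  set.seed(7)
  n <- 40L
  x <- array(rnorm(n * 65 * 12), c(n, 65, 12))
  params <- fp$init_bilstm_params(12, c(4, 3, 2), 2)
  fwd <- fp$bilstm_forward(x, params, training = FALSE, keep_cache = FALSE)
  expect_true(all(abs(rowSums(fwd$p) - 1) < 1e-6))

  labels <- rep(c(0L, 1L), n / 2)
  f <- make_frames(x, labels)
  fit <- fit_detector(f, detector_config(hidden_sizes = c(4, 3, 2)),
                      train_schedule(epochs = 1, batch_size = 20, seed = 1))
  pred <- predict(fit, f)
  expect_identical(nrow(pred), n)
  expect_true(all(pred$p1 >= 0 & pred$p1 <= 1))

  bad <- make_frames(array(rnorm(10 * 65 * 5), c(10, 65, 5)), rep(0:1, 5))
  expect_error(predict(fit, bad), class = "fetalpeaks_shape_error")
})

test_that("the learning rate drops exactly once, by the configured factor", {
  sch <- train_schedule(epochs = 15, initial_lr = 5e-4)
  lrs <- vapply(1:15, lr_at, numeric(1), schedule = sch)
  expect_true(all(diff(lrs) <= 0))
  drops <- which(diff(lrs) < 0)
  expect_length(drops, 1)
  expect_equal(lrs[drops + 1] / lrs[drops], 0.1)
  expect_equal(drops, ceiling(15 / 2))
})

test_that("unit class weights reduce the loss to the unweighted cross-entropy", {
  set.seed(8)
  p <- matrix(runif(20), 10, 2)
  p <- p / rowSums(p)
  y <- rbinom(10, 1, 0.5)
  lw <- fp$weighted_ce(p, y, c(1, 1))$loss
  plain <- -mean(log(p[cbind(1:10, y + 1)]))
  expect_equal(lw, plain)
})

test_that("single-class training sets are refused", {
  x <- array(rnorm(20 * 65 * 12), c(20, 65, 12))
  f <- make_frames(x, rep(0L, 20))
  expect_error(fit_detector(f), class = "fetalpeaks_imbalance_error")
})

test_that("tidy and glance summarize the fitted model", {
  set.seed(14)
  n <- 30
  x <- array(rnorm(n * 65 * 12), c(n, 65, 12))
  f <- make_frames(x, rep(c(0L, 1L), n / 2))
  fit <- fit_detector(f, detector_config(hidden_sizes = c(3, 2, 2)),
                      train_schedule(epochs = 1, batch_size = 15, seed = 2))
  td <- tidy(fit)
  expect_true(all(c("parameter", "rows", "cols", "norm") %in% names(td)))
  expect_identical(nrow(td), 3L * 2L * 3L + 2L)
  gl <- glance(fit)
  expect_identical(gl$epochs, 1L)
  expect_equal(gl$w0, 1)
})
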