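test_that("initialization is seeded, shaped by config, and validated", {
  m1 <- narx_model(narx_config(seed = 7))
  m2 <- narx_model(narx_config(seed = 7))
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, narx_model(narx_config(seed = 8))$weights))

  expect_equal(dim(m1$weights$W1), c(20L, 20L))
  expect_equal(dim(m1$weights$W2), c(13L, 20L))
  expect_equal(dim(m1$weights$W3), c(1L, 13L))
  expect_error(narx_config(hidden = c(0, 13)), "positive")
  expect_error(narx_config(n_taps = 0), "n_taps")
})

test_that("one-step forward pass matches the per-neuron oracle", {
  zero <- constant_model(NA, lo = 0, hi = 10)
  zero$weights$b3 <- 0
  # all-zero network: scaled output 0 unscales to the range midpoint
  expect_equal(forward_one_step(zero, rep(4, 20)), 5)

  cm <- constant_model(8.25, lo = 0, hi = 10)
  expect_equal(forward_one_step(cm, rep(1, 20)), 8.25)
  expect_equal(forward_one_step(cm, 20:1), 8.25)

  for (seed in 1:50) {
    m <- random_model(seed)
    taps <- with_seed(seed + 1000, stats::runif(20, 3, 16))
    expect_equal(forward_one_step(m, taps), oracle_forward(m, taps),
                 tolerance = 1e-10)
  }
  expect_error(forward_one_step(random_model(1), rep(5, 19)), "taps")
  expect_error(forward_one_step(narx_model(), rep(5, 20)), "scaler")
})

test_that("closing the loop changes mode only, exactly once", {
  m <- random_model(3)
  cl <- close_loop(m)
  expect_identical(cl$weights, m$weights)
  expect_equal(cl$mode, "closed_loop")
  taps <- rep(8, 20)
  expect_identical(predict_recursive(cl, taps, 1), forward_one_step(m, taps))
  expect_error(close_loop(cl), "already")
  expect_error(predict_recursive(m, taps, 5), "closed")
})

test_that("recursive prediction matches a naive shifting-buffer oracle", {
  cm <- close_loop(constant_model(6.5))
  expect_equal(predict_recursive(cm, with_seed(2, runif(20, 3, 16)), 20),
               rep(6.5, 20))

  for (seed in 1:30) {
    m <- close_loop(random_model(seed))
    taps <- with_seed(seed + 500, stats::runif(20, 3, 16))
    expect_equal(predict_recursive(m, taps, 20),
                 oracle_recursive(m, taps, 20), tolerance = 1e-10)
  }
  expect_error(predict_recursive(close_loop(random_model(1)), rep(5, 20), 21),
               "n_steps")
})

test_that("predictions are bounded by the output layer's reach", {
  # tanh hidden activations lie in (-1,1), so the scaled output can never
  # exceed ||W3||_1 + |b3| in magnitude
  for (seed in 1:20) {
    m <- close_loop(random_model(seed))
    bound <- sum(abs(m$weights$W3)) + abs(m$weights$b3)
    lim <- invert_scaler(m$scaler, c(-bound, bound))
    preds <- predict_recursive(m, with_seed(seed, runif(20, 3, 16)), 20)
    expect_true(all(preds >= lim[1] & preds <= lim[2]))
  }
})

test_that("open-loop training fits a constant and is seed-deterministic", {
  s <- glucose_series((0:79) * 5, rep(7.5, 80) + 1e-6 * (0:79))
  ws <- make_windows(s)
  tc <- train_config(max_epochs = 300, validation_fraction = 0, seed = 1)
  fit <- train_open_loop(narx_model(narx_config(seed = 1)), ws, tc)
  pred <- forward_one_step(fit$model, rep(7.5, 20))
  expect_equal(pred, 7.5, tolerance = 1e-3)
  expect_lte(fit$report$epochs_run, 300)

  fit2 <- train_open_loop(narx_model(narx_config(seed = 1)), ws, tc)
  expect_identical(fit$model$weights, fit2$model$weights)
  expect_identical(fit$report, fit2$report)

  expect_error(train_open_loop(narx_model(), list(), tc), "windows")
  closed <- close_loop(random_model(1))
  expect_error(train_open_loop(closed, ws, tc), "open-loop")
})

test_that("teacher forcing unrolls 20 one-step pairs per 40-sample window", {
  w <- list(inputs = as.numeric(1:20) / 10, targets = as.numeric(21:40) / 10)
  up <- glynarx:::unroll_pairs(list(w), 20, "teacher_forced")
  expect_equal(dim(up$X), c(20L, 20L))
  full <- c(w$inputs, w$targets)
  for (k in 1:20) {
    expect_identical(up$X[k, ], full[k:(k + 19)])
    expect_identical(up$y[k], full[k + 20])
  }
  direct <- glynarx:::unroll_pairs(list(w), 20, "direct")
  expect_equal(dim(direct$X), c(1L, 20L))
  expect_identical(direct$y, full[40])
})

test_that("model files round-trip exactly and reject bad schemas", {
  f <- withr::local_tempfile(fileext = ".json")
  m <- close_loop(random_model(13))
  save_narx(m, f)
  back <- load_narx(f)
  expect_identical(back$weights, m$weights)
  expect_identical(back$scaler, m$scaler)
  taps <- with_seed(4, runif(20, 3, 16))
  expect_identical(predict_recursive(back, taps, 20),
                   predict_recursive(m, taps, 20))

  obj <- jsonlite::fromJSON(f)
  obj$scaler <- NULL
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), f)
  expect_error(load_narx(f), "scaler")

  obj <- jsonlite::fromJSON(save_narx(m, f))
  obj$schema <- "glynarx-model/0"
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), f)
  expect_error(load_narx(f), "unsupported")

  expect_error(save_narx(narx_model(), f), "scaler")
  expect_error(load_narx(file.path(tempdir(), "nope.json")), "not found")
})
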