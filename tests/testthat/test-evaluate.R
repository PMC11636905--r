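test_that("sliding evaluation pairs prediction k with truth k steps ahead", {
  # against a literal per-position re-derivation of the protocol
  m <- close_loop(random_model(5))
  s <- generate_profile(sim_config(days = 1, seed = 5))
  s <- glucose_series(s$times[1:120], s$values[1:120])
  ev <- evaluate_horizons(m, s, horizons = c(15, 100), stride = 3)
  for (r in ev$results) {
    k <- r$horizon_minutes / 5
    pos <- seq(1, length(s$values) - 20 - k + 1, by = 3)
    manual_pred <- vapply(pos, function(p)
      predict_recursive(m, s$values[p:(p + 19)], k)[k], numeric(1))
    expect_equal(r$predicted, manual_pred, tolerance = 1e-10)
    expect_identical(r$measured, s$values[pos + 19 + k])
  }
})

test_that("persistence on a linear ramp errs by exactly k * slope", {
  # a sharp alignment check: at horizon k the last tap lags truth by k
  # steps of the ramp, so any off-by-one would shift the error
  d <- 0.01
  s <- glucose_series((0:199) * 5, 5 + d * (0:199))
  pb <- persistence_baseline(s, horizons = c(5, 50, 100))
  for (r in pb$results) {
    k <- r$horizon_minutes / 5
    expect_equal(r$measured - r$predicted, rep(d * k, length(r$measured)),
                 tolerance = 1e-12)
  }
  # and on a constant series the persistence error vanishes
  const <- glucose_series((0:99) * 5, rep(7, 100) + 1e-9 * (0:99))
  expect_lt(rmse(persistence_baseline(const, 5)$results[[1]]), 1e-8)
})

test_that("a perfect predictor scores FIT 100, RMSE 0, zone A 100 at all PHs", {
  s <- generate_profile(sim_config(days = 1, seed = 9))
  v <- s$values
  for (ph in c(15, 60, 100)) {
    k <- ph / 5
    pos <- seq(1, length(v) - 20 - k + 1)
    # oracle stub: returns the true future at every position
    r <- prediction_result(v[pos + 19 + k], v[pos + 19 + k], ph)
    expect_equal(fit_percent(r), 100)
    expect_equal(rmse(r), 0)
    expect_equal(zone_summary(r)$percent[1], 100)
  }
})

test_that("pipeline trains end to end on a short synthetic trace", {
  s <- generate_profile(sim_config(days = 2, seed = 4))
  res <- train_glucose_predictor(
    s$times, s$values, n_test = 150,
    config = narx_config(seed = 4),
    tc = train_config(max_epochs = 120, patience = 40, seed = 4))
  expect_equal(res$model$mode, "closed_loop")
  expect_equal(length(res$test), 150L)
  expect_equal(sum(vapply(res$train_segments, length, integer(1))),
               2 * 288 - 150)
  expect_true(is.finite(res$report$final_val_mse))
  ev <- evaluate_horizons(res$model, res$test, horizons = c(15, 100))
  expect_equal(ev$metrics$ph_min, c(15, 100))
  expect_true(all(is.finite(ev$metrics$rmse_mmol_per_l)))

  expect_error(train_glucose_predictor(s$times, s$values, n_test = 600,
                                       config = narx_config(seed = 1)),
               "n_test")
  expect_error(train_glucose_predictor((0:20) * 5, rep(7, 21)),
               "no usable segments")
})

test_that("scripted entry points write outputs and manifests", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "sim.csv")
  run_simulate(days = 2, seed = 11, out = csv)
  expect_true(file.exists(csv))
  expect_true(file.exists(paste0(csv, ".manifest.json")))
  expect_equal(length(read_cgm_csv(csv)), 576L)

  model_file <- file.path(dir, "model.json")
  run_train(csv, model_file, n_test = 150, seed = 11,
            tc = train_config(max_epochs = 60, patience = 30, seed = 11))
  expect_true(file.exists(model_file))
  m <- load_narx(model_file)
  expect_equal(m$mode, "closed_loop")

  out <- file.path(dir, "eval")
  ev <- run_evaluate(model_file, csv, out, horizons = c(15, 30),
                     n_test = 150, seed = 11)
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "zones.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  tab <- utils::read.csv(file.path(out, "metrics.csv"))
  expect_equal(tab$ph_min, c(15, 30))
})
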