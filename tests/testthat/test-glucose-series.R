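test_that("glucose_series enforces its invariants", {
  expect_s3_class(glucose_series(c(0, 5, 10), c(5, 5.5, 6)), "glucose_series")
  expect_error(glucose_series(c(0, 5), c(5, 5.5, 6)), "length")
  expect_error(glucose_series(c(0, 5, 9), c(5, 5.5, 6)), "uniform")
  expect_error(glucose_series(c(0, 5, 5), c(5, 5.5, 6)), "increasing|uniform")
  expect_error(glucose_series(c(0, 5), c(5, -1)), "finite")
  expect_error(glucose_series(numeric(0), numeric(0)), "at least one")
})

test_that("CSV reading parses both units and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,glucose", "0,5.0", "5,5.5", "10,6.0"), f)
  s <- read_cgm_csv(f)
  expect_equal(s$values, c(5.0, 5.5, 6.0))
  expect_equal(length(s), 3L)

  writeLines(c("time_min,glucose", "0,90.09", "5,99.10", "10,108.11"), f)
  s2 <- read_cgm_csv(f, value_unit = "mg/dl")
  expect_equal(s2$values, c(5.0, 5.5, 6.0), tolerance = 1e-2)

  writeLines(character(0), f)
  expect_error(read_cgm_csv(f), "empty")

  writeLines(c("time_min,glucose", "0,5.0", "5,banana"), f)
  expect_error(read_cgm_csv(f), "line 3")

  writeLines(c("time_min,glucose", "10,5.0", "5,5.5"), f)
  expect_error(read_cgm_csv(f), "increasing")
})

test_that("CSV round-trip preserves values exactly", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- generate_profile(sim_config(days = 1, seed = 3))
  write_cgm_csv(s, f)
  back <- read_cgm_csv(f)
  expect_identical(back$values, s$values)
  expect_identical(back$times, s$times)

  # a full-scale (multi-day, ~4916-sample) profile survives the same trip
  big <- generate_profile(sim_config(days = 18, seed = 9))
  s_full <- glucose_series(big$times[1:4916], big$values[1:4916])
  write_cgm_csv(s_full, f)
  expect_identical(read_cgm_csv(f)$values, s_full$values)

  expect_error(write_cgm_csv(list(times = 1, values = numeric(0)), f))
})

test_that("gap segmentation splits, drops short fragments, keeps values", {
  v <- seq(5, 7, length.out = 100)
  t100 <- (0:99) * 5
  segs <- segment_by_gaps(t100, v, max_gap = 10)
  expect_length(segs, 1)
  expect_equal(length(segs[[1]]), 100L)
  expect_identical(segs[[1]]$values, v)

  # 30-min hole after 45 samples: leading 45 kept, trailing 15 dropped
  t60 <- c((0:44) * 5, 250 + (0:14) * 5)
  v60 <- seq(5, 8, length.out = 60)
  segs <- segment_by_gaps(t60, v60, max_gap = 10)
  expect_length(segs, 1)
  expect_equal(length(segs[[1]]), 45L)
  expect_identical(segs[[1]]$values, v60[1:45])
  expect_equal(segs[[1]]$times[1], 0)

  # samples never invented: retained values are a subset of the input
  expect_true(all(segs[[1]]$values %in% v60))

  # irregular spacing within a would-be segment is an invariant violation
  t_alt <- cumsum(c(0, rep(c(5, 6), 25)))
  expect_error(segment_by_gaps(t_alt, rep(6, 51), max_gap = 10), "uniform")

  expect_length(segment_by_gaps(numeric(0), numeric(0)), 0)
})

test_that("leading-n split has the documented sizes and concatenates back", {
  big <- generate_profile(sim_config(days = 18, seed = 2))
  s <- glucose_series(big$times[1:4916], big$values[1:4916])
  sp <- split_first_n(s, 500)
  expect_equal(length(sp$test), 500L)
  expect_equal(length(sp$train), 4416L)
  expect_identical(c(sp$test$values, sp$train$values), s$values)

  s10 <- glucose_series((0:9) * 5, 4 + 1:10 / 10)
  sp <- split_first_n(s10, 3)
  expect_identical(sp$test$values, s10$values[1:3])
  expect_identical(sp$train$values, s10$values[4:10])
  expect_error(split_first_n(s10, 10), "n_test")
  expect_error(split_first_n(s10, 0), "n_test")
})
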