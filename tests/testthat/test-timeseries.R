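# Time-series container, breakpoint detection and per-phase partitions.

test_that("culture_timeseries validates its input", {
  expect_error(culture_timeseries(data.frame(x = 1:3)), "time_h")
  expect_error(culture_timeseries(data.frame(time_h = c(1, 1, 2))),
               "strictly increasing")
  expect_warning(culture_timeseries(data.frame(time_h = 1:3, bogus = 1)),
                 "unknown columns")
})

test_that("CSV round trip preserves the trajectory", {
  ts <- simulate_culture("lowEh_CO_only", t_end = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts, path)
  back <- read_timeseries(path)
  expect_equal(back$Fe2_mM, ts$Fe2_mM, tolerance = 1e-12)
  expect_equal(back$time_h, ts$time_h)
})

test_that("breakpoint detection matches the exhaustive-search oracle", {
  t <- seq(0, 60, by = 2)
  y <- ifelse(t <= 24, 0.5 * t, 12 + 0.05 * (t - 24))
  ts <- culture_timeseries(data.frame(time_h = t, Fe2_mM = y))
  bp <- detect_breakpoint(ts)
  expect_true(bp$distinct)
  expect_equal(bp$time, breakpoint_oracle(t, y))
  expect_lte(abs(bp$time - 24), 2)   # within one sampling interval
})

test_that("noisy two-slope curves give stable breakpoints across seeds", {
  t <- seq(0, 60, by = 2)
  clean <- ifelse(t <= 24, 0.5 * t, 12 + 0.05 * (t - 24))
  times <- vapply(1:3, function(s) {
    set.seed(s)
    y <- clean + rnorm(length(t), 0, 0.3)
    detect_breakpoint(culture_timeseries(
      data.frame(time_h = t, Fe2_mM = y)))$time
  }, numeric(1))
  expect_true(max(times) - min(times) <= 4)   # within 2 sampling intervals
})

test_that("a perfectly linear curve is flagged as single-phase", {
  t <- seq(0, 30, by = 2)
  ts <- culture_timeseries(data.frame(time_h = t, Fe2_mM = 0.3 * t))
  expect_warning(bp <- detect_breakpoint(ts), "no distinct phases")
  expect_false(bp$distinct)
  expect_error(detect_breakpoint(culture_timeseries(
    data.frame(time_h = 1:4, Fe2_mM = 1:4))), "at least 6")
})

test_that("partitions recovered from simulated cultures match the generator", {
  ts <- simulate_culture("ferrihydrite_CO_lactate")
  truth <- attr(ts, "truth")
  phases <- partition_from_timeseries(ts, breakpoints = truth$switch_time)
  expect_length(phases, 2)
  fr1 <- phases[[1]]$partition$fraction_fe
  fr2 <- phases[[2]]$partition$fraction_fe
  expect_equal(fr1, truth$partition_phase1, tolerance = 0.05)
  expect_equal(fr2, truth$partition_phase2, tolerance = 0.05)
})

test_that("glauconite mode attributes all iron electrons to CO (no acetate)", {
  ts <- simulate_culture("glauconite_CO_lactate")
  phases <- partition_from_timeseries(ts)
  expect_length(phases, 1)
  eq <- phases[[1]]$equation
  expect_equal(unname(eq["lactate"]), 0)
  expect_equal(phases[[1]]$partition$fraction_fe,
               attr(ts, "truth")$partition_phase1, tolerance = 0.05)
})

test_that("single-phase call spans the full trajectory and bad breakpoints error", {
  ts <- simulate_culture("lowEh_CO_only", t_end = 40)
  phases <- partition_from_timeseries(ts)
  expect_length(phases, 1)
  expect_equal(phases[[1]]$from, 0)
  expect_equal(phases[[1]]$to, 40)
  expect_error(partition_from_timeseries(ts, breakpoints = 500),
               "inside the time range")
})
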