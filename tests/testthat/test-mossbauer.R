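# Doublet model, spectrum simulation, site fractions and phase assignment.

test_that("a single doublet absorbs at delta +/- splitting/2", {
  s <- simulate_spectrum(list(doublet(1.2, 1.8, 0.3, 0.05)), baseline = 1e6)
  v <- s$velocity
  minima <- v[which(diff(sign(diff(s$counts))) > 0) + 1]
  expect_length(minima, 2)
  expect_equal(sort(minima), c(0.3, 2.1), tolerance = 0.02)
})

test_that("an empty model yields a flat spectrum at the baseline", {
  s <- simulate_spectrum(data.frame(delta = numeric(0),
                                    splitting = numeric(0),
                                    fwhm = numeric(0), area = numeric(0),
                                    label = character(0)),
                         baseline = 5e5)
  expect_true(all(s$counts == 5e5))
})

test_that("integrated absorption matches the configured areas by quadrature", {
  model <- data.frame(delta = c(0.36, 1.2), splitting = c(0.6, 1.8),
                      fwhm = 0.3, area = c(0.06, 0.03), label = NA)
  s <- simulate_spectrum(model, baseline = 1e6,
                         grid = velocity_grid(4, 512))
  dv <- mean(diff(s$velocity))
  total <- sum(1 - s$counts / s$baseline) * dv
  # analytic integral of each truncated Lorentzian over [-4, 4]
  lor_mass <- function(center, hw)
    (atan((4 - center) / hw) + atan((4 + center) / hw)) / pi
  expected <- 0
  for (i in seq_len(nrow(model))) {
    hw <- model$fwhm[i] / 2
    for (line in model$delta[i] + c(-1, 1) * model$splitting[i] / 2)
      expected <- expected + model$area[i] / 2 * lor_mass(line, hw)
  }
  expect_equal(total, expected, tolerance = 0.01)
})

test_that("excess absorption and invalid grids are rejected", {
  expect_error(simulate_spectrum(list(doublet(0, 0.5, 0.1, 1.5)),
                                 baseline = 1e6), "absorption")
  expect_error(simulate_spectrum(list(doublet(0, 1)), grid = 1:10),
               "grid")
  expect_error(simulate_spectrum(list(doublet(0, 1, area = 0.1)),
                                 noise = TRUE), "seed")
})

test_that("site fractions normalise areas and reject degenerate input", {
  expect_equal(site_fractions(c(1, 3)), c(0.25, 0.75))
  expect_equal(site_fractions(5), 1)
  expect_error(site_fractions(c(0, 0)), "all areas are zero")
  expect_error(site_fractions(c(-1, 2)), "non-negative")
})

test_that("phase assignment uses the first matching window and falls through", {
  lib <- default_phase_library()
  df <- data.frame(delta = c(1.22, 0.35, 5.0),
                   splitting = c(1.80, 0.60, 0.1),
                   fwhm = 0.3, area = 1, label = NA)
  out <- assign_phases(df, lib)
  expect_equal(out$label, c("siderite", "Fe3+ octahedral silicate",
                            "unassigned"))
  expect_equal(out$state[1:2], c("Fe2+", "Fe3+"))
})

test_that("ferrous share sums Fe2+ doublet fractions in percent", {
  expect_equal(fe2_share(assign_phases(spectrum_preset("glauconite_initial"))),
               2.2, tolerance = 1e-9)
  expect_equal(fe2_share(assign_phases(spectrum_preset("glauconite_166h"))),
               5.7, tolerance = 1e-9)
  all_ferric <- data.frame(delta = 0.36, splitting = 0.6, fwhm = 0.3,
                           area = 1, label = NA)
  expect_equal(fe2_share(assign_phases(all_ferric)), 0)
})

test_that("spectrum presets encode the published stages", {
  for (nm in c("glauconite_initial", "glauconite_166h", "glauconite_960h")) {
    m <- spectrum_preset(nm, total_absorption = 1)
    expect_equal(sum(m$area), 1, tolerance = 1e-9)
  }
  m960 <- spectrum_preset("glauconite_960h")
  expect_equal(nrow(m960), 4)
  expect_equal(100 * m960$area[m960$label == "siderite"] / sum(m960$area),
               3.9, tolerance = 1e-9)
  expect_error(spectrum_preset("nope"), "valid presets")
})

test_that("two-column spectrum files round trip", {
  s <- simulate_spectrum(spectrum_preset("glauconite_166h"), baseline = 1e6,
                         noise = TRUE, seed = 1)
  path <- withr::local_tempfile(fileext = ".dat")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$velocity, s$velocity, tolerance = 1e-9)
  expect_equal(back$counts, s$counts)
  expect_equal(back$baseline, 1e6, tolerance = 0.01 * 1e6)
})

test_that("doublet YAML model files round trip", {
  m <- spectrum_preset("glauconite_960h")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_doublet_yaml(m, path)
  back <- read_doublet_yaml(path)
  expect_equal(back$delta, m$delta)
  expect_equal(back$area, m$area, tolerance = 1e-12)
  expect_equal(back$label, m$label)
})
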