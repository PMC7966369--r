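# wavelength grids, resampling, power normalization, photon arithmetic

test_that("wl_grid bin bookkeeping and invariants hold", {
  g <- wl_grid(300, 320, 0.5)
  expect_equal(g$n, 41L)
  expect_equal(g$centers[1], 300)
  expect_equal(g$centers[g$n], 320)
  expect_equal(unique(diff(g$centers)), 0.5)
  expect_error(wl_grid(320, 300), class = "photokin_input_error")
  expect_error(wl_grid(300, 320, step = 0), class = "photokin_input_error")
  expect_equal(mono_grid(415)$n, 1L)
})

test_that("resample interpolates linearly and preserves identity/constants", {
  g <- wl_grid(300, 310, 0.5)
  s <- spectrum(g$centers, seq(1, 5, length.out = g$n), unit = "relative")
  expect_equal(resample(s, g)$value, s$value) # identity on own grid
  s2 <- spectrum(c(295, 315), c(5, 5), unit = "relative")
  expect_equal(resample(s2, g)$value, rep(5, g$n)) # constants preserved
  s3 <- spectrum(c(300, 301), c(0, 2), unit = "relative")
  out <- resample(s3, wl_grid(300, 301, 0.5))
  expect_equal(out$value, c(0, 1, 2)) # hand linear interpolation at 300.5
})

test_that("resample zero-fills out-of-range bins with a log message", {
  g <- wl_grid(300, 340, 1)
  s <- spectrum(c(310, 320), c(1, 1), unit = "relative")
  expect_message(out <- resample(s, g), class = "photokin_log")
  expect_equal(out$value[g$centers < 310], rep(0, sum(g$centers < 310)))
  expect_equal(out$value[g$centers >= 310 & g$centers <= 320],
    rep(1, 11))
  # idempotent on its own output grid
  expect_equal(resample(out, g)$value, out$value)
})

test_that("malformed spectra are rejected", {
  expect_error(spectrum(numeric(0), numeric(0)), class = "photokin_input_error")
  expect_error(spectrum(c(300, 299), c(1, 1)), class = "photokin_format_error")
  expect_error(spectrum(c(300, 301), c(-1, 1)), class = "photokin_input_error")
  expect_error(
    spectrum(c(300, 301), c(0.5, 1.2), unit = "transmittance"),
    class = "photokin_input_error"
  )
})

test_that("normalize_emission makes the bin-sum integral the measured power", {
  g <- wl_grid(330, 339.5, 0.5) # 20 bins spanning 10 nm
  shape <- spectrum(g$centers, rep(1, g$n), unit = "relative")
  dens <- normalize_emission(shape, 1)
  expect_equal(dens$value, rep(0.1, g$n)) # 1 W over 10 nm
  expect_equal(sum(dens$value) * g$step, 1)
  # linearity in power
  expect_equal(normalize_emission(shape, 2)$value, 2 * dens$value)
  # degenerate inputs
  expect_error(normalize_emission(shape, 0), class = "photokin_input_error")
  expect_equal(
    sum(normalize_emission(shape, 0, allow_zero = TRUE)$value), 0
  )
  zero_shape <- spectrum(g$centers, rep(0, g$n), unit = "relative")
  expect_error(normalize_emission(zero_shape, 1), class = "photokin_degenerate_error")
})

test_that("photons_from_power implements E = hc/lambda per bin", {
  g <- mono_grid(380)
  dens <- spectrum(g$centers, 1 / g$step, unit = "spectral_power") # 1 W total
  f <- photons_from_power(dens, 1)
  expect_equal(f$value, 1 * 380e-9 / hcNA) # 3.176e-6 mol
  expect_equal(f$value, 3.1766e-6, tolerance = 1e-4)
  # linear in power and duration
  f2 <- photons_from_power(spectrum(g$centers, 2 / g$step, unit = "spectral_power"), 1)
  expect_equal(f2$value, 2 * f$value, tolerance = 1e-12)
  f3 <- photons_from_power(dens, 7)
  expect_equal(f3$value, 7 * f$value, tolerance = 1e-12)
  expect_error(photons_from_power(dens, 0), class = "photokin_input_error")
})

test_that("energy <-> photon round trip recovers the input energy", {
  g <- wl_grid(300, 400, 0.5)
  shape <- fixture_spectrum(g, "led_gaussian", center = 343, fwhm = 12)
  for (p in c(0.013, 0.12, 1.7)) {
    f <- photons_from_power(normalize_emission(shape, p), duration_s = 1)
    expect_equal(field_energy_J(f), p, tolerance = 1e-12)
  }
})

test_that("pulse-train photon doses match the closed form", {
  # 1 pulse of 184 uJ at 325 nm
  one <- sum(photons_from_pulses(325, 184e-6, 1)$value)
  expect_equal(one, 184e-6 * 325e-9 / hcNA)
  expect_equal(one, 5.0e-10, tolerance = 2e-3)
  # 0 pulses -> zero field
  expect_equal(sum(photons_from_pulses(325, 184e-6, 0)$value), 0)
  # 264 s at 20 Hz: the lambda-orthogonality experiment dose at 325 nm
  expect_equal(sum(photons_from_pulses(325, 184e-6, 264 * 20)$value) * 1e6,
    2.64,
    tolerance = 2e-3
  )
  # 135 min at 20 Hz, 1.0 mJ at 415 nm
  expect_equal(sum(photons_from_pulses(415, 1e-3, 135 * 60 * 20)$value),
    5.62e-4,
    tolerance = 1e-4
  )
  # center must be inside the grid
  expect_error(
    photons_from_pulses(500, 1e-4, 10, grid = wl_grid(300, 400)),
    class = "photokin_range_error"
  )
})

test_that("fixture spectra have their defining analytic properties", {
  g <- wl_grid(280, 450)
  led <- fixture_spectrum(g, "led_gaussian", center = 343, fwhm = 12)
  expect_equal(sum(led$value) * g$step, 1) # unit integral
  peak <- g$centers[which.max(led$value)]
  expect_equal(peak, 343, tolerance = 1e-6)
  half <- led$value >= max(led$value) / 2
  expect_equal(diff(range(g$centers[half])), 12, tolerance = 0.1)

  tr <- fixture_spectrum(g, "vessel_logistic")
  expect_true(all(tr$value > 0 & tr$value < 1))
  expect_true(all(diff(tr$value) >= 0)) # monotone with wavelength

  bands <- list(
    list(center = 310, width = 15, eps_max = 2000),
    list(center = 370, width = 25, eps_max = 500)
  )
  ab <- fixture_spectrum(g, "absorber_bands", bands = bands)
  expected <- 2000 * exp(-(g$centers - 310)^2 / (2 * 15^2)) +
    500 * exp(-(g$centers - 370)^2 / (2 * 25^2))
  expect_equal(ab$value, expected)
  expect_equal(spectrum_unit(ab), "molar_attenuation")
})

test_that("spectrum CSV files round-trip and reject bad input", {
  g <- wl_grid(300, 310)
  s <- fixture_spectrum(g, "led_gaussian", center = 305, fwhm = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  back <- read_spectrum_csv(path, unit = "relative")
  expect_equal(back$wavelength_nm, s$wavelength_nm)
  expect_equal(back$value, s$value)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_spectrum_csv(bad), class = "photokin_format_error")
  expect_error(read_spectrum_csv("no-such-file.csv"), class = "photokin_io_error")
})
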