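# wavelength-by-wavelength lambda-orthogonality selectivity prediction

# optically thin two-chromophore fixture with an abundant shared trap
thin_pair <- function(eps1 = 50, eps2 = 5, n_segments = 4) {
  g <- mono_grid(320)
  list(
    species = dplyr::bind_rows(
      photo_species("X1", spectrum(g$centers, eps1, unit = "molar_attenuation"),
        "chromophore", 2e-9
      ),
      photo_species("X2", spectrum(g$centers, eps2, unit = "molar_attenuation"),
        "chromophore", 2e-9
      ),
      photo_species("T", zero_spectrum(g), "trap", 1e-6),
      photo_species("P1", zero_spectrum(g), "product", 0),
      photo_species("P2", zero_spectrum(g), "product", 0)
    ),
    vessel = vessel(
      spectrum(g$centers, 1, unit = "transmittance"), 1, 1e-4, n_segments
    )
  )
}

rx_pair <- function(phi1, phi2) {
  dplyr::bind_rows(
    photo_reaction("X1", "T", "P1", phi1),
    photo_reaction("X2", "T", "P2", phi2)
  )
}

test_that("a transparent competitor gives perfect selectivity", {
  tp <- thin_pair(eps2 = 0)
  res <- scan_selectivity(tp$species, rx_pair(0.5, 0.5), tp$vessel,
    lambdas = 320, pulse_energy_J = 2.5e-4,
    target_conversion = 0.9, pulse_cap = 1e5
  )
  expect_equal(res$leading, "X1")
  expect_equal(res$conv_other, 0)
  expect_false(res$hit_cap)
  expect_equal(res$conv_leading, 0.9, tolerance = 1e-2)
  expect_gt(res$selectivity, 1e5) # floored denominator
})

test_that("identical chromophores reach the target together", {
  tp <- thin_pair(eps2 = 50)
  res <- scan_selectivity(tp$species, rx_pair(0.5, 0.5), tp$vessel,
    lambdas = 320, pulse_energy_J = 2.5e-4,
    target_conversion = 0.9, pulse_cap = 1e5
  )
  expect_equal(res$conv_other, res$conv_leading, tolerance = 1e-2)
  expect_equal(res$selectivity, 1.0, tolerance = 1e-2)
})

test_that("thin-limit cross conversion matches the closed form and a pulse-by-pulse oracle", {
  tp <- thin_pair(eps1 = 50, eps2 = 5)
  target <- 0.9
  res <- scan_selectivity(tp$species, rx_pair(0.5, 0.05), tp$vessel,
    lambdas = 320, pulse_energy_J = 2.5e-4,
    target_conversion = target, pulse_cap = 1e6
  )
  # d n2 / d n1 = (phi2 eps2 c2)/(phi1 eps1 c1): exponent 0.01 here
  closed <- 1 - (1 - target)^((0.05 * 5) / (0.5 * 50))
  expect_equal(res$conv_other, closed, tolerance = 2e-2)

  # brute-force pulse-by-pulse integration, independent of the engine
  q_pulse <- 2.5e-4 * 320e-9 / hcNA
  n1 <- 2e-9
  n2 <- 2e-9
  vol <- 1e-4
  pulses <- 0
  repeat {
    a1 <- 50 * (n1 / vol) * 1
    a2 <- 5 * (n2 / vol) * 1
    abs_tot <- q_pulse * (1 - 10^(-(a1 + a2)))
    n1 <- n1 - 0.5 * abs_tot * a1 / (a1 + a2)
    n2 <- n2 - 0.05 * abs_tot * a2 / (a1 + a2)
    pulses <- pulses + 1
    if (1 - n1 / 2e-9 >= target) break
  }
  expect_equal(res$conv_other, 1 - n2 / 2e-9, tolerance = 2e-2)
  expect_equal(res$pulses, pulses, tolerance = 2e-2)
})

test_that("swapping the reaction labels mirrors the scan output", {
  tp <- thin_pair(eps1 = 50, eps2 = 5)
  rx <- rx_pair(0.5, 0.05)
  a <- scan_selectivity(tp$species, rx, tp$vessel, 320, 2.5e-4,
    target_conversion = 0.8, pulse_cap = 1e6
  )
  b <- scan_selectivity(tp$species, rx[2:1, ], tp$vessel, 320, 2.5e-4,
    target_conversion = 0.8, pulse_cap = 1e6
  )
  expect_equal(b$leading, a$leading)
  expect_equal(b$conv_leading, a$conv_leading, tolerance = 1e-9)
  expect_equal(b$conv_other, a$conv_other, tolerance = 1e-9)
})

test_that("pulses to target fall as the leading reaction gets faster", {
  tp <- thin_pair()
  pulses <- vapply(c(0.2, 0.4, 0.8), function(phi) {
    scan_selectivity(tp$species, rx_pair(phi, 0.01), tp$vessel, 320, 2.5e-4,
      target_conversion = 0.7, pulse_cap = 1e6
    )$pulses
  }, numeric(1))
  expect_true(all(diff(pulses) < 0))
})

test_that("an unreactive wavelength is flagged at the pulse cap", {
  tp <- thin_pair(eps1 = 0, eps2 = 0)
  res <- scan_selectivity(tp$species, rx_pair(0.5, 0.5), tp$vessel, 320, 2.5e-4,
    target_conversion = 0.9, pulse_cap = 200
  )
  expect_true(res$hit_cap)
  expect_equal(res$conv_leading, 0)
})

test_that("selectivity_ratio is a floored conversion quotient", {
  expect_equal(selectivity_ratio(0.93, 0.05), 18.6)
  expect_equal(selectivity_ratio(0.9, 0), 0.9e6)
  expect_equal(selectivity_ratio(0.4, 0.4), 1)
  expect_error(selectivity_ratio(0.5, -0.1), class = "photokin_input_error")
})
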