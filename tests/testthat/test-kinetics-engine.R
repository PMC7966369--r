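# the iterative 1 s / 0.5 nm time-stepping engine

test_that("a non-reactive chromophore absorbs light but nothing converts", {
  sys <- mono_system(eps_A = 5000)
  sim <- simulate_photoreaction(sys$species, sys$reaction(0), sys$source,
    sys$vessel,
    duration_s = 5, snapshots = TRUE
  )
  expect_equal(final_conversion(sim), 0)
  expect_equal(unname(rowSums(sim$final_state)["A"]), 1.15e-6)
  # the beam is attenuated all the same
  m <- sim$maps[sim$maps$t_s == 0, ]
  expect_lt(m$photons_mol[nrow(m)], m$photons_mol[1])
})

test_that("Stark-Einstein bookkeeping: product = Phi x absorbed photons", {
  # optically thick single segment, all photons land on A, Phi = 0.1
  q_target <- 1e-8 # mol photons / s
  e_pulse <- q_target * hcNA / 307e-9
  sys <- mono_system(
    eps_A = 1e7, n_segments = 1, pulse_energy_J = e_pulse,
    rep_rate_Hz = 1
  )
  sim <- simulate_photoreaction(sys$species, sys$reaction(0.1), sys$source,
    sys$vessel,
    duration_s = 1, snapshots = FALSE
  )
  expect_equal(unname(sim$final_state["P", 1]), 1e-9, tolerance = 1e-12)
})

test_that("mixing redistributes amounts without changing totals", {
  m <- matrix(c(4e-7, 0, 0, 0), nrow = 1, dimnames = list("A", NULL))
  mixed <- mix_segments(m)
  expect_equal(as.numeric(mixed), rep(1e-7, 4))
  expect_equal(sum(mixed), sum(m))
  # already-uniform states are unchanged
  u <- matrix(2e-7, 2, 5, dimnames = list(c("A", "B"), NULL))
  expect_equal(mix_segments(u), u)
})

test_that("optically thick limit: conversion is linear with slope Phi*q/n0", {
  sys <- mono_system(eps_A = 1e4, n_segments = 5)
  phi <- 0.1
  sim <- simulate_photoreaction(sys$species, sys$reaction(phi), sys$source,
    sys$vessel,
    duration_s = 100, snapshots = FALSE
  )
  q <- mono_q_per_s(sys)
  slope_expected <- phi * q / 1.15e-6
  conv <- sim$trace$conversion_A
  expect_equal(conv[101] / 100, slope_expected, tolerance = 1e-9)
  expect_equal(max(abs(diff(conv) - slope_expected)), 0, tolerance = 1e-9 * slope_expected)
})

test_that("optically thin limit: first-order decay matching the closed form", {
  n_A <- 5e-8 # 1e-4 M in 0.5 mL -> A_tot ~ 0.0018, well inside the thin limit
  sys <- mono_system(eps_A = 30, n_A = n_A, n_trap = 1e-6, n_segments = 10)
  phi <- 0.3
  sim <- simulate_photoreaction(sys$species, sys$reaction(phi), sys$source,
    sys$vessel,
    duration_s = 1500, snapshots = FALSE
  )
  q <- mono_q_per_s(sys)
  k <- phi * q * log(10) * 30 * 0.6 / 5e-4
  tt <- sim$trace$t_s
  n_ratio <- 1 - sim$trace$conversion_A
  expect_equal(n_ratio, exp(-k * tt), tolerance = 5e-3)
})

test_that("the engine matches a fine-step reference integrator", {
  skip_if_not_installed("deSolve")
  # moderately thick: the regime between the two closed-form limits
  sys <- mono_system(eps_A = 1500, n_segments = 20)
  phi <- 0.115
  sim <- simulate_photoreaction(sys$species, sys$reaction(phi), sys$source,
    sys$vessel,
    duration_s = 600, snapshots = FALSE
  )
  q <- mono_q_per_s(sys)
  rhs <- function(t, y, p) {
    a_tot <- 1500 * (y[1] / 5e-4) * 0.6
    list(-phi * q * (1 - 10^(-a_tot)))
  }
  ref <- deSolve::ode(
    y = c(n = 1.15e-6), times = seq(0, 600, by = 50), func = rhs,
    parms = NULL, method = "ode45", atol = 1e-14, rtol = 1e-10
  )
  conv_ref <- 1 - ref[, "n"] / 1.15e-6
  conv_sim <- sim$trace$conversion_A[sim$trace$t_s %in% seq(0, 600, by = 50)]
  expect_equal(conv_sim[-1], conv_ref[-1], tolerance = 5e-3)
})

test_that("results converge in the number of segments", {
  s25 <- led_system(n_segments = 25)
  s50 <- led_system(n_segments = 50)
  c25 <- final_conversion(simulate_photoreaction(
    s25$species, s25$reaction(), s25$source, s25$vessel, 300,
    snapshots = FALSE
  ))
  c50 <- final_conversion(simulate_photoreaction(
    s50$species, s50$reaction(), s50$source, s50$vessel, 300,
    snapshots = FALSE
  ))
  expect_equal(c25, c50, tolerance = 1e-3)
})

test_that("for optically thin uniform systems mixing is immaterial", {
  sys <- mono_system(eps_A = 30, n_A = 5e-8, n_trap = 1e-6, n_segments = 10)
  args <- list(sys$species, sys$reaction(0.3), sys$source, sys$vessel, 300)
  on_mix <- do.call(simulate_photoreaction, c(args, list(mix = TRUE, snapshots = FALSE)))
  no_mix <- do.call(simulate_photoreaction, c(args, list(mix = FALSE, snapshots = FALSE)))
  expect_equal(final_conversion(no_mix), final_conversion(on_mix), tolerance = 1e-3)
})

test_that("conversion is monotone and the trap caps total turnover", {
  sys <- mono_system(eps_A = 1e4, n_trap = 0.1 * 1.15e-6, n_segments = 5)
  sim <- simulate_photoreaction(sys$species, sys$reaction(0.2), sys$source,
    sys$vessel,
    duration_s = 400, snapshots = FALSE
  )
  conv <- sim$trace$conversion_A
  expect_true(all(diff(conv) >= -1e-15))
  expect_lte(sum(sim$final_state["P", ]), 0.1 * 1.15e-6 + 1e-18)
  expect_equal(final_conversion(sim), 0.1, tolerance = 1e-9)
  # no amount ever goes negative
  expect_true(all(sim$final_state >= 0))
})

test_that("a competitive absorber strictly retards conversion at every time", {
  plain <- led_system(n_segments = 20)
  shaded <- led_system(n_segments = 20, with_hnba = TRUE)
  sim_p <- simulate_photoreaction(
    plain$species, plain$reaction(), plain$source, plain$vessel, 240,
    snapshots = FALSE
  )
  sim_s <- simulate_photoreaction(
    shaded$species, shaded$reaction(), shaded$source, shaded$vessel, 240,
    snapshots = FALSE
  )
  d <- sim_p$trace$conversion_A[-1] - sim_s$trace$conversion_A[-1]
  expect_true(all(d > 0))
})

test_that("photon and mass ledgers balance through an LED run", {
  sys <- led_system(n_segments = 20, with_hnba = TRUE)
  sim <- simulate_photoreaction(sys$species, sys$reaction(), sys$source,
    sys$vessel,
    duration_s = 150, snapshots = FALSE, debug_conservation = TRUE
  )
  expect_lt(sim$conservation[["photon_rel"]], 1e-12)
  expect_lt(sim$conservation[["mass_rel"]], 1e-10)
})

test_that("attenuation maps have the documented shape and endpoints", {
  sys <- led_system(n_segments = 15, n_A = 8e-6) # optically thick start
  sim <- simulate_photoreaction(sys$species, sys$reaction(), sys$source,
    sys$vessel,
    duration_s = 9
  )
  expect_setequal(unique(sim$maps$t_s), c(0, 3, 6, 9))
  m0 <- sim$maps[sim$maps$t_s == 0, ]
  expect_equal(nrow(m0), 15 * sys$grid$n)
  # photons non-increasing along the stack at fixed wavelength, t = 0
  by_seg <- tapply(m0$photons_mol, m0$segment, sum)
  expect_true(all(diff(by_seg) <= 1e-18))
  # thick sample: essentially nothing reaches the back at t = 0
  expect_lt(by_seg[15], 1e-4 * by_seg[1])
})

test_that("degenerate and inconsistent configurations are rejected early", {
  sys <- mono_system()
  bad_rx <- photo_reaction("A", "T", "missing", 0.1)
  expect_error(
    simulate_photoreaction(sys$species, bad_rx, sys$source, sys$vessel, 1),
    class = "photokin_config_error"
  )
  two <- dplyr::bind_rows(
    photo_reaction("A", "T", "P", 0.1),
    photo_reaction("A", "T", "P", 0.2)
  )
  expect_error(
    simulate_photoreaction(sys$species, two, sys$source, sys$vessel, 1),
    class = "photokin_config_error"
  )
  # duration 0: a t = 0 trace row and the initial attenuation map only
  sim0 <- simulate_photoreaction(sys$species, sys$reaction(0.1), sys$source, sys$vessel, 0)
  expect_equal(nrow(sim0$trace), 1L)
  expect_equal(unique(sim0$maps$t_s), 0L)
})
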