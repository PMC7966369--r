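#' Light sources
#'
#' Two source models are supported. An LED is a measured emission *shape*
#' (arbitrary units) plus the optical power measured at the sample position;
#' the shape is power-normalized with [normalize_emission()]. A pulsed laser
#' is treated as monochromatic: all energy of a pulse goes into the single
#' wavelength bin containing the center wavelength.
#'
#' @param shape Emission shape, a [spectrum()] on a uniform grid.
#' @param power_W Measured output power at the sample position, W (> 0).
#' @return A `light_source` object.
#' @export
#' @examples
#' g <- wl_grid(320, 370)
#' led <- led_source(fixture_spectrum(g, "led_gaussian", center = 343), power_W = 0.025)
led_source <- function(shape, power_W) {
  shape <- as_spectrum(shape)
  if (!is.numeric(power_W) || length(power_W) != 1 || power_W <= 0) {
    abort("`power_W` must be a single value > 0.", class = "photokin_input_error")
  }
  structure(
    list(kind = "led", shape = shape, power_W = power_W),
    class = "light_source"
  )
}

#' @param center_nm Laser center wavelength, nm.
#' @param pulse_energy_J Energy per pulse, J (> 0).
#' @param rep_rate_Hz Pulse repetition rate, Hz (> 0); the engine aggregates
#'   `rep_rate_Hz` pulses into each 1 s step.
#' @rdname led_source
#' @export
laser_source <- function(center_nm, pulse_energy_J, rep_rate_Hz = 20) {
  if (pulse_energy_J <= 0 || rep_rate_Hz <= 0) {
    abort("`pulse_energy_J` and `rep_rate_Hz` must be > 0.",
      class = "photokin_input_error"
    )
  }
  structure(
    list(
      kind = "pulsed_laser", center_nm = center_nm,
      pulse_energy_J = pulse_energy_J, rep_rate_Hz = rep_rate_Hz
    ),
    class = "light_source"
  )
}

#' @export
print.light_source <- function(x, ...) {
  if (x$kind == "led") {
    cat(sprintf("<light_source> LED, %g W at sample\n", x$power_W))
  } else {
    cat(sprintf(
      "<light_source> pulsed laser, %g nm, %g J/pulse at %g Hz\n",
      x$center_nm, x$pulse_energy_J, x$rep_rate_Hz
    ))
  }
  invisible(x)
}

#' Power-normalize an LED emission shape
#'
#' Rescales an emission shape so that its wavelength integral (bin-sum times
#' step) equals the output power measured at the sample position, giving a
#' spectral power density in W nm^-1.
#'
#' @param shape A [spectrum()] on a uniform grid (arbitrary units).
#' @param measured_power_W Measured LED power, W.
#' @param allow_zero Permit `measured_power_W = 0` (returns an all-zero
#'   density); otherwise zero power is an error.
#' @return A [spectrum()] with unit `spectral_power`.
#' @export
normalize_emission <- function(shape, measured_power_W, allow_zero = FALSE) {
  shape <- as_spectrum(shape)
  grid <- spectrum_grid(shape)
  if (is.null(grid)) {
    abort("emission shape must be on a uniform grid.", class = "photokin_input_error")
  }
  if (measured_power_W == 0 && allow_zero) {
    return(spectrum(shape$wavelength_nm, rep(0, nrow(shape)), unit = "spectral_power"))
  }
  if (measured_power_W <= 0) {
    abort("`measured_power_W` must be > 0 (or set `allow_zero = TRUE`).",
      class = "photokin_input_error"
    )
  }
  integral <- sum(shape$value) * grid$step
  if (integral <= 0) {
    abort("emission shape integrates to zero.", class = "photokin_degenerate_error")
  }
  spectrum(shape$wavelength_nm, shape$value * measured_power_W / integral,
    unit = "spectral_power"
  )
}

#' Convert spectral power to moles of photons per bin
#'
#' Per bin, `photons_mol = P(lambda) * step * duration * lambda / (h c N_A)`
#' with `lambda` the bin center in metres: each photon carries `h c / lambda`
#' joules, and photon amounts are tracked in moles (einsteins).
#'
#' @param power_density A [spectrum()] with unit `spectral_power` (W nm^-1).
#' @param duration_s Duration, s (> 0).
#' @return A photon field: a [spectrum()] with unit `photon_mol`, moles of
#'   photons per wavelength bin delivered during `duration_s`.
#' @export
#' @examples
#' g <- mono_grid(380)
#' pd <- spectrum(g$centers, 1 / g$step, unit = "spectral_power") # 1 W total
#' photons_from_power(pd, 1)$value # 3.176e-6 mol
photons_from_power <- function(power_density, duration_s) {
  power_density <- as_spectrum(power_density)
  if (!spectrum_unit(power_density) %in% c("spectral_power")) {
    abort("`power_density` must have unit `spectral_power`.",
      class = "photokin_input_error"
    )
  }
  if (duration_s <= 0) abort("`duration_s` must be > 0.", class = "photokin_input_error")
  grid <- spectrum_grid(power_density)
  if (is.null(grid)) abort("power density must be on a uniform grid.", class = "photokin_input_error")
  joule_per_bin <- power_density$value * grid$step * duration_s
  mol <- joule_per_bin * (power_density$wavelength_nm * 1e-9) / photokin_constants$hcNA
  spectrum(power_density$wavelength_nm, mol, unit = "photon_mol")
}

#' Photon dose of a pulse train
#'
#' A monochromatic photon field holding
#' `n_pulses * pulse_energy_J * lambda / (h c N_A)` moles of photons in the
#' bin containing `center_nm`.
#'
#' @param center_nm Laser wavelength, nm; must lie within `grid`.
#' @param pulse_energy_J Energy per pulse, J (> 0).
#' @param n_pulses Number of pulses (>= 0).
#' @param grid [wl_grid()] for the field (default: a single bin at
#'   `center_nm`).
#' @return A [spectrum()] with unit `photon_mol`.
#' @export
#' @examples
#' # 264 s at 20 Hz, 184 uJ/pulse, 325 nm -> 2.64 umol photons
#' sum(photons_from_pulses(325, 184e-6, 264 * 20)$value)
photons_from_pulses <- function(center_nm, pulse_energy_J, n_pulses,
                                grid = mono_grid(center_nm)) {
  if (pulse_energy_J <= 0) abort("`pulse_energy_J` must be > 0.", class = "photokin_input_error")
  if (n_pulses < 0) abort("`n_pulses` must be >= 0.", class = "photokin_input_error")
  grid <- as_wl_grid(grid)
  i <- grid_bin_index(grid, center_nm)
  mol <- rep(0, grid$n)
  mol[i] <- n_pulses * pulse_energy_J * (center_nm * 1e-9) / photokin_constants$hcNA
  spectrum(grid$centers, mol, unit = "photon_mol")
}

#' Energy carried by a photon field
#'
#' Inverse of [photons_from_power()] up to the duration factor: total joules
#' represented by a `photon_mol` spectrum.
#'
#' @param field A [spectrum()] with unit `photon_mol`.
#' @return Total energy in J.
#' @export
field_energy_J <- function(field) {
  field <- as_spectrum(field)
  sum(field$value * photokin_constants$hcNA / (field$wavelength_nm * 1e-9))
}

## photons entering the vessel per 1 s step, as a plain numeric vector on the
## engine grid (internal fast path used by the kinetics engine)
source_photons_per_second <- function(source, grid) {
  grid <- as_wl_grid(grid)
  if (source$kind == "led") {
    dens <- normalize_emission(resample(source$shape, grid), source$power_W)
    photons_from_power(dens, 1)$value
  } else {
    photons_from_pulses(source$center_nm, source$pulse_energy_J,
      n_pulses = source$rep_rate_Hz, grid = grid
    )$value
  }
}
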