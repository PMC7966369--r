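# Shared builders for small reaction systems used across the test files.
# All fixtures are generated in code; nothing is read from disk.

hcNA <- photokin_constants$hcNA

# single-chromophore monochromatic system: A + trap -> product, only A
# absorbs (eps L/mol/cm at the laser line), perfectly transparent vessel
mono_system <- function(center_nm = 307, eps_A = 2600, n_A = 1.15e-6,
                        n_trap = 2.71e-6, volume_L = 5e-4,
                        path_cm = 0.6, n_segments = 10,
                        pulse_energy_J = 2e-4, rep_rate_Hz = 20,
                        eps_trap = 0, vessel_T = 1) {
  g <- mono_grid(center_nm)
  sp <- dplyr::bind_rows(
    photo_species("A", spectrum(g$centers, eps_A, unit = "molar_attenuation"),
      "chromophore",
      amount_mol = n_A
    ),
    photo_species("T", spectrum(g$centers, eps_trap, unit = "molar_attenuation"),
      "trap",
      amount_mol = n_trap
    ),
    photo_species("P", zero_spectrum(g), "product", 0)
  )
  list(
    grid = g, species = sp,
    vessel = vessel(
      spectrum(g$centers, vessel_T, unit = "transmittance"),
      path_cm, volume_L, n_segments
    ),
    source = laser_source(center_nm, pulse_energy_J, rep_rate_Hz),
    reaction = function(phi) photo_reaction("A", "T", "P", phi)
  )
}

# photons per second delivered by a mono_system source (before vessel)
mono_q_per_s <- function(sys) {
  src <- sys$source
  src$rep_rate_Hz * src$pulse_energy_J * (src$center_nm * 1e-9) / hcNA
}

# LED-driven photoenol-style system built from the synthetic chromophore
# library; study conditions: 2.3 mM chromophore, 2.36 eq trap, 0.5 mL fill,
# 0.6 cm path, 25 mW LED centred at 343 nm
led_system <- function(n_segments = 50, power_W = 0.025, center = 343,
                       with_hnba = FALSE, hnba_eq = 0.65,
                       grid = wl_grid(280, 450), volume_L = 5e-4,
                       n_A = 2.3e-3 * 5e-4) {
  lib <- synthetic_chromophores(grid)
  sp <- dplyr::bind_rows(
    photo_species("A", lib$A, "chromophore", n_A),
    photo_species("NEM", lib$NEM, "trap", 2.36 * n_A),
    photo_species("AP", lib$AP, "product", 0)
  )
  if (with_hnba) {
    sp <- dplyr::bind_rows(
      sp, photo_species("HNBA", lib$HNBA, "inert_absorber", hnba_eq * n_A)
    )
  }
  list(
    grid = grid, species = sp,
    vessel = vessel(
      fixture_spectrum(grid, "vessel_logistic"), 0.6, volume_L, n_segments
    ),
    source = led_source(
      fixture_spectrum(grid, "led_gaussian", center = center, fwhm = 12),
      power_W
    ),
    reaction = function(phi = fit_qy_surface(qy_anchors_A())) {
      photo_reaction("A", "NEM", "AP", phi)
    }
  )
}

final_conversion <- function(sim, chrom = "A") {
  tr <- sim$trace
  tr[[paste0("conversion_", chrom)]][nrow(tr)]
}
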