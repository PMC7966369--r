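#' Estimate a quantum yield from an observed conversion
#'
#' Inverts the forward simulator by bisection on a constant Phi in (0, 1\]:
#' the forward conversion after a fixed photon dose is strictly increasing
#' in Phi, so the root is unique. Iteration stops when the simulated
#' conversion matches the observation to `tol` (1e-4 absolute by default) or
#' after `max_iter` bisections.
#'
#' `fit_monochromatic_qy()` reproduces the tunable-laser geometry: a
#' monochromatic pulsed source and, by default, *no* mixing (quantum-yield
#' determinations are run without a stir bar, so the solution is treated as
#' a static segment stack). `fit_apparent_qy()` is the polychromatic (LED)
#' variant with ideal mixing; the fitted value is an apparent quantum yield,
#' an effective Phi applicable to the wavelengths emitted by that LED.
#'
#' @param species,reactions,vessel The system, see [photo_species()],
#'   [photo_reaction()] and [vessel()]. The `qy` entry of the (single)
#'   reaction is ignored -- it is the unknown.
#' @param source A [laser_source()] (monochromatic fit) or [led_source()]
#'   (apparent fit).
#' @param duration_s Irradiation time of the experiment, s.
#' @param observed Observed conversion fraction, in \[0, 1).
#' @param mix Override the default mixing mode.
#' @param tol Absolute tolerance on conversion. Default 1e-4.
#' @param max_iter Maximum bisection steps. Default 60.
#' @return The fitted Phi (a single number in \[0, 1\]).
#' @export
#' @examples
#' g <- mono_grid(307)
#' sp <- dplyr::bind_rows(
#'   photo_species("A", spectrum(g$centers, 2600, "molar_attenuation"), "chromophore", 1.15e-6),
#'   photo_species("NEM", zero_spectrum(g), "trap", 2.71e-6),
#'   photo_species("AP", zero_spectrum(g), "product", 0)
#' )
#' rx <- photo_reaction("A", "NEM", "AP", 0.5) # placeholder qy
#' ves <- vessel(
#'   spectrum(g$centers, 0.9, "transmittance"), 0.6, 5e-4, 10
#' )
#' src <- laser_source(307, 2e-4, 20)
#' obs <- tail(tidy(simulate_photoreaction(
#'   sp, photo_reaction("A", "NEM", "AP", 0.115), src, ves, 120,
#'   mix = FALSE, snapshots = FALSE
#' ))$conversion_A, 1)
#' fit_monochromatic_qy(sp, rx, src, ves, 120, obs) # ~0.115
fit_monochromatic_qy <- function(species, reactions, source, vessel,
                                 duration_s, observed, mix = FALSE,
                                 tol = 1e-4, max_iter = 60) {
  invert_qy(species, reactions, source, vessel, duration_s, observed,
    mix = mix, tol = tol, max_iter = max_iter
  )
}

#' @rdname fit_monochromatic_qy
#' @export
fit_apparent_qy <- function(species, reactions, source, vessel,
                            duration_s, observed, mix = TRUE,
                            tol = 1e-4, max_iter = 60) {
  invert_qy(species, reactions, source, vessel, duration_s, observed,
    mix = mix, tol = tol, max_iter = max_iter
  )
}

invert_qy <- function(species, reactions, source, vessel, duration_s,
                      observed, mix, tol, max_iter) {
  reactions <- tibble::as_tibble(reactions)
  if (nrow(reactions) != 1) {
    abort("quantum-yield fitting expects exactly one reaction.",
      class = "photokin_input_error"
    )
  }
  if (observed < 0 || observed >= 1) {
    abort("`observed` conversion must be in [0, 1).", class = "photokin_input_error")
  }
  if (observed == 0) {
    return(0)
  }
  forward <- function(phi) {
    rx <- reactions
    rx$qy <- list(phi)
    sim <- simulate_photoreaction(species, rx, source, vessel, duration_s,
      mix = mix, snapshots = FALSE
    )
    tr <- sim$trace
    tr[[paste0("conversion_", reactions$chromophore[1])]][nrow(tr)]
  }
  hi_conv <- forward(1)
  if (hi_conv < observed - tol) {
    abort(
      sprintf(
        "observed conversion %.4g is unreachable even at Phi = 1 (max %.4g): photon dose or attenuation inputs are inconsistent with the observation.",
        observed, hi_conv
      ),
      class = "photokin_infeasible_error"
    )
  }
  lo <- 0
  hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    conv <- forward(mid)
    if (abs(conv - observed) < tol) {
      return(mid)
    }
    if (conv < observed) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
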