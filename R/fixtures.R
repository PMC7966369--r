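#' Synthetic fixture spectra
#'
#' Deterministic, analytically defined stand-ins for measured spectra, used
#' by the examples and the test suite. Three kinds are provided:
#' \describe{
#'   \item{`led_gaussian`}{LED emission shape: a Gaussian of given center and
#'     full width at half maximum (default 12 nm, typical of the 10-15 nm
#'     FWHM of common LEDs), normalized to unit bin-sum integral.}
#'   \item{`vessel_logistic`}{glass-vial transmittance: a logistic curve
#'     rising with wavelength from deep-UV opacity to a visible-range
#'     plateau, values strictly inside (0, 1).}
#'   \item{`absorber_bands`}{molar attenuation coefficient: a sum of
#'     Gaussian absorption bands `eps_max * exp(-(l - center)^2 / (2 w^2))`.}
#' }
#' All kinds are deterministic given their parameters; `seed` is accepted for
#' interface uniformity and ignored.
#'
#' @param grid Target [wl_grid()].
#' @param kind One of `"led_gaussian"`, `"vessel_logistic"`,
#'   `"absorber_bands"`.
#' @param center,fwhm Gaussian LED parameters, nm.
#' @param midpoint,scale,plateau Logistic transmittance parameters:
#'   half-rise wavelength (nm), steepness (nm), visible-range plateau (0-1).
#' @param bands For `absorber_bands`: a list of `list(center, width,
#'   eps_max)` entries (nm, nm, L mol^-1 cm^-1).
#' @param seed Ignored (fixtures are deterministic).
#' @return A [spectrum()] with the appropriate unit tag.
#' @export
#' @examples
#' g <- wl_grid(280, 450)
#' led <- fixture_spectrum(g, "led_gaussian", center = 343, fwhm = 12)
#' sum(led$value) * 0.5 # integrates to 1
fixture_spectrum <- function(grid,
                             kind = c("led_gaussian", "vessel_logistic", "absorber_bands"),
                             center = 343, fwhm = 12,
                             midpoint = 310, scale = 8, plateau = 0.92,
                             bands = list(list(center = 320, width = 20, eps_max = 1000)),
                             seed = NULL) {
  kind <- match.arg(kind)
  grid <- as_wl_grid(grid)
  w <- grid$centers
  switch(kind,
    led_gaussian = {
      if (fwhm <= 0) abort("`fwhm` must be > 0.", class = "photokin_input_error")
      sigma <- fwhm / (2 * sqrt(2 * log(2)))
      v <- exp(-(w - center)^2 / (2 * sigma^2))
      tot <- sum(v) * grid$step
      if (tot == 0) abort("LED band falls entirely outside the grid.", class = "photokin_input_error")
      spectrum(w, v / tot, unit = "relative")
    },
    vessel_logistic = {
      if (plateau <= 0 || plateau >= 1) {
        abort("`plateau` must be in (0, 1).", class = "photokin_input_error")
      }
      v <- plateau / (1 + exp(-(w - midpoint) / scale))
      spectrum(w, v, unit = "transmittance")
    },
    absorber_bands = {
      v <- rep(0, grid$n)
      for (b in bands) {
        v <- v + b$eps_max * exp(-(w - b$center)^2 / (2 * b$width^2))
      }
      spectrum(w, v, unit = "molar_attenuation")
    }
  )
}

#' Synthetic chromophore library
#'
#' Molar attenuation spectra for a worked two-chromophore photoenol ligation
#' system, built from [fixture_spectrum()] absorption bands. These are
#' synthetic: band positions and magnitudes emulate the qualitative features
#' of a thioether o-methylbenzaldehyde (`A`, reactive out to ~420 nm with
#' strongest short-wavelength absorption near 307 nm), its alkoxy analogue
#' (`B`, blue-shifted, more strongly absorbing below ~340 nm), the maleimide
#' trap (`NEM`, weak tail below ~330 nm), the ligation products (`AP`, `BP`,
#' absorbing further in the UV), and a nitroaromatic competitive absorber
#' (`HNBA`, broad strong bands across the UV-A). They are not digitised
#' measured spectra.
#'
#' @param grid Target [wl_grid()].
#' @return Named list of [spectrum()] objects (`A`, `B`, `NEM`, `AP`, `BP`,
#'   `HNBA`), unit `molar_attenuation`.
#' @export
#' @examples
#' lib <- synthetic_chromophores(wl_grid(280, 450))
#' names(lib)
synthetic_chromophores <- function(grid) {
  grid <- as_wl_grid(grid)
  bandset <- function(...) fixture_spectrum(grid, "absorber_bands", bands = list(...))
  list(
    A = bandset(
      list(center = 307, width = 16, eps_max = 2600),
      list(center = 348, width = 26, eps_max = 950),
      list(center = 395, width = 22, eps_max = 140)
    ),
    B = bandset(
      list(center = 295, width = 13, eps_max = 5200),
      list(center = 326, width = 11, eps_max = 1600)
    ),
    NEM = bandset(list(center = 300, width = 22, eps_max = 620)),
    AP = bandset(
      list(center = 282, width = 18, eps_max = 1500),
      list(center = 330, width = 18, eps_max = 90)
    ),
    BP = bandset(list(center = 280, width = 16, eps_max = 1700)),
    HNBA = bandset(
      list(center = 312, width = 26, eps_max = 4200),
      list(center = 378, width = 34, eps_max = 1100)
    )
  )
}
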