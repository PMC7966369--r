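#' Physical constants used by the photon bookkeeping
#'
#' CODATA-2018 exact values, kept in a single table so that the simulation
#' engine, the unit conversions and the test-suite oracles agree bit-for-bit.
#'
#' @format A named list:
#' \describe{
#'   \item{h}{Planck constant, J s.}
#'   \item{c0}{Speed of light in vacuum, m s^-1.}
#'   \item{N_A}{Avogadro constant, mol^-1.}
#'   \item{hcNA}{`h * c0 * N_A`, J m mol^-1 -- one mole of photons of
#'     wavelength lambda (in m) carries `hcNA / lambda` joules.}
#'   \item{version}{Identifier written into run manifests.}
#' }
#' @export
#' @examples
#' # energy of one einstein (mole of photons) at 380 nm, in kJ
#' photokin_constants$hcNA / 380e-9 / 1000
photokin_constants <- local({
  h <- 6.62607015e-34
  c0 <- 299792458
  N_A <- 6.02214076e23
  list(h = h, c0 = c0, N_A = N_A, hcNA = h * c0 * N_A, version = "CODATA-2018")
})

## J per mol of photons at wavelength lambda_m (metres); inverse gives mol/J
energy_per_mol_photons <- function(lambda_m) photokin_constants$hcNA / lambda_m
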