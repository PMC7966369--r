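#' Reaction vessel
#'
#' The solution is modelled as a stack of `n_segments` equal-volume slices
#' along a single collimated beam axis; each slice has optical path
#' `path_length_cm / n_segments`. The (wavelength-dependent) vessel
#' transmittance is applied once at the front face.
#'
#' @param transmittance A [spectrum()] with unit `transmittance`.
#' @param path_length_cm Total optical path through the solution, cm (> 0).
#' @param volume_L Solution volume, L (> 0).
#' @param n_segments Number of slices (>= 1). Default 50.
#' @return A `vessel` object.
#' @export
#' @examples
#' g <- wl_grid(280, 450)
#' v <- vessel(fixture_spectrum(g, "vessel_logistic"), 0.6, 5e-4)
vessel <- function(transmittance, path_length_cm, volume_L, n_segments = 50L) {
  transmittance <- as_spectrum(transmittance)
  if (spectrum_unit(transmittance) != "transmittance") {
    abort("`transmittance` must have unit `transmittance`.", class = "photokin_input_error")
  }
  if (path_length_cm <= 0 || volume_L <= 0 || n_segments < 1) {
    abort("vessel geometry must be positive with n_segments >= 1.",
      class = "photokin_input_error"
    )
  }
  structure(
    list(
      transmittance = transmittance,
      path_length_cm = path_length_cm, volume_L = volume_L,
      n_segments = as.integer(n_segments),
      l_seg_cm = path_length_cm / n_segments,
      v_seg_L = volume_L / n_segments
    ),
    class = "vessel"
  )
}

#' @export
print.vessel <- function(x, ...) {
  cat(sprintf(
    "<vessel> path %g cm, volume %g L, %d segments\n",
    x$path_length_cm, x$volume_L, x$n_segments
  ))
  invisible(x)
}

#' Apply vessel transmittance to a photon field
#'
#' Photons lost at the vessel wall: per bin, `out = in * T(lambda)`. Applied
#' once, at solution entry.
#'
#' @param field A [spectrum()] with unit `photon_mol`.
#' @param vessel A [vessel()]; its transmittance is resampled to the field
#'   grid if needed.
#' @return The attenuated photon field.
#' @export
apply_vessel <- function(field, vessel) {
  field <- as_spectrum(field)
  tr <- resample(vessel$transmittance, spectrum_grid(field))
  spectrum(field$wavelength_nm, field$value * tr$value, unit = "photon_mol")
}

#' Beer-Lambert absorption in one segment at one wavelength
#'
#' Decadic Beer-Lambert: total absorbance `A = sum_i eps_i c_i l_seg`; the
#' transmitted fraction is `10^-A` and the absorbed photons are partitioned
#' among species in proportion to their `eps_i c_i` contributions (the
#' fractional absorption that governs competitive/inner-filter absorption).
#' Vectorized over wavelength bins: `incident_mol` may be a vector and
#' `epsilons` a matrix with one row per bin.
#'
#' @param incident_mol Incident photons, mol (scalar or per-bin vector).
#' @param epsilons Named vector of molar attenuation coefficients
#'   (L mol^-1 cm^-1) at this bin, or an `n_bins x n_species` matrix.
#' @param concentrations Named vector of concentrations, mol L^-1.
#' @param l_seg_cm Segment path length, cm.
#' @return A list: `transmitted` (mol), `absorbed` (species-named vector, or
#'   `n_bins x n_species` matrix, mol).
#' @export
#' @examples
#' attenuate_segment(1e-6, c(A = 3000), c(A = 1e-3), 0.1) # A = 0.3
attenuate_segment <- function(incident_mol, epsilons, concentrations, l_seg_cm) {
  if (is.matrix(epsilons)) {
    E <- epsilons
  } else {
    E <- matrix(epsilons, nrow = 1, dimnames = list(NULL, names(epsilons)))
  }
  conc <- concentrations[colnames(E) %||% names(concentrations)]
  if (any(conc < 0) || any(E < 0) || l_seg_cm < 0 || any(incident_mol < 0)) {
    abort("attenuate_segment inputs must be >= 0.", class = "photokin_input_error")
  }
  contrib <- sweep(E, 2, as.numeric(conc), `*`) * l_seg_cm # per-species eps*c*l
  a_tot <- rowSums(contrib)
  t_frac <- 10^(-a_tot)
  absorbed_tot <- incident_mol * (1 - t_frac)
  share <- contrib / ifelse(a_tot > 0, a_tot, 1)
  share[a_tot == 0, ] <- 0
  absorbed <- share * absorbed_tot
  transmitted <- incident_mol * t_frac
  if (nrow(E) == 1 && !is.matrix(epsilons)) {
    list(transmitted = transmitted, absorbed = drop(absorbed))
  } else {
    list(transmitted = transmitted, absorbed = absorbed)
  }
}

#' Propagate a photon field through the segment stack
#'
#' Applies [attenuate_segment()] sequentially front to back for every
#' wavelength bin, recording the full absorption ledger.
#'
#' @param field A [spectrum()] with unit `photon_mol` (photons entering the
#'   solution, i.e. after [apply_vessel()]).
#' @param eps_matrix `n_bins x n_species` matrix of molar attenuation
#'   coefficients on the field grid (named columns).
#' @param seg_conc `n_species x n_segments` matrix of concentrations
#'   (mol L^-1), rows named as `eps_matrix` columns.
#' @param l_seg_cm Segment path length, cm.
#' @return A list: `entering` (`n_bins x n_segments`, photons entering each
#'   segment), `absorbed` (`n_bins x n_species x n_segments` array), and
#'   `exit` (photon vector leaving the last segment).
#' @export
propagate_stack <- function(field, eps_matrix, seg_conc, l_seg_cm) {
  field <- as_spectrum(field)
  n_seg <- ncol(seg_conc)
  n_bins <- nrow(eps_matrix)
  stopifnot(nrow(field) == n_bins, nrow(seg_conc) == ncol(eps_matrix))
  q <- field$value
  entering <- matrix(0, n_bins, n_seg)
  absorbed <- array(0, dim = c(n_bins, ncol(eps_matrix), n_seg),
    dimnames = list(NULL, colnames(eps_matrix), NULL)
  )
  for (s in seq_len(n_seg)) {
    entering[, s] <- q
    res <- attenuate_segment(q, eps_matrix, seg_conc[, s], l_seg_cm)
    absorbed[, , s] <- res$absorbed
    q <- res$transmitted
  }
  list(entering = entering, absorbed = absorbed, exit = q)
}
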