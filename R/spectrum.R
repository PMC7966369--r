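#' Spectra as tidy tibbles
#'
#' A photokin spectrum is a tibble with columns `wavelength_nm` and `value`,
#' sampled at the bin centers of a [wl_grid()], plus a unit tag. Recognised
#' units:
#' \describe{
#'   \item{`molar_attenuation`}{decadic molar attenuation coefficient
#'     epsilon_lambda, L mol^-1 cm^-1.}
#'   \item{`transmittance`}{dimensionless, in \[0, 1\].}
#'   \item{`spectral_power`}{spectral power density, W nm^-1.}
#'   \item{`photon_mol`}{moles of photons per wavelength bin.}
#'   \item{`relative`}{arbitrary shape, e.g. an unnormalised LED emission.}
#' }
#'
#' @param wavelength_nm Numeric vector of bin centers (strictly increasing,
#'   uniform spacing).
#' @param value Numeric vector, same length, all values >= 0.
#' @param unit Unit tag, one of the strings above.
#' @return A tibble of class `photokin_spectrum` with attributes `unit` and
#'   `grid`.
#' @export
#' @examples
#' g <- wl_grid(300, 301, 0.5)
#' spectrum(g$centers, c(0, 1, 2), unit = "relative")
spectrum <- function(wavelength_nm, value,
                     unit = c(
                       "relative", "molar_attenuation", "transmittance",
                       "spectral_power", "photon_mol"
                     )) {
  unit <- match.arg(unit)
  if (length(wavelength_nm) == 0) {
    abort("empty spectrum.", class = "photokin_input_error")
  }
  if (length(wavelength_nm) != length(value)) {
    abort("`wavelength_nm` and `value` lengths differ.", class = "photokin_input_error")
  }
  if (any(!is.finite(wavelength_nm)) || any(!is.finite(value))) {
    abort("non-finite entries in spectrum.", class = "photokin_input_error")
  }
  if (is.unsorted(wavelength_nm, strictly = TRUE)) {
    abort("`wavelength_nm` must be strictly increasing.", class = "photokin_format_error")
  }
  if (any(value < 0)) {
    abort("spectrum values must be >= 0.", class = "photokin_input_error")
  }
  if (unit == "transmittance" && any(value > 1 + 1e-12)) {
    abort("transmittance values must be <= 1.", class = "photokin_input_error")
  }
  out <- tibble(wavelength_nm = as.numeric(wavelength_nm), value = as.numeric(value))
  grid <- infer_grid(out$wavelength_nm)
  structure(out,
    class = c("photokin_spectrum", class(out)),
    unit = unit, grid = grid
  )
}

## a uniform wavelength vector maps back to its wl_grid; NULL if non-uniform
infer_grid <- function(w) {
  if (length(w) == 1) {
    return(mono_grid(w))
  }
  d <- diff(w)
  if (max(abs(d - d[1])) < 1e-9 * max(abs(d[1]), 1)) {
    wl_grid(w[1], w[length(w)], d[1])
  } else {
    NULL
  }
}

#' @export
print.photokin_spectrum <- function(x, ...) {
  cat(sprintf("<photokin_spectrum> unit: %s\n", spectrum_unit(x)))
  NextMethod()
}

#' Unit tag of a spectrum
#' @param x A [spectrum()].
#' @return The unit string.
#' @export
spectrum_unit <- function(x) attr(x, "unit") %||% "relative"

spectrum_grid <- function(x) attr(x, "grid") %||% infer_grid(x$wavelength_nm)

## coerce a plain two-column data frame to a spectrum, keeping any unit tag
as_spectrum <- function(x, unit = NULL) {
  if (inherits(x, "photokin_spectrum") && is.null(unit)) return(x)
  if (!is.data.frame(x) || !all(c("wavelength_nm", "value") %in% names(x))) {
    abort("a spectrum needs columns `wavelength_nm` and `value`.",
      class = "photokin_format_error"
    )
  }
  spectrum(x$wavelength_nm, x$value, unit = unit %||% spectrum_unit(x))
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation at the bin centers of `grid`. Bins outside the range
#' of the input spectrum are filled with zero; when that happens a message is
#' emitted once per call (class `photokin_log`), because emission or
#' attenuation tails beyond the measured range must not abort a run.
#'
#' @param spec A [spectrum()] or a data frame with `wavelength_nm`, `value`.
#' @param grid Target [wl_grid()].
#' @return A [spectrum()] on `grid`, same unit tag.
#' @export
#' @examples
#' s <- spectrum(c(300, 301), c(0, 2), unit = "relative")
#' resample(s, wl_grid(300, 301, 0.5))$value # 0 1 2
resample <- function(spec, grid) {
  spec <- as_spectrum(spec)
  grid <- as_wl_grid(grid)
  if (nrow(spec) == 1) {
    # degenerate single point: value carried into its own bin, 0 elsewhere
    v <- rep(0, grid$n)
    i <- tryCatch(grid_bin_index(grid, spec$wavelength_nm), error = function(e) NA)
    if (!is.na(i)) v[i] <- spec$value
    return(spectrum(grid$centers, v, unit = spectrum_unit(spec)))
  }
  out <- approx(spec$wavelength_nm, spec$value,
    xout = grid$centers,
    method = "linear", rule = 1
  )$y
  n_out <- sum(is.na(out))
  if (n_out > 0) {
    inform(
      sprintf(
        "resample: %d of %d bins outside the input range %g-%g nm were zero-filled.",
        n_out, grid$n, min(spec$wavelength_nm), max(spec$wavelength_nm)
      ),
      class = "photokin_log"
    )
    out[is.na(out)] <- 0
  }
  out[out < 0] <- 0
  spectrum(grid$centers, out, unit = spectrum_unit(spec))
}

#' Read / write the two-column spectrum CSV format
#'
#' The on-disk format is a comma-separated file with header
#' `wavelength_nm,value`; lines starting with `#` are comments. The unit is
#' not stored in the file and must be supplied on read.
#'
#' @param path File path.
#' @param unit Unit tag to attach (see [spectrum()]).
#' @return `read_spectrum_csv()` returns a [spectrum()];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, unit = "relative") {
  if (!file.exists(path)) {
    abort(sprintf("spectrum file not found: %s", path), class = "photokin_io_error")
  }
  df <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_double())
  )
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    abort(
      sprintf("%s: expected columns `wavelength_nm,value`.", path),
      class = "photokin_format_error"
    )
  }
  if (is.unsorted(df$wavelength_nm, strictly = TRUE)) {
    abort(sprintf("%s: wavelength column must be strictly increasing.", path),
      class = "photokin_format_error"
    )
  }
  spectrum(df$wavelength_nm, df$value, unit = unit)
}

#' @param spec Spectrum to write.
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  spec <- as_spectrum(spec)
  readr::write_csv(spec[, c("wavelength_nm", "value")], path)
  invisible(path)
}

## zero spectrum on a grid (e.g. a species transparent in the studied window)
#' All-zero spectrum on a grid
#' @param grid A [wl_grid()].
#' @param unit Unit tag.
#' @return A [spectrum()] of zeros.
#' @export
zero_spectrum <- function(grid, unit = "molar_attenuation") {
  grid <- as_wl_grid(grid)
  spectrum(grid$centers, rep(0, grid$n), unit = unit)
}
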