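#' Uniform wavelength grid
#'
#' All wavelength-resolved quantities in photokin live on a uniform grid of
#' bin centers `lambda_min + k * step`. The default 0.5 nm step matches the
#' wavelength increment the simulation engine iterates over; integrals over
#' wavelength use the bin-sum convention (`sum(values) * step`).
#'
#' @param lambda_min,lambda_max Grid limits in nm (`lambda_min < lambda_max`,
#'   or equal for a single-bin monochromatic grid).
#' @param step Bin width in nm, > 0. Default 0.5.
#' @return An object of class `wl_grid`: a list with `lambda_min`,
#'   `lambda_max`, `step`, `n` (bin count) and `centers` (bin centers, nm).
#' @export
#' @examples
#' g <- wl_grid(300, 320)
#' g$n
#' head(g$centers)
wl_grid <- function(lambda_min, lambda_max, step = 0.5) {
  stopifnot(is.numeric(lambda_min), is.numeric(lambda_max), is.numeric(step))
  if (step <= 0) abort("`step` must be > 0.", class = "photokin_input_error")
  if (lambda_min > lambda_max) {
    abort("`lambda_min` must be <= `lambda_max`.", class = "photokin_input_error")
  }
  n <- floor((lambda_max - lambda_min) / step + 1e-9) + 1L
  structure(
    list(
      lambda_min = lambda_min, lambda_max = lambda_max, step = step,
      n = as.integer(n),
      centers = lambda_min + (seq_len(n) - 1) * step
    ),
    class = "wl_grid"
  )
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf(
    "<wl_grid> %g-%g nm, step %g nm, %d bins\n",
    x$lambda_min, x$lambda_max, x$step, x$n
  ))
  invisible(x)
}

#' Single-bin grid for monochromatic (laser) light
#'
#' @param center_nm Wavelength of the single bin, nm.
#' @param step Nominal bin width, nm (bookkeeping only).
#' @return A `wl_grid` with one bin centered at `center_nm`.
#' @export
mono_grid <- function(center_nm, step = 0.5) wl_grid(center_nm, center_nm, step)

as_wl_grid <- function(x) {
  if (inherits(x, "wl_grid")) return(x)
  abort("expected a `wl_grid` object.", class = "photokin_input_error")
}

## index of the bin containing a wavelength; error if outside the grid span
grid_bin_index <- function(grid, wavelength_nm) {
  half <- grid$step / 2
  if (wavelength_nm < grid$lambda_min - half || wavelength_nm > grid$lambda_max + half) {
    abort(
      sprintf(
        "wavelength %g nm lies outside the grid span %g-%g nm.",
        wavelength_nm, grid$lambda_min, grid$lambda_max
      ),
      class = "photokin_range_error"
    )
  }
  idx <- round((wavelength_nm - grid$lambda_min) / grid$step) + 1L
  min(max(as.integer(idx), 1L), grid$n)
}
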