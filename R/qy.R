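#' Packaged quantum-yield anchor tables
#'
#' Reaction quantum yields Phi measured with a monochromatic tunable laser,
#' for the thioether o-methylbenzaldehyde chromophore (`qy_anchors_A()`) and
#' its dodecyl thioether analogue (`qy_anchors_C()`). The A table contains
#' the wavelength profile at the 2.3 mM reference concentration -- a low
#' yield at the 420 nm red edge rising to a 0.028 plateau across 345-400 nm
#' and a 0.115 maximum at 307 nm -- plus two concentration series (at 382 nm
#' and 307 nm) showing the increase of Phi with dilution. The C table has
#' two wavelength anchors and no measured concentration dependence.
#'
#' @return A tibble with columns `wavelength_nm`, `concentration_M`, `phi`,
#'   `uncertainty` (NA where no uncertainty was reported; `concentration_M`
#'   NA where the measurement concentration is unspecified -- such anchors
#'   are taken at the reference concentration when fitting).
#' @export
#' @examples
#' qy_anchors_A()
qy_anchors_A <- function() {
  tibble::tribble(
    ~wavelength_nm, ~concentration_M, ~phi, ~uncertainty,
    307, 1.1e-3, 0.133, NA,
    307, 2.3e-3, 0.115, 0.023,
    307, 4.8e-3, 0.059, NA,
    345, 2.3e-3, 0.028, 0.0037,
    360, 2.3e-3, 0.028, 0.0037,
    380, 2.3e-3, 0.028, 0.0037,
    382, 0.13e-3, 0.057, NA,
    382, 2.3e-3, 0.028, NA,
    382, 4.8e-3, 0.016, NA,
    400, 2.3e-3, 0.028, 0.0037,
    420, 2.3e-3, 0.0026, 0.0010
  )
}

#' @rdname qy_anchors_A
#' @export
qy_anchors_C <- function() {
  tibble::tribble(
    ~wavelength_nm, ~concentration_M, ~phi, ~uncertainty,
    285, NA, 0.012, 0.0017,
    360, NA, 0.008, 0.0007
  )
}

#' Read a quantum-yield anchor CSV
#'
#' Format: header `wavelength_nm,concentration_M,phi` with an optional
#' `uncertainty` column; `#` comments allowed.
#'
#' @param path File path.
#' @return An anchor tibble as returned by [qy_anchors_A()].
#' @export
read_qy_anchors_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("anchor file not found: %s", path), class = "photokin_io_error")
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("wavelength_nm", "concentration_M", "phi")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: expected columns %s.", path, paste(need, collapse = ",")),
      class = "photokin_format_error"
    )
  }
  if (!"uncertainty" %in% names(df)) df$uncertainty <- NA_real_
  tibble::as_tibble(df[, c(need, "uncertainty")])
}

## shape-preserving piecewise-cubic (pchip) through (x, y); returns a
## function clamped to the data range (edge values held outside)
pchip_fun <- function(x, y) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  if (length(x) == 1) {
    force(y)
    return(function(z) rep(y, length(z)))
  }
  if (length(x) == 2) {
    # a two-point segment: linear (pchip needs three nodes)
    lin <- approxfun(x, y, rule = 2)
    return(function(z) lin(z))
  }
  function(z) {
    zc <- pmin(pmax(z, x[1]), x[length(x)])
    pracma::pchip(x, y, zc)
  }
}

#' Fit the reaction quantum-yield surface Phi(lambda, c)
#'
#' Builds a smooth, bounded surface through monochromatic anchor
#' measurements. The wavelength profile `f(lambda)` is a shape-preserving
#' (pchip) piecewise cubic through the anchors at the reference
#' concentration -- no overshoot or ringing above the measured maximum. The
#' concentration dependence is a multiplicative correction: each wavelength
#' with two or more anchor concentrations contributes a monotone ratio curve
#' `g_lambda(c) = Phi(lambda, c) / f(lambda)` (pchip in c, edge values held
#' outside the measured range), and the correction applied at an arbitrary
#' wavelength interpolates linearly in lambda between the ratio curves of
#' the neighbouring measured series (held constant beyond the outermost
#' series). With a single concentration series this reduces to the fully
#' separable form `f(lambda) * g(c)`; with several, every anchor of every
#' series is reproduced exactly. With no concentration series the surface is
#' constant in c (a message is emitted).
#'
#' @param anchors Anchor tibble (see [qy_anchors_A()]).
#' @param reference_concentration Concentration of the wavelength-profile
#'   anchors, mol L^-1. Default 2.3e-3.
#' @param red_edge_nm Width of the linear decay to zero beyond the last
#'   (reddest) anchor; default 5 nm (no reactivity is assumed a few nm past
#'   the longest measured reactive wavelength). On the blue edge the profile
#'   holds its edge value.
#' @return An object of class `qy_surface`. Evaluate with [predict()] /
#'   [qy_eval()]; inspect with [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' surf <- fit_qy_surface(qy_anchors_A())
#' qy_eval(surf, 382, 0.13e-3) # 0.057
#' qy_eval(surf, 307, 2.3e-3) # 0.115
fit_qy_surface <- function(anchors, reference_concentration = 2.3e-3,
                           red_edge_nm = 5) {
  anchors <- tibble::as_tibble(anchors)
  need <- c("wavelength_nm", "concentration_M", "phi")
  if (!all(need %in% names(anchors)) || nrow(anchors) == 0) {
    abort("`anchors` needs rows and columns wavelength_nm, concentration_M, phi.",
      class = "photokin_input_error"
    )
  }
  if (!"uncertainty" %in% names(anchors)) anchors$uncertainty <- NA_real_
  if (any(anchors$phi < 0 | anchors$phi > 1)) {
    abort("anchor phi values must lie in [0, 1].", class = "photokin_input_error")
  }
  if (any(anchors$wavelength_nm <= 0) ||
    any(!is.na(anchors$concentration_M) & anchors$concentration_M <= 0)) {
    abort("anchor wavelengths and concentrations must be > 0.",
      class = "photokin_input_error"
    )
  }
  c_ref <- reference_concentration
  cc <- ifelse(is.na(anchors$concentration_M), c_ref, anchors$concentration_M)
  key <- paste(signif(anchors$wavelength_nm, 10), signif(cc, 10))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(dup, function(k) {
      length(unique(anchors$phi[key == k])) > 1
    }, logical(1))
    if (any(conflict)) {
      abort("duplicate (wavelength, concentration) anchors with conflicting phi.",
        class = "photokin_input_error"
      )
    }
  }

  # wavelength profile at the reference concentration
  at_ref <- abs(cc - c_ref) <= 1e-9 * c_ref
  prof <- anchors[at_ref, ]
  prof <- prof[!duplicated(prof$wavelength_nm), ]
  if (nrow(prof) == 0) {
    abort("no anchors at the reference concentration to define f(lambda).",
      class = "photokin_input_error"
    )
  }
  if (nrow(prof) == 1) {
    inform("single wavelength anchor: surface is constant in lambda.",
      class = "photokin_log"
    )
  }
  f_fun <- pchip_fun(prof$wavelength_nm, prof$phi)
  lam_rng <- range(prof$wavelength_nm)

  # concentration ratio curves, one per wavelength with >= 2 concentrations
  with_c <- anchors[!is.na(anchors$concentration_M), ]
  series <- list()
  for (lam in sort(unique(with_c$wavelength_nm))) {
    sub <- with_c[with_c$wavelength_nm == lam, ]
    if (length(unique(sub$concentration_M)) < 2) next
    f_here <- f_fun(lam)
    if (f_here <= 0) next
    series[[length(series) + 1]] <- list(
      wavelength_nm = lam,
      conc = sub$concentration_M,
      ratio = sub$phi / f_here,
      g = pchip_fun(sub$concentration_M, sub$phi / f_here)
    )
  }
  if (length(series) == 0) {
    inform("no concentration series among the anchors: surface is constant in c.",
      class = "photokin_log"
    )
  }
  structure(
    list(
      anchors = anchors, reference_concentration = c_ref,
      red_edge_nm = red_edge_nm,
      f = f_fun, lambda_range = lam_rng,
      series = series,
      series_lambda = vapply(series, `[[`, numeric(1), "wavelength_nm")
    ),
    class = "qy_surface"
  )
}

## wavelength profile with edge rules: hold on the blue edge, linear decay
## to zero over red_edge_nm past the reddest anchor
qy_lambda_profile <- function(object, wavelength_nm) {
  f <- object$f(wavelength_nm)
  hi <- object$lambda_range[2]
  over <- wavelength_nm > hi
  if (any(over)) {
    decay <- pmax(0, 1 - (wavelength_nm[over] - hi) / object$red_edge_nm)
    f[over] <- object$f(hi) * decay
  }
  f
}

## concentration correction G(lambda, c): per-series ratio curves blended
## linearly in lambda, held beyond the outermost series
qy_conc_factor <- function(object, wavelength_nm, concentration_M) {
  ns <- length(object$series)
  if (ns == 0) {
    return(rep(1, max(length(wavelength_nm), length(concentration_M))))
  }
  r <- vapply(object$series, function(s) s$g(concentration_M), numeric(length(concentration_M)))
  r <- matrix(r, nrow = length(concentration_M))
  if (ns == 1) {
    return(r[, 1])
  }
  sl <- object$series_lambda
  lam <- pmin(pmax(wavelength_nm, sl[1]), sl[ns])
  i <- findInterval(lam, sl, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), ns - 1L)
  w <- (lam - sl[i]) / (sl[i + 1] - sl[i])
  idx <- seq_along(lam)
  (1 - w) * r[cbind(idx, i)] + w * r[cbind(idx, i + 1L)]
}

#' Evaluate a fitted quantum-yield surface
#'
#' @param object A `qy_surface` from [fit_qy_surface()].
#' @param wavelength_nm,concentration_M Evaluation points (vectors are
#'   recycled to a common length). The engine evaluates at the *current*
#'   chromophore concentration, so Phi rises as the reaction consumes the
#'   starting materials.
#' @param ... Unused.
#' @return Phi values, clamped to \[0, 1\]. Beyond the reddest anchor the
#'   profile decays linearly to zero over `red_edge_nm`; on the blue edge
#'   and outside the measured concentration range, edge values are held.
#' @export
predict.qy_surface <- function(object, wavelength_nm, concentration_M = NULL, ...) {
  if (is.null(concentration_M)) concentration_M <- object$reference_concentration
  n <- max(length(wavelength_nm), length(concentration_M))
  wavelength_nm <- rep_len(wavelength_nm, n)
  concentration_M <- rep_len(concentration_M, n)
  phi <- qy_lambda_profile(object, wavelength_nm) *
    qy_conc_factor(object, wavelength_nm, concentration_M)
  pmin(pmax(phi, 0), 1)
}

#' @rdname predict.qy_surface
#' @param surface A `qy_surface`.
#' @export
qy_eval <- function(surface, wavelength_nm, concentration_M = NULL) {
  predict(surface, wavelength_nm, concentration_M)
}

#' @export
print.qy_surface <- function(x, ...) {
  cat(sprintf(
    "<qy_surface> %d anchors, lambda %g-%g nm, %d concentration series, c_ref %g M\n",
    nrow(x$anchors), x$lambda_range[1], x$lambda_range[2],
    length(x$series), x$reference_concentration
  ))
  invisible(x)
}

#' @method tidy qy_surface
#' @export
tidy.qy_surface <- function(x, ...) {
  a <- x$anchors
  cc <- ifelse(is.na(a$concentration_M), x$reference_concentration, a$concentration_M)
  fitted <- predict(x, a$wavelength_nm, cc)
  dplyr::mutate(a, .fitted = fitted, .resid = .data$phi - fitted)
}

#' @method glance qy_surface
#' @export
glance.qy_surface <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_anchors = nrow(td),
    n_conc_series = length(x$series),
    lambda_min_nm = x$lambda_range[1],
    lambda_max_nm = x$lambda_range[2],
    max_abs_resid = max(abs(td$.resid))
  )
}

#' @method autoplot qy_surface
#' @export
autoplot.qy_surface <- function(object, lambda = NULL, conc = NULL, ...) {
  lambda <- lambda %||% seq(object$lambda_range[1] - 10,
    object$lambda_range[2] + 10,
    by = 1
  )
  with_c <- object$anchors$concentration_M
  crng <- if (all(is.na(with_c))) {
    object$reference_concentration * c(0.5, 2)
  } else {
    range(with_c, na.rm = TRUE)
  }
  conc <- conc %||% seq(crng[1], crng[2], length.out = 80)
  df <- tidyr::expand_grid(wavelength_nm = lambda, concentration_M = conc)
  df$phi <- predict(object, df$wavelength_nm, df$concentration_M)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$concentration_M * 1e3)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$phi)) +
    ggplot2::geom_point(
      data = dplyr::filter(object$anchors, !is.na(.data$concentration_M)),
      ggplot2::aes(y = .data$concentration_M * 1e3),
      colour = "white", shape = 21
    ) +
    ggplot2::scale_fill_viridis_c(name = expression(Phi)) +
    ggplot2::labs(
      x = "wavelength (nm)", y = "concentration (mM)",
      title = "Reaction quantum yield surface"
    )
}
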