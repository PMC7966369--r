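#' Simulate a wavelength-resolved photoreaction
#'
#' The iterative engine at the heart of photokin. Time advances in fixed 1 s
#' steps. Within each step, the photon dose delivered by the source during
#' one second (after vessel-wall losses) is propagated through the stack of
#' solution segments; in every wavelength bin and segment, decadic
#' Beer-Lambert absorption splits the photons among all absorbing species in
#' proportion to their `eps * c` contributions. For each photoreaction the
#' product formed in a segment is
#' `sum over bins of Phi(lambda, c_chromophore) * photons absorbed by the
#' chromophore`, clamped so that neither the chromophore nor the trap can be
#' driven negative (one product event consumes one of each). Photons
#' absorbed by traps, products and inert absorbers attenuate the beam but
#' are non-productive. After the chemistry of each step the solution is
#' ideally mixed (amounts redistributed uniformly across segments), unless
#' `mix = FALSE` (the unstirred geometry used for quantum-yield
#' determinations). The engine is fully deterministic.
#'
#' Two or more photoreactions may share a trap: reactions are processed in
#' table order within a step and draw jointly on the shared pool (the
#' within-step amounts are small enough that the ordering is immaterial).
#'
#' @param species Species tibble, see [photo_species()].
#' @param reactions Reaction tibble, see [photo_reaction()]. May have any
#'   number of rows; two rows sharing a trap is the competing
#'   (lambda-orthogonality) configuration.
#' @param source A [led_source()] or [laser_source()]. A pulsed laser
#'   delivers `rep_rate_Hz` pulses per 1 s step.
#' @param vessel A [vessel()].
#' @param duration_s Total irradiation time, whole seconds (>= 0).
#' @param grid Engine [wl_grid()]; default: the LED shape's grid, or a
#'   single bin at the laser line. All spectra are resampled onto it.
#' @param mix Ideal mixing after every step (default TRUE).
#' @param snapshots Record light-attenuation maps at t = 0, T/3, 2T/3 and T
#'   (floored to whole seconds). Default TRUE.
#' @param debug_conservation Check photon conservation (entry = absorbed +
#'   exit) per bin at every step and record the worst relative error.
#' @return A `photokin_sim` object with elements
#'   \describe{
#'     \item{trace}{tibble: `t_s`, one `conversion_<chromophore>` column per
#'       reaction (product formed / initial chromophore), one
#'       `amount_<species>` column per species (mol).}
#'     \item{maps}{tibble of light-attenuation maps, long format: `t_s`,
#'       `segment`, `wavelength_nm`, `photons_mol` -- photons entering each
#'       segment during one second at the snapshot time.}
#'     \item{final_state}{species x segments matrix of amounts, mol.}
#'     \item{conservation}{max relative photon / mass conservation errors
#'       (when `debug_conservation = TRUE`).}
#'   }
#'   `tidy()` returns the trace, `glance()` a one-row summary, `autoplot()`
#'   the conversion curves.
#' @export
#' @examples
#' g <- wl_grid(280, 450)
#' lib <- synthetic_chromophores(g)
#' sp <- dplyr::bind_rows(
#'   photo_species("A", lib$A, "chromophore", 1.15e-6),
#'   photo_species("NEM", lib$NEM, "trap", 2.71e-6),
#'   photo_species("AP", lib$AP, "product", 0)
#' )
#' rx <- photo_reaction("A", "NEM", "AP", qy = fit_qy_surface(qy_anchors_A()))
#' led <- led_source(fixture_spectrum(g, "led_gaussian", center = 343), 0.025)
#' ves <- vessel(fixture_spectrum(g, "vessel_logistic"), 0.6, 5e-4, n_segments = 20)
#' sim <- simulate_photoreaction(sp, rx, led, ves, duration_s = 60)
#' tail(tidy(sim), 1)
simulate_photoreaction <- function(species, reactions, source, vessel,
                                   duration_s, grid = NULL, mix = TRUE,
                                   snapshots = TRUE,
                                   debug_conservation = FALSE) {
  duration_s <- as.integer(duration_s)
  if (duration_s < 0) abort("`duration_s` must be >= 0.", class = "photokin_config_error")
  eng <- engine_context(species, reactions, source, vessel, grid)
  snap_times <- if (snapshots) {
    unique(c(0L, floor(duration_s / 3), floor(2 * duration_s / 3), duration_s))
  } else {
    integer(0)
  }
  run_engine(eng, duration_s,
    mix = mix, snap_times = snap_times,
    debug_conservation = debug_conservation
  )
}

## assemble the internal engine context: resampled matrices, per-second
## photon dose, compiled quantum-yield evaluators, initial segmented state
engine_context <- function(species, reactions, source, vessel, grid = NULL) {
  if (!inherits(source, "light_source")) {
    abort("`source` must be a light_source.", class = "photokin_config_error")
  }
  if (!inherits(vessel, "vessel")) {
    abort("`vessel` must be a vessel.", class = "photokin_config_error")
  }
  if (is.null(grid)) {
    grid <- if (source$kind == "led") {
      g <- spectrum_grid(source$shape)
      if (is.null(g)) abort("LED shape must be on a uniform grid.", class = "photokin_config_error")
      g
    } else {
      mono_grid(source$center_nm)
    }
  }
  sys <- build_system(species, reactions, vessel, grid)
  q_source <- source_photons_per_second(source, grid)
  t_vessel <- resample(vessel$transmittance, grid)$value
  q1 <- q_source * t_vessel # photons/s entering the solution
  n_sp <- nrow(sys$species)
  S0 <- matrix(sys$species$amount_mol / vessel$n_segments,
    nrow = n_sp, ncol = vessel$n_segments,
    dimnames = list(sys$species$name, NULL)
  )
  rx <- lapply(seq_len(nrow(sys$reactions)), function(r) {
    list(
      ic = sys$idx[[sys$reactions$chromophore[r]]],
      it = sys$idx[[sys$reactions$trap[r]]],
      ip = sys$idx[[sys$reactions$product[r]]],
      qy = compile_qy(sys$reactions$qy[[r]], grid$centers),
      chromophore = sys$reactions$chromophore[r]
    )
  })
  list(
    grid = grid, eps = sys$eps, q1 = q1,
    species = sys$species, reactions = sys$reactions, rx = rx,
    vessel = vessel, n0 = setNames(sys$species$amount_mol, sys$species$name),
    S0 = S0
  )
}

## compile a quantum yield (surface or fixed scalar) into a fast evaluator
## phi(bin vector) as a function of the current chromophore concentration
compile_qy <- function(qy, lambda_vec) {
  if (is.numeric(qy)) {
    phi <- rep(qy, length(lambda_vec))
    return(function(conc) phi)
  }
  f_vec <- qy_lambda_profile(qy, lambda_vec)
  ns <- length(qy$series)
  if (ns == 0) {
    phi0 <- pmin(pmax(f_vec, 0), 1)
    return(function(conc) phi0)
  }
  # tabulate each ratio curve on a fine concentration grid (edges held)
  crng <- range(unlist(lapply(qy$series, `[[`, "conc")))
  cgrid <- seq(crng[1], crng[2], length.out = 4001)
  gfuns <- lapply(qy$series, function(s) approxfun(cgrid, s$g(cgrid), rule = 2))
  if (ns == 1) {
    g1 <- gfuns[[1]]
    return(function(conc) pmin(pmax(f_vec * g1(conc), 0), 1))
  }
  sl <- qy$series_lambda
  lam <- pmin(pmax(lambda_vec, sl[1]), sl[ns])
  i <- pmin(pmax(findInterval(lam, sl, rightmost.closed = TRUE), 1L), ns - 1L)
  w <- (lam - sl[i]) / (sl[i + 1] - sl[i])
  function(conc) {
    rs <- vapply(gfuns, function(g) g(conc), numeric(1))
    pmin(pmax(f_vec * ((1 - w) * rs[i] + w * rs[i + 1L]), 0), 1)
  }
}

## one 1 s step: propagate, react, clamp; optionally return the map of
## photons entering each segment and the conservation error
engine_step <- function(S, eng, q_in, collect_entering = FALSE,
                        debug_conservation = FALSE) {
  E <- eng$eps
  l_seg <- eng$vessel$l_seg_cm
  v_seg <- eng$vessel$v_seg_L
  n_seg <- ncol(S)
  q <- q_in
  entering <- if (collect_entering) matrix(0, length(q), n_seg) else NULL
  cons_err <- 0
  for (s in seq_len(n_seg)) {
    if (collect_entering) entering[, s] <- q
    conc <- S[, s] / v_seg
    a_tot <- drop(E %*% conc) * l_seg
    t10 <- 10^(-a_tot)
    abs_tot <- q * (1 - t10)
    pos <- a_tot > 0
    for (r in eng$rx) {
      contrib <- E[, r$ic] * conc[r$ic] * l_seg
      abs_x <- numeric(length(q))
      abs_x[pos] <- abs_tot[pos] * contrib[pos] / a_tot[pos]
      phi <- r$qy(conc[r$ic])
      d_p <- sum(phi * abs_x)
      d_p <- min(d_p, S[r$ic, s], S[r$it, s])
      S[r$ic, s] <- S[r$ic, s] - d_p
      S[r$it, s] <- S[r$it, s] - d_p
      S[r$ip, s] <- S[r$ip, s] + d_p
    }
    if (debug_conservation) {
      recon <- abs_tot + q * t10
      ref <- pmax(q, .Machine$double.xmin)
      cons_err <- max(cons_err, max(abs(recon - q) / ref))
    }
    q <- q * t10
  }
  list(S = S, exit = q, entering = entering, cons_err = cons_err)
}

#' Ideally mix a segmented state
#'
#' Redistributes every species uniformly across the equal-volume segments
#' (amounts set to the per-segment mean); totals are conserved.
#'
#' @param amounts A species x segments matrix of amounts (mol).
#' @return Matrix of the same shape with uniform columns.
#' @export
#' @examples
#' mix_segments(matrix(c(4e-7, 0, 0, 0), nrow = 1))
mix_segments <- function(amounts) {
  totals <- rowSums(amounts)
  matrix(totals / ncol(amounts),
    nrow = nrow(amounts), ncol = ncol(amounts),
    dimnames = dimnames(amounts)
  )
}

## main loop shared by simulate_photoreaction and the selectivity scan
run_engine <- function(eng, duration_s, mix = TRUE, snap_times = integer(0),
                       debug_conservation = FALSE, S = NULL) {
  S <- S %||% eng$S0
  n_rx <- length(eng$rx)
  n_sp <- nrow(S)
  chrom0 <- vapply(eng$rx, function(r) max(eng$n0[[r$ic]], .Machine$double.xmin), numeric(1))
  conv <- matrix(0, duration_s + 1, n_rx)
  amounts <- matrix(0, duration_s + 1, n_sp, dimnames = list(NULL, rownames(S)))
  amounts[1, ] <- rowSums(S)
  maps <- list()
  if (0L %in% snap_times) maps[["0"]] <- attmap_from_state(S, eng)
  max_cons <- 0
  mass0 <- mass_invariants(S, eng)
  max_mass <- 0
  t <- 0L
  while (t < duration_s) {
    st <- engine_step(S, eng, eng$q1, debug_conservation = debug_conservation)
    S <- st$S
    max_cons <- max(max_cons, st$cons_err)
    if (mix) S <- mix_segments(S)
    t <- t + 1L
    amounts[t + 1, ] <- rowSums(S)
    conv[t + 1, ] <- vapply(
      seq_len(n_rx),
      function(r) sum(S[eng$rx[[r]]$ip, ]) - eng$n0[[eng$rx[[r]]$ip]],
      numeric(1)
    ) / chrom0
    if (debug_conservation) {
      m <- mass_invariants(S, eng)
      max_mass <- max(max_mass, max(abs(m - mass0) / pmax(mass0, .Machine$double.xmin)))
    }
    if (t %in% snap_times) maps[[as.character(t)]] <- attmap_from_state(S, eng)
  }
  trace <- tibble(t_s = 0:duration_s)
  for (r in seq_len(n_rx)) {
    trace[[paste0("conversion_", eng$rx[[r]]$chromophore)]] <- conv[, r]
  }
  for (j in seq_len(n_sp)) {
    trace[[paste0("amount_", rownames(S)[j])]] <- amounts[, j]
  }
  map_tbl <- if (length(maps) > 0) {
    dplyr::bind_rows(lapply(names(maps), function(tt) {
      dplyr::mutate(maps[[tt]], t_s = as.integer(tt), .before = 1)
    }))
  } else {
    tibble(
      t_s = integer(), segment = integer(),
      wavelength_nm = numeric(), photons_mol = numeric()
    )
  }
  structure(
    list(
      trace = trace, maps = map_tbl, final_state = S,
      grid = eng$grid, species = eng$species, reactions = eng$reactions,
      vessel = eng$vessel,
      conservation = if (debug_conservation) {
        c(photon_rel = max_cons, mass_rel = max_mass)
      } else {
        NULL
      }
    ),
    class = "photokin_sim"
  )
}

## chromophore+product and trap+all products totals (must stay constant)
mass_invariants <- function(S, eng) {
  tot <- rowSums(S)
  out <- numeric(0)
  for (r in eng$rx) {
    out <- c(out, tot[r$ic] + tot[r$ip])
  }
  traps <- unique(vapply(eng$rx, function(r) r$it, numeric(1)))
  for (it in traps) {
    prods <- vapply(
      Filter(function(r) r$it == it, eng$rx),
      function(r) tot[r$ip] - eng$n0[[r$ip]], numeric(1)
    )
    out <- c(out, tot[it] + sum(prods))
  }
  out
}

## light-attenuation map of the current state: photons (mol) entering each
## segment per wavelength bin during one second, before any chemistry
attmap_from_state <- function(S, eng) {
  st <- engine_step(S, eng, eng$q1, collect_entering = TRUE)
  tibble(
    segment = rep(seq_len(ncol(S)), each = eng$grid$n),
    wavelength_nm = rep(eng$grid$centers, ncol(S)),
    photons_mol = as.vector(st$entering)
  )
}

#' Light-attenuation map for a system state
#'
#' Photons (mol) per 0.5 nm wavelength bin entering each solution segment
#' during one second of irradiation, for the current composition -- the
#' spatio-spectral picture of where light is absorbed.
#'
#' @inheritParams simulate_photoreaction
#' @param state Optional species x segments amounts matrix; default: the
#'   initial amounts spread uniformly.
#' @return A tibble `segment`, `wavelength_nm`, `photons_mol`.
#' @export
attenuation_map <- function(species, reactions, source, vessel, grid = NULL,
                            state = NULL) {
  eng <- engine_context(species, reactions, source, vessel, grid)
  attmap_from_state(state %||% eng$S0, eng)
}

#' @export
print.photokin_sim <- function(x, ...) {
  n_t <- nrow(x$trace) - 1
  cat(sprintf(
    "<photokin_sim> %d s, %d reactions, %d segments, %d wavelength bins\n",
    n_t, nrow(x$reactions), x$vessel$n_segments, x$grid$n
  ))
  conv_cols <- grep("^conversion_", names(x$trace), value = TRUE)
  for (cc in conv_cols) {
    cat(sprintf("  final %s: %.4f\n", cc, x$trace[[cc]][nrow(x$trace)]))
  }
  invisible(x)
}

#' @method tidy photokin_sim
#' @export
tidy.photokin_sim <- function(x, ...) x$trace

#' @method glance photokin_sim
#' @export
glance.photokin_sim <- function(x, ...) {
  tr <- x$trace
  conv_cols <- grep("^conversion_", names(tr), value = TRUE)
  out <- tibble(
    duration_s = tr$t_s[nrow(tr)],
    n_reactions = nrow(x$reactions),
    n_segments = x$vessel$n_segments,
    n_bins = x$grid$n
  )
  for (cc in conv_cols) out[[paste0("final_", cc)]] <- tr[[cc]][nrow(tr)]
  out
}

#' @method autoplot photokin_sim
#' @export
autoplot.photokin_sim <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    object$trace[, c("t_s", grep("^conversion_", names(object$trace), value = TRUE))],
    -"t_s",
    names_to = "reaction", names_prefix = "conversion_",
    values_to = "conversion"
  )
  ggplot2::ggplot(tr, ggplot2::aes(.data$t_s, .data$conversion, colour = .data$reaction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "irradiation time (s)", y = "conversion") +
    ggplot2::ylim(0, 1)
}

#' Heatmap of a light-attenuation map
#'
#' @param sim A `photokin_sim` with recorded maps, or a map tibble from
#'   [attenuation_map()].
#' @return A ggplot: wavelength x segment heatmaps of photons per bin,
#'   faceted by snapshot time when several are present.
#' @export
plot_attenuation_map <- function(sim) {
  maps <- if (inherits(sim, "photokin_sim")) sim$maps else sim
  if (nrow(maps) == 0) abort("no attenuation maps recorded.", class = "photokin_input_error")
  p <- ggplot2::ggplot(maps, ggplot2::aes(.data$wavelength_nm, .data$segment)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$photons_mol)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "photons (mol)") +
    ggplot2::labs(x = "wavelength (nm)", y = "segment (front to back)")
  if ("t_s" %in% names(maps) && length(unique(maps$t_s)) > 1) {
    p <- p + ggplot2::facet_wrap(~t_s, labeller = ggplot2::label_both)
  }
  p
}
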