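#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON) with the shape
#' ```yaml
#' mode: simulate            # simulate | competing | scan | estimate-qy
#' grid: {lambda_min: 280, lambda_max: 450, step: 0.5}
#' species:
#'   - {name: A, role: chromophore, amount_mol: 1.15e-6, epsilon: eps_A.csv}
#'   - {name: NEM, role: trap, amount_mol: 2.71e-6, epsilon: eps_NEM.csv}
#'   - {name: AP, role: product, amount_mol: 0, epsilon: zero}
#' reactions:
#'   - {chromophore: A, trap: NEM, product: AP, qy: anchors_A}
#' vessel: {transmittance: vial.csv, path_length_cm: 0.6,
#'          volume_L: 5.0e-4, n_segments: 50}
#' source: {kind: led, shape: led2.csv, power_W: 0.025}
#' duration_s: 3600
#' ```
#' `epsilon`/`transmittance`/`shape` entries are spectrum CSV paths resolved
#' relative to the config file (`zero` gives a transparent species); `qy` is
#' a number (fixed apparent Phi), the name of a packaged anchor table
#' (`anchors_A`, `anchors_C`), or an anchor CSV path. A laser source block
#' is `{kind: laser, center_nm, pulse_energy_J, rep_rate_Hz}`. All
#' validation problems are collected and reported together, each naming the
#' offending field.
#'
#' @param path Config file path.
#' @return A validated config (class `photokin_config`), carrying the raw
#'   parsed list plus the constructed `species`, `reactions`, `vessel`,
#'   `source` and `grid` objects.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "photokin_io_error")
  }
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  build_run_config(raw, base_dir = dirname(path))
}

#' @param raw A config as a nested list (as parsed from YAML/JSON).
#' @param base_dir Directory against which relative file paths resolve.
#' @rdname load_run_config
#' @export
build_run_config <- function(raw, base_dir = ".") {
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  res <- function(p) if (is.character(p) && !file.exists(p)) file.path(base_dir, p) else p

  need(is.list(raw$grid), "`grid` block missing.")
  grid <- NULL
  if (is.list(raw$grid)) {
    g <- raw$grid
    need(is.numeric(g$lambda_min) && is.numeric(g$lambda_max), "`grid.lambda_min`/`grid.lambda_max` must be numbers.")
    if (is.numeric(g$lambda_min) && is.numeric(g$lambda_max)) {
      grid <- tryCatch(wl_grid(g$lambda_min, g$lambda_max, g$step %||% 0.5),
        error = function(e) {
          errs <<- c(errs, paste0("`grid`: ", conditionMessage(e)))
          NULL
        }
      )
    }
  }

  load_spec <- function(entry, field, unit) {
    if (identical(entry, "zero")) {
      if (!is.null(grid)) {
        return(zero_spectrum(grid, unit = unit))
      }
      return(NULL)
    }
    p <- res(entry)
    if (!is.character(entry) || !file.exists(p)) {
      errs <<- c(errs, sprintf("`%s`: file not found (%s).", field, entry))
      return(NULL)
    }
    tryCatch(read_spectrum_csv(p, unit = unit), error = function(e) {
      errs <<- c(errs, sprintf("`%s`: %s", field, conditionMessage(e)))
      NULL
    })
  }

  species <- NULL
  need(is.list(raw$species) && length(raw$species) > 0, "`species` list missing or empty.")
  if (is.list(raw$species) && length(raw$species) > 0) {
    rows <- lapply(seq_along(raw$species), function(i) {
      s <- raw$species[[i]]
      f <- sprintf("species[%d]", i)
      need(is.character(s$name), sprintf("`%s.name` missing.", f))
      need(
        is.character(s$role) &&
          s$role %in% c("chromophore", "trap", "product", "inert_absorber"),
        sprintf("`%s.role` must be chromophore/trap/product/inert_absorber.", f)
      )
      need(is.numeric(s$amount_mol) && s$amount_mol >= 0, sprintf("`%s.amount_mol` must be >= 0.", f))
      eps <- load_spec(s$epsilon, paste0(f, ".epsilon"), "molar_attenuation")
      if (is.null(eps) || !is.character(s$name) || !is.numeric(s$amount_mol) ||
        s$amount_mol < 0) {
        return(NULL)
      }
      photo_species(s$name, eps, s$role, s$amount_mol)
    })
    if (!any(vapply(rows, is.null, logical(1)))) species <- dplyr::bind_rows(rows)
  }

  reactions <- NULL
  need(is.list(raw$reactions) && length(raw$reactions) > 0, "`reactions` list missing or empty.")
  if (is.list(raw$reactions) && length(raw$reactions) > 0) {
    rows <- lapply(seq_along(raw$reactions), function(i) {
      r <- raw$reactions[[i]]
      f <- sprintf("reactions[%d]", i)
      for (col in c("chromophore", "trap", "product")) {
        need(is.character(r[[col]]), sprintf("`%s.%s` missing.", f, col))
      }
      qy <- r$qy
      qy_obj <- if (is.numeric(qy)) {
        qy
      } else if (identical(qy, "anchors_A")) {
        fit_qy_surface(qy_anchors_A())
      } else if (identical(qy, "anchors_C")) {
        fit_qy_surface(qy_anchors_C())
      } else if (is.character(qy) && file.exists(res(qy))) {
        fit_qy_surface(read_qy_anchors_csv(res(qy)))
      } else {
        need(FALSE, sprintf("`%s.qy` must be a number, anchors_A/anchors_C, or an anchor CSV path.", f))
        NULL
      }
      if (is.null(qy_obj) || !all(vapply(c("chromophore", "trap", "product"), function(cn) is.character(r[[cn]]), logical(1)))) {
        return(NULL)
      }
      photo_reaction(r$chromophore, r$trap, r$product, qy_obj)
    })
    if (!any(vapply(rows, is.null, logical(1)))) reactions <- dplyr::bind_rows(rows)
  }

  ves <- NULL
  need(is.list(raw$vessel), "`vessel` block missing.")
  if (is.list(raw$vessel)) {
    v <- raw$vessel
    for (fld in c("path_length_cm", "volume_L")) {
      need(
        is.numeric(v[[fld]]) && v[[fld]] > 0,
        sprintf("`vessel.%s` must be > 0.", fld)
      )
    }
    tr <- load_spec(v$transmittance, "vessel.transmittance", "transmittance")
    if (!is.null(tr) && is.numeric(v$path_length_cm) && v$path_length_cm > 0 &&
      is.numeric(v$volume_L) && v$volume_L > 0) {
      ves <- vessel(tr, v$path_length_cm, v$volume_L, v$n_segments %||% 50L)
    }
  }

  src <- NULL
  need(is.list(raw$source), "`source` block missing.")
  if (is.list(raw$source)) {
    s <- raw$source
    if (identical(s$kind, "led")) {
      shape <- load_spec(s$shape, "source.shape", "relative")
      need(is.numeric(s$power_W) && s$power_W > 0, "`source.power_W` must be > 0.")
      if (!is.null(shape) && is.numeric(s$power_W) && s$power_W > 0) {
        src <- led_source(if (is.null(grid)) shape else resample(shape, grid), s$power_W)
      }
    } else if (identical(s$kind, "laser")) {
      need(is.numeric(s$center_nm), "`source.center_nm` must be a number.")
      need(is.numeric(s$pulse_energy_J) && s$pulse_energy_J > 0, "`source.pulse_energy_J` must be > 0.")
      if (is.numeric(s$center_nm) && is.numeric(s$pulse_energy_J) && s$pulse_energy_J > 0) {
        src <- laser_source(s$center_nm, s$pulse_energy_J, s$rep_rate_Hz %||% 20)
      }
    } else {
      need(FALSE, "`source.kind` must be `led` or `laser`.")
    }
  }

  mode <- raw$mode %||% "simulate"
  need(mode %in% c("simulate", "competing", "scan", "estimate-qy"), "`mode` must be simulate/competing/scan/estimate-qy.")
  if (!identical(mode, "scan")) {
    need(
      is.numeric(raw$duration_s) && raw$duration_s >= 0,
      "`duration_s` must be a number >= 0."
    )
  }

  if (length(errs) > 0) {
    abort(paste(c("invalid configuration:", errs), collapse = "\n  - "),
      class = "photokin_config_error"
    )
  }
  structure(
    list(
      raw = raw, mode = mode, grid = grid, species = species,
      reactions = reactions, vessel = ves, source = src,
      duration_s = raw$duration_s, scan = raw$scan
    ),
    class = "photokin_config"
  )
}

#' @param config A `photokin_config`.
#' @rdname load_run_config
#' @export
write_run_config <- function(config, path) {
  raw <- if (inherits(config, "photokin_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run a validated configuration
#'
#' Dispatches on the config `mode`: `simulate` and `competing` run
#' [simulate_photoreaction()], `scan` runs [scan_selectivity()] using the
#' `scan` block (`lambdas` or `lambda_min`/`lambda_max`/`lambda_step`,
#' `target_conversion`, `pulse_cap`), and `estimate-qy` runs the
#' appropriate inverse fit against `observed`.
#'
#' @param config A `photokin_config` from [load_run_config()].
#' @param observed Observed conversion (estimate-qy mode only).
#' @return The mode's result object.
#' @export
run_config <- function(config, observed = NULL) {
  stopifnot(inherits(config, "photokin_config"))
  switch(config$mode,
    simulate = ,
    competing = simulate_photoreaction(
      config$species, config$reactions, config$source, config$vessel,
      config$duration_s,
      grid = config$grid
    ),
    scan = {
      sc <- config$scan %||% list()
      lambdas <- sc$lambdas %||%
        seq(sc$lambda_min, sc$lambda_max, by = sc$lambda_step %||% 5)
      scan_selectivity(
        config$species, config$reactions, config$vessel, lambdas,
        pulse_energy_J = config$source$pulse_energy_J,
        rep_rate_Hz = config$source$rep_rate_Hz,
        target_conversion = sc$target_conversion %||% 0.9,
        pulse_cap = sc$pulse_cap %||% 1e6
      )
    },
    `estimate-qy` = {
      if (is.null(observed)) {
        abort("estimate-qy mode needs `observed`.", class = "photokin_input_error")
      }
      if (config$source$kind == "led") {
        fit_apparent_qy(
          config$species, config$reactions, config$source,
          config$vessel, config$duration_s, observed
        )
      } else {
        fit_monochromatic_qy(
          config$species, config$reactions, config$source,
          config$vessel, config$duration_s, observed
        )
      }
    }
  )
}

#' Write simulation outputs to a directory
#'
#' Writes `trace.csv` (the conversion/amount trace), one `attmap_<t>.csv`
#' per recorded snapshot (long format: `t_s`, `segment`, `wavelength_nm`,
#' `photons_mol`) and `run_manifest.json` recording file checksums, the
#' constants version and the package version. Reruns of an identical
#' configuration are bit-identical except for the manifest timestamp.
#'
#' @param sim A `photokin_sim`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_outputs <- function(sim, outdir) {
  stopifnot(inherits(sim, "photokin_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  trace_path <- file.path(outdir, "trace.csv")
  readr::write_csv(sim$trace, trace_path)
  files <- c(files, trace_path)
  for (tt in unique(sim$maps$t_s)) {
    p <- file.path(outdir, sprintf("attmap_%d.csv", tt))
    readr::write_csv(dplyr::filter(sim$maps, .data$t_s == tt), p)
    files <- c(files, p)
  }
  manifest <- list(
    package = "photokin",
    version = as.character(utils::packageVersion("photokin")),
    constants = photokin_constants$version,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_segments = sim$vessel$n_segments,
    grid = list(
      lambda_min = sim$grid$lambda_min, lambda_max = sim$grid$lambda_max,
      step = sim$grid$step
    ),
    files = lapply(
      setNames(files, basename(files)),
      function(f) list(md5 = unname(tools::md5sum(f)))
    )
  )
  man_path <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, man_path))
}
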