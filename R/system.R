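#' Species and photoreaction tables
#'
#' A reaction system is described by two tibbles. The species table has one
#' row per molecular species with its role (`chromophore`, `trap`,
#' `product`, or `inert_absorber`), the initial amount in mol, and its molar
#' attenuation spectrum as a list-column. The reaction table has one row per
#' photoreaction with 1:1:1 stoichiometry -- each product-forming event
#' consumes one chromophore and one trap molecule -- and the quantum yield
#' as a list-column holding either a fitted [fit_qy_surface()] object or a
#' single fixed (apparent) Phi.
#'
#' @param name Species name.
#' @param epsilon Molar attenuation [spectrum()] (unit `molar_attenuation`);
#'   use [zero_spectrum()] for species transparent in the studied window.
#' @param role One of `"chromophore"`, `"trap"`, `"product"`,
#'   `"inert_absorber"`.
#' @param amount_mol Initial amount, mol (>= 0).
#' @return `photo_species()`: a one-row tibble; combine rows with
#'   [dplyr::bind_rows()].
#' @export
#' @examples
#' g <- wl_grid(280, 450)
#' lib <- synthetic_chromophores(g)
#' sp <- dplyr::bind_rows(
#'   photo_species("A", lib$A, "chromophore", 1.15e-6),
#'   photo_species("NEM", lib$NEM, "trap", 2.71e-6),
#'   photo_species("AP", lib$AP, "product", 0)
#' )
photo_species <- function(name, epsilon,
                          role = c("chromophore", "trap", "product", "inert_absorber"),
                          amount_mol = 0) {
  role <- match.arg(role)
  epsilon <- as_spectrum(epsilon)
  if (amount_mol < 0) abort("`amount_mol` must be >= 0.", class = "photokin_input_error")
  tibble(
    name = name, role = role, amount_mol = amount_mol,
    epsilon = list(epsilon)
  )
}

#' @param chromophore,trap,product Species names referring to rows of the
#'   species table.
#' @param qy Either a `qy_surface` or a single numeric fixed/apparent Phi in
#'   \[0, 1\].
#' @rdname photo_species
#' @export
photo_reaction <- function(chromophore, trap, product, qy) {
  if (is.numeric(qy)) {
    if (length(qy) != 1 || qy < 0 || qy > 1) {
      abort("fixed `qy` must be a single value in [0, 1].", class = "photokin_input_error")
    }
  } else if (!inherits(qy, "qy_surface")) {
    abort("`qy` must be a number or a `qy_surface`.", class = "photokin_input_error")
  }
  tibble(
    chromophore = chromophore, trap = trap, product = product,
    qy = list(qy)
  )
}

## validate the system against the engine grid; returns internal matrices
build_system <- function(species, reactions, vessel, grid) {
  species <- tibble::as_tibble(species)
  reactions <- tibble::as_tibble(reactions)
  errs <- character()
  need_sp <- c("name", "role", "amount_mol", "epsilon")
  if (!all(need_sp %in% names(species))) {
    abort("species table needs columns name, role, amount_mol, epsilon.",
      class = "photokin_config_error"
    )
  }
  if (anyDuplicated(species$name)) errs <- c(errs, "duplicate species names.")
  for (r in seq_len(nrow(reactions))) {
    for (col in c("chromophore", "trap", "product")) {
      nm <- reactions[[col]][r]
      if (!nm %in% species$name) {
        errs <- c(errs, sprintf("reaction %d: %s `%s` is not in the species table.", r, col, nm))
      }
    }
  }
  chrom_use <- table(reactions$chromophore)
  if (any(chrom_use > 1)) {
    errs <- c(errs, "a chromophore may drive only one photoreaction.")
  }
  if (length(errs) > 0) {
    abort(paste(errs, collapse = "\n"), class = "photokin_config_error")
  }
  eps <- vapply(
    species$epsilon,
    function(e) resample(as_spectrum(e), grid)$value,
    numeric(grid$n)
  )
  eps <- matrix(eps, nrow = grid$n, dimnames = list(NULL, species$name))
  list(
    species = species, reactions = reactions,
    eps = eps,
    idx = setNames(seq_len(nrow(species)), species$name)
  )
}
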