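#' Nonbonded parameters of a (possibly alchemical) monovalent cation
#'
#' Bundles the Lennard-Jones parameters and charge of an ion species, plus an
#' optional list of pair-specific overrides (NBFIX-style corrections) keyed by
#' ligand atom class.  The `rmin` field is the Rmin/2 convention: the
#' ion--ligand pair minimum-energy distance is the sum of the two Rmin/2
#' values unless an override is present.
#'
#' @param species Label: `"Na"`, `"K"`, or `"hybrid"` for a
#'   lambda-interpolated alchemical intermediate.
#' @param epsilon LJ well depth, kcal/mol (> 0).
#' @param rmin LJ Rmin/2, Angstrom (> 0).
#' @param charge Ion charge in e; must be +1 for Na and K.
#' @param nbfix Named list of pair overrides; each element is
#'   `list(epsilon=, rmin=)` giving the *pair* well depth and minimum-energy
#'   distance for the named ligand atom class.
#' @return An object of class `ion_params`.
#' @seealso [default_ion_params()], [interpolate_ion_params()]
#' @export
ion_params <- function(species, epsilon, rmin, charge = 1, nbfix = list()) {
  stopifnot(is.character(species), length(species) == 1)
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.numeric(rmin) || rmin <= 0) stop("rmin must be > 0")
  if (species %in% c("Na", "K") && charge != 1)
    stop("Na and K carry charge +1")
  if (length(nbfix)) {
    ok <- vapply(nbfix, function(x)
      is.list(x) && all(c("epsilon", "rmin") %in% names(x)), logical(1))
    if (!all(ok) || is.null(names(nbfix)) || any(names(nbfix) == ""))
      stop("nbfix must be a named list of list(epsilon=, rmin=) entries")
  }
  structure(list(species = species, charge = charge,
                 epsilon = as.numeric(epsilon), rmin = as.numeric(rmin),
                 nbfix = nbfix),
            class = "ion_params")
}

#' Packaged default ion parameters
#'
#' Reads the packaged defaults file (published fixed-charge monovalent-ion
#' Lennard-Jones values) and returns the parameter set for one species.
#'
#' @param species `"Na"` or `"K"`.
#' @return An [ion_params()] object.
#' @export
#' @examples
#' default_ion_params("Na")
default_ion_params <- function(species = c("Na", "K")) {
  species <- match.arg(species)
  path <- system.file("extdata", "ion_defaults.json", package = "pumpsel",
                      mustWork = TRUE)
  defs <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  d <- defs[[species]]
  nb <- if (length(d$nbfix)) lapply(d$nbfix, as.list) else list()
  ion_params(species, epsilon = d$epsilon, rmin = d$rmin, nbfix = nb)
}

#' @export
print.ion_params <- function(x, ...) {
  cat(sprintf("ion %-6s  q=%+g e  eps=%g kcal/mol  rmin/2=%g A  (%d pair overrides)\n",
              x$species, x$charge, x$epsilon, x$rmin, length(x$nbfix)))
  invisible(x)
}

#' Linear alchemical interpolation between Na+ and K+ parameters
#'
#' Every Lennard-Jones parameter and every pair-specific override is
#' interpolated linearly in the coupling factor `lambda`; the charge stays
#' +1 throughout.  `lambda = 0` returns the Na+ parameters exactly and
#' `lambda = 1` the K+ parameters exactly; `lambda = 0.5` is the Na/K hybrid
#' at the middle of the interpolation.
#'
#' @param na,k [ion_params()] for the two endpoints.  Their `nbfix` override
#'   lists must name the same ligand atom classes.
#' @param lambda Coupling factor in \[0, 1\].
#' @return An [ion_params()] object (species `"Na"`, `"K"` or `"hybrid"`).
#' @export
interpolate_ion_params <- function(na, k, lambda) {
  stopifnot(inherits(na, "ion_params"), inherits(k, "ion_params"))
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  if (!setequal(names(na$nbfix), names(k$nbfix)))
    stop("nbfix override lists of the two species name different classes")
  if (lambda == 0) return(na)
  if (lambda == 1) return(k)
  mix <- function(a, b) (1 - lambda) * a + lambda * b
  nb <- lapply(names(na$nbfix), function(cl)
    list(epsilon = mix(na$nbfix[[cl]]$epsilon, k$nbfix[[cl]]$epsilon),
         rmin = mix(na$nbfix[[cl]]$rmin, k$nbfix[[cl]]$rmin)))
  names(nb) <- names(na$nbfix)
  ion_params("hybrid",
             epsilon = mix(na$epsilon, k$epsilon),
             rmin = mix(na$rmin, k$rmin),
             charge = 1, nbfix = nb)
}
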