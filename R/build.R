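#' Build a reduced binding-site model from a scenario description
#'
#' Deterministically instantiates a [binding_site_model()] from a structured
#' scenario configuration (an R list or a path to a JSON file).  Ligand
#' anchors are placed on a ring of radius `anchor_radius` with alternating
#' out-of-plane offsets, giving a roughly octahedral cage for 4--8 ligands.
#' Identical configurations yield identical models.
#'
#' Recognised config fields (all optional except `n_ligands`):
#' `id`, `n_ligands` (4--8 typical), `ligand_charges` (vector, e),
#' `protonated`/`mutated` (logical vectors), `dipole_q`, `arm_length`,
#' `cone_angle`, `anchor_radius`, `anchor_z`, `torsion` (list with `k`, `n`,
#' `chi0`), `confinement_radius`, `wall_k`, `temperature`, `ion`
#' (`"Na"`/`"K"`), `restraint` (logical or list with `k_r`, `k_theta`,
#' `k_psi`), `seed`, `sampling` (list `n_steps`, `thin`), `droplet`
#' (list `n_solvent`, `radius`).
#'
#' @param config A named list or a path to a JSON scenario file.
#' @return A [binding_site_model()]; the validated config is attached as
#'   attribute `"config"`.
#' @export
#' @examples
#' m <- build_binding_site(list(n_ligands = 6, ligand_charges = c(-1, -1, 0, 0, 0, 0)))
#' m
build_binding_site <- function(config) {
  cfg <- normalize_scenario_config(config)
  n <- cfg$n_ligands
  phi <- 2 * pi * (seq_len(n) - 1) / n
  zoff <- cfg$anchor_z * rep_len(c(1, -1), n)
  tor <- data.frame(k = cfg$torsion$k, n = as.integer(cfg$torsion$n),
                    chi0 = cfg$torsion$chi0)
  ligands <- lapply(seq_len(n), function(i)
    ligand_spec(id = sprintf("L%d", i),
                anchor = c(cfg$anchor_radius * cos(phi[i]),
                           cfg$anchor_radius * sin(phi[i]), zoff[i]),
                arm_length = cfg$arm_length, cone_angle = cfg$cone_angle,
                dipole_q = cfg$dipole_q, charge = cfg$ligand_charges[i],
                protonated = cfg$protonated[i], mutated = cfg$mutated[i],
                torsion = tor, epsilon = cfg$ligand_epsilon,
                rmin = cfg$ligand_rmin))
  anchors <- default_anchor_points()
  rst <- NULL
  if (!isFALSE(cfg$restraint)) {
    rk <- if (is.list(cfg$restraint)) cfg$restraint else list()
    rst <- restraint_from_reference(c(0, 0, 0), anchors,
                                    k_r = rk$k_r %||% 10,
                                    k_theta = rk$k_theta %||% 200,
                                    k_psi = rk$k_psi %||% 200)
  }
  ion <- if (inherits(cfg$ion, "ion_params")) cfg$ion
         else default_ion_params(cfg$ion)
  m <- binding_site_model(ligands, ion = ion,
                          confinement_radius = cfg$confinement_radius,
                          wall_k = cfg$wall_k, temperature = cfg$temperature,
                          restraint = rst, anchors = anchors)
  attr(m, "config") <- cfg
  m
}

# fill defaults and validate a scenario configuration
normalize_scenario_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  n <- config$n_ligands %||% 6L
  if (!is.numeric(n) || n < 1) stop("n_ligands must be a positive count")
  n <- as.integer(n)
  cfg <- list(
    id = config$id %||% "scenario",
    seed = as.integer(config$seed %||% 1L),
    n_ligands = n,
    ligand_charges = rep_len(as.numeric(config$ligand_charges %||% 0), n),
    protonated = rep_len(as.logical(config$protonated %||% FALSE), n),
    mutated = rep_len(as.logical(config$mutated %||% FALSE), n),
    dipole_q = config$dipole_q %||% 0.55,
    arm_length = config$arm_length %||% 2.0,
    cone_angle = config$cone_angle %||% 60,
    anchor_radius = config$anchor_radius %||% 3.2,
    anchor_z = config$anchor_z %||% 0.8,
    ligand_epsilon = config$ligand_epsilon %||% 0.12,
    ligand_rmin = config$ligand_rmin %||% 1.7,
    torsion = config$torsion %||% list(k = c(1.5, 0.8), n = c(3, 1),
                                       chi0 = c(0, 60)),
    confinement_radius = config$confinement_radius %||% 5,
    wall_k = config$wall_k %||% 10,
    temperature = config$temperature %||% .DEFAULT_T,
    ion = config$ion %||% "Na",
    restraint = config$restraint %||% TRUE,
    sampling = list(n_steps = config$sampling$n_steps %||% 2000L,
                    thin = config$sampling$thin %||% 5L),
    droplet = list(n_solvent = config$droplet$n_solvent %||% 12L,
                   radius = config$droplet$radius %||% 6))
  if (cfg$anchor_radius <= 0 || cfg$arm_length <= 0 ||
      cfg$confinement_radius <= 0)
    stop("geometry parameters must be positive")
  cfg
}

#' Serialize a binding-site model to JSON
#'
#' Writes a lossless JSON document for a model (full double precision);
#' [model_from_json()] reconstructs an identical model.
#'
#' @param model A [binding_site_model()].
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "binding_site_model"))
  lig <- lapply(model$ligands, function(l)
    list(id = l$id, anchor = l$anchor, arm_length = l$arm_length,
         cone_angle = l$cone_angle, dipole_q = l$dipole_q,
         charge = l$charge, protonated = l$protonated, mutated = l$mutated,
         torsion = as.list(l$torsion), epsilon = l$epsilon, rmin = l$rmin,
         class = l$class))
  rst <- if (!is.null(model$restraint)) unclass(model$restraint)
  obj <- list(ligands = lig,
              ion = unclass(model$ion),
              confinement_radius = model$confinement_radius,
              wall_k = model$wall_k, temperature = model$temperature,
              restraint = rst, anchors = model$anchors)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Reconstruct a model from its JSON serialization
#'
#' @param json A JSON string or a path to a JSON file produced by
#'   [model_to_json()].
#' @return A [binding_site_model()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ligands <- lapply(obj$ligands, function(l)
    ligand_spec(id = l$id, anchor = unlist(l$anchor),
                arm_length = l$arm_length, cone_angle = l$cone_angle,
                dipole_q = l$dipole_q, charge = l$charge,
                protonated = l$protonated, mutated = l$mutated,
                torsion = data.frame(k = unlist(l$torsion$k),
                                     n = unlist(l$torsion$n),
                                     chi0 = unlist(l$torsion$chi0)),
                epsilon = l$epsilon, rmin = l$rmin, class = l$class))
  ion <- ion_params(obj$ion$species, epsilon = obj$ion$epsilon,
                    rmin = obj$ion$rmin, charge = obj$ion$charge,
                    nbfix = lapply(obj$ion$nbfix, as.list))
  rst <- if (!is.null(obj$restraint))
    restraint_spec(r0 = obj$restraint$r0, theta0 = obj$restraint$theta0,
                   psi0 = obj$restraint$psi0, k_r = obj$restraint$k_r,
                   k_theta = obj$restraint$k_theta,
                   k_psi = obj$restraint$k_psi)
  binding_site_model(ligands, ion = ion,
                     confinement_radius = obj$confinement_radius,
                     wall_k = obj$wall_k, temperature = obj$temperature,
                     restraint = rst,
                     anchors = lapply(obj$anchors, unlist))
}
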