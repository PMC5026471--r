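#' Reduced flexible binding-site model
#'
#' The desk-scale surrogate for a GSBP-reduced pump binding pocket: one mobile
#' monovalent cation coordinated by a small number of flexible dipolar
#' ligands, confined by a half-harmonic spherical wall (replacing the
#' implicit-solvent boundary), with an optional harmonic restraint tying the
#' ion to three fixed protein anchor points.  The Hamiltonian is
#' Coulomb + Lennard-Jones + intrinsic torsions + confinement + restraint.
#'
#' @param ligands List of [ligand_spec()] objects.
#' @param ion [ion_params()] of the bound ion.
#' @param confinement_radius Radius of the spherical wall, Angstrom.
#' @param wall_k Wall stiffness, kcal/mol/A^2 (0 switches the wall off).
#' @param temperature Kelvin.
#' @param restraint Optional [restraint_spec()].
#' @param anchors List of fixed protein anchor points `p1`, `p2`, `p3`
#'   (3-vectors); must be non-collinear.
#' @return An object of class `binding_site_model`.
#' @seealso [build_binding_site()] for construction from a scenario config,
#'   [total_energy()] for evaluation.
#' @export
binding_site_model <- function(ligands, ion = default_ion_params("Na"),
                               confinement_radius = 5, wall_k = 10,
                               temperature = .DEFAULT_T, restraint = NULL,
                               anchors = default_anchor_points()) {
  stopifnot(length(ligands) >= 1,
            all(vapply(ligands, inherits, logical(1), "ligand_spec")),
            inherits(ion, "ion_params"))
  if (confinement_radius <= 0) stop("confinement radius must be positive")
  if (wall_k < 0) stop("wall stiffness must be >= 0")
  if (!is.null(restraint)) stopifnot(inherits(restraint, "restraint_spec"))
  v1 <- anchors$p2 - anchors$p1
  v2 <- anchors$p3 - anchors$p1
  if (vnorm(cross3(v1, v2)) < 1e-8)
    stop("anchor points p1, p2, p3 are collinear")
  amat <- t(vapply(ligands, `[[`, numeric(3), "anchor"))
  if (nrow(amat) > 1 && min(dist(amat)) < 0.5)
    stop("overlapping ligand anchors (closer than 0.5 A)")
  if (any(sqrt(rowSums(amat^2)) > confinement_radius + 1e-9))
    stop("all ligand anchors must lie inside the confinement radius")
  m <- structure(list(ligands = ligands, ion = ion,
                      confinement_radius = confinement_radius,
                      wall_k = wall_k, temperature = temperature,
                      restraint = restraint, anchors = anchors),
                 class = "binding_site_model")
  precompute_site_tables(m)
}

# Precompute everything chi-independent: site parameter vectors, ligand-
# ligand pair tables, tip-geometry matrices, concatenated torsion terms.
precompute_site_tables <- function(m) {
  lg <- m$ligands
  n <- length(lg)
  base_pos <- t(vapply(lg, `[[`, numeric(3), "anchor"))
  b0 <- e1m <- e2m <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- lg[[i]]$frame
    L <- lg[[i]]$arm_length
    a <- deg2rad(lg[[i]]$cone_angle)
    b0[i, ] <- lg[[i]]$anchor + L * cos(a) * f$u
    e1m[i, ] <- L * sin(a) * f$e1
    e2m[i, ] <- L * sin(a) * f$e2
  }
  dip <- vapply(lg, `[[`, numeric(1), "dipole_q")
  extra0 <- vapply(lg, ligand_tip_extra, numeric(1))
  eps_site <- c(vapply(lg, `[[`, numeric(1), "epsilon"),
                vapply(lg, `[[`, numeric(1), "epsilon"))
  rmin_site <- c(vapply(lg, `[[`, numeric(1), "rmin"),
                 vapply(lg, ligand_tip_rmin, numeric(1)))
  cls_site <- rep(vapply(lg, `[[`, character(1), "class"), 2)
  ligidx <- rep(seq_len(n), 2)                 # sites: bases then tips
  # ligand-ligand pair tables (upper triangle, different ligands only)
  ns <- 2L * n
  pr <- which(upper.tri(matrix(0, ns, ns)) &
              outer(ligidx, ligidx, `!=`), arr.ind = TRUE)
  ll <- list(i = pr[, 1], j = pr[, 2],
             eps = sqrt(eps_site[pr[, 1]] * eps_site[pr[, 2]]),
             rmin = rmin_site[pr[, 1]] + rmin_site[pr[, 2]])
  tor <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- lg[[i]]$torsion
    if (!nrow(tt)) return(NULL)
    cbind(k = tt$k, n = tt$n, chi0 = tt$chi0, lig = i)
  }))
  torv <- if (!is.null(tor))
    list(k = tor[, "k"], n = tor[, "n"], chi0 = tor[, "chi0"],
         lig = as.integer(tor[, "lig"]))
  m$tables <- list(n = n, base_pos = base_pos, b0 = b0, e1 = e1m, e2 = e2m,
                   dip = dip, extra0 = extra0, eps_site = eps_site,
                   rmin_site = rmin_site, cls_site = cls_site,
                   ligidx = ligidx, ll = ll, torsion = torv)
  m
}

#' Initial configuration of a model
#'
#' Deterministic starting state: ion at the pocket centre (or droplet
#' centre), all torsions at 0, droplet solvent on a regular spherical
#' lattice with dipoles pointing outward.
#'
#' @param model A model object.
#' @param ... Unused.
#' @return A state list understood by [total_energy()] and [run_mc()].
#' @export
initial_state <- function(model, ...) UseMethod("initial_state")

#' @export
initial_state.binding_site_model <- function(model, ...) {
  list(ion = c(0, 0, 0), chi = rep(0, model$tables$n))
}

#' Total potential energy of a configuration
#'
#' Evaluates the full model Hamiltonian for one configuration, optionally
#' under modified potentials (alchemical ion parameters, scaled restraint,
#' fractional deprotonation, boosting potentials, umbrella bias).
#'
#' @param model A `binding_site_model`, `bulk_droplet_model` or `toy_model`.
#' @param state A state list (for binding sites: `ion` 3-vector and `chi`
#'   vector of torsions in degrees).
#' @param ion Optional [ion_params()] overriding the model ion.
#' @param modifiers Optional list of potential modifiers:
#'   \describe{
#'     \item{ion}{replacement [ion_params()] (alchemical interpolation);}
#'     \item{restraint_scale}{scalar multiplying the restraint term;}
#'     \item{deprot}{`list(id=, lambda=)` fractional deprotonation of one
#'       protonatable ligand (charges only);}
#'     \item{boosts}{list of `list(id=, bp=, strength=)` applying
#'       `-strength * U_BP(chi)` to the named ligand's torsion;}
#'     \item{bias}{`list(torsion=, center=, k=)` harmonic umbrella bias on
#'       one torsion (k in kcal/mol/rad^2, center in degrees).}
#'   }
#' @param decompose If `TRUE`, return a named list of energy terms instead
#'   of the scalar total.
#' @param ... Unused.
#' @return Energy in kcal/mol, or a named list of terms when
#'   `decompose = TRUE`.
#' @export
total_energy <- function(model, state, ion = NULL, modifiers = NULL,
                         decompose = FALSE, ...) UseMethod("total_energy")

#' @export
total_energy.binding_site_model <- function(model, state, ion = NULL,
                                            modifiers = NULL,
                                            decompose = FALSE, ...) {
  tb <- model$tables
  n <- tb$n
  ionp <- modifiers$ion %||% ion %||% model$ion
  x <- state$ion
  if (!all(is.finite(x))) stop("non-finite ion coordinates")
  chi <- wrap_deg(state$chi)
  cr <- cos(deg2rad(chi)); sr <- sin(deg2rad(chi))
  tips <- tb$b0 + tb$e1 * cr + tb$e2 * sr
  sites <- rbind(tb$base_pos, tips)            # bases 1..n, tips n+1..2n
  extra <- tb$extra0
  if (!is.null(modifiers$deprot)) {
    idx <- resolve_ligand(model, modifiers$deprot$id)
    if (model$ligands[[idx]]$charge == 0)
      stop("ligand is not protonatable (formal charge 0)")
    extra[idx] <- ligand_tip_extra(model$ligands[[idx]],
                                   deprot_lambda = modifiers$deprot$lambda)
  }
  q <- c(tb$dip, -tb$dip + extra)
  # ion--site nonbonded
  d1 <- sites[, 1] - x[1]; d2 <- sites[, 2] - x[2]; d3 <- sites[, 3] - x[3]
  d <- sqrt(d1 * d1 + d2 * d2 + d3 * d3)
  e_coul <- .COULOMB * ionp$charge * sum(q / d)
  eps_p <- sqrt(ionp$epsilon * tb$eps_site)
  rmin_p <- ionp$rmin + tb$rmin_site
  if (length(ionp$nbfix)) {
    hit <- match(tb$cls_site, names(ionp$nbfix))
    sel <- which(!is.na(hit))
    for (s in sel) {
      ov <- ionp$nbfix[[hit[s]]]
      eps_p[s] <- ov$epsilon
      rmin_p[s] <- ov$rmin
    }
  }
  sr6 <- (rmin_p / d)^6
  e_lj <- sum(eps_p * (sr6 * sr6 - 2 * sr6))
  # ligand--ligand nonbonded (different ligands only)
  ll <- tb$ll
  if (length(ll$i)) {
    dd <- sites[ll$i, , drop = FALSE] - sites[ll$j, , drop = FALSE]
    dij <- sqrt(rowSums(dd * dd))
    e_coul <- e_coul + .COULOMB * sum(q[ll$i] * q[ll$j] / dij)
    s6 <- (ll$rmin / dij)^6
    e_lj <- e_lj + sum(ll$eps * (s6 * s6 - 2 * s6))
  }
  # torsions (intrinsic + boosts)
  e_tor <- 0
  tor <- tb$torsion
  if (!is.null(tor))
    e_tor <- sum(tor$k * (1 + cos((tor$n * (chi[tor$lig] - tor$chi0)) *
                                  (pi / 180))))
  if (!is.null(modifiers$boosts)) {
    for (bo in modifiers$boosts) {
      idx <- resolve_ligand(model, bo$id)
      e_tor <- e_tor - bo$strength * evaluate_boost(bo$bp, chi[idx])
    }
  }
  # confinement wall (ion only; ligands are tethered by construction)
  rion <- vnorm(x)
  e_wall <- if (model$wall_k > 0 && rion > model$confinement_radius)
    0.5 * model$wall_k * (rion - model$confinement_radius)^2 else 0
  # restraint
  e_rst <- 0
  rs <- modifiers$restraint_scale %||% 1
  if (!is.null(model$restraint) && rs != 0)
    e_rst <- rs * restraint_energy(x, model$restraint, model$anchors)
  e_bias <- bias_energy(modifiers$bias, chi)
  tot <- e_coul + e_lj + e_tor + e_wall + e_rst + e_bias
  if (decompose)
    list(coulomb = e_coul, lj = e_lj, torsion = e_tor, wall = e_wall,
         restraint = e_rst, bias = e_bias, total = tot)
  else tot
}

bias_energy <- function(bias, chi) {
  if (is.null(bias)) return(0)
  dchi <- wrap_rad(deg2rad(chi[bias$torsion] - bias$center))
  0.5 * bias$k * dchi^2
}

resolve_ligand <- function(model, id) {
  if (is.null(model$ligands)) return(1L)   # single-torsion models
  if (is.numeric(id)) {
    if (id < 1 || id > length(model$ligands)) stop("no such ligand: ", id)
    return(as.integer(id))
  }
  idx <- match(id, vapply(model$ligands, `[[`, character(1), "id"))
  if (is.na(idx)) stop("no such ligand: ", id)
  idx
}

#' @export
print.binding_site_model <- function(x, ...) {
  net <- sum(vapply(x$ligands, ligand_tip_extra, numeric(1)))
  cat(sprintf(
    "binding site: %d ligands (net formal charge %+g e), ion %s, R=%g A, T=%g K, %s\n",
    length(x$ligands), net, x$ion$species, x$confinement_radius,
    x$temperature,
    if (is.null(x$restraint)) "unrestrained" else "restrained"))
  invisible(x)
}

# rigid-body transform of the whole system (ligand anchors and frames,
# protein anchor points); used to verify frame invariance
rotate_model <- function(model, R, shift = c(0, 0, 0)) {
  rot <- function(v) as.numeric(R %*% v)
  lg <- lapply(model$ligands, function(l) {
    l$anchor <- rot(l$anchor) + shift
    l$frame <- lapply(l$frame, rot)
    l
  })
  anc <- lapply(model$anchors, function(p) rot(p) + shift)
  m <- model
  m$ligands <- lg
  m$anchors <- anc
  precompute_site_tables(m)
}

rotate_state <- function(state, R, shift = c(0, 0, 0)) {
  state$ion <- as.numeric(R %*% state$ion) + shift
  state
}
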