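#' Bulk droplet model (ion or solute in a solvent sphere)
#'
#' Desk-scale surrogate for the ion-in-water-sphere reference system: a
#' droplet of point-dipole solvent "molecules" held together by a
#' half-harmonic spherical boundary, containing either one mobile ion (for
#' the bulk alchemical ion-swap leg) or one protonatable dipolar solute (for
#' the bulk deprotonation leg), or both absent components of the pair.
#' Each solvent molecule has a Lennard-Jones centre and charges +/-q at
#' +/- d/2 along its orientation vector (dipole moment q*d, tuned to a
#' water-like 2.4 D).
#'
#' @param n_solvent Number of solvent dipoles (> 0).
#' @param radius Droplet radius, Angstrom.
#' @param dipole_q Solvent charge magnitude, e.
#' @param dipole_length Charge separation d, Angstrom.
#' @param solvent_epsilon,solvent_rmin Solvent LJ centre parameters
#'   (kcal/mol, Rmin/2 in A), water-oxygen-like defaults.
#' @param wall_k Boundary stiffness, kcal/mol/A^2.
#' @param ion [ion_params()] of the mobile ion, or `NULL` for none.
#' @param ion_restraint_k Weak harmonic restraint holding the ion at the
#'   centre, kcal/mol/A^2 (0.5 by default, 0 switches it off).
#' @param solute Optional [ligand_spec()]: a protonatable solute anchored
#'   near the centre (used by the bulk deprotonation leg).
#' @param temperature Kelvin.
#' @return An object of class `bulk_droplet_model`.
#' @export
bulk_droplet_model <- function(n_solvent = 12, radius = 6, dipole_q = 0.417,
                               dipole_length = 1.2,
                               solvent_epsilon = 0.1521,
                               solvent_rmin = 1.7682, wall_k = 10,
                               ion = default_ion_params("Na"),
                               ion_restraint_k = 0.5, solute = NULL,
                               temperature = .DEFAULT_T) {
  if (n_solvent < 1) stop("solvent count must be > 0")
  if (radius <= 0 || wall_k < 0) stop("invalid droplet geometry")
  if (!is.null(ion)) stopifnot(inherits(ion, "ion_params"))
  if (!is.null(solute)) stopifnot(inherits(solute, "ligand_spec"))
  structure(list(n_solvent = as.integer(n_solvent), radius = radius,
                 dipole_q = dipole_q, dipole_length = dipole_length,
                 solvent_epsilon = solvent_epsilon,
                 solvent_rmin = solvent_rmin, wall_k = wall_k, ion = ion,
                 ion_restraint_k = ion_restraint_k, solute = solute,
                 temperature = temperature),
            class = "bulk_droplet_model")
}

# evenly distributed points on a sphere (Fibonacci lattice), deterministic
fibonacci_sphere <- function(n, r) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta), r * cos(phi))
}

#' @export
initial_state.bulk_droplet_model <- function(model, ...) {
  pos <- fibonacci_sphere(model$n_solvent, 0.6 * model$radius)
  dir <- pos / sqrt(rowSums(pos^2))    # minus end towards the centre
  st <- list(solvent_pos = pos, solvent_dir = dir)
  if (!is.null(model$ion)) st$ion <- c(0, 0, 0)
  if (!is.null(model$solute)) st$chi <- 0
  st
}

#' @export
total_energy.bulk_droplet_model <- function(model, state, ion = NULL,
                                            modifiers = NULL,
                                            decompose = FALSE, ...) {
  ionp <- modifiers$ion %||% ion %||% model$ion
  m <- model$n_solvent
  sp <- state$solvent_pos
  sd2 <- state$solvent_dir * (model$dipole_length / 2)
  # assemble site table: positions, charges, LJ flags, molecule ids
  pos <- rbind(sp, sp + sd2, sp - sd2)
  q <- c(rep(0, m), rep(model$dipole_q, m), rep(-model$dipole_q, m))
  lj_eps <- c(rep(model$solvent_epsilon, m), rep(NA_real_, 2 * m))
  lj_rmin <- c(rep(model$solvent_rmin, m), rep(NA_real_, 2 * m))
  mol <- rep(seq_len(m), 3)
  cls <- rep("water", 3 * m)
  if (!is.null(model$solute)) {
    lg <- model$solute
    chi <- wrap_deg(state$chi)
    extra <- ligand_tip_extra(lg)
    if (!is.null(modifiers$deprot)) {
      if (lg$charge == 0) stop("solute is not protonatable")
      extra <- ligand_tip_extra(lg, deprot_lambda = modifiers$deprot$lambda)
    }
    pos <- rbind(pos, lg$anchor, ligand_tip_position(lg, chi))
    q <- c(q, lg$dipole_q, -lg$dipole_q + extra)
    lj_eps <- c(lj_eps, lg$epsilon, lg$epsilon)
    lj_rmin <- c(lj_rmin, lg$rmin, ligand_tip_rmin(lg))
    mol <- c(mol, 0L, 0L)
    cls <- c(cls, "solute_base", lg$class)
  }
  has_ion <- !is.null(ionp)
  if (has_ion) {
    if (!all(is.finite(state$ion))) stop("non-finite ion coordinates")
    pos <- rbind(pos, state$ion)
    q <- c(q, ionp$charge)
    lj_eps <- c(lj_eps, ionp$epsilon)
    lj_rmin <- c(lj_rmin, ionp$rmin)
    mol <- c(mol, -1L)
    cls <- c(cls, "ion")
  }
  ns <- nrow(pos)
  pr <- which(upper.tri(matrix(TRUE, ns, ns)) &
              outer(mol, mol, `!=`), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  dd <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
  dij <- sqrt(rowSums(dd * dd))
  qq <- q[i] * q[j]
  cc <- qq != 0
  e_coul <- .COULOMB * sum(qq[cc] / dij[cc])
  act <- !is.na(lj_eps[i]) & !is.na(lj_eps[j])
  eps_p <- sqrt(lj_eps[i][act] * lj_eps[j][act])
  rmin_p <- lj_rmin[i][act] + lj_rmin[j][act]
  if (has_ion && length(ionp$nbfix)) {
    ii <- i[act]; jj <- j[act]
    ion_site <- ns
    partner <- ifelse(ii == ion_site, jj, ifelse(jj == ion_site, ii, NA))
    hit <- match(cls[partner], names(ionp$nbfix))
    for (kx in which(!is.na(hit))) {
      ov <- ionp$nbfix[[hit[kx]]]
      eps_p[kx] <- ov$epsilon
      rmin_p[kx] <- ov$rmin
    }
  }
  s6 <- (rmin_p / dij[act])^6
  e_lj <- sum(eps_p * (s6 * s6 - 2 * s6))
  # boundary on solvent centres and ion; weak central restraint on the ion
  rc <- sqrt(rowSums(sp^2))
  over <- rc > model$radius
  e_wall <- if (any(over))
    0.5 * model$wall_k * sum((rc[over] - model$radius)^2) else 0
  e_rst <- 0
  if (has_ion) {
    ri <- vnorm(state$ion)
    if (ri > model$radius)
      e_wall <- e_wall + 0.5 * model$wall_k * (ri - model$radius)^2
    if (model$ion_restraint_k > 0)
      e_rst <- 0.5 * model$ion_restraint_k * ri^2
  }
  e_tor <- if (!is.null(model$solute))
    ligand_torsion_energy(model$solute, wrap_deg(state$chi)) else 0
  tot <- e_coul + e_lj + e_tor + e_wall + e_rst
  if (decompose)
    list(coulomb = e_coul, lj = e_lj, torsion = e_tor, wall = e_wall,
         restraint = e_rst, bias = 0, total = tot)
  else tot
}

#' @export
print.bulk_droplet_model <- function(x, ...) {
  cat(sprintf("bulk droplet: %d solvent dipoles, R=%g A, %s%s, T=%g K\n",
              x$n_solvent, x$radius,
              if (is.null(x$ion)) "no ion" else paste0("ion ", x$ion$species),
              if (is.null(x$solute)) "" else ", protonatable solute",
              x$temperature))
  invisible(x)
}

#' Minimal test model wrapping a user-supplied energy function
#'
#' A bare-bones model whose state is a numeric vector and whose energy is an
#' arbitrary function; used for closed-form sampler checks (harmonic wells,
#' multi-well chains).
#'
#' @param energy Function `state -> kcal/mol`.
#' @param state0 Initial numeric state vector.
#' @param temperature Kelvin.
#' @return An object of class `toy_model`.
#' @export
toy_model <- function(energy, state0, temperature = .DEFAULT_T) {
  stopifnot(is.function(energy), is.numeric(state0))
  structure(list(energy = energy, state0 = state0,
                 temperature = temperature),
            class = "toy_model")
}

#' @export
initial_state.toy_model <- function(model, ...) list(x = model$state0)

#' @export
total_energy.toy_model <- function(model, state, ion = NULL,
                                   modifiers = NULL, decompose = FALSE, ...) {
  e <- model$energy(state$x)
  if (decompose) list(total = e) else e
}
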