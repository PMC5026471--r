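#' Translational/orientational restraint on the bound ion
#'
#' Harmonic restraint on the internal coordinates that tie the ion to three
#' fixed protein anchor points p1, p2, p3: the distance r (ion to p1), the
#' angle theta (ion-p1-p2) and the torsion psi (ion-p1-p2-p3),
#' \deqn{u_{trans} = \tfrac12 [k_r (r-r_0)^2 + k_\theta(\theta-\theta_0)^2 +
#'   k_\psi(\psi-\psi_0)^2],}
#' with angles in radians and angular differences wrapped to (-pi, pi].
#'
#' @param r0 Equilibrium distance, Angstrom.
#' @param theta0,psi0 Equilibrium angle and torsion, degrees
#'   (0 < theta0 < 180).
#' @param k_r Distance force constant, kcal/mol/A^2 (default 10).
#' @param k_theta,k_psi Angular force constants, kcal/mol/rad^2 (default 200).
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(r0, theta0, psi0, k_r = 10, k_theta = 200,
                           k_psi = 200) {
  if (any(c(k_r, k_theta, k_psi) < 0)) stop("force constants must be >= 0")
  if (r0 <= 0) stop("r0 must be positive")
  if (theta0 <= 0 || theta0 >= 180) stop("theta0 must lie strictly in (0, 180)")
  structure(list(r0 = r0, theta0 = theta0, psi0 = psi0,
                 k_r = k_r, k_theta = k_theta, k_psi = k_psi),
            class = "restraint_spec")
}

#' Restraint energy of an ion position
#'
#' Evaluates the harmonic translational restraint for an ion at `ion_pos`
#' given the anchor points.  See [restraint_spec()] for the functional form.
#'
#' @param ion_pos Ion position, numeric 3-vector (Angstrom).
#' @param spec A [restraint_spec()].
#' @param anchors List with elements `p1`, `p2`, `p3` (3-vectors).
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(ion_pos, spec, anchors) {
  stopifnot(inherits(spec, "restraint_spec"))
  p1 <- anchors$p1; p2 <- anchors$p2; p3 <- anchors$p3
  d <- ion_pos - p1
  r <- vnorm(d)
  if (r < 1e-9)
    stop("ion coincides with anchor p1; restraint distance undefined")
  e <- 0.5 * spec$k_r * (r - spec$r0)^2
  if (spec$k_theta > 0) {
    th <- bond_angle(ion_pos, p1, p2)
    dth <- wrap_rad(th - deg2rad(spec$theta0))
    e <- e + 0.5 * spec$k_theta * dth^2
  }
  if (spec$k_psi > 0) {
    ps <- dihedral_angle(ion_pos, p1, p2, p3)
    dps <- wrap_rad(ps - deg2rad(spec$psi0))
    e <- e + 0.5 * spec$k_psi * dps^2
  }
  e
}

# default protein anchor points of the reduced site (below the pocket floor)
default_anchor_points <- function() {
  list(p1 = c(0, 0, -3.5), p2 = c(2.5, 0, -4.5), p3 = c(2.5, 2.5, -5.5))
}

# restraint with equilibrium values measured from a reference ion position
# (the analogue of taking r0/theta0/psi0 from a short equilibration)
restraint_from_reference <- function(ion_pos, anchors, k_r = 10,
                                     k_theta = 200, k_psi = 200) {
  r0 <- vnorm(ion_pos - anchors$p1)
  th0 <- rad2deg(bond_angle(ion_pos, anchors$p1, anchors$p2))
  ps0 <- rad2deg(dihedral_angle(ion_pos, anchors$p1, anchors$p2, anchors$p3))
  restraint_spec(r0 = r0, theta0 = th0, psi0 = ps0,
                 k_r = k_r, k_theta = k_theta, k_psi = k_psi)
}
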