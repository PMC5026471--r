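#' A flexible dipolar coordinating ligand
#'
#' One coordinating group of the reduced binding site: a rigid arm on a fixed
#' anchor point carrying a dipole (+q at the base, -q at the tip) whose
#' orientation swings around one side-chain-like torsion chi.  The tip mimics
#' a carbonyl/carboxylate oxygen: it carries the coordinating charge and the
#' ligand Lennard-Jones class.  Acidic ligands add an extra formal charge on
#' the tip when deprotonated; the `protonated` flag neutralises it (charges
#' only -- connectivity and LJ parameters are untouched).  The `mutated` flag
#' is the D-to-N style substitution surrogate: the formal charge is removed
#' regardless of protonation and the tip LJ radius grows by 0.2 A (a bulkier
#' but neutral amide group in place of a charged oxygen).
#'
#' The intrinsic torsion potential is a cosine series,
#' sum_n k_n (1 + cos(n (chi - chi0_n))), giving the multi-well rotamer
#' landscape that makes boosting potentials worthwhile.
#'
#' @param id Ligand identifier (character).
#' @param anchor Fixed anchor point, numeric 3-vector (Angstrom); must not be
#'   the origin (the arm frame points from the anchor towards the pocket
#'   centre).
#' @param arm_length Arm length, Angstrom.
#' @param cone_angle Half-angle of the cone swept by the tip around the
#'   inward axis, degrees.
#' @param dipole_q Dipole charge magnitude q, e (+q base, -q tip).
#' @param charge Formal charge of the deprotonated form (0 or -1 typically).
#' @param protonated Logical; protonation neutralises the formal charge.
#' @param mutated Logical; charge-neutralising substitution (adds 0.2 A to
#'   the tip LJ radius).
#' @param torsion data.frame with columns `k` (kcal/mol), `n` (integer
#'   multiplicity), `chi0` (degrees): the intrinsic torsion terms.
#' @param epsilon,rmin Tip/base LJ class parameters (kcal/mol, Rmin/2 in A).
#' @param class LJ atom-class label used to match NBFIX-style overrides.
#' @return An object of class `ligand_spec`.
#' @export
ligand_spec <- function(id, anchor, arm_length = 2.0, cone_angle = 60,
                        dipole_q = 0.55, charge = 0, protonated = FALSE,
                        mutated = FALSE,
                        torsion = data.frame(k = c(1.5, 0.8), n = c(3L, 1L),
                                             chi0 = c(0, 60)),
                        epsilon = 0.12, rmin = 1.7, class = "carbonyl") {
  anchor <- as.numeric(anchor)
  if (length(anchor) != 3 || !all(is.finite(anchor)))
    stop("anchor must be a finite 3-vector")
  if (arm_length <= 0 || cone_angle <= 0 || epsilon <= 0 || rmin <= 0)
    stop("geometry and LJ parameters must be positive")
  torsion <- as.data.frame(torsion)
  if (nrow(torsion) &&
      !all(c("k", "n", "chi0") %in% names(torsion)))
    stop("torsion needs columns k, n, chi0")
  structure(list(id = as.character(id), anchor = anchor,
                 arm_length = arm_length, cone_angle = cone_angle,
                 dipole_q = dipole_q, charge = charge,
                 protonated = isTRUE(protonated), mutated = isTRUE(mutated),
                 torsion = torsion, epsilon = epsilon, rmin = rmin,
                 class = as.character(class),
                 frame = anchor_frame(anchor)),
            class = "ligand_spec")
}

# formal (extra) charge carried on the tip; deprot_lambda, when given,
# overrides the protonation flag with a fractional deprotonation coupling
ligand_tip_extra <- function(lig, deprot_lambda = NULL) {
  if (lig$mutated) return(0)
  if (!is.null(deprot_lambda)) return(deprot_lambda * lig$charge)
  if (lig$protonated) 0 else lig$charge
}

# effective tip LJ radius (mutation adds bulk)
ligand_tip_rmin <- function(lig) lig$rmin + if (lig$mutated) 0.2 else 0

# tip position for a torsion value chi (degrees)
ligand_tip_position <- function(lig, chi) {
  a <- deg2rad(lig$cone_angle)
  cr <- deg2rad(chi)
  f <- lig$frame
  lig$anchor + lig$arm_length *
    (cos(a) * f$u + sin(a) * (cos(cr) * f$e1 + sin(cr) * f$e2))
}

# intrinsic torsion energy of one ligand at chi (degrees), kcal/mol
ligand_torsion_energy <- function(lig, chi) {
  tt <- lig$torsion
  if (!nrow(tt)) return(0)
  sum(tt$k * (1 + cos(deg2rad(tt$n * (chi - tt$chi0)))))
}
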