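# Shared miniature models for the test suite.

# small uncharged dipolar site (soft, good alchemical overlap)
tiny_dipole_site <- function(n_ligands = 3, dipole_q = 0.45,
                             restraint = TRUE) {
  build_binding_site(list(n_ligands = n_ligands, dipole_q = dipole_q,
                          ligand_charges = 0, restraint = restraint))
}

# single-ligand site with an exactly known tip geometry: anchor (0,0,2),
# cone angle 90 deg, arm L -> tip at (0,-L,2) for chi = 0
known_geometry_site <- function(arm = 1.5, dipole_q = 0, charge = -1,
                                epsilon = 1e-9) {
  lig <- ligand_spec("L1", anchor = c(0, 0, 2), arm_length = arm,
                     cone_angle = 90, dipole_q = dipole_q, charge = charge,
                     torsion = data.frame(k = numeric(), n = integer(),
                                          chi0 = numeric()),
                     epsilon = epsilon, rmin = 1.7)
  binding_site_model(list(lig), wall_k = 0, restraint = NULL)
}

default_anchors <- function() {
  list(p1 = c(0, 0, -3.5), p2 = c(2.5, 0, -4.5), p3 = c(2.5, 2.5, -5.5))
}

rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c) + diag(c, 3) +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s
}
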