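test_that("ion parameter interpolation is linear with exact endpoints", {
  na <- ion_params("Na", epsilon = 0.0469, rmin = 1.36375,
                   nbfix = list(carbonyl = list(epsilon = 0.07, rmin = 3.0)))
  k <- ion_params("K", epsilon = 0.0870, rmin = 1.76375,
                  nbfix = list(carbonyl = list(epsilon = 0.10, rmin = 3.4)))
  expect_identical(interpolate_ion_params(na, k, 0), na)
  expect_identical(interpolate_ion_params(na, k, 1), k)
  h <- interpolate_ion_params(na, k, 0.5)
  expect_equal(h$epsilon, (0.0469 + 0.0870) / 2)
  expect_equal(h$rmin, (1.36375 + 1.76375) / 2)
  expect_equal(h$nbfix$carbonyl$epsilon, 0.085)
  expect_equal(h$nbfix$carbonyl$rmin, 3.2)
  expect_equal(h$charge, 1)
  bad <- ion_params("K", epsilon = 0.087, rmin = 1.76,
                    nbfix = list(other = list(epsilon = 1, rmin = 1)))
  expect_error(interpolate_ion_params(na, bad, 0.5), "classes")
  expect_error(interpolate_ion_params(na, k, 1.5), "lambda")
})

test_that("endpoint energies from interpolated parameters are exact", {
  m <- tiny_dipole_site(n_ligands = 3)
  na <- default_ion_params("Na"); k <- default_ion_params("K")
  st <- initial_state(m)
  st$ion <- c(0.4, 0.2, -0.1)
  e_na <- total_energy(m, st, modifiers = list(ion = na))
  e0 <- total_energy(m, st,
                     modifiers = list(ion = interpolate_ion_params(na, k, 0)))
  expect_identical(e0, e_na)
  e_k <- total_energy(m, st, modifiers = list(ion = k))
  e1 <- total_energy(m, st,
                     modifiers = list(ion = interpolate_ion_params(na, k, 1)))
  expect_identical(e1, e_k)
})

test_that("identical species give a null transformation", {
  m <- tiny_dipole_site(n_ligands = 3)
  na <- default_ion_params("Na")
  f <- three_point_alchemy(m, na, na, n_steps = 600, seed = 2)
  expect_equal(f$dg, 0, tolerance = 1e-9)
})

test_that("reversing the swap flips the sign of the free energy", {
  m <- tiny_dipole_site(n_ligands = 3)
  na <- default_ion_params("Na"); k <- default_ion_params("K")
  fw <- three_point_alchemy(m, na, k, n_steps = 2000, seed = 11)
  bw <- three_point_alchemy(m, k, na, n_steps = 2000, seed = 12)
  tol <- 3 * sqrt(fw$err^2 + bw$err^2) + 0.1
  expect_lt(abs(fw$dg + bw$dg), tol)
})

test_that("three-point estimate agrees with the exponential-averaging oracle", {
  m <- tiny_dipole_site(n_ligands = 2)
  na <- default_ion_params("Na"); k <- default_ion_params("K")
  f <- three_point_alchemy(m, na, k, n_steps = 3000, seed = 31, thin = 4)
  # independent Zwanzig chain over the same intermediate: fresh samplings,
  # forward exponential averaging across each half-leg
  mods <- lapply(c(0, 0.5), function(l)
    list(ion = interpolate_ion_params(na, k, l)))
  dz <- numeric(2)
  for (i in 1:2) {
    tgt <- list(ion = interpolate_ion_params(na, k, c(0.5, 1)[i]))
    s <- run_mc(m, n_steps = 6000, seed = 200 + i, thin = 4,
                modifiers = mods[[i]])
    du <- vapply(s$states, function(fr)
      total_energy(m, fr, modifiers = tgt) -
        total_energy(m, fr, modifiers = mods[[i]]), numeric(1))
    dz[i] <- zwanzig_oracle(du)
  }
  expect_lt(abs(f$dg - sum(dz)), 3 * f$err + 0.35)
})

test_that("releasing a zero-stiffness restraint costs nothing", {
  m <- build_binding_site(list(n_ligands = 3,
                               restraint = list(k_r = 0, k_theta = 0,
                                                k_psi = 0)))
  f <- decouple_restraint_leg(m, n_steps = 300, seed = 2,
                              lambdas = seq(0, 1, length.out = 3))
  expect_equal(f$dg, 0, tolerance = 1e-9)
  m2 <- build_binding_site(list(n_ligands = 3, restraint = FALSE))
  expect_error(decouple_restraint_leg(m2, n_steps = 100, seed = 1),
               "no restraint")
})

test_that("restraint release on a flat landscape matches quadrature", {
  # near-ideal ion in a wall-bounded sphere: the release free energy is
  # -kBT ln(Z_free / Z_restrained) with both integrals known by quadrature
  lig <- ligand_spec("L1", anchor = c(0, 0, 3), dipole_q = 0, charge = 0,
                     epsilon = 1e-9,
                     torsion = data.frame(k = numeric(), n = integer(),
                                          chi0 = numeric()))
  anc <- default_anchors()
  rst <- pumpsel:::restraint_from_reference(c(0, 0, 0), anc)
  m <- binding_site_model(list(lig), confinement_radius = 4, wall_k = 10,
                          restraint = rst, anchors = anc)
  f <- decouple_restraint_leg(m, n_steps = 4000, seed = 9,
                              lambdas = seq(0, 1, length.out = 8))
  kT <- KB * TREF
  z_rest <- ft_quadrature(rst$r0, rst$theta0, rst$k_r, rst$k_theta,
                          rst$k_psi)
  b <- 1 / kT
  z_free <- stats::integrate(function(r)
    4 * pi * r^2 * exp(-b * ifelse(r > 4, 0.5 * 10 * (r - 4)^2, 0)),
    0, 10, rel.tol = 1e-10)$value
  expected <- -kT * log(z_free / z_rest)
  expect_lt(abs(f$dg - expected), 3 * f$err + 0.15)
})

test_that("restraint release is species-symmetric on a symmetric model", {
  m <- tiny_dipole_site(n_ligands = 3)
  ion <- ion_params("X", epsilon = 0.06, rmin = 1.5)
  f1 <- decouple_restraint_leg(m, ion = ion, n_steps = 1000, seed = 5,
                               lambdas = seq(0, 1, length.out = 5))
  f2 <- decouple_restraint_leg(m, ion = ion, n_steps = 1000, seed = 6,
                               lambdas = seq(0, 1, length.out = 5))
  expect_lt(abs(f1$dg - f2$dg), 3 * sqrt(f1$err^2 + f2$err^2) + 0.1)
})

test_that("deprotonation legs respect protonatability and environment", {
  cfg <- list(n_ligands = 3, ligand_charges = c(-1, 0, 0),
              protonated = c(TRUE, FALSE, FALSE))
  m <- build_binding_site(cfg)
  expect_error(deprotonation_leg(m, target = 2, n_steps = 50, seed = 1),
               "not protonatable")
  sched <- seq(0, 1, length.out = 5)
  f_neutral <- deprotonation_leg(m, target = 1, lambdas = sched,
                                 n_steps = 800, seed = 3)
  # add a deprotonated (negative) neighbour: deprotonation becomes harder
  cfg$ligand_charges <- c(-1, -1, 0)
  cfg$protonated <- c(TRUE, FALSE, FALSE)
  m_neg <- build_binding_site(cfg)
  f_neg <- deprotonation_leg(m_neg, target = 1, lambdas = sched,
                             n_steps = 800, seed = 3)
  expect_gt(f_neg$dg, f_neutral$dg)
})

test_that("identical site and bulk environments give a zero pKa shift", {
  solute <- ligand_spec("asp", anchor = c(0, 0, 0.8), dipole_q = 0.45,
                        charge = -1, protonated = TRUE)
  d <- bulk_droplet_model(n_solvent = 8, radius = 5, ion = NULL,
                          solute = solute)
  sched <- seq(0, 1, length.out = 4)
  f1 <- deprotonation_leg(d, lambdas = sched, n_steps = 600, seed = 4)
  f2 <- deprotonation_leg(d, lambdas = sched, n_steps = 600, seed = 4)
  expect_identical(f1$dg, f2$dg)
  pk <- pka_from_legs(f1$dg, f2$dg)
  expect_equal(pk$dpka, 0)
  expect_equal(pk$pka, 4.1)
})
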