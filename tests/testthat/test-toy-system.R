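test_that("scenario construction tracks ligand protonation charges", {
  cfg <- list(n_ligands = 6, ligand_charges = c(-1, -1, 0, 0, 0, 0))
  m <- build_binding_site(cfg)
  net <- sum(vapply(m$ligands, pumpsel:::ligand_tip_extra, numeric(1)))
  expect_equal(net, -2)

  cfg$protonated <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  m2 <- build_binding_site(cfg)
  net2 <- sum(vapply(m2$ligands, pumpsel:::ligand_tip_extra, numeric(1)))
  expect_equal(net2, -1)
})

test_that("identical configs give identical serialized models", {
  cfg <- list(n_ligands = 5, ligand_charges = c(-1, 0, 0, 0, 0),
              seed = 42)
  j1 <- model_to_json(build_binding_site(cfg))
  j2 <- model_to_json(build_binding_site(cfg))
  expect_identical(j1, j2)
})

test_that("model JSON serialization round-trips losslessly", {
  m <- build_binding_site(list(n_ligands = 4,
                               ligand_charges = c(-1, 0, 0, 0),
                               mutated = c(FALSE, TRUE, FALSE, FALSE)))
  m2 <- model_from_json(model_to_json(m))
  expect_identical(model_to_json(m), model_to_json(m2))
  st <- initial_state(m)
  st$ion <- c(0.3, -0.2, 0.4)
  st$chi <- c(10, -40, 125, 77)
  expect_equal(total_energy(m, st), total_energy(m2, st),
               tolerance = 1e-12)
})

test_that("Coulomb term matches the hand-computed point-charge value", {
  # tip sits at (0, -1.5, 2): 2.5 A from an ion at the origin
  m <- known_geometry_site(arm = 1.5, charge = -1)
  st <- list(ion = c(0, 0, 0), chi = 0)
  terms <- total_energy(m, st, decompose = TRUE)
  expect_equal(terms$coulomb, 332.0716 * 1 * (-1) / 2.5, tolerance = 1e-10)
})

test_that("nonbonded terms vanish at infinite ion separation", {
  m <- known_geometry_site(charge = -1, epsilon = 0.12)
  st <- list(ion = c(1e6, 0, 0), chi = 0)
  terms <- total_energy(m, st, decompose = TRUE)
  expect_lt(abs(terms$coulomb), 1e-3)
  expect_lt(abs(terms$lj), 1e-12)
  st$ion <- c(1e8, 0, 0)
  expect_lt(abs(total_energy(m, st, decompose = TRUE)$coulomb), 1e-5)
})

test_that("restraint energy reproduces the harmonic worked values", {
  anc <- default_anchors()
  # equilibrium values measured at the origin -> zero energy there
  rs <- pumpsel:::restraint_from_reference(c(0, 0, 0), anc)
  expect_equal(restraint_energy(c(0, 0, 0), rs, anc), 0)

  # 1 A radial stretch with angles at equilibrium: 1/2 * 10 * 1^2 = 5
  dir <- -anc$p1 / sqrt(sum(anc$p1^2))
  rs2 <- restraint_spec(r0 = 3.5, theta0 = rs$theta0, psi0 = rs$psi0,
                        k_r = 10, k_theta = 0, k_psi = 0)
  expect_equal(restraint_energy(dir * 1, rs2, anc), 5, tolerance = 1e-10)

  # 180 degree torsion offset at k_psi = 200: 1/2 * 200 * pi^2 ~ 987
  rs3 <- restraint_spec(r0 = 3.5, theta0 = rs$theta0,
                        psi0 = pumpsel:::wrap_deg(rs$psi0 + 180),
                        k_r = 0, k_theta = 0, k_psi = 200)
  expect_equal(restraint_energy(c(0, 0, 0), rs3, anc), 100 * pi^2,
               tolerance = 1e-8)
  expect_error(restraint_energy(anc$p1, rs, anc), "coincides")
})

test_that("energy is 360-degree periodic in every torsion", {
  m <- build_binding_site(list(n_ligands = 4,
                               ligand_charges = c(-1, 0, 0, 0)))
  st <- initial_state(m)
  st$chi <- c(23.4, -110.2, 171.9, 66.6)
  e1 <- total_energy(m, st)
  st$chi <- st$chi + 360
  expect_equal(total_energy(m, st), e1, tolerance = 1e-10)
  st$chi <- st$chi - 720
  expect_equal(total_energy(m, st), e1, tolerance = 1e-10)
})

test_that("protonation changes Coulomb terms only", {
  cfg <- list(n_ligands = 4, ligand_charges = c(-1, 0, 0, 0))
  m_dep <- build_binding_site(cfg)
  cfg$protonated <- c(TRUE, FALSE, FALSE, FALSE)
  m_pro <- build_binding_site(cfg)
  st <- initial_state(m_dep)
  st$ion <- c(0.5, 0.1, -0.3)
  st$chi <- c(15, -60, 100, 170)
  t1 <- total_energy(m_dep, st, decompose = TRUE)
  t2 <- total_energy(m_pro, st, decompose = TRUE)
  expect_identical(t1$lj, t2$lj)
  expect_identical(t1$torsion, t2$torsion)
  expect_false(isTRUE(all.equal(t1$coulomb, t2$coulomb)))
})

test_that("mutation neutralises the tip and bulks its LJ radius", {
  cfg <- list(n_ligands = 4, ligand_charges = c(-1, 0, 0, 0))
  m_wt <- build_binding_site(cfg)
  cfg$mutated <- c(TRUE, FALSE, FALSE, FALSE)
  m_mut <- build_binding_site(cfg)
  expect_equal(pumpsel:::ligand_tip_extra(m_mut$ligands[[1]]), 0)
  expect_equal(pumpsel:::ligand_tip_rmin(m_mut$ligands[[1]]),
               pumpsel:::ligand_tip_rmin(m_wt$ligands[[1]]) + 0.2)
})

test_that("energy is invariant under rigid rotation of the whole system", {
  m <- build_binding_site(list(n_ligands = 5,
                               ligand_charges = c(-1, -1, 0, 0, 0)))
  st <- initial_state(m)
  st$ion <- c(0.4, -0.2, 0.3)
  st$chi <- c(30, -45, 90, 150, -120)
  e1 <- total_energy(m, st)
  R <- rotation_about(c(1, 2, 0.5), 1.1)
  m_rot <- pumpsel:::rotate_model(m, R)
  st_rot <- pumpsel:::rotate_state(st, R)
  expect_equal(total_energy(m_rot, st_rot), e1, tolerance = 1e-9)
})

test_that("invalid geometries and parameters are rejected", {
  expect_error(build_binding_site(list(n_ligands = 2, anchor_radius = -1)),
               "positive")
  lig <- ligand_spec("a", anchor = c(1, 0, 0))
  expect_error(binding_site_model(list(lig, lig)), "overlapping")
  expect_error(ion_params("Na", epsilon = -0.1, rmin = 1.4), "epsilon")
  expect_error(ion_params("Na", epsilon = 0.05, rmin = 1.4, charge = 2),
               "charge")
  expect_error(restraint_spec(r0 = 3, theta0 = 0, psi0 = 0), "theta0")
  expect_error(restraint_spec(r0 = 3, theta0 = 90, psi0 = 0, k_r = -1),
               "force constants")
})
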