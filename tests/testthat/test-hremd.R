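test_that("replica topology follows the two-dimensional edge rule", {
  for (dims in list(c(1, 1), c(2, 3), c(5, 4), c(16, 8))) {
    nl <- dims[1]; nb <- dims[2]
    topo <- build_topology(nl, nb)
    expect_equal(nrow(topo$replicas), nl * nb)
    expect_equal(nrow(topo$edges), nl * (nb - 1) + (nl - 1))
    r <- topo$replicas
    for (e in seq_len(nrow(topo$edges))) {
      a <- r[topo$edges$a[e], ]; b <- r[topo$edges$b[e], ]
      if (topo$edges$type[e] == "boost") {
        expect_equal(a$i_lambda, b$i_lambda)
        expect_equal(abs(a$i_boost - b$i_boost), 1L)
      } else {
        expect_equal(abs(a$i_lambda - b$i_lambda), 1L)
        expect_equal(a$boost, 0)
        expect_equal(b$boost, 0)
      }
    }
  }
  expect_equal(build_topology(1, 1)$edges$a, integer(0))
  expect_error(build_topology(0, 2), ">= 1")
  expect_error(build_topology(2, 2, boost_values = c(0.1, 1)), "boost")
})

test_that("exchange acceptance is Metropolis in the cross energies", {
  u <- function(s) 0.5 * s$x^2
  st <- list(x = 1)
  # identical potentials: delta = 0, always accepted
  for (i in 1:5)
    expect_true(attempt_exchange(st, list(x = -2), u, u)$accepted)
  # hard overlap under the partner potential: always rejected
  uinf <- function(s) if (abs(s$x) > 1) Inf else 0
  u0 <- function(s) 0
  res <- attempt_exchange(list(x = 0), list(x = 5), uinf, u0)
  expect_false(res$accepted)
  expect_identical(res$delta, Inf)
})

test_that("long-run exchange rate matches the quadrature oracle", {
  kT <- KB * TREF
  ka <- 2; kb <- 12
  ua <- function(s) 0.5 * ka * s$x^2
  ub <- function(s) 0.5 * kb * s$x^2
  # oracle: E[min(1, exp(-beta delta))] over independent Boltzmann samples,
  # brute-force on a quadrature grid
  sa <- sqrt(kT / ka); sb <- sqrt(kT / kb)
  xg <- seq(-6, 6, length.out = 301)
  pa <- dnorm(xg, sd = sa); pb <- dnorm(xg, sd = sb)
  acc <- outer(xg, xg, function(x, y)
    pmin(1, exp(-((0.5 * ka * y^2 + 0.5 * kb * x^2) -
                  (0.5 * ka * x^2 + 0.5 * kb * y^2)) / kT)))
  wgt <- outer(pa, pb)
  oracle <- sum(acc * wgt) / sum(wgt)
  set.seed(99)
  n <- 20000
  xa <- rnorm(n, sd = sa); xb <- rnorm(n, sd = sb)
  hits <- vapply(seq_len(n), function(i)
    attempt_exchange(list(x = xa[i]), list(x = xb[i]), ua, ub)$accepted,
    logical(1))
  se <- sqrt(oracle * (1 - oracle) / n)
  expect_lt(abs(mean(hits) - oracle), 4 * se + 0.005)
})

test_that("the replica walk is seed-reproducible and boost-mobile", {
  tm <- torsion_model(data.frame(k = 1.2, n = 2, chi0 = 0))
  bp <- boosting_potential(k = 1.2, chi0 = c(0))
  topo <- build_topology(1, 3)
  mk <- function(lambda, boost)
    list(boosts = list(list(id = 1, bp = bp, strength = boost)))
  r1 <- run_hremd(tm, topo, mk, n_sweeps = 40, steps_per_sweep = 15,
                  seed = 4)
  r2 <- run_hremd(tm, topo, mk, n_sweeps = 40, steps_per_sweep = 15,
                  seed = 4)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$exchange_stats, r2$exchange_stats)
  # every configuration visits at least two boost levels
  visited <- rowSums(r1$visits > 0)
  expect_true(all(visited >= 2))
})

test_that("exchanges preserve the zero-boost Boltzmann distribution", {
  tors <- data.frame(k = c(1.2, 0.4), n = c(3, 1), chi0 = c(60, 0))
  tm <- torsion_model(tors)
  efun <- function(chi)
    sum(tors$k * (1 + cos((tors$n * (chi - tors$chi0)) * pi / 180)))
  bounds <- c(-180, -60, 60, 180)
  p_exact <- basin_probs(Vectorize(efun), bounds)
  bp <- boosting_potential(k = c(1.2, 0.4), chi0 = c(60, 0))
  topo <- build_topology(1, 2)
  mk <- function(lambda, boost)
    list(boosts = list(list(id = 1, bp = bp, strength = boost)))
  r <- run_hremd(tm, topo, mk, n_sweeps = 800, steps_per_sweep = 10,
                 seed = 17)
  chi <- vapply(r$frames[[1]], function(f) f$chi, numeric(1))
  occ <- as.numeric(table(cut(chi, bounds)) / length(chi))
  expect_lt(max(abs(occ - p_exact)), 0.08)
})

test_that("a single boost level degenerates to plain window exchange", {
  topo <- build_topology(3, 1)
  expect_equal(nrow(topo$edges), 2L)
  expect_true(all(topo$edges$type == "lambda"))
})

test_that("frozen exchanges reproduce independent-window estimates", {
  m <- tiny_dipole_site(n_ligands = 2)
  na <- default_ion_params("Na"); k <- default_ion_params("K")
  frozen <- hremd_ion_swap(m, na, k, n_lambda = 3, n_boost = 1,
                           n_sweeps = 120, steps_per_sweep = 25, seed = 21,
                           exchange = FALSE)
  # independent-window reference built outside the replica machinery
  lams <- c(0, 0.5, 1)
  mods <- lapply(lams, function(l)
    list(ion = interpolate_ion_params(na, k, l)))
  ser <- lapply(seq_along(lams), function(i)
    run_mc(m, n_steps = 3000, seed = 100 + i, thin = 10,
           modifiers = mods[[i]]))
  ref <- pumpsel:::fep_from_cross(cross_energies(m, ser, mods))
  tol <- 3 * sqrt(frozen$err^2 + ref$err^2) + 0.1
  expect_lt(abs(frozen$dg - ref$dg), tol)
})
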