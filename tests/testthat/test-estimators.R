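test_that("two identical states give exactly zero free-energy difference", {
  set.seed(3)
  x <- rnorm(200)
  u <- rbind(0.5 * x^2, 0.5 * x^2)
  w <- wham_multistate(u, temperature = TREF, origin = rep(1:2, each = 100))
  expect_equal(w$f[2], 0, tolerance = 1e-12)
})

test_that("two harmonic states recover the closed-form free energy", {
  kT <- KB * TREF
  k1 <- 4; k2 <- 16
  set.seed(41)
  n <- 6000
  x <- c(rnorm(n, sd = sqrt(kT / k1)), rnorm(n, sd = sqrt(kT / k2)))
  u <- rbind(0.5 * k1 * x^2, 0.5 * k2 * x^2)
  w <- wham_multistate(u, temperature = TREF, origin = rep(1:2, each = n))
  exact <- kT / 2 * log(k2 / k1)
  expect_lt(abs(w$f[2] - exact), 0.05)
})

test_that("multistate WHAM agrees with the Bennett acceptance-ratio oracle", {
  kT <- KB * TREF
  k1 <- 3; k2 <- 20
  set.seed(7)
  n <- 3000
  xa <- rnorm(n, sd = sqrt(kT / k1))
  xb <- rnorm(n, sd = sqrt(kT / k2))
  ua <- function(x) 0.5 * k1 * x^2
  ub <- function(x) 0.5 * k2 * x^2
  u <- rbind(ua(c(xa, xb)), ub(c(xa, xb)))
  w <- wham_multistate(u, temperature = TREF, origin = rep(1:2, each = n))
  bar <- bar_oracle(ub(xa) - ua(xa), ua(xb) - ub(xb))
  expect_lt(abs(w$f[2] - bar), 0.05)
  # and both near the closed form
  expect_lt(abs(bar - kT / 2 * log(k2 / k1)), 0.05)
})

test_that("a frozen configuration reduces WHAM to exact energy differences", {
  # one frame per state with linear-in-lambda energies: f_k = U_k exactly
  u_vals <- c(0, 1.3, 2.6, 3.9)
  u <- matrix(rep(u_vals, 4), nrow = 4, byrow = FALSE)
  w <- wham_multistate(u, temperature = TREF, origin = 1:4)
  expect_equal(w$f, u_vals - u_vals[1], tolerance = 1e-8)
})

test_that("WHAM free energies shift correctly under column offsets", {
  kT <- KB * TREF
  set.seed(13)
  x <- c(rnorm(500, sd = 1), rnorm(500, sd = 0.5))
  u <- rbind(0.5 * x^2, 2 * x^2)
  org <- rep(1:2, each = 500)
  w0 <- wham_multistate(u, temperature = TREF, origin = org)
  # adding a constant to one state's energies shifts its f by that constant
  u2 <- u; u2[2, ] <- u2[2, ] + 3.21
  w1 <- wham_multistate(u2, temperature = TREF, origin = org)
  expect_equal(w1$f[2], w0$f[2] + 3.21, tolerance = 1e-6)
  # state relabeling permutes the (anchored) free energies consistently
  u3 <- u[c(2, 1), ]
  w2 <- wham_multistate(u3, temperature = TREF,
                        origin = c(2, 1)[org])
  expect_equal(w2$f[2] - w2$f[1], -(w0$f[2] - w0$f[1]), tolerance = 1e-6)
})

test_that("umbrella WHAM recovers a known generating potential", {
  K <- 1.5
  tm <- torsion_model(data.frame(k = K, n = 1, chi0 = 0))
  sc <- umbrella_scan(tm, n_steps = 8000, seed = 11, thin = 8)
  pmf <- wham_umbrella(sc)
  truth <- K * (1 + cospi(pmf$chi / 180))
  truth <- truth - min(truth)
  ok <- is.finite(pmf$w)
  expect_gt(mean(ok), 0.95)
  rms <- sqrt(mean((pmf$w[ok] - truth[ok])^2))
  expect_lt(rms, 0.12)
  expect_equal(min(pmf$w, na.rm = TRUE), 0)
})

test_that("a single unbiased window reduces to the histogram estimate", {
  tm <- torsion_model(data.frame(k = 0.4, n = 1, chi0 = 0))
  w <- umbrella_windows(spacing = 360, force_k = 0)
  sc <- umbrella_scan(tm, windows = w, n_steps = 8000, seed = 23, thin = 4)
  pmf <- wham_umbrella(sc, n_bins = 24)
  kT <- KB * TREF
  h <- pmf$counts
  direct <- -kT * log(h / sum(h))
  direct <- direct - min(direct)
  expect_equal(pmf$w, direct, tolerance = 1e-9)
})

test_that("a flat potential yields a flat PMF within sampling error", {
  tm <- torsion_model(data.frame(k = 0, n = 1, chi0 = 0))
  sc <- umbrella_scan(tm, windows = umbrella_windows(spacing = 10),
                      n_steps = 4000, seed = 5, thin = 5)
  pmf <- wham_umbrella(sc, n_bins = 36)
  expect_lt(max(pmf$w, na.rm = TRUE), 0.35)
})

test_that("the WHAM residual decreases monotonically while iterating", {
  kT <- KB * TREF
  set.seed(2)
  x <- c(rnorm(400, sd = 1), rnorm(400, sd = 0.6))
  u <- rbind(0.5 * x^2, 1.5 * x^2)
  w <- wham_multistate(u, temperature = TREF, origin = rep(1:2, each = 400))
  expect_true(all(diff(w$residual_history) <= 1e-10))
  tm <- torsion_model(data.frame(k = 1, n = 2, chi0 = 0))
  sc <- umbrella_scan(tm, windows = umbrella_windows(spacing = 20),
                      n_steps = 1500, seed = 3, thin = 5)
  pm <- wham_umbrella(sc, n_bins = 36)
  hist <- pm$residual_history
  expect_true(all(diff(hist) <= 1e-8 + 0.05 * hist[-length(hist)]))
})

test_that("block errors follow the known-distribution expectations", {
  expect_equal(block_error(rep(2.5, 100)), 0)
  set.seed(8)
  sigma <- 1.7
  x <- rnorm(5000, sd = sigma)
  # 10 contiguous blocks of 500: SD of block means ~ sigma/sqrt(500)
  expect_lt(abs(block_error(x, 10) - sigma / sqrt(500)),
            0.6 * sigma / sqrt(500))
  # degenerate partition: one frame per block recovers the sample SD
  expect_equal(block_error(x, length(x)), sd(x))
  expect_error(block_error(rnorm(5), 10), "fewer frames")
})

test_that("cross-energy matrices validate their inputs", {
  m <- tiny_dipole_site(n_ligands = 2)
  s <- run_mc(m, n_steps = 200, seed = 1, thin = 10)
  x <- cross_energies(m, list(s), list(NULL))
  expect_s3_class(x, "cross_energy")
  expect_equal(dim(x$u), c(1L, length(s$states)))
  expect_error(wham_multistate(matrix(c(1, NaN), 1, 2), temperature = TREF,
                               origin = c(1, 1)), "non-finite")
})
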