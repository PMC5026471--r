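# Independent oracles used to cross-check the package estimators.  These are
# deliberately separate implementations (closed forms, quadrature, root
# finding) that share no code with the estimation paths they validate.

KB <- 0.0019872041
TREF <- 303.15

# Bennett acceptance-ratio estimate of f_B - f_A (kcal/mol) from forward and
# reverse work values (kcal/mol), solved with uniroot on Bennett's implicit
# equation.  wf = U_B - U_A evaluated on A-samples; wr = U_A - U_B on
# B-samples.
bar_oracle <- function(wf, wr, temperature = TREF) {
  kT <- KB * temperature
  n0 <- length(wf); n1 <- length(wr)
  # two-state self-consistency: sum over all samples of the reverse-state
  # weight equals n1; w = (U_B - U_A)/kT on every sample
  w_all <- c(wf, -wr) / kT
  m <- log(n0 / n1)
  g <- function(d) sum(1 / (1 + exp(m + w_all - d))) - n1
  lo <- min(w_all) - 100
  hi <- max(w_all) + 100
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root * kT
}

# Zwanzig exponential-averaging estimate of f_B - f_A from forward energy
# differences on A-samples
zwanzig_oracle <- function(du, temperature = TREF) {
  kT <- KB * temperature
  -kT * log(mean(exp(-du / kT)))
}

# translational freedom factor by numerical quadrature of
# int r^2 sin(theta) exp(-u_trans/kBT) dr dtheta dpsi (separable)
ft_quadrature <- function(r0, theta0_deg, k_r, k_theta, k_psi,
                          temperature = TREF) {
  b <- 1 / (KB * temperature)
  th0 <- theta0_deg * pi / 180
  sig <- sqrt(1 / (b * k_r))
  ir <- stats::integrate(function(r) r^2 * exp(-0.5 * b * k_r * (r - r0)^2),
                         max(0, r0 - 20 * sig), r0 + 20 * sig,
                         rel.tol = 1e-10)$value
  ith <- stats::integrate(function(t) sin(t) * exp(-0.5 * b * k_theta *
                                                   (t - th0)^2),
                          0, pi, rel.tol = 1e-10)$value
  ips <- stats::integrate(function(p) exp(-0.5 * b * k_psi * p^2),
                          -pi, pi, rel.tol = 1e-10)$value
  ir * ith * ips
}

# Boltzmann probabilities of angular basins of a 1-D periodic potential
# (energy_fn in kcal/mol over degrees), by quadrature
basin_probs <- function(energy_fn, boundaries, temperature = TREF) {
  b <- 1 / (KB * temperature)
  z <- vapply(seq_len(length(boundaries) - 1), function(i)
    stats::integrate(function(x) exp(-b * energy_fn(x)),
                     boundaries[i], boundaries[i + 1],
                     rel.tol = 1e-9)$value, numeric(1))
  z / sum(z)
}

# hand-coded evaluation of the boosting cosine series (independent of
# evaluate_boost): sum_n k_n {1 + cos[n (chi - chi0_n)]} in degrees
boost_by_hand <- function(k, chi0, chi) {
  out <- numeric(length(chi))
  for (i in seq_along(chi)) {
    acc <- 0
    for (n in seq_along(k))
      acc <- acc + k[n] * (1 + cospi(n * (chi[i] - chi0[n]) / 180))
    out[i] <- acc
  }
  out
}
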