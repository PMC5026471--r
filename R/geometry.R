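# Small 3-vector geometry helpers (internal).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angle in degrees into [-180, 180)
wrap_deg <- function(x) ((x + 180) %% 360) - 180

# wrap an angle in radians into (-pi, pi]
wrap_rad <- function(x) {
  y <- x %% (2 * pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle at vertex b formed by points a-b-c, radians in [0, pi]
bond_angle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(max(-1, min(1, cosang)))
}

# torsion a-b-c-d, radians in (-pi, pi]
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# orthonormal frame attached to a ligand anchor: u points from the anchor
# towards the origin (the pocket centre), e1/e2 span the cone around u.
anchor_frame <- function(anchor) {
  r <- vnorm(anchor)
  if (r < 1e-8)
    stop("ligand anchor cannot sit at the origin", call. = FALSE)
  u <- -anchor / r
  ref <- if (abs(u[3]) < 0.99) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(u, ref)
  e1 <- e1 / vnorm(e1)
  e2 <- cross3(u, e1)
  list(u = u, e1 = e1, e2 = e2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# deterministic polynomial hash of a character scalar (fixture checksums,
# provenance stamps); modulus 2^31-1 keeps everything in exact double range
poly_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% p
  sprintf("%010d", h)
}
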