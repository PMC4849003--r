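# Small 3D geometry kernel shared by the helix generator, the side-chain
# builder and the SASA module. All coordinates are in Angstrom, angles in
# degrees at the API surface (converted to radians internally).

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalised")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
# Natural extension reference frame (NeRF) placement: position atom D given
# positions of A, B, C, the bond length C-D, the angle B-C-D (deg) and the
# dihedral A-B-C-D (deg).
place_atom <- function(a, b, c, blen, ang, tors) {
  ang <- deg2rad(ang)
  tors <- deg2rad(tors)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-blen * cos(ang),
          blen * sin(ang) * cos(tors),
          blen * sin(ang) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @noRd
# Dihedral angle A-B-C-D in degrees, in (-180, 180].
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' @noRd
# Virtual C-beta position from backbone N, CA, C for an L-amino acid
# (ideal tetrahedral construction).
place_cbeta <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * cc)
}

#' @noRd
# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral). Used by the Shrake-Rupley SASA routine.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}
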