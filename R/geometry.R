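# Small 3D geometry helpers used by the chain builder and hydrogen placement.

vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Natural extension reference frame: place atom d bonded to c, with bond
# length |cd|, angle b-c-d (degrees) and torsion a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2); v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Rigid-body superposition (Kabsch) of two point sets (n x 3); returns a
# function mapping coordinates from the `from` frame to the `to` frame.
rigid_transform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  function(x) {
    x <- matrix(x, ncol = 3)
    sweep(sweep(x, 2, cf) %*% t(R), 2, ct, "+")
  }
}
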