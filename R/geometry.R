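# Small 3D geometry kernel shared by the trajectory generator and the
# structural metrics. Coordinates are plain numeric matrices (atoms x 3), Å.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop_hd("Zero-length vector has no direction.", "geometry_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Planar angle at a vertex
#'
#' Angle in degrees formed at point `b` by the segments `b`–`a` and `b`–`c`.
#' Used for backbone geometry checks and the helix-kink metric.
#'
#' @param a,b,c Numeric length-3 coordinate vectors (Å).
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_at <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Signed dihedral a-b-c-d in degrees, in (-180, 180].
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Place atom D with bond length r to C, angle(B,C,D) = theta (deg) and
# dihedral(A,B,C,D) = chi (deg): the standard internal-to-Cartesian step.
# Sign convention matches dihedral_angle(), i.e. the IUPAC torsion sense.
place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Optimal rigid-body (Kabsch) superposition of `mobile` onto `ref` using the
# rows in `fit_idx`; returns the transformed full coordinate set.
kabsch_transform <- function(mobile, ref, fit_idx = seq_len(nrow(mobile))) {
  P <- mobile[fit_idx, , drop = FALSE]
  Q <- ref[fit_idx, , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, cp) %*% t(R), 2, cq, "+")
}

coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
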