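# Small 3D geometry kernel shared by the structural modules.

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

#' Dihedral angle defined by four points
#'
#' Returns the signed torsion angle, in degrees in (-180, 180], of the
#' plane (p1, p2, p3) against the plane (p2, p3, p4), using the standard
#' atan2 formulation (IUPAC sign convention).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return numeric scalar, degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Natural extension reference frame (NeRF): place atom D given A, B, C and
# the internal coordinates |CD|, angle(B,C,D) and torsion(A,B,C,D).
# Angles in degrees.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Optimal rigid superposition (Kabsch).  Returns function(xyz) applying the
# transform that maps `mobile` onto `fixed`; both are n x 3 matrices.
kabsch_transform <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), nrow(mobile) >= 3)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm)
  b <- sweep(fixed, 2, cf)
  h <- t(a) %*% b
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  function(xyz) {
    xyz <- as.matrix(xyz)
    sweep(sweep(xyz, 2, cm) %*% t(rot), 2, cf, `+`)
  }
}

# Random (seeded) proper rotation matrix, used in invariance tests and
# fixture generation.
random_rotation <- function() {
  repeat {
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    if (abs(det(q) - 1) < 1e-9) return(q)
  }
}
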