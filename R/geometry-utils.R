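# Internal 3-D geometry primitives shared by the frame, conformation and
# fixture code. All coordinates are in Angstrom, all angles in degrees unless
# a function name says otherwise.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Signed dihedral p1-p2-p3-p4 in (-180, 180].
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.angle3 <- function(p1, p2, p3) {
  u <- .unit(p1 - p2)
  v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Rotation matrix about a unit axis (Rodrigues), angle in degrees.
.rotAxis <- function(axis, theta) {
  a <- .unit(axis)
  t <- theta * pi / 180
  ct <- cos(t); st <- sin(t)
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + st * K + (1 - ct) * (K %*% K)
}

# Rotation from three Euler-like parameters (used by the rigid-placement
# optimisers; any smooth 3-parameter chart is fine there).
.rotEuler <- function(p) {
  .rotAxis(c(1, 0, 0), p[1L]) %*% .rotAxis(c(0, 1, 0), p[2L]) %*%
    .rotAxis(c(0, 0, 1), p[3L])
}

# Total-least-squares plane through the rows of X: list(center, normal).
.planeTLS <- function(X) {
  ctr <- colMeans(X)
  s <- svd(sweep(X, 2L, ctr))
  list(center = ctr, normal = s$v[, 3L])
}

# Place atom D given A, B, C and internal coordinates bond |CD|,
# angle B-C-D and torsion A-B-C-D (degrees). Standard NeRF construction.
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

# Orthonormal local frame at anchor `a` built from two neighbour positions;
# returns 3x3 matrix with columns (u, v, w).
.localFrame <- function(a, n1, n2) {
  u <- .unit(n1 - a)
  v0 <- (n2 - a) - sum((n2 - a) * u) * u
  v <- .unit(v0)
  cbind(u, v, .cross(u, v))
}

# Ray-casting point-in-polygon (non-strict about vertex degeneracies, which
# never arise for base rings). poly is an n x 2 matrix of ordered vertices.
.pointInPolygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if ((yi > pt[2L]) != (yj > pt[2L])) {
      xint <- xi + (pt[2L] - yi) / (yj - yi) * (xj - xi)
      if (pt[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Vectorised convex-polygon membership: all cross products of edge vectors
# with vertex->point vectors share a sign. pts is m x 2, poly n x 2 (ordered).
.inConvexPolygon <- function(pts, poly) {
  n <- nrow(poly)
  res <- rep(TRUE, nrow(pts))
  sgn <- rep(0, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1L] - poly[i, 1L]
    ey <- poly[j, 2L] - poly[i, 2L]
    cr <- ex * (pts[, 2L] - poly[i, 2L]) - ey * (pts[, 1L] - poly[i, 1L])
    s <- sign(cr)
    first <- sgn == 0
    sgn[first] <- s[first]
    res <- res & (s == sgn | s == 0)
    res[s == 0] <- FALSE   # on an edge: not strictly inside
  }
  res
}

# Optimal-superposition RMSD between two N x 3 coordinate sets (Kabsch).
.fitRMSD <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  a <- sweep(A, 2L, colMeans(A))
  b <- sweep(B, 2L, colMeans(B))
  s <- svd(t(a) %*% b)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a %*% R - b)^2)))
}
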