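# Independent oracles used by the property tests. These reimplement the
# geometric definitions with plain, brute-force code that shares no logic
# with the package's annotation path.

# Ray-casting point-in-polygon (the package path uses a convex sign test).
oracleInPolygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- poly[i, 2L]; yj <- poly[j, 2L]
    if ((yi > pt[2L]) != (yj > pt[2L])) {
      xint <- poly[i, 1L] + (pt[2L] - yi) / (yj - yi) * (poly[j, 1L] - poly[i, 1L])
      if (pt[1L] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Conic inequality for the (optionally expanded) fitted ellipse of one ring.
oracleInEllipse <- function(pt, ell, expanded = FALSE) {
  k <- 1
  if (expanded) {
    rmax <- max(sqrt(rowSums(sweep(ell@poly, 2L, ell@center2d)^2)))
    k <- (rmax + ell@expansion) / rmax
  }
  d <- pt - ell@center2d
  co <- cos(ell@orientation); si <- sin(ell@orientation)
  xr <- d[1L] * co + d[2L] * si
  yr <- -d[1L] * si + d[2L] * co
  (xr / (k * ell@semiAxes[1L]))^2 + (yr / (k * ell@semiAxes[2L]))^2 < 1
}

# Brute-force membership classification of an in-plane point.
oracleLocate <- function(frame, xy) {
  inPoly <- vapply(frame@rings, function(e) oracleInPolygon(xy, e@poly),
                   logical(1L))
  if (any(inPoly)) return("inside_ring")
  inExp <- vapply(frame@rings, function(e) oracleInEllipse(xy, e, TRUE),
                  logical(1L))
  if (any(inExp)) return("inside_expanded_ellipse")
  "outside"
}

# Brute-force contact annotation for one ordered (base, oxygen-owner) pair:
# enumerate every (oxygen, case) combination exactly as the rules state and
# reduce by the selection order. Returns NULL or list(atom, z, category).
oracleAnnotate <- function(frame, oxygenNt, params) {
  atoms <- intersect(params@oxygenAtoms, rownames(oxygenNt$atoms))
  rows <- list()
  for (a in atoms) {
    d <- oxygenNt$atoms[a, ] - frame@center
    z <- sum(d * frame@normal)
    xy <- c(sum(d * frame@basis[, 1L]), sum(d * frame@basis[, 2L]))
    loc <- oracleLocate(frame, xy)
    rows[[a]] <- list(atom = a, z = z, xy = xy, loc = loc,
                      dc = sqrt(sum(xy^2)))
  }
  caseA <- Filter(function(r) r$loc == "inside_ring" &&
                    abs(r$z) > params@zMin && abs(r$z) <= params@zMaxTrue, rows)
  if (length(caseA)) {
    best <- caseA[[which.min(vapply(caseA, function(r) abs(r$z), 1))]]
    return(list(atom = best$atom, z = best$z, category = "true"))
  }
  caseB <- Filter(function(r) r$loc == "inside_ring" &&
                    abs(r$z) > params@zMaxTrue && abs(r$z) <= params@zMaxNear,
                  rows)
  if (length(caseB)) {
    best <- caseB[[which.min(vapply(caseB, function(r) abs(r$z), 1))]]
    return(list(atom = best$atom, z = best$z, category = "near"))
  }
  caseC <- Filter(function(r) r$loc == "inside_expanded_ellipse" &&
                    abs(r$z) <= params@zMaxTrue &&
                    (!params@nearLowerBound || abs(r$z) > params@zMin), rows)
  if (length(caseC)) {
    best <- caseC[[which.min(vapply(caseC, function(r) r$dc, 1))]]
    return(list(atom = best$atom, z = best$z, category = "near"))
  }
  NULL
}

# Optimal-superposition RMSD by a quaternion-free Kabsch implementation
# (oracle for the bio3d-based package path).
oracleRMSD <- function(A, B) {
  a <- sweep(A, 2L, colMeans(A))
  b <- sweep(B, 2L, colMeans(B))
  H <- t(a) %*% b
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((a %*% R - b)^2)))
}

# RMS distance of points to the plane (ctr, n) — the quantity a
# total-least-squares plane minimises.
planeDist <- function(X, ctr, n) sqrt(mean((sweep(X, 2L, ctr) %*% n)^2))

# A record carrying only backbone-oxygen atoms at given coordinates, for
# direct placement tests.
oxygenProbe <- function(coords, chain = "B", seq = 9L) {
  m <- do.call(rbind, coords)
  rownames(m) <- names(coords)
  nucleotideRecord("U", m, chain = chain, seq = seq)
}

randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(a*a+b*b-c*c-d*d, 2*(b*c+a*d), 2*(b*d-a*c),
           2*(b*c-a*d), a*a-b*b+c*c-d*d, 2*(c*d+a*b),
           2*(b*d+a*c), 2*(c*d-a*b), a*a-b*b-c*c+d*d), 3L, 3L)
}

rigidMove <- function(nt, R = randomRotation(), t = rnorm(3, 0, 10)) {
  nt$atoms <- sweep(nt$atoms %*% t(R), 2L, t, "+")
  nt
}
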