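# Nucleobase reference frames: geometric center, signed normal (3'-face
# convention), in-plane basis and per-ring fitted/expanded ellipses.

# Direct least-squares conic fit constrained to an ellipse (generalised
# eigenproblem formulation), followed by conversion to center/axes/angle.
.fitEllipseConic <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  D1 <- cbind(x * x, x * y, y * y)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("degenerate ring geometry: ", conditionMessage(e)))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
  ev <- eigen(M)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1L, ] * vec[3L, ] - vec[2L, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop("input points do not determine an ellipse")
  a1 <- vec[, ok[1L]]
  c(a1, Tm %*% a1)   # (A, B, C, D, E, F)
}

.conicToGeometric <- function(conic) {
  A <- conic[1L]; B <- conic[2L]; C <- conic[3L]
  D <- conic[4L]; E <- conic[5L]; F <- conic[6L]
  den <- B * B - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx * cx + B * cx * cy + C * cy * cy + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2L, 2L)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values
  if (any(lam * (-Fc) <= 0)) stop("conic is not a real ellipse")
  ax <- sqrt(-Fc / lam)             # lam sorted decreasing -> ax increasing
  major <- which.max(ax)
  orient <- atan2(eq$vectors[2L, major], eq$vectors[1L, major])
  if (orient < 0) orient <- orient + pi
  list(center = c(cx, cy), a = max(ax), b = min(ax), orientation = orient)
}

#' Fit the ellipse of a nucleobase ring
#'
#' Least-squares conic fit constrained to an ellipse through the in-plane
#' ring-atom positions. The expanded ("near") boundary is the fitted ellipse
#' scaled about its center so that it passes \code{expansion} Angstrom
#' radially beyond the most outlying ring atom.
#'
#' @param xy matrix of 5 or 6 in-plane points (cyclic order), non-collinear.
#' @param expansion radial expansion in Angstrom (default 0.3).
#' @param ringAtoms optional atom names for the vertices.
#' @return a \code{RingEllipse}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 7)[-7]
#' fitRingEllipse(cbind(1.4 * cos(th), 1.4 * sin(th)))
#' @export
fitRingEllipse <- function(xy, expansion = 0.3, ringAtoms = character()) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L, nrow(xy) %in% c(5L, 6L))
  if (qr(sweep(xy, 2L, colMeans(xy)))$rank < 2L)
    stop("ring points are collinear")
  geo <- .conicToGeometric(.fitEllipseConic(xy))
  # radial residual of the fit
  rel <- sweep(xy, 2L, geo$center)
  ct <- cos(-geo$orientation); st <- sin(-geo$orientation)
  xr <- rel[, 1L] * ct - rel[, 2L] * st
  yr <- rel[, 1L] * st + rel[, 2L] * ct
  rpt <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  rell <- 1 / sqrt((cos(phi) / geo$a)^2 + (sin(phi) / geo$b)^2)
  new("RingEllipse",
      ringAtoms = as.character(ringAtoms), center2d = geo$center,
      semiAxes = c(geo$a, geo$b), orientation = geo$orientation,
      expansion = expansion, residual = sqrt(mean((rpt - rell)^2)),
      poly = xy)
}

# Radial scale factor of the expanded ellipse.
.expansionFactor <- function(ell) {
  if (ell@expansion <= 0) return(1)
  rmax <- max(sqrt(rowSums(sweep(ell@poly, 2L, ell@center2d)^2)))
  (rmax + ell@expansion) / rmax
}

# Ellipse membership for an m x 2 matrix of points; `scale` multiplies both
# semi-axes (1 = fitted ellipse).
.inEllipse <- function(pts, ell, scale = 1) {
  rel <- sweep(pts, 2L, ell@center2d)
  ct <- cos(-ell@orientation); st <- sin(-ell@orientation)
  xr <- rel[, 1L] * ct - rel[, 2L] * st
  yr <- rel[, 1L] * st + rel[, 2L] * ct
  (xr / (scale * ell@semiAxes[1L]))^2 + (yr / (scale * ell@semiAxes[2L]))^2 < 1
}

#' Compute the reference frame of a nucleobase
#'
#' The center is the unweighted mean of the base heavy atoms (ring plus
#' exocyclic substituents, or ring atoms only with
#' \code{centerAtoms = "ring"}); the plane is the total-least-squares plane
#' through the same atoms; the normal sign is fixed by the stored intra-base
#' convention so that the positive normal points toward the 3'-face in a
#' regular RNA helix.
#'
#' @param nt a nucleotide record with all ring atoms present.
#' @param expansion ellipse expansion passed to \code{\link{fitRingEllipse}}.
#' @param centerAtoms "base" (default: all base heavy atoms) or "ring".
#' @return a \code{BaseFrame}, or NULL (with a warning) when a ring atom is
#'   missing.
#' @examples
#' fr <- baseFrame(buildNucleotide("G", chi = -160, puckerP = 18))
#' fr@normal
#' @export
baseFrame <- function(nt, expansion = 0.3, centerAtoms = c("base", "ring")) {
  centerAtoms <- match.arg(centerAtoms)
  ring <- .ringAtoms(nt$base)
  if (!.hasAtoms(nt, ring)) {
    warning(sprintf("nucleotide %s: missing ring atom, no frame computed", ntKey(nt)))
    return(NULL)
  }
  heavy <- if (centerAtoms == "base")
    intersect(.baseHeavyAtoms[[nt$base]], rownames(nt$atoms)) else ring
  X <- nt$atoms[heavy, , drop = FALSE]
  pl <- .planeTLS(X)
  ref <- .normalRefAtoms[[nt$base]]
  v1 <- .atomXYZ(nt, ref[2L]) - .atomXYZ(nt, ref[1L])
  v2 <- .atomXYZ(nt, ref[3L]) - .atomXYZ(nt, ref[1L])
  n <- pl$normal
  if (sum(n * .cross(v1, v2)) < 0) n <- -n
  gly <- .atomXYZ(nt, .glyN[[nt$base]])
  b1v <- (gly - pl$center) - sum((gly - pl$center) * n) * n
  b1 <- .unit(b1v)
  basis <- cbind(b1, .cross(n, b1))
  dimnames(basis) <- NULL
  proj2d <- function(names) {
    rel <- sweep(nt$atoms[names, , drop = FALSE], 2L, pl$center)
    cbind(rel %*% basis[, 1L], rel %*% basis[, 2L])
  }
  rings <- lapply(.ringSets[[nt$base]], function(names)
    fitRingEllipse(proj2d(names), expansion = expansion, ringAtoms = names))
  new("BaseFrame", base = nt$base, center = pl$center, normal = n,
      basis = basis, rings = rings)
}

#' Express a point in a base frame
#'
#' @param frame a \code{BaseFrame}.
#' @param point 3-D coordinate.
#' @return numeric (x, y, z): in-plane coordinates and the signed distance
#'   along the normal (z > 0 = 3'-face side).
#' @export
projectOntoFrame <- function(frame, point) {
  d <- point - frame@center
  c(x = sum(d * frame@basis[, 1L]), y = sum(d * frame@basis[, 2L]),
    z = sum(d * frame@normal))
}

#' Locate an in-plane point relative to the ring system
#'
#' "Inside a ring" means strictly inside the polygon formed by the ring
#' atoms' in-plane positions; "inside the expanded ellipse" means outside
#' every ring polygon but inside at least one expanded ellipse. For purines
#' both rings are examined; a point inside both polygons (possible only at
#' the fused bond) is attributed in the annotator, not here.
#'
#' @param frame a \code{BaseFrame}.
#' @param xy in-plane coordinate (length 2).
#' @return list with \code{status} ("inside_ring", "inside_expanded_ellipse"
#'   or "outside") and \code{ring} (index of the matched ring, or NA).
#' @export
locateProjection <- function(frame, xy) {
  pts <- matrix(xy, 1L, 2L)
  inPoly <- vapply(frame@rings, function(e) .inConvexPolygon(pts, e@poly),
                   logical(1L))
  if (any(inPoly)) {
    hits <- which(inPoly)
    if (length(hits) > 1L) {
      d <- vapply(frame@rings[hits], function(e)
        sum((xy - colMeans(e@poly))^2), numeric(1L))
      hits <- hits[which.min(d)]
    }
    return(list(status = "inside_ring", ring = hits[1L]))
  }
  inExp <- vapply(frame@rings, function(e)
    .inEllipse(pts, e, scale = .expansionFactor(e)), logical(1L))
  if (any(inExp)) {
    hits <- which(inExp)
    if (length(hits) > 1L) {
      d <- vapply(frame@rings[hits], function(e)
        sum((xy - e@center2d)^2), numeric(1L))
      hits <- hits[which.min(d)]
    }
    return(list(status = "inside_expanded_ellipse", ring = hits[1L]))
  }
  list(status = "outside", ring = NA_integer_)
}
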