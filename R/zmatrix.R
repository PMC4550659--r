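# Internal-coordinate (Z-matrix) construction and reconstruction. Reference
# atoms are chosen for numerical stability: the distance reference is the
# nearest previously defined atom, the angle reference the nearest other,
# and the dihedral reference the nearest that keeps the reference triple
# non-collinear. The choice is not critical -- optimized positions do not
# depend on the starting coordinate system -- but nearest-neighbour
# references keep angles well conditioned.

.vnorm <- function(v) sqrt(sum(v^2))

.angle_deg <- function(a, b, c) {
  # angle at b, degrees in [0, 180]
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.collinear <- function(p, q, r, tol = 1e-6) {
  u <- q - p; v <- r - p
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  .vnorm(cr) < tol * max(.vnorm(u) * .vnorm(v), 1e-12)
}

#' Convert Cartesian coordinates to internal (Z-matrix) coordinates
#'
#' Row k references up to three previously defined atoms: `r1` (distance,
#' Angstrom), `r2` (angle at `r1`, degrees) and `r3` (dihedral, degrees).
#' `r1` is the nearest previously defined atom, `r2` the nearest other, and
#' `r3` the nearest that makes `(r1, r2, r3)` non-collinear (falling back to
#' the next-nearest candidates).
#'
#' @param atoms atom table with coordinates; no two atoms may coincide
#'   within 1e-6 Angstrom.
#' @return data.frame of class `zmatrix` with columns `element`, `distance`,
#'   `angle`, `dihedral`, `r1`, `r2`, `r3` (NA where not applicable).
#' @export
cartesian_to_internal <- function(atoms) {
  n <- nrow(atoms)
  if (n < 1) stop("at least one atom required")
  if (!has_coordinates(atoms)) stop("atoms lack coordinates")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (n > 1) {
    dm <- as.matrix(stats::dist(xyz))
    if (any(dm[upper.tri(dm)] < 1e-6)) stop("coincident atoms in input")
  }
  z <- data.frame(element = atoms$element,
                  distance = NA_real_, angle = NA_real_, dihedral = NA_real_,
                  r1 = NA_integer_, r2 = NA_integer_, r3 = NA_integer_,
                  stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    if (k == 1) next
    prev <- seq_len(k - 1L)
    ord <- prev[order(dm[k, prev])]
    r1 <- ord[1]
    z$r1[k] <- r1
    z$distance[k] <- dm[k, r1]
    if (k == 2) next
    r2cand <- setdiff(ord, r1)
    r2 <- r2cand[1]
    z$r2[k] <- r2
    z$angle[k] <- .angle_deg(xyz[k, ], xyz[r1, ], xyz[r2, ])
    if (k == 3) next
    r3 <- NA_integer_
    for (cand in setdiff(ord, c(r1, r2))) {
      if (!.collinear(xyz[r1, ], xyz[r2, ], xyz[cand, ])) { r3 <- cand; break }
    }
    if (is.na(r3)) {
      # all remaining references collinear with (r1, r2): fall back to the
      # nearest candidate; the dihedral is then degenerate but harmless
      r3 <- setdiff(ord, c(r1, r2))[1]
    }
    z$r3[k] <- r3
    z$dihedral[k] <- .dihedral_deg(xyz[k, ], xyz[r1, ], xyz[r2, ], xyz[r3, ])
  }
  class(z) <- c("zmatrix", "data.frame")
  z
}

#' Rebuild Cartesian coordinates from a Z-matrix
#'
#' Places atom 1 at the origin, atom 2 along x, atom 3 in the xy-plane, and
#' every later atom by its distance/angle/dihedral relative to its reference
#' atoms. The absolute orientation is unconstrained; all pairwise distances
#' are reproduced.
#'
#' @param zmat a `zmatrix` data.frame from [cartesian_to_internal()].
#' @return atom table with coordinates.
#' @export
internal_to_cartesian <- function(zmat) {
  n <- nrow(zmat)
  xyz <- matrix(0, n, 3)
  if (n >= 2) xyz[2, ] <- c(zmat$distance[2], 0, 0)
  if (n >= 3) {
    r1 <- zmat$r1[3]; r2 <- zmat$r2[3]
    th <- zmat$angle[3] * pi / 180
    d <- zmat$distance[3]
    # in-plane placement relative to r1, towards/away from r2 along x
    dirx <- sign(xyz[r2, 1] - xyz[r1, 1])
    if (dirx == 0) dirx <- 1
    xyz[3, ] <- xyz[r1, ] + c(dirx * d * cos(th), d * sin(th), 0)
  }
  for (k in seq_len(n)) {
    if (k <= 3) next
    r1 <- zmat$r1[k]; r2 <- zmat$r2[k]; r3 <- zmat$r3[k]
    d <- zmat$distance[k]
    th <- zmat$angle[k] * pi / 180
    ph <- if (is.na(zmat$dihedral[k])) 0 else zmat$dihedral[k] * pi / 180
    b <- xyz[r1, ]; a <- xyz[r2, ]; cpt <- xyz[r3, ]
    # local frame at b (NeRF-style placement)
    bc <- b - a; bc <- bc / .vnorm(bc)
    ab <- a - cpt
    nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nn <- .vnorm(nv)
    if (nn < 1e-10) {
      # degenerate (collinear) reference frame: any perpendicular will do
      pv <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      nv <- c(bc[2] * pv[3] - bc[3] * pv[2],
              bc[3] * pv[1] - bc[1] * pv[3],
              bc[1] * pv[2] - bc[2] * pv[1])
      nn <- .vnorm(nv)
    }
    nv <- nv / nn
    mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
            nv[3] * bc[1] - nv[1] * bc[3],
            nv[1] * bc[2] - nv[2] * bc[1])
    d2 <- c(-d * cos(th), d * sin(th) * cos(ph), -d * sin(th) * sin(ph))
    xyz[k, ] <- b + d2[1] * bc + d2[2] * mv + d2[3] * nv
  }
  atoms(zmat$element, xyz[, 1], xyz[, 2], xyz[, 3])
}
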