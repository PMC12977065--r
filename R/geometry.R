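# Geometry primitives: Kabsch superposition, internal-coordinate atom
# placement, torsions, signed volumes.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `ref`, proper
#' rotations only (the reflection branch of the SVD solution is rejected by
#' determinant correction, so enantiomers are never superimposed onto each
#' other).
#'
#' @param mobile,ref n x 3 coordinate matrices (same n).
#' @return list with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` best fits `ref`, and `rmsd` over the
#'   fitted points.
#' @keywords internal
kabsch_fit <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), ncol(mobile) == 3L, ncol(ref) == 3L)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2L, cm); Q <- sweep(ref, 2L, cr)
  s <- svd(crossprod(P, Q))          # P^T Q = U D V^T
  d <- sign(det(tcrossprod(s$u, s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- P %*% R
  list(rotation = R,
       translation = cr - as.numeric(cm %*% R),
       rmsd = sqrt(sum((fitted - Q)^2) / nrow(ref)))
}

# Apply a kabsch_fit derived on a subset to a full coordinate matrix.
apply_fit <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, `+`)
}

#' Heavy-atom RMSD between two conformers
#'
#' Minimal root-mean-square deviation over all proper rigid superpositions
#' (optimal rotation + translation, no reflection). Symmetric in its
#' arguments. No atom-permutation canonicalisation is attempted: atoms are
#' compared strictly by index.
#'
#' @param a,b [ts_structure] objects with identical symbol sequences.
#' @param heavy_only if `TRUE` (default) hydrogens are excluded.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, heavy_only = TRUE) {
  stopifnot(inherits(a, "ts_structure"), inherits(b, "ts_structure"))
  if (!same_symbols(a, b)) {
    stop("structures have different symbol sequences; RMSD is undefined")
  }
  sel <- if (heavy_only) which(is_heavy(a$symbols)) else seq_along(a$symbols)
  if (length(sel) == 0L) sel <- seq_along(a$symbols)  # all-H edge case
  kabsch_fit(a$coords[sel, , drop = FALSE], b$coords[sel, , drop = FALSE])$rmsd
}

# Internal-coordinate (NeRF) placement: position atom d given positions of
# a-b-c, the bond length c-d, angle b-c-d (deg) and dihedral a-b-c-d (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference atoms in place_atom")
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Signed dihedral angle (degrees, in (-180, 180]) for points p1-p2-p3-p4.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Signed volume of the tetrahedron spanned by 4 points (chirality probe).
signed_volume <- function(p) {
  det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])) / 6
}

# Full pairwise Euclidean distance matrix.
dist_matrix <- function(coords) as.matrix(stats::dist(coords))

# Rotate `moving` atom coordinates about the axis p1->p2 by `deg` degrees.
rotate_about_axis <- function(coords, moving, p1, p2, deg) {
  ax <- p2 - p1; ax <- ax / sqrt(sum(ax^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shifted <- sweep(coords[moving, , drop = FALSE], 2L, p1)
  coords[moving, ] <- sweep(shifted %*% t(R), 2L, p1, `+`)
  coords
}
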