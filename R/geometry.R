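# Small 3D vector helpers shared by the builders and the contact/H-bond code.
# All coordinates are in Angstroms, all angles in degrees unless noted.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180

#' Place an atom from internal coordinates
#'
#' Standard NeRF chain extension: given three previously placed atoms
#' \code{a}, \code{b}, \code{c}, returns the position \code{d} such that
#' \code{|cd| = bond}, the angle b-c-d equals \code{angle} and the dihedral
#' a-b-c-d equals \code{dihedral}.
#'
#' @param a,b,c numeric xyz vectors of the three reference atoms.
#' @param bond bond length c-d in Angstroms.
#' @param angle planar angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return numeric xyz vector for the new atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- -deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Perpendicular distance of points (rows of `pts`) from the least-squares
# line through `axis_pts` (rows). Used to find the residue bulging out of
# the local helix axis.
dist_to_axis <- function(pts, axis_pts) {
  ctr <- colMeans(axis_pts)
  sv <- svd(sweep(axis_pts, 2, ctr))
  dirv <- sv$v[, 1]
  rel <- sweep(pts, 2, ctr)
  proj <- rel %*% dirv
  perp <- rel - proj %*% t(dirv)
  sqrt(rowSums(perp^2))
}

# Random rigid-body motion, used by tests; returns a function mapping an
# n x 3 matrix of coordinates.
rigid_motion <- function(angles = c(0.3, -1.1, 2.0), shift = c(5, -3, 11)) {
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- rz(angles[3]) %*% ry(angles[2]) %*% rx(angles[1])
  function(xyz) sweep(xyz %*% t(R), 2, shift, `+`)
}
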