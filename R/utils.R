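# Small geometry/numeric helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signed dihedral angle between four points
#'
#' Returns the torsion about the b--c axis in degrees on the branch
#' (-180, 180], with -180 mapped to +180.
#'
#' @param a,b,c,d Numeric 3-vectors (Cartesian, Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  # IUPAC sign convention (matches the field's torsion tools)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  # canonical branch: map exact -180 to +180
  if (isTRUE(all.equal(ang, -180))) ang <- 180
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# NeRF atom placement: position a new atom given three reference atoms,
# a bond length (new-c), a bond angle b-c-new (degrees) and a dihedral
# a-b-c-new (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(dih) * sin(pi - ang),
          bond * sin(dih) * sin(pi - ang))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c + rot %*% d2)
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# All pairwise distances between two coordinate sets (n x 3, m x 3),
# with orthorhombic minimum-image convention when box lengths are given.
pair_distances <- function(xa, xb, box = NULL) {
  if (is.null(box)) {
    dx <- outer(xa[, 1], xb[, 1], "-")
    dy <- outer(xa[, 2], xb[, 2], "-")
    dz <- outer(xa[, 3], xb[, 3], "-")
  } else {
    mi <- function(d, L) d - L * round(d / L)
    dx <- mi(outer(xa[, 1], xb[, 1], "-"), box[1])
    dy <- mi(outer(xa[, 2], xb[, 2], "-"), box[2])
    dz <- mi(outer(xa[, 3], xb[, 3], "-"), box[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

mdain_abort <- function(msg, class) {
  stop(structure(class = c(class, "mdain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
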