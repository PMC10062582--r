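# Small 3D geometry kernel: vector helpers, dihedral measurement, and
# internal-coordinate (NeRF) atom placement. Everything works in Angstrom
# and degrees; torsions are reported in (-180, 180].

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Dihedral angle defined by four points
#'
#' Returns the torsion angle of the bond p2--p3 as seen from p1 towards p4,
#' using the standard atan2 formulation. The IUPAC sign convention is used:
#' looking down p2->p3, a clockwise rotation of p4 relative to p1 is positive.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit3(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) construction: given three reference positions
#' a, b, c, returns the position d with |c-d| = bond, angle(b,c,d) = angle
#' and dihedral(a,b,c,d) = torsion.
#'
#' @param a,b,c numeric 3-vectors, Angstrom; must not be collinear.
#' @param bond bond length c--d in Angstrom (> 0).
#' @param angle bond angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric 3-vector, the placed position.
#' @export
place_internal <- function(a, b, c, bond, angle, torsion) {
  stopifnot(bond > 0)
  bc <- c - b
  ab <- b - a
  n <- .cross3(ab, bc)
  if (.norm3(n) < 1e-8 * max(.norm3(ab) * .norm3(bc), 1e-12))
    stop("degenerate reference geometry: the three reference atoms are collinear")
  bc_u <- .unit3(bc)
  n_u <- .unit3(n)
  m_u <- .cross3(n_u, bc_u)
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               -bond * sin(th) * sin(ph))
  c + d_local[1L] * bc_u + d_local[2L] * m_u + d_local[3L] * n_u
}

# van der Waals radii (Angstrom), Bondi-style values as commonly used for
# clash scoring; unknown elements fall back to carbon.
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  MG = 1.73, "NA" = 2.27, K = 2.75, CA = 2.31, ZN = 1.39, FE = 2.00, MN = 2.05
)

#' van der Waals radius lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom; unknown elements get the
#'   carbon radius (1.70).
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(trimws(element))]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Uniformly random 3x3 rotation matrix (quaternion method); consumes RNG.
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q * q))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)
  ), nrow = 3L, byrow = TRUE)
}
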