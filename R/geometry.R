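# Internal-coordinate geometry kernel: NeRF atom placement and measurement
# of distances, planar angles and dihedrals.  All angles in degrees;
# dihedrals follow the IUPAC convention (cis = 0, range (-180, 180]).

DEG <- pi / 180

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' such that `|d - c| = bond_length`, the angle b-c-d equals `bond_angle`
#' and the dihedral a-b-c-d equals `torsion` (IUPAC sign convention).
#' This is the kernel used to extend a peptide chain atom by atom from
#' bond lengths, bond angles and torsion restraints.
#'
#' @param a,b,c Numeric length-3 reference coordinates (Angstrom).
#' @param bond_length Distance c-d in Angstrom (> 0).
#' @param bond_angle Planar angle b-c-d in degrees.
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Numeric length-3 coordinates of the new atom.
#' @examples
#' d <- place_atom(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), 1, 90, 0)
#' measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), d)  # ~0
#' @export
place_atom <- function(a, b, c, bond_length, bond_angle, torsion) {
  stopifnot(bond_length > 0)
  bc <- c - b
  nbc <- vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- vnorm(n)
  if (nbc < 1e-9 || nn < 1e-9 * max(vnorm(ab), 1) * max(nbc, 1)) {
    stop("place_atom: reference atoms are collinear or coincident")
  }
  bc <- bc / nbc
  n <- n / nn
  m <- cross3(n, bc)
  ang <- bond_angle * DEG
  tor <- torsion * DEG
  d2 <- bond_length * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Measure distance, angle and dihedral
#'
#' `measure_distance`, `measure_angle` and `measure_dihedral` recompute the
#' internal coordinates implied by 2, 3 and 4 points respectively; they are
#' the inverses of [place_atom()] and are used throughout the tests to
#' verify built geometry.
#'
#' @param a,b,c,d Numeric length-3 coordinates.
#' @return Distance in Angstrom, or angle/dihedral in degrees
#'   (dihedral in (-180, 180]).
#' @export
measure_distance <- function(a, b) vnorm(b - a)

#' @rdname measure_distance
#' @export
measure_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) / DEG
}

#' @rdname measure_distance
#' @export
measure_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(b2 / vnorm(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle (deg) into (-180, 180]
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x == -180] <- 180
  x
}
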