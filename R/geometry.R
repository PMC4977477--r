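# Internal geometry: ideal backbone parameters and torsion-space kinematics.
# Six atoms per residue, in fixed order N, H, CA, CB, C, O (glycine carries an
# HA pseudo-atom in the CB slot). Bond lengths/angles are standard peptide
# ideals; only phi/psi vary, omega is held trans.

.GEOM <- list(
  b_N_CA  = 1.458, b_CA_C = 1.525, b_C_N = 1.329,
  b_C_O   = 1.231, b_N_H  = 1.010, b_CA_CB = 1.530, b_CA_HA = 1.090,
  a_C_N_CA = 121.7, a_N_CA_C = 111.2, a_CA_C_N = 116.2,
  a_CA_C_O = 120.8, a_C_N_H  = 119.0, a_N_CA_CB = 110.5,
  d_CB = -122.6,   # improper C-N-CA-CB, fixes the side-chain marker position
  omega = 180
)

.ATOM_NAMES <- c("N", "H", "CA", "CB", "C", "O")

#' Normalize angles to the half-open interval (-180, 180]
#'
#' All torsions in the package live on the circle; this is the canonical
#' representative. The map is idempotent.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180].
#' @export
#' @examples
#' normalize_angle(c(190, -181, 360, 180))
normalize_angle <- function(x) {
  a <- x %% 360
  a[a > 180] <- a[a > 180] - 360
  # guard against -180 produced by floating error in %%
  a[a <= -180] <- a[a <= -180] + 360
  a
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# Signed dihedral p1-p2-p3-p4 in degrees, in (-180, 180].
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- .cross3(n1, b2n)
  normalize_angle(atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# NeRF placement: position atom D bonded to C with given internal coordinates
# (bond C-D, angle B-C-D, dihedral A-B-C-D, both in degrees).
.place_atom <- function(a, b, c3, bond, angle, torsion) {
  th <- angle * pi / 180
  ch <- -torsion * pi / 180
  bc <- c3 - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c3 + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
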