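#' @include AllClasses.R
NULL

## standard 3-letter amino-acid codes, alphabetical
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

## heavy-atom van der Waals radii (Angstrom) used for SASA and the
## soft-sphere excluded-volume term
ELEMENT_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)

is_hydrogen <- function(elesy) toupper(elesy) %in% c("H", "D")

## element symbol from an atom name when the element column is absent:
## strip leading digits, take the first letter (PDB v2-era convention)
element_from_name <- function(elety) {
  s <- sub("^[0-9]+", "", trimws(elety))
  toupper(substr(s, 1L, 1L))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## place atom D from reference positions A, B, C given bond |C-D|,
## angle B-C-D (degrees) and dihedral A-B-C-D (degrees); standard
## natural-extension reference frame construction
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  C + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## rotation matrix for angle theta (radians) about unit axis u (Rodrigues)
rotation_matrix <- function(u, theta) {
  u <- unit(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

## rotate rows of an n x 3 matrix about the axis through `origin` along `u`
rotate_about_axis <- function(xyz, origin, u, theta) {
  R <- rotation_matrix(u, theta)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, "+")
}

## golden-spiral points on the unit sphere; deterministic for a given n
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## squared distances between one point and rows of a matrix
row_dist2 <- function(xyz, p) {
  (xyz[, 1L] - p[1L])^2 + (xyz[, 2L] - p[2L])^2 + (xyz[, 3L] - p[3L])^2
}

## all pairwise distances between rows of a (m x 3) and b (k x 3): m x k
cross_dist <- function(a, b) {
  m <- nrow(a); k <- nrow(b)
  dx <- matrix(a[, 1L], m, k) - matrix(b[, 1L], m, k, byrow = TRUE)
  dy <- matrix(a[, 2L], m, k) - matrix(b[, 2L], m, k, byrow = TRUE)
  dz <- matrix(a[, 3L], m, k) - matrix(b[, 3L], m, k, byrow = TRUE)
  sqrt(dx * dx + dy * dy + dz * dz)
}
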