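# Small vector-geometry kernel shared by the builder, the secondary-structure
# assigner and the geometric observables.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) abort("degenerate geometry: zero-length vector")
  a / n
}

# Unsigned angle between two vectors, degrees in [0, 180].
angle_deg <- function(u, v) {
  cosang <- sum(vunit(u) * vunit(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Signed dihedral a-b-c-d in degrees, IUPAC convention.
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF placement: coordinates of atom D bonded to C, given reference atoms
# A-B-C, bond length r (C-D), bond angle theta (B-C-D, degrees) and dihedral
# phi (A-B-C-D, degrees).
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- -phi * pi / 180  # sign such that measured dihedral_deg(a,b,c,d) == phi
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# Rigid-body transform helpers -------------------------------------------

# Apply rotation R (3x3) then translation t to an N x 3 coordinate matrix.
transform_coords <- function(xyz, rot = diag(3), trans = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2, -trans)
}

# Rotation matrix about an arbitrary unit axis by angle degrees (Rodrigues).
rotation_about <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_one <- setNames(names(aa_three), unname(aa_three))

check_sequence <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(letters1), names(aa_three))
  if (length(bad) > 0) {
    abort(paste0("unknown amino-acid letter(s): ", paste(bad, collapse = ", ")))
  }
  letters1
}
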