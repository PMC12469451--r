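# Internal vector geometry: frame-vectorised NeRF atom placement,
# backbone dihedrals and Kabsch superposition. All coordinates in nm,
# angles in degrees at the interfaces.

DEG <- pi / 180

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_normalize <- function(a) a / sqrt(rowSums(a^2))

# Place atom D from reference atoms A, B, C (each an n x 3 matrix across
# frames) given bond length |C-D|, bond angle B-C-D and torsion A-B-C-D.
# Standard natural-extension-of-reference-frame construction, vectorised
# over frames.
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * DEG
  ph <- torsion_deg * DEG
  n <- nrow(C)
  bond <- rep_len(bond, n); th <- rep_len(th, n); ph <- rep_len(ph, n)
  bc <- row_normalize(C - B)
  nrm <- row_normalize(row_cross(B - A, bc))
  m <- row_cross(nrm, bc)
  d2 <- cbind(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  C + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * nrm
}

# Torsion angle (degrees, in (-180, 180]) for four n x 3 point sets.
row_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, row_normalize(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) / DEG
}

# Kabsch: optimal-rotation RMSD between two m x 3 coordinate sets.
kabsch_rmsd <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xc %*% rot - yc)^2)))
}
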