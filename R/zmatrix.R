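# Internal-coordinate (Z-matrix) machinery for alpha-terpinene.
#
# A fixed Z-matrix over the 26 atoms lets anchor geometries be expressed,
# compared and interpolated in internal coordinates (bond lengths, angles,
# dihedrals) and rebuilt in Cartesians.  Interpolating internals rather
# than Cartesians keeps CH2/CH3 groups intact while the ring torsions
# swing open.  The tree follows the open-chain connectivity
# C6-C1(-C2(-C7,-C8))-C3 / C6-C9-C5(-C10)-C4, so the C3--C4 ring-closure
# distance is emergent, not a coordinate: it stays meaningful both before
# and after bond rupture.

# Atom order: carbons first, then hydrogens; each row: element, label (or
# ""), and the three reference atoms (distance, angle, dihedral).
terpinene_zmatrix <- function() {
  z <- rbind(
    c("C", "C6",  NA,    NA,    NA),
    c("C", "C1",  "C6",  NA,    NA),
    c("C", "C3",  "C1",  "C6",  NA),
    c("C", "C9",  "C6",  "C1",  "C3"),
    c("C", "C5",  "C9",  "C6",  "C1"),
    c("C", "C4",  "C5",  "C9",  "C6"),
    c("C", "C2",  "C1",  "C6",  "C9"),
    c("C", "C10", "C5",  "C9",  "C6"),
    c("C", "C7",  "C2",  "C1",  "C6"),
    c("C", "C8",  "C2",  "C1",  "C6"),
    c("H", "H6",  "C6",  "C9",  "C5"),
    c("H", "H9",  "C9",  "C6",  "C1"),
    c("H", "H3a", "C3",  "C1",  "C6"),
    c("H", "H3b", "C3",  "C1",  "C6"),
    c("H", "H4a", "C4",  "C5",  "C9"),
    c("H", "H4b", "C4",  "C5",  "C9"),
    c("H", "H2",  "C2",  "C1",  "C6"),
    c("H", "H7a", "C7",  "C2",  "C1"),
    c("H", "H7b", "C7",  "C2",  "C1"),
    c("H", "H7c", "C7",  "C2",  "C1"),
    c("H", "H8a", "C8",  "C2",  "C1"),
    c("H", "H8b", "C8",  "C2",  "C1"),
    c("H", "H8c", "C8",  "C2",  "C1"),
    c("H", "H10a", "C10", "C5", "C9"),
    c("H", "H10b", "C10", "C5", "C9"),
    c("H", "H10c", "C10", "C5", "C9"))
  colnames(z) <- c("element", "name", "ref_d", "ref_a", "ref_t")
  idx <- stats::setNames(seq_len(nrow(z)), z[, "name"])
  list(element = z[, "element"], name = z[, "name"],
       ref_d = unname(idx[z[, "ref_d"]]),
       ref_a = unname(idx[z[, "ref_a"]]),
       ref_t = unname(idx[z[, "ref_t"]]),
       index = idx)
}

terpinene_carbon_map <- function() {
  idx <- terpinene_zmatrix()$index
  labs <- paste0("C", 1:10)
  stats::setNames(as.integer(idx[labs]), labs)
}

# Place atom D given references A (dihedral), B (angle), C (distance):
# |D-C| = r, angle D-C-B = theta, torsion D-C-B-A = phi (degrees).
place_atom <- function(a, b, c, r, theta, phi) {
  # torsion sign matches dihedral_angle(d, c, b, a)
  th <- theta * pi / 180; ph <- -phi * pi / 180
  bc <- vnorm(c - b)
  n <- vnorm(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_loc <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d_loc[1] * bc + d_loc[2] * m + d_loc[3] * n
}

# Rebuild Cartesians from an internal-coordinate list with components
# r (length 25, atoms 2..26), ang (24, atoms 3..26), tor (23, atoms 4..26).
zmatrix_rebuild <- function(internals, zm = terpinene_zmatrix()) {
  n <- length(zm$element)
  xyz <- matrix(0, n, 3)
  # atoms 1-3 span the initial frame: atom 2 on +x, atom 3 in the xy-plane
  # (atom 3 references atoms 2 and 1 in the canonical table)
  xyz[2, 1] <- internals$r[1]
  th <- internals$ang[1] * pi / 180
  xyz[3, ] <- xyz[2, ] + internals$r[2] * c(-cos(th), sin(th), 0)
  for (i in 4:n) {
    xyz[i, ] <- place_atom(xyz[zm$ref_t[i], ], xyz[zm$ref_a[i], ],
                           xyz[zm$ref_d[i], ],
                           internals$r[i - 1], internals$ang[i - 2],
                           internals$tor[i - 3])
  }
  molecular_geometry(zm$element, xyz, terpinene_carbon_map())
}

angle_deg <- function(p1, p2, p3) {
  v1 <- vnorm(p1 - p2); v2 <- vnorm(p3 - p2)
  acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
}

# Measure the Z-matrix internal coordinates of a geometry whose atoms are
# in the canonical terpinene order.
zmatrix_internals <- function(geom, zm = terpinene_zmatrix()) {
  xyz <- geom$coords
  n <- length(zm$element)
  r <- numeric(n - 1); ang <- numeric(n - 2); tor <- numeric(n - 3)
  for (i in 2:n)
    r[i - 1] <- sqrt(sum((xyz[i, ] - xyz[zm$ref_d[i], ])^2))
  for (i in 3:n)
    ang[i - 2] <- angle_deg(xyz[i, ], xyz[zm$ref_d[i], ], xyz[zm$ref_a[i], ])
  for (i in 4:n)
    tor[i - 3] <- dihedral_angle(xyz[i, ], xyz[zm$ref_d[i], ],
                                 xyz[zm$ref_a[i], ], xyz[zm$ref_t[i], ])
  list(r = r, ang = ang, tor = tor)
}

# Shortest-path interpolation between two internal-coordinate sets:
# lengths and angles linearly, torsions along the shorter arc.
interp_internals <- function(z0, z1, lambda) {
  dtor <- ((z1$tor - z0$tor + 180) %% 360) - 180
  list(r = z0$r + lambda * (z1$r - z0$r),
       ang = z0$ang + lambda * (z1$ang - z0$ang),
       tor = z0$tor + lambda * dtor)
}

# Signed internal-coordinate difference (torsions wrapped) and its
# application as a persistent offset.
diff_internals <- function(z, z_ref) {
  list(r = z$r - z_ref$r, ang = z$ang - z_ref$ang,
       tor = ((z$tor - z_ref$tor + 180) %% 360) - 180)
}

add_internals <- function(z, delta) {
  list(r = z$r + delta$r, ang = z$ang + delta$ang, tor = z$tor + delta$tor)
}
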