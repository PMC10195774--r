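# Molecular geometry representation and the alpha-terpinene carbon frame.
#
# Units are fixed package-wide: Angstrom (distances), degrees (angles),
# femtoseconds (time), eV (energies).

#' Construct a labelled molecular geometry
#'
#' A `molecular_geometry` bundles element symbols, Cartesian coordinates in
#' Angstrom, and a map from the fixed carbon labels `C1`..`C10` of
#' alpha-terpinene to rows of the coordinate matrix.  The carbon numbering
#' follows the standard frame for the cyclohexadiene chromophore: ring
#' carbons C1, C3, C4, C5, C9, C6 (with the sigma bond broken on
#' ring-opening being C3--C4), isopropyl carbons C2 (CH), C7, C8, and the
#' methyl reporter carbon C10 on C5.
#'
#' @param elements character vector of chemical symbols (`"C"` or `"H"`).
#' @param coords numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param carbon_map named integer vector mapping labels `C1`..`C10` to row
#'   indices of `coords`.  May name fewer carbons for toy systems.
#' @return an object of class `molecular_geometry`.
#' @export
molecular_geometry <- function(elements, coords, carbon_map = integer()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(elements))
    stop("coords must have one row per element")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  if (length(carbon_map)) {
    if (is.null(names(carbon_map)) || anyDuplicated(names(carbon_map)) ||
        anyDuplicated(carbon_map))
      stop("carbon_map must be a bijection label -> atom index")
    if (any(carbon_map < 1L | carbon_map > nrow(coords)))
      stop("carbon_map indices out of range")
    if (!all(elements[carbon_map] == "C"))
      stop("carbon_map must point at carbon atoms")
  }
  structure(list(elements = as.character(elements), coords = coords,
                 carbon_map = carbon_map),
            class = "molecular_geometry")
}

#' @export
print.molecular_geometry <- function(x, ...) {
  cat(sprintf("molecular_geometry: %d atoms (%d C, %d H), %d labelled carbons\n",
              length(x$elements), sum(x$elements == "C"),
              sum(x$elements == "H"), length(x$carbon_map)))
  invisible(x)
}

carbon_xyz <- function(geom, label) {
  i <- match(label, names(geom$carbon_map))
  if (is.na(i)) stop("unknown carbon label: ", label)
  geom$coords[geom$carbon_map[[i]], ]
}

#' Distance between two labelled carbons
#'
#' @param geom a [molecular_geometry()].
#' @param a,b carbon labels (`"C1"`..`"C10"`).
#' @return Euclidean distance in Angstrom.
#' @export
pair_distance <- function(geom, a, b) {
  d <- carbon_xyz(geom, a) - carbon_xyz(geom, b)
  sqrt(sum(d * d))
}

#' The fixed bond topology of closed-ring alpha-terpinene
#'
#' Ten carbon--carbon bonds: the six ring bonds (C1-C3, C1-C6, C6-C9,
#' C9-C5, C5-C4, C4-C3) plus the isopropyl (C1-C2, C2-C7, C2-C8) and
#' methyl (C5-C10) substituent bonds.  The topology is that of the closed
#' reactant and is deliberately kept fixed throughout the dynamics so that
#' reactant-frame coordination spheres remain meaningful after the
#' C3--C4 bond ruptures.
#'
#' @return an object of class `bond_topology`: a two-column character
#'   matrix of unordered bonded label pairs.
#' @export
terpinene_topology <- function() {
  bonds <- rbind(
    c("C1", "C3"), c("C1", "C6"), c("C6", "C9"),
    c("C9", "C5"), c("C5", "C4"), c("C4", "C3"),
    c("C1", "C2"), c("C2", "C7"), c("C2", "C8"), c("C5", "C10"))
  structure(bonds, class = "bond_topology")
}

topology_graph <- function(topology) {
  igraph::graph_from_edgelist(unclass(topology), directed = FALSE)
}

#' Carbon labels of a topology
#' @param topology a bond topology matrix.
#' @return sorted character vector of labels.
#' @export
topology_labels <- function(topology) {
  labs <- unique(as.vector(unclass(topology)))
  labs[order(as.integer(sub("^C", "", labs)))]
}

#' Coordination sphere of a carbon pair
#'
#' The coordination sphere of a pair is the shortest bond-path length
#' between the two carbons in the fixed reactant bond graph: sphere 1 =
#' bonded, sphere 2 = geminal (bonded to a common carbon), sphere 3 =
#' separated by three bonds (cis/trans conformers about the central bond).
#'
#' @param topology a [terpinene_topology()]-style bond topology.
#' @param a,b carbon labels.
#' @return nonnegative integer bond-path length (0 iff `a == b`).
#' @export
coordination_sphere <- function(topology, a, b) {
  g <- topology_graph(topology)
  if (!all(c(a, b) %in% igraph::V(g)$name))
    stop("label not in topology: ", paste(setdiff(c(a, b), igraph::V(g)$name),
                                          collapse = ", "))
  d <- igraph::distances(g, v = a, to = b)[1, 1]
  if (!is.finite(d)) stop("labels are disconnected in the bond topology")
  as.integer(d)
}

#' Dihedral angle of four points
#'
#' Signed torsion p1-p2-p3-p4 in degrees, in (-180, 180].
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  ang * 180 / pi
}

#' Cis/trans conformation of a third-sphere carbon pair
#'
#' Third-sphere pairs a-x-y-b sit either cis (|dihedral| < 90 degrees) or
#' trans about their central bond x-y; in the rigid closed ring this makes
#' the third-sphere distance distribution bimodal (~3 vs ~4 Angstrom).
#' The central bond is taken from a shortest bond path in the fixed
#' reactant topology.
#'
#' @param geom a labelled [molecular_geometry()].
#' @param topology the fixed bond topology.
#' @param a,b carbon labels with `coordination_sphere(topology, a, b) == 3`.
#' @return `"cis"` or `"trans"`.
#' @export
cis_trans_label <- function(geom, topology, a, b) {
  g <- topology_graph(topology)
  if (coordination_sphere(topology, a, b) != 3L)
    stop("cis/trans labels are defined for third-sphere pairs only")
  path <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1]]
  path <- igraph::V(g)$name[path]
  dih <- dihedral_angle(carbon_xyz(geom, path[1]), carbon_xyz(geom, path[2]),
                        carbon_xyz(geom, path[3]), carbon_xyz(geom, path[4]))
  if (abs(dih) < 90) "cis" else "trans"
}

# --- small vector helpers -------------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("degenerate (zero-length) vector")
  v / n
}

plane_normal <- function(p1, p2, p3) vnorm(vcross(p2 - p1, p3 - p1))

# Least-squares plane through >= 3 points: returns centroid + unit normal
# (smallest principal component of the centered coordinates).
lsq_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-9) stop("plane-defining atoms are (near-)collinear")
  list(center = ctr, normal = sv$v[, 3])
}

# Signed angle between two planes.  Normals are canonicalized to a
# common hemisphere (dot >= 0) so the magnitude -- the full angle between
# the plane normals -- lies in [0, 90] degrees; the sign is the sense of
# the rotation carrying the reference normal into the moving one,
# referred to `axis`.
signed_plane_angle <- function(n_ref, n_mov, axis) {
  n_ref <- vnorm(n_ref); n_mov <- vnorm(n_mov); axis <- vnorm(axis)
  if (sum(n_ref * n_mov) < 0) n_mov <- -n_mov
  cr <- vcross(n_ref, n_mov)
  mag <- atan2(sqrt(sum(cr * cr)), sum(n_ref * n_mov)) * 180 / pi
  if (sum(cr * axis) < 0) -mag else mag
}

# Consistently oriented normal of the ordered ring C1-C3-C4-C5-C9-C6,
# used to fix the hemisphere of reference-plane normals.
ring_orientation_normal <- function(geom) {
  ring <- c("C1", "C3", "C4", "C5", "C9", "C6")
  pts <- t(vapply(ring, function(l) carbon_xyz(geom, l), numeric(3)))
  ctr <- colMeans(pts)
  n <- c(0, 0, 0)
  for (i in seq_along(ring)) {
    j <- if (i == length(ring)) 1L else i + 1L
    n <- n + vcross(pts[i, ] - ctr, pts[j, ] - ctr)
  }
  vnorm(n)
}

# The two CH2 hydrogens on a labelled carbon: the (exactly two expected)
# hydrogens within `tol` Angstrom; ambiguous assignments are an error.
ch2_hydrogens <- function(geom, label, tol = 1.3) {
  ctr <- carbon_xyz(geom, label)
  hyd <- which(geom$elements == "H")
  d <- sqrt(rowSums(sweep(geom$coords[hyd, , drop = FALSE], 2, ctr)^2))
  sel <- hyd[d <= tol]
  if (length(sel) < 2)
    stop("fewer than two hydrogens within ", tol, " Angstrom of ", label)
  if (length(sel) > 2)
    stop("ambiguous CH2 hydrogen assignment at ", label)
  geom$coords[sel, , drop = FALSE]
}

#' Conrotatory planarization coordinate phi
#'
#' Rehybridization of the C3 and C4 CH2 groups from sp3 to sp2 planarizes
#' them with respect to the terminal double bonds of the triene
#' photoproduct.  `phi_c3` is the signed angle between the plane of the C3
#' CH2 group (C3 and its two hydrogens) and the plane through C1, C2, C3;
#' `phi_c4` the analogous angle between the C4 CH2 plane and the plane
#' through C4, C5, C10.  Signs follow the rotation sense about the side
#' axes C3->C1 and C4->C5 so that the conrotatory sum `phi_sum =
#' phi_c3 + phi_c4` adds for conrotatory and cancels for disrotatory
#' motion.  All angles are in degrees and invariant under rigid motions.
#'
#' @param geom a labelled [molecular_geometry()] with resolvable CH2
#'   hydrogens on C3 and C4 (the two H within 1.3 Angstrom).
#' @return list with `phi_c3`, `phi_c4`, `phi_sum` (degrees).
#' @export
conrotatory_phi <- function(geom) {
  n0 <- ring_orientation_normal(geom)
  orient <- function(n) if (sum(n * n0) < 0) -n else n

  h3 <- ch2_hydrogens(geom, "C3")
  h4 <- ch2_hydrogens(geom, "C4")
  n_ref3 <- orient(plane_normal(carbon_xyz(geom, "C1"), carbon_xyz(geom, "C2"),
                                carbon_xyz(geom, "C3")))
  n_mov3 <- plane_normal(carbon_xyz(geom, "C3"), h3[1, ], h3[2, ])
  phi_c3 <- signed_plane_angle(n_ref3, n_mov3,
                               carbon_xyz(geom, "C1") - carbon_xyz(geom, "C3"))
  n_ref4 <- orient(plane_normal(carbon_xyz(geom, "C4"), carbon_xyz(geom, "C5"),
                                carbon_xyz(geom, "C10")))
  n_mov4 <- plane_normal(carbon_xyz(geom, "C4"), h4[1, ], h4[2, ])
  phi_c4 <- signed_plane_angle(n_ref4, n_mov4,
                               carbon_xyz(geom, "C5") - carbon_xyz(geom, "C4"))
  list(phi_c3 = phi_c3, phi_c4 = phi_c4, phi_sum = phi_c3 + phi_c4)
}

#' Conrotatory deplanarization coordinate psi
#'
#' Deplanarization of the substituent-bearing planes with respect to the
#' conjugated diene of the reactant.  The reference plane is the
#' least-squares plane through C1, C6, C9, C5; `psi_c1side` is the signed
#' angle of the C1,C2,C3 plane against it, `psi_c5side` that of the
#' C4,C5,C10 plane, with rotation senses about the axes C3->C1 and C4->C5.
#' `psi_sum` is the conrotatory (signed) sum.  Degrees; rigid-motion
#' invariant.
#'
#' @param geom a labelled [molecular_geometry()].
#' @return list with `psi_c1side`, `psi_c5side`, `psi_sum` (degrees).
#' @export
conrotatory_psi <- function(geom) {
  n0 <- ring_orientation_normal(geom)
  orient <- function(n) if (sum(n * n0) < 0) -n else n
  pts <- t(vapply(c("C1", "C6", "C9", "C5"),
                  function(l) carbon_xyz(geom, l), numeric(3)))
  n_ref <- orient(lsq_plane(pts)$normal)
  n1 <- plane_normal(carbon_xyz(geom, "C1"), carbon_xyz(geom, "C2"),
                     carbon_xyz(geom, "C3"))
  n2 <- plane_normal(carbon_xyz(geom, "C4"), carbon_xyz(geom, "C5"),
                     carbon_xyz(geom, "C10"))
  psi1 <- signed_plane_angle(n_ref, n1,
                             carbon_xyz(geom, "C1") - carbon_xyz(geom, "C3"))
  psi2 <- signed_plane_angle(n_ref, n2,
                             carbon_xyz(geom, "C5") - carbon_xyz(geom, "C4"))
  list(psi_c1side = psi1, psi_c5side = psi2, psi_sum = psi1 + psi2)
}
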