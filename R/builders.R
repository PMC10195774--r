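# Built fixture geometries: closed reactant, pericyclic minimum,
# ring-open MECI, and the four open-chain triene photoproduct isomers.
#
# Geometries are constructed from standard bond lengths (C=C 1.34,
# conjugated C-C 1.45-1.47, sp3 C-C 1.53, C-H 1.09 Angstrom) and sp2/sp3
# angles on the fixed Z-matrix.  Ring torsions are structural constants
# solved once so the emergent C3--C4 closure distance hits its target
# (reactant half-chair 1.54, pericyclic 1.60, ring-open MECI 2.2).
# These are idealized stand-ins for the quantum-chemical stationary
# points; the shipped inst/extdata copies are marked "_synthetic".

# half-chair ring torsions (C9-C6-C1-C3, C5-C9-C6-C1, C4-C5-C9-C6):
.RING_TORS_REACTANT <- c(-19.154, 13.255, 18.869)   # closes at 1.537
.RING_TORS_PERI <- c(-22.539, 14.001, 22.541)       # closes at 1.600
.RING_TORS_MECI <- c(-36.132, 27.000, 36.133)       # closes at 2.200
.OOP_METHYL_PERI <- 26.85   # methyl out-of-plane torsion, deg: C3-C10 = 3.55

rotamer_theta <- function(rotamer) {
  if (!rotamer %in% 1:3) stop("rotamer must be 1, 2 or 3")
  c(180, 60, 300)[rotamer]
}

internals_from_values <- function(vals, zm = terpinene_zmatrix()) {
  n <- length(zm$element)
  r <- numeric(n - 1); ang <- numeric(n - 2); tor <- numeric(n - 3)
  for (nm in names(vals)) {
    i <- zm$index[[nm]]; v <- vals[[nm]]
    r[i - 1] <- v[1]
    if (i >= 3) ang[i - 2] <- v[2]
    if (i >= 4) tor[i - 3] <- v[3]
  }
  list(r = r, ang = ang, tor = tor)
}

# Closed-ring family (reactant / pericyclic / MECI) builder.  Substituent
# and CH2 torsions depend on the placed ring carbons, so the skeleton is
# rebuilt once to measure them.
build_closed_ring <- function(tors, r16, r13, r69, r95, r54, a3, a4,
                              theta_r, oop_methyl, oop_ipr) {
  zm <- terpinene_zmatrix()
  vals <- list(
    C1 = c(r16, NA, NA), C3 = c(r13, a3, NA), C9 = c(r69, 120, tors[1]),
    C5 = c(r95, 120, tors[2]), C4 = c(r54, a4, tors[3]),
    C2 = c(1.51, 122, 0), C10 = c(1.50, 117.5, 0),
    C7 = c(1.53, 112, theta_r + 120), C8 = c(1.53, 112, theta_r + 240),
    H6 = c(1.09, 120, 180), H9 = c(1.09, 120, 180),
    H3a = c(1.09, 109.5, 0), H3b = c(1.09, 109.5, 0),
    H4a = c(1.09, 109.5, 0), H4b = c(1.09, 109.5, 0),
    H2 = c(1.09, 107, theta_r),
    H7a = c(1.09, 110.5, 60), H7b = c(1.09, 110.5, 180), H7c = c(1.09, 110.5, 300),
    H8a = c(1.09, 110.5, 60), H8b = c(1.09, 110.5, 180), H8c = c(1.09, 110.5, 300),
    H10a = c(1.09, 110.5, 60), H10b = c(1.09, 110.5, 180), H10c = c(1.09, 110.5, 300))
  g0 <- zmatrix_rebuild(internals_from_values(vals, zm), zm)
  x <- g0$coords; ix <- zm$index
  tor_c3 <- dihedral_angle(x[ix[["C3"]], ], x[ix[["C1"]], ],
                           x[ix[["C6"]], ], x[ix[["C9"]], ])
  vals$C2[3] <- tor_c3 + 180 + oop_ipr       # anti to C3 in the sp2 plane
  vals$C10[3] <- tors[3] + 180 + oop_methyl  # anti to C4, plus OOP bend
  g1 <- zmatrix_rebuild(internals_from_values(vals, zm), zm)
  x <- g1$coords
  tau3 <- dihedral_angle(x[ix[["C4"]], ], x[ix[["C3"]], ],
                         x[ix[["C1"]], ], x[ix[["C6"]], ])
  tau4 <- dihedral_angle(x[ix[["C3"]], ], x[ix[["C4"]], ],
                         x[ix[["C5"]], ], x[ix[["C9"]], ])
  vals$H3a[3] <- tau3 + 120; vals$H3b[3] <- tau3 - 120
  vals$H4a[3] <- tau4 + 120; vals$H4b[3] <- tau4 - 120
  zmatrix_rebuild(internals_from_values(vals, zm), zm)
}

#' Build the closed-ring alpha-terpinene reactant
#'
#' Idealized half-chair 1,3-cyclohexadiene core with isopropyl (on C1 via
#' C2) and methyl (C10 on C5) substituents, 10 carbons + 16 hydrogens.
#' The three rotamers differ by the isopropyl torsion about C1--C2 (which
#' of the three staggered slots the C2 hydrogen occupies).
#'
#' @param rotamer integer 1, 2 or 3.
#' @return a labelled [molecular_geometry()].
#' @export
build_terpinene <- function(rotamer = 1) {
  build_closed_ring(.RING_TORS_REACTANT, r16 = 1.338, r13 = 1.50,
                    r69 = 1.47, r95 = 1.338, r54 = 1.50, a3 = 120, a4 = 120,
                    theta_r = rotamer_theta(rotamer),
                    oop_methyl = 0, oop_ipr = 0)
}

#' Build the pericyclic-minimum anchor geometry
#'
#' The S1 pericyclic minimum: the C3--C4 sigma bond elongated to 1.6
#' Angstrom, partial pi-bond alternation, and out-of-plane bending of the
#' methyl (and, weaker, isopropyl) substituent.  The default methyl
#' out-of-plane torsion reproduces a C3--C10 reporter distance of 3.55
#' Angstrom.
#'
#' @param rotamer integer 1, 2 or 3.
#' @param oop_methyl methyl out-of-plane torsion in degrees; the isopropyl
#'   side follows conrotatorily at 0.4 x this value.
#' @return a labelled [molecular_geometry()].
#' @export
build_pericyclic <- function(rotamer = 1, oop_methyl = .OOP_METHYL_PERI) {
  build_closed_ring(.RING_TORS_PERI, r16 = 1.345, r13 = 1.495,
                    r69 = 1.462, r95 = 1.345, r54 = 1.495, a3 = 120, a4 = 120,
                    theta_r = rotamer_theta(rotamer),
                    oop_methyl = oop_methyl, oop_ipr = 0.4 * oop_methyl)
}

#' Build the ring-open minimum-energy conical intersection anchor
#'
#' The ring-open S0/S1 MECI: the C3--C4 distance elongated to ~2.2
#' Angstrom with the substituent out-of-plane bending retained.
#'
#' @inheritParams build_pericyclic
#' @return a labelled [molecular_geometry()].
#' @export
build_meci <- function(rotamer = 1, oop_methyl = .OOP_METHYL_PERI) {
  build_closed_ring(.RING_TORS_MECI, r16 = 1.40, r13 = 1.42,
                    r69 = 1.41, r95 = 1.40, r54 = 1.42, a3 = 122, a4 = 122,
                    theta_r = rotamer_theta(rotamer),
                    oop_methyl = oop_methyl, oop_ipr = 0.4 * oop_methyl)
}

# single-bond torsions (C9-C6-C1-C3, C4-C5-C9-C6) per terminal-dihedral
# isomer, chosen by a nonbonded-clearance scan: skewed-cis ~40-55 deg and
# twisted-trans ~120 deg relieve the bay strain of the Z-triene.  The
# t-isomers additionally rotate the isopropyl by one staggered slot to
# avoid methyl contacts across the bay.
.OPEN_TORS <- list(cZc = c(40, 55), cZt = c(40, -120),
                   tZc = c(120, -40), tZt = c(120, 120))
.OPEN_THETA_OFF <- c(cZc = 0, cZt = 0, tZc = -120, tZt = -120)

#' Build an open-chain triene photoproduct anchor
#'
#' Ring-opened product C3H2=C1(iPr)-C6H=C9H-C5(CH3)=C4H2 with the central
#' double bond Z and the two single-bond conformations set by the isomer
#' label (cZc, cZt, tZc, tZt).  All isomers have C3--C4 > 2.5 Angstrom.
#'
#' @param isomer one of `"cZc"`, `"cZt"`, `"tZc"`, `"tZt"`.
#' @param rotamer integer 1, 2 or 3 (isopropyl rotamer).
#' @return a labelled [molecular_geometry()].
#' @export
build_open_product <- function(isomer = "cZc", rotamer = 1) {
  s <- .OPEN_TORS[[isomer]]
  if (is.null(s)) stop("unknown product isomer: ", isomer)
  theta_r <- rotamer_theta(rotamer) + .OPEN_THETA_OFF[[isomer]]
  zm <- terpinene_zmatrix()
  vals <- list(
    C1 = c(1.45, NA, NA), C3 = c(1.34, 124, NA), C9 = c(1.34, 124, s[1]),
    C5 = c(1.45, 124, 0), C4 = c(1.34, 124, s[2]),
    C2 = c(1.50, 118, s[1] + 180), C10 = c(1.50, 118, s[2] + 180),
    C7 = c(1.53, 112, theta_r + 120), C8 = c(1.53, 112, theta_r + 240),
    H6 = c(1.09, 118, 180), H9 = c(1.09, 118, 180),
    H3a = c(1.09, 121, 0), H3b = c(1.09, 121, 180),
    H4a = c(1.09, 121, 0), H4b = c(1.09, 121, 180),
    H2 = c(1.09, 107, theta_r),
    H7a = c(1.09, 110.5, 60), H7b = c(1.09, 110.5, 180), H7c = c(1.09, 110.5, 300),
    H8a = c(1.09, 110.5, 60), H8b = c(1.09, 110.5, 180), H8c = c(1.09, 110.5, 300),
    H10a = c(1.09, 110.5, 60), H10b = c(1.09, 110.5, 180), H10c = c(1.09, 110.5, 300))
  zmatrix_rebuild(internals_from_values(vals, zm), zm)
}

#' Anchor geometries for the surrogate generator
#'
#' @param rotamer integer 1, 2 or 3.
#' @param oop_methyl pericyclic methyl out-of-plane torsion, degrees.
#' @return list with `reactant`, `pericyclic`, `meci`, and `open_products`
#'   (a named list over the four terminal-dihedral isomers).
#' @export
anchor_set <- function(rotamer = 1, oop_methyl = .OOP_METHYL_PERI) {
  list(reactant = build_terpinene(rotamer),
       pericyclic = build_pericyclic(rotamer, oop_methyl),
       meci = build_meci(rotamer, oop_methyl),
       open_products = stats::setNames(
         lapply(names(.OPEN_TORS), build_open_product, rotamer = rotamer),
         names(.OPEN_TORS)))
}
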