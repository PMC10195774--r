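# Geometry core: distances, coordination spheres, cis/trans labels and
# the conrotatory angle coordinates.

test_that("pair_distance matches the componentwise formula and is symmetric", {
  set.seed(11)
  for (rep in 1:20) {
    xyz <- matrix(stats::rnorm(30, sd = 2), 10)
    g <- toy_geometry(xyz, carbon_map = stats::setNames(1:10, paste0("C", 1:10)))
    pr <- all_carbon_pairs()[sample.int(45, 5), , drop = FALSE]
    for (k in seq_len(nrow(pr))) {
      i <- as.integer(sub("C", "", pr[k, 1])); j <- as.integer(sub("C", "", pr[k, 2]))
      expected <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      expect_equal(pair_distance(g, pr[k, 1], pr[k, 2]), expected, tolerance = 1e-12)
      expect_identical(pair_distance(g, pr[k, 1], pr[k, 2]),
                       pair_distance(g, pr[k, 2], pr[k, 1]))
    }
  }
  g <- build_terpinene()
  expect_identical(pair_distance(g, "C3", "C3"), 0)
  expect_error(pair_distance(g, "C3", "C11"), "unknown carbon label")
})

test_that("coordination_sphere equals a brute-force BFS oracle on all 45 pairs", {
  topo <- terpinene_topology()
  edges <- unclass(topo)
  pr <- all_carbon_pairs()
  for (k in seq_len(nrow(pr))) {
    expect_identical(coordination_sphere(topo, pr[k, 1], pr[k, 2]),
                     bfs_sphere(edges, pr[k, 1], pr[k, 2]))
  }
  # named examples: geminal, vicinal-plus-one, bonded, identity
  expect_identical(coordination_sphere(topo, "C3", "C5"), 2L)
  expect_identical(coordination_sphere(topo, "C3", "C10"), 3L)
  for (k in seq_len(nrow(edges)))
    expect_identical(coordination_sphere(topo, edges[k, 1], edges[k, 2]), 1L)
  expect_identical(coordination_sphere(topo, "C7", "C7"), 0L)
  expect_error(coordination_sphere(topo, "C3", "C99"), "not in topology")
})

test_that("coordination_sphere satisfies the triangle inequality", {
  topo <- terpinene_topology()
  labs <- topology_labels(topo)
  set.seed(4)
  for (rep in 1:50) {
    abc <- sample(labs, 3)
    expect_lte(coordination_sphere(topo, abc[1], abc[3]),
               coordination_sphere(topo, abc[1], abc[2]) +
                 coordination_sphere(topo, abc[2], abc[3]))
  }
})

test_that("reactant topology has 10 bonds, correct degrees, 10 sphere-1 pairs", {
  topo <- terpinene_topology()
  expect_identical(nrow(unclass(topo)), 10L)
  degs <- table(as.vector(unclass(topo)))
  expect_identical(unname(degs[["C2"]]), 3L)
  expect_identical(unname(degs[["C10"]]), 1L)
  tab <- sphere_table(topo)
  expect_identical(sum(tab$sphere == 1L), 10L)
  expect_identical(nrow(tab), 45L)   # exhaustive partition of all pairs
})

test_that("cis/trans labels: reactant examples, planar chain, mirror parity", {
  g <- build_terpinene()
  topo <- terpinene_topology()
  expect_identical(cis_trans_label(g, topo, "C3", "C9"), "cis")
  expect_identical(cis_trans_label(g, topo, "C3", "C10"), "trans")
  expect_error(cis_trans_label(g, topo, "C3", "C5"), "third-sphere")

  # every third-sphere pair receives a label
  tab <- sphere_table(topo, g)
  third <- tab[tab$sphere == 3L, ]
  expect_true(all(third$sublabel %in% c("cis", "trans")))

  # constructed planar 4-carbon chain with a 0-degree dihedral is cis
  chain <- toy_geometry(rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0),
                              c(1.5, 2.3, 0)),
                        carbon_map = c(C3 = 1L, C4 = 2L, C5 = 3L, C10 = 4L))
  mini_topo <- structure(rbind(c("C3", "C4"), c("C4", "C5"), c("C5", "C10")),
                         class = "bond_topology")
  expect_identical(cis_trans_label(chain, mini_topo, "C3", "C10"), "cis")

  # dihedral magnitude is parity-even: labels survive mirror reflection
  gm <- molecular_geometry(g$elements, g$coords %*% diag(c(1, 1, -1)),
                           g$carbon_map)
  for (k in seq_len(nrow(third)))
    expect_identical(cis_trans_label(gm, topo, third$a[k], third$b[k]),
                     third$sublabel[k])
})

test_that("phi and psi are invariant under rigid motions to 1e-6 degree", {
  g <- build_pericyclic()
  phi0 <- conrotatory_phi(g); psi0 <- conrotatory_psi(g)
  set.seed(7)
  for (rep in 1:100) {
    gr <- apply_rigid(g)
    expect_equal(conrotatory_phi(gr)$phi_sum, phi0$phi_sum, tolerance = 1e-6)
    expect_equal(conrotatory_psi(gr)$psi_sum, psi0$psi_sum, tolerance = 1e-6)
  }
  # distances too
  d0 <- pair_distance(g, "C3", "C10")
  for (rep in 1:10)
    expect_equal(pair_distance(apply_rigid(g), "C3", "C10"), d0,
                 tolerance = 1e-9)
})

test_that("psi_c5side tracks a constructed rotation of C10 about the C9-C5 axis", {
  g <- build_terpinene()
  ix <- g$carbon_map
  hyd <- which(g$elements == "H")
  h10 <- hyd[sqrt(rowSums(sweep(g$coords[hyd, ], 2,
                                g$coords[ix[["C10"]], ])^2)) < 1.3]
  got <- numeric(0)
  for (ang in c(5, 12, 25)) {
    gr <- rotate_about_axis(g, c(ix[["C10"]], h10),
                            g$coords[ix[["C9"]], ], g$coords[ix[["C5"]], ],
                            ang)
    # oracle: explicit normal-vector computation on the rotated geometry
    n_ref <- {
      pts <- gr$coords[c(ix[["C1"]], ix[["C6"]], ix[["C9"]], ix[["C5"]]), ]
      ctr <- colMeans(pts); sv <- svd(sweep(pts, 2, ctr)); sv$v[, 3]
    }
    n_mov <- {
      p <- gr$coords[c(ix[["C4"]], ix[["C5"]], ix[["C10"]]), ]
      v <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
      v / sqrt(sum(v^2))
    }
    expected_mag <- acos(min(1, abs(sum(n_ref * n_mov) /
                                      sqrt(sum(n_ref^2))))) * 180 / pi
    got <- c(got, conrotatory_psi(gr)$psi_c5side)
    expect_equal(abs(got[length(got)]), expected_mag, tolerance = 1e-6)
  }
  # larger constructed rotations move the coordinate monotonically
  expect_true(all(diff(got) > 0) || all(diff(got) < 0))
})

test_that("phi is zero for coincident planes and recovers constructed rotations", {
  # plant the CH2 hydrogens inside the reference planes: both phi
  # components vanish
  gp <- planarize_ch2(build_terpinene(), "C3", c("C1", "C2"))
  gp <- planarize_ch2(gp, "C4", c("C5", "C10"))
  phi <- conrotatory_phi(gp)
  expect_equal(phi$phi_c3, 0, tolerance = 1e-8)
  expect_equal(phi$phi_c4, 0, tolerance = 1e-8)
  expect_equal(phi$phi_sum, 0, tolerance = 1e-8)

  # rotating the CH2 about the side axis from the coincident configuration
  # is recovered linearly (fixed orientation sign s)
  ix <- gp$carbon_map
  hyd <- which(gp$elements == "H")
  h3 <- hyd[sqrt(rowSums(sweep(gp$coords[hyd, ], 2,
                               gp$coords[ix[["C3"]], ])^2)) < 1.3]
  g8 <- rotate_about_axis(gp, h3, gp$coords[ix[["C3"]], ],
                          gp$coords[ix[["C1"]], ], 8)
  s <- sign(conrotatory_phi(g8)$phi_c3)
  for (ang in c(-25, -8, 8, 25)) {
    gr <- rotate_about_axis(gp, h3, gp$coords[ix[["C3"]], ],
                            gp$coords[ix[["C1"]], ], ang)
    expect_equal(conrotatory_phi(gr)$phi_c3, s * ang, tolerance = 1e-6)
  }
})
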