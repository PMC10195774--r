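# Surrogate wavepacket generator and its auxiliary utilities.

test_that("thermal sampling: zero sigma copies, determinism, CLT mean", {
  g <- build_terpinene()
  copies <- sample_thermal(g, thermal_sigma = 0, n = 3, seed = 1)
  for (cp in copies) expect_identical(cp$coords, g$coords)

  a <- sample_thermal(g, n = 4, seed = 11)
  b <- sample_thermal(g, n = 4, seed = 11)
  for (k in 1:4) expect_identical(a[[k]]$coords, b[[k]]$coords)

  n <- 400
  ens <- sample_thermal(g, thermal_sigma = c(C = 0.03, H = 0.06), n = n,
                        seed = 3)
  avg <- Reduce(`+`, lapply(ens, `[[`, "coords")) / n
  tol <- 4 * 0.06 / sqrt(n)
  expect_lt(max(abs(avg - g$coords)), tol)
})

test_that("generated ensembles are seed-reproducible and conserve population", {
  p <- surrogate_params(n_traj = 12, seed = 21, t_max = 400, dt = 25)
  e1 <- generate_ensemble(p)
  e2 <- generate_ensemble(p)
  for (k in seq_along(e1$trajectories)) {
    expect_identical(e1$trajectories[[k]]$coords, e2$trajectories[[k]]$coords)
    expect_identical(e1$trajectories[[k]]$state, e2$trajectories[[k]]$state)
  }
  tot <- Reduce(`+`, lapply(e1$trajectories, `[[`, "weight"))
  expect_lt(max(abs(tot - 1)), 1e-9)
  expect_equal(population_trace(e1, "S0") + population_trace(e1, "S1"),
               rep(1, length(e1$time_grid)), tolerance = 1e-9)
})

test_that("p_open = 0 closes every trajectory; p_open = 1 opens every one", {
  e0 <- generate_ensemble(surrogate_params(n_traj = 15, p_open = 0,
                                           seed = 2, t_max = 900, dt = 50))
  expect_equal(branching_fraction(e0), 0)
  e1 <- generate_ensemble(surrogate_params(n_traj = 15, p_open = 1,
                                           seed = 2, t_max = 900, dt = 50))
  expect_equal(branching_fraction(e1), 1)
})

test_that("branching recovers p_open within binomial sampling error", {
  p <- surrogate_params(n_traj = 400, p_open = 0.30, seed = 6,
                        t_max = 1000, dt = 50)
  ens <- generate_ensemble(p)
  bf <- branching_fraction(ens)
  expect_lt(abs(bf - 0.30), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("sigma bond stays intact on S1 and breaks only on S0", {
  ens <- generate_ensemble(surrogate_params(n_traj = 40, seed = 9,
                                            t_max = 1000, dt = 25))
  s1 <- expectation(ens, coord_distance("C3", "C4"), "S1")
  expect_lt(max(s1, na.rm = TRUE), 1.9)
  s0 <- expectation(ens, coord_distance("C3", "C4"), "S0")
  expect_gt(s0[length(s0)], 2.2)
})

test_that("noiseless S1 morph keeps the C3-C4 distance within [1.45, 1.9]", {
  ens <- generate_ensemble(surrogate_params(n_traj = 4, thermal_sigma = 0,
                                            seed = 14, t_max = 1000, dt = 25))
  for (tr in ens$trajectories) {
    s1_frames <- which(tr$state == "S1")
    for (i in s1_frames) {
      g <- molecular_geometry(ens$elements, tr$coords[, , i],
                              ens$carbon_map)
      d <- pair_distance(g, "C3", "C4")
      expect_gte(d, 1.45); expect_lte(d, 1.9)
    }
  }
})

test_that("the C3-C10 reporter dips at the configured time", {
  for (dip in c(80, 120)) {
    ens <- generate_ensemble(surrogate_params(n_traj = 50, seed = 31,
                                              dip_time = dip,
                                              t_max = 350, dt = 5))
    tr <- expectation(ens, coord_distance("C3", "C10"), "S1")
    # restrict to delays with enough surviving S1 population for the
    # expectation to be statistically meaningful
    ok <- population_trace(ens, "S1") >= 0.15
    t_min <- ens$time_grid[ok][which.min(tr[ok])]
    expect_lt(abs(t_min - dip), 50)
    # the dip approaches the pericyclic anchor value
    expect_lt(abs(min(tr, na.rm = TRUE) - 3.55), 0.1)
  }
})

test_that("deplanarization rises on S1 toward the anchor amplitude", {
  ens <- generate_ensemble(surrogate_params(n_traj = 20, seed = 13,
                                            t_max = 300, dt = 25))
  psi <- expectation(ens, function(g) conrotatory_psi(g)$psi_sum, "S1")
  i_dip <- which.min(abs(ens$time_grid - 100))
  expect_gt(psi[i_dip] - psi[1], 20)
  # psi_max control: the anchor amplitude follows the requested target
  oop <- pericyclic_oop_for_psi(25)
  expect_equal(conrotatory_psi(build_pericyclic(oop_methyl = oop))$psi_sum,
               25, tolerance = 1e-6)
})

test_that("open and closed channels are anti-correlated with the product state", {
  ens <- generate_ensemble(surrogate_params(n_traj = 30, seed = 44,
                                            p_open = 0.5, t_max = 1000,
                                            dt = 50))
  i <- length(ens$time_grid)
  d34 <- vapply(seq_along(ens$trajectories), function(k)
    pair_distance(ensemble_frame(ens, k, i), "C3", "C4"), numeric(1))
  # bimodal split: nothing stuck between closed (~1.54) and open (> 2.5)
  expect_true(all(d34 < 2.0 | d34 > 2.5))
})

test_that("broadened spectrum: line positions, widths, integral", {
  sp <- broadened_spectrum(4.8, 1, fwhm = 0.2)
  expect_equal(sp$energy_ev[which.max(sp$intensity)], 4.8, tolerance = 0.002)
  half <- max(sp$intensity) / 2
  above <- range(sp$energy_ev[sp$intensity >= half])
  expect_equal(diff(above), 0.2, tolerance = 0.02)

  two <- broadened_spectrum(c(3, 5), c(1, 1), fwhm = 0.2)
  pk <- sort(two$energy_ev[order(two$intensity, decreasing = TRUE)[1:2]])
  expect_equal(two$intensity[two$energy_ev == pk[1]],
               two$intensity[two$energy_ev == pk[2]], tolerance = 1e-9)

  # quadrature vs closed form: integral equals the strength sum
  sp2 <- broadened_spectrum(c(4.2, 4.9), c(0.7, 1.3), fwhm = 0.2)
  expect_equal(sum(sp2$intensity) * 0.001, 2.0, tolerance = 1e-6)
  expect_error(broadened_spectrum(c(1, 2), 1), "equal length")
})

test_that("initial-condition selection window arithmetic", {
  expect_identical(select_initial_conditions(5.05), 1L)
  expect_identical(length(select_initial_conditions(5.36)), 0L)
  expect_identical(select_initial_conditions(numeric(0)), integer(0))
  e <- c(4.6, 5.05, 5.34, 5.36, 5.8)
  expect_identical(select_initial_conditions(e), c(2L, 3L))
  expect_error(select_initial_conditions(5, window = 0), "positive")
})
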