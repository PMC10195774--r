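# Phenomenological surrogate generator emulating the statistical
# structure of nonadiabatic wavepacket simulations of the ring-opening:
# thermal starts, S1 relaxation with early methyl out-of-plane bending,
# stochastic internal conversion, and branching into open/closed
# channels.  No forces or energies are involved -- the generator morphs
# between anchor geometries in internal coordinates (Cartesian
# interpolation would collapse the CH2/CH3 groups while the ring
# torsions swing).

#' Surrogate generator parameters
#'
#' @param n_traj number of trajectories.
#' @param p_open ring-opening branching fraction (default 0.58).
#' @param hop_latency fs before which no internal conversion occurs.
#' @param hop_tau exponential timescale of hop times past the latency, fs.
#' @param psi_max deplanarization amplitude of the pericyclic anchor in
#'   degrees of methyl out-of-plane torsion; `NULL` uses the default
#'   anchor (calibrated so the C3--C10 reporter reaches 3.55 Angstrom).
#' @param dip_time fs at which the S1 morph (and hence the C3--C10
#'   minimum) peaks; default 100.
#' @param open_ramp post-hop morph timescale toward the product anchor, fs.
#' @param thermal_sigma named Cartesian thermal displacement sigmas per
#'   element, Angstrom.
#' @param seed integer seed.
#' @param rotamer isopropyl rotamer 1, 2 or 3.
#' @param t_max,dt native time span and step of the generated grid, fs.
#' @return list of class `surrogate_params`.
#' @export
surrogate_params <- function(n_traj = 400, p_open = 0.58, hop_latency = 60,
                             hop_tau = 120, psi_max = NULL, dip_time = 100,
                             open_ramp = 100,
                             thermal_sigma = c(C = 0.03, H = 0.06),
                             seed = 1, rotamer = 1,
                             t_max = 1000, dt = 5) {
  stopifnot(n_traj >= 1, p_open >= 0, p_open <= 1, hop_latency > 0,
            hop_tau > 0, dip_time > 0, open_ramp > 0,
            all(thermal_sigma >= 0), dt > 0, t_max > dt)
  structure(list(n_traj = as.integer(n_traj), p_open = p_open,
                 hop_latency = hop_latency, hop_tau = hop_tau,
                 psi_max = psi_max, dip_time = dip_time,
                 open_ramp = open_ramp, thermal_sigma = thermal_sigma,
                 seed = as.integer(seed), rotamer = as.integer(rotamer),
                 t_max = t_max, dt = dt),
            class = "surrogate_params")
}

#' Thermal sampling of a geometry
#'
#' Independent Gaussian Cartesian displacements per atom (a cheap
#' stand-in for harmonic Wigner sampling): sigma 0.03 Angstrom for C and
#' 0.06 for H by default.
#'
#' @param geom a [molecular_geometry()].
#' @param thermal_sigma named per-element sigmas (Angstrom) or one number.
#' @param n number of samples.
#' @param seed integer seed.
#' @return list of `n` geometries.
#' @export
sample_thermal <- function(geom, thermal_sigma = c(C = 0.03, H = 0.06),
                           n = 1, seed = 1) {
  if (length(thermal_sigma) == 1 && is.null(names(thermal_sigma)))
    thermal_sigma <- stats::setNames(rep(thermal_sigma, 2), c("C", "H"))
  sig <- thermal_sigma[geom$elements]
  if (anyNA(sig)) stop("thermal_sigma missing for some element")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    noise <- matrix(stats::rnorm(3 * length(sig), sd = rep(sig, 3)),
                    ncol = 3)
    molecular_geometry(geom$elements, geom$coords + noise, geom$carbon_map)
  })
}

# S1 morph parameter: cosine ramp 0 -> 1 peaking exactly at dip_time,
# then a partial relaxation back toward 0.7.  The rebound keeps the
# reporter-distance minimum a clear feature at dip_time (vibrational
# coherence decaying after the first approach to the pericyclic region).
s1_lambda <- function(t, dip_time) {
  lam <- 0.5 * (1 - cos(pi * pmin(t / dip_time, 1)))
  late <- t > dip_time
  lam[late] <- 1 - 0.3 * (1 - exp(-(t[late] - dip_time) / 150))
  lam
}

#' Generate a surrogate wavepacket ensemble
#'
#' Each trajectory starts from a thermally displaced reactant, morphs in
#' internal coordinates toward the pericyclic anchor on S1 (methyl
#' out-of-plane bending raising the deplanarization coordinate and
#' dipping the C3--C10 reporter at `dip_time`), hops to S0 at
#' `hop_latency` + Exp(`hop_tau`), and then either morphs to a uniformly
#' chosen open-product anchor (probability `p_open`; the C3--C4 distance
#' grows past 2.2 Angstrom) or relaxes back to its reactant start.
#' Trajectories carry equal, constant weights.
#'
#' @param params a [surrogate_params()].
#' @param time_grid optional analysis grid, fs (default the native
#'   `seq(0, t_max, dt)` grid).
#' @return a [wavepacket_ensemble()].
#' @export
generate_ensemble <- function(params = surrogate_params(), time_grid = NULL) {
  zm <- terpinene_zmatrix()
  oop <- if (is.null(params$psi_max)) .OOP_METHYL_PERI
         else pericyclic_oop_for_psi(params$psi_max, params$rotamer)
  reac <- build_terpinene(params$rotamer)
  peri <- build_pericyclic(params$rotamer, oop)
  opens <- lapply(names(.OPEN_TORS), build_open_product,
                  rotamer = params$rotamer)
  z_peri <- zmatrix_internals(peri, zm)
  z_open <- lapply(opens, zmatrix_internals, zm = zm)
  if (is.null(time_grid)) time_grid <- seq(0, params$t_max, by = params$dt)
  nt <- length(time_grid)
  lam <- s1_lambda(time_grid, params$dip_time)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  n <- params$n_traj
  hop_times <- params$hop_latency + stats::rexp(n, rate = 1 / params$hop_tau)
  goes_open <- stats::runif(n) < params$p_open
  isomer_idx <- sample.int(length(z_open), n, replace = TRUE)
  starts <- sample_thermal(reac, params$thermal_sigma, n,
                           seed = params$seed + 1L)

  z_reac <- zmatrix_internals(reac, zm)
  natoms <- length(reac$elements)
  trajectories <- vector("list", n)
  for (k in seq_len(n)) {
    z0 <- zmatrix_internals(starts[[k]], zm)
    # the thermal displacement persists as an internal-coordinate offset
    # along the whole trajectory (the ensemble never collapses onto the
    # anchors)
    delta0 <- diff_internals(z0, z_reac)
    thop <- hop_times[k]
    lam_hop <- s1_lambda(thop, params$dip_time)
    z_hop <- add_internals(interp_internals(z_reac, z_peri, lam_hop), delta0)
    z_tgt <- if (goes_open[k])
      add_internals(z_open[[isomer_idx[k]]], delta0) else z0
    coords <- array(0, c(natoms, 3, nt))
    state <- character(nt)
    for (i in seq_len(nt)) {
      t <- time_grid[i]
      if (t < thop) {
        zi <- add_internals(interp_internals(z_reac, z_peri, lam[i]), delta0)
        state[i] <- "S1"
      } else {
        mu <- 1 - exp(-(t - thop) / params$open_ramp)
        zi <- interp_internals(z_hop, z_tgt, mu)
        state[i] <- "S0"
      }
      coords[, , i] <- zmatrix_rebuild(zi, zm)$coords
    }
    trajectories[[k]] <- weighted_trajectory(time_grid, coords, state,
                                             rep(1 / n, nt))
  }
  wavepacket_ensemble(trajectories, time_grid, reac$elements,
                      reac$carbon_map)
}

#' Methyl out-of-plane torsion achieving a target deplanarization sum
#'
#' Solves for the pericyclic-anchor methyl out-of-plane torsion whose
#' conrotatory deplanarization sum psi equals `psi_target` degrees.
#'
#' @param psi_target degrees.
#' @param rotamer isopropyl rotamer.
#' @return out-of-plane torsion in degrees.
#' @export
pericyclic_oop_for_psi <- function(psi_target, rotamer = 1) {
  f <- function(o) conrotatory_psi(build_pericyclic(rotamer, o))$psi_sum -
    psi_target
  stats::uniroot(f, c(-5, 70), extendInt = "yes")$root
}

#' Gaussian-broadened stick spectrum
#'
#' Sum of oscillator-strength-scaled Gaussians of fixed FWHM centered at
#' the transition energies (homogeneous broadening of a sampled UV
#' spectrum).
#'
#' @param energies transition energies, eV.
#' @param strengths oscillator strengths (same length).
#' @param fwhm Gaussian FWHM in eV (default 0.2).
#' @param grid evaluation grid, eV; defaults to the energy range plus
#'   3 FWHM at 1 meV resolution.
#' @return data.frame with `energy_ev` and `intensity`.
#' @export
broadened_spectrum <- function(energies, strengths, fwhm = 0.2, grid = NULL) {
  if (length(energies) != length(strengths))
    stop("energies and strengths must have equal length")
  if (fwhm <= 0) stop("fwhm must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (is.null(grid)) {
    if (!length(energies)) grid <- seq(0, 1, by = 0.001)
    else grid <- seq(min(energies) - 3 * fwhm, max(energies) + 3 * fwhm,
                     by = 0.001)
  }
  intensity <- numeric(length(grid))
  for (k in seq_along(energies))
    intensity <- intensity + strengths[k] * stats::dnorm(grid, energies[k],
                                                         sigma)
  data.frame(energy_ev = grid, intensity = intensity)
}

#' Select initial conditions within an excitation window
#'
#' Indices of transition energies whose red-shifted value lies within
#' `window` of the pump photon energy: |(E - red_shift) - pump| <=
#' window.  Defaults: pump 4.65 eV, window 0.3 eV, red-shift 0.4 eV.
#'
#' @param energies transition energies, eV.
#' @param pump pump photon energy, eV.
#' @param window acceptance half-window, eV.
#' @param red_shift spectrum alignment shift, eV.
#' @return integer index vector.
#' @export
select_initial_conditions <- function(energies, pump = 4.65, window = 0.3,
                                      red_shift = 0.4) {
  if (window <= 0) stop("window must be positive")
  which(abs((energies - red_shift) - pump) <= window)
}
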