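# Weighted, state-labelled trajectory ensembles on a common time grid --
# a discrete stand-in for a trajectory-basis-function wavepacket
# expansion: each trajectory carries a population-like weight time series
# and an electronic-state label per frame.

#' Construct a weighted trajectory
#'
#' @param times strictly increasing frame times, fs.
#' @param coords numeric array `[n_atoms, 3, n_times]`, Angstrom.
#' @param state character vector (`"S0"`/`"S1"`) per frame.
#' @param weight nonnegative weight per frame (population-like).
#' @return object of class `weighted_trajectory`.
#' @export
weighted_trajectory <- function(times, coords, state, weight) {
  nt <- length(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("frame times must be strictly increasing")
  if (dim(coords)[3] != nt || length(state) != nt || length(weight) != nt)
    stop("times, coords, state and weight must agree in length")
  if (any(weight < 0)) stop("weights must be nonnegative")
  if (!all(state %in% c("S0", "S1"))) stop("states must be S0 or S1")
  structure(list(times = times, coords = coords, state = state,
                 weight = weight),
            class = "weighted_trajectory")
}

#' Construct a wavepacket ensemble
#'
#' Trajectories must share the common time grid; total weight is required
#' to be 1 at every time (to 1e-9), i.e. population is conserved.
#'
#' @param trajectories list of [weighted_trajectory()].
#' @param time_grid common time grid, fs.
#' @param elements atom element symbols (shared by all trajectories).
#' @param carbon_map shared carbon label map.
#' @return object of class `wavepacket_ensemble`.
#' @export
wavepacket_ensemble <- function(trajectories, time_grid, elements, carbon_map) {
  if (!length(trajectories)) stop("empty ensemble")
  for (tr in trajectories)
    if (!isTRUE(all.equal(tr$times, time_grid)))
      stop("all trajectories must share the common time grid")
  tot <- Reduce(`+`, lapply(trajectories, `[[`, "weight"))
  if (max(abs(tot - 1)) > 1e-9)
    stop("total trajectory weight must be 1 at every time")
  structure(list(trajectories = trajectories, time_grid = time_grid,
                 elements = elements, carbon_map = carbon_map),
            class = "wavepacket_ensemble")
}

#' @export
print.wavepacket_ensemble <- function(x, ...) {
  cat(sprintf("wavepacket_ensemble: %d trajectories, %d times (%g..%g fs)\n",
              length(x$trajectories), length(x$time_grid),
              min(x$time_grid), max(x$time_grid)))
  invisible(x)
}

#' Extract one frame of a trajectory as a molecular geometry
#'
#' @param ens a [wavepacket_ensemble()].
#' @param trajectory trajectory index.
#' @param time_index frame index on the common grid.
#' @return a [molecular_geometry()].
#' @export
ensemble_frame <- function(ens, trajectory, time_index) {
  molecular_geometry(ens$elements,
                     ens$trajectories[[trajectory]]$coords[, , time_index],
                     ens$carbon_map)
}

time_index_of <- function(ens, t) {
  i <- which.min(abs(ens$time_grid - t))
  if (abs(ens$time_grid[i] - t) > 1e-6)
    stop("time ", t, " fs is not on the ensemble grid")
  i
}

#' Electronic-state population trace
#'
#' Sum of trajectory weights in the requested state at each grid time.
#' The S0 and S1 traces are complementary (sum to 1).
#'
#' @param ens a [wavepacket_ensemble()].
#' @param state `"S0"` or `"S1"`.
#' @return numeric vector over `ens$time_grid`.
#' @export
population_trace <- function(ens, state = "S0") {
  if (!state %in% c("S0", "S1")) stop("state must be S0 or S1")
  out <- numeric(length(ens$time_grid))
  for (tr in ens$trajectories)
    out <- out + tr$weight * (tr$state == state)
  out
}

#' State-filtered expectation value of a geometric coordinate
#'
#' Weight-normalized mean of `coord` over the frames in the requested
#' state.  Times with zero filtered weight are returned as `NA` (masked),
#' not as an error.
#'
#' @param ens a [wavepacket_ensemble()].
#' @param coord function `molecular_geometry -> numeric(1)`.
#' @param state `"S0"`, `"S1"`, or `NULL` for all frames.
#' @return numeric vector over `ens$time_grid` (NA where undefined).
#' @export
expectation <- function(ens, coord, state = NULL) {
  nt <- length(ens$time_grid)
  num <- numeric(nt); den <- numeric(nt)
  for (k in seq_along(ens$trajectories)) {
    tr <- ens$trajectories[[k]]
    sel <- if (is.null(state)) rep(TRUE, nt) else tr$state == state
    for (i in which(sel & tr$weight > 0)) {
      v <- coord(ensemble_frame(ens, k, i))
      num[i] <- num[i] + tr$weight[i] * v
      den[i] <- den[i] + tr$weight[i]
    }
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Coordinate helper: a labelled carbon-carbon distance
#'
#' @param a,b carbon labels.
#' @return function usable as `coord` in [expectation()].
#' @export
coord_distance <- function(a, b) {
  force(a); force(b)
  function(geom) pair_distance(geom, a, b)
}

#' Two-dimensional excited-state wavepacket density projection
#'
#' Gaussian-kernel density of the S1 frames at time `t` over two
#' geometric coordinates, with trajectory weights as masses: a discrete
#' surrogate for projecting frozen-Gaussian basis functions.  The grid
#' integral equals the S1 population at `t`.
#'
#' @param ens a [wavepacket_ensemble()].
#' @param coord_x,coord_y coordinate functions (see [coord_distance()]).
#' @param t time on the ensemble grid, fs.
#' @param kernel_widths Gaussian sigma per axis (default 0.05 Angstrom
#'   for distances, 2 degrees for angles).
#' @param x_grid,y_grid optional evaluation grids; defaults cover the
#'   sample range plus 5 sigma.
#' @param state electronic state to project (default `"S1"`).
#' @return list of class `density_2d`: `x`, `y`, `density` (|x| by |y|).
#' @export
density_projection_2d <- function(ens, coord_x, coord_y, t,
                                  kernel_widths = c(0.05, 2),
                                  x_grid = NULL, y_grid = NULL,
                                  state = "S1") {
  if (any(kernel_widths <= 0)) stop("kernel widths must be positive")
  i <- time_index_of(ens, t)
  xs <- numeric(0); ys <- numeric(0); ws <- numeric(0)
  for (k in seq_along(ens$trajectories)) {
    tr <- ens$trajectories[[k]]
    if (tr$state[i] == state && tr$weight[i] > 0) {
      g <- ensemble_frame(ens, k, i)
      xs <- c(xs, coord_x(g)); ys <- c(ys, coord_y(g))
      ws <- c(ws, tr$weight[i])
    }
  }
  sx <- kernel_widths[1]; sy <- kernel_widths[2]
  if (is.null(x_grid))
    x_grid <- if (length(xs)) seq(min(xs) - 5 * sx, max(xs) + 5 * sx,
                                  length.out = 101) else seq(0, 1, length.out = 11)
  if (is.null(y_grid))
    y_grid <- if (length(ys)) seq(min(ys) - 5 * sy, max(ys) + 5 * sy,
                                  length.out = 101) else seq(0, 1, length.out = 11)
  dens <- matrix(0, length(x_grid), length(y_grid))
  for (j in seq_along(xs)) {
    dens <- dens + ws[j] *
      (stats::dnorm(x_grid, xs[j], sx) %o% stats::dnorm(y_grid, ys[j], sy))
  }
  structure(list(x = x_grid, y = y_grid, density = dens,
                 samples = data.frame(x = xs, y = ys, w = ws)),
            class = "density_2d")
}

#' Ring-opening branching fraction
#'
#' Among the S0-weighted frames at `at_time`, the fraction of population
#' whose C3--C4 distance exceeds `open_threshold` (population-weighted by
#' default; `count_trajectories = TRUE` counts trajectories instead).
#' Classification is done at a single analysis time -- by default the
#' final grid time -- rather than by first threshold crossing, which
#' avoids transient recrossing ambiguity.
#'
#' @param ens a [wavepacket_ensemble()].
#' @param open_threshold Angstrom, default 2.0.
#' @param at_time analysis time, fs (default: final grid time).
#' @param count_trajectories logical; count trajectories with equal
#'   weight instead of population weighting.
#' @return fraction in `[0, 1]`.
#' @export
branching_fraction <- function(ens, open_threshold = 2.0, at_time = NULL,
                               count_trajectories = FALSE) {
  i <- if (is.null(at_time)) length(ens$time_grid)
       else time_index_of(ens, at_time)
  num <- 0; den <- 0
  for (k in seq_along(ens$trajectories)) {
    tr <- ens$trajectories[[k]]
    if (tr$state[i] == "S0" && tr$weight[i] > 0) {
      w <- if (count_trajectories) 1 else tr$weight[i]
      g <- ensemble_frame(ens, k, i)
      den <- den + w
      if (pair_distance(g, "C3", "C4") > open_threshold) num <- num + w
    }
  }
  if (den == 0) stop("no S0 population at the requested time")
  num / den
}
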