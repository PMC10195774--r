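# Independent-atom-model (IAM) forward simulation of gas-phase electron
# diffraction: rotationally averaged Debye sM(s) curves and damped
# sine-transform pair distribution functions.

# Five-Gaussian parameterization of elastic electron scattering
# amplitudes f(s') = sum a_i exp(-b_i s'^2), s' = sin(theta)/lambda in
# 1/Angstrom (Peng-style coefficients for neutral atoms, amplitudes in
# Angstrom).  The package's momentum transfer s = 4*pi*sin(theta)/lambda.
.FORM_FACTORS <- list(
  H = list(a = c(0.0349, 0.1201, 0.1970, 0.0573, 0.1195),
           b = c(0.5347, 3.5867, 12.3471, 18.9525, 38.6269)),
  C = list(a = c(0.0893, 0.2563, 0.7570, 1.0487, 0.3575),
           b = c(0.2465, 1.7100, 6.4094, 18.6113, 50.2523)))

#' Elastic electron scattering amplitude
#'
#' @param element `"C"` or `"H"`.
#' @param s momentum transfer grid, 1/Angstrom (s = 4 pi sin(theta)/lambda).
#' @return amplitude f(s) in Angstrom (positive, monotone non-increasing).
#' @export
form_factor <- function(element, s) {
  ff <- .FORM_FACTORS[[element]]
  if (is.null(ff)) stop("no form factor tabulated for element: ", element)
  sp2 <- (s / (4 * pi))^2
  out <- numeric(length(s))
  for (k in seq_along(ff$a)) out <- out + ff$a[k] * exp(-ff$b[k] * sp2)
  out
}

#' Default diffraction transform configuration
#'
#' The working momentum-transfer window, transform damping and real-space
#' grid.  `damping_alpha` defaults so the damping factor exp(-alpha s^2)
#' is 0.1 at `s_max` (compromise between real-space resolution and
#' truncation ripple).
#'
#' @param s_min,s_max,ds momentum-transfer window and step, 1/Angstrom.
#' @param damping_alpha damping constant, Angstrom^2.
#' @param r_min,r_max,dr real-space grid, Angstrom.
#' @param excitation_fraction fraction of molecules excited, used to scale
#'   experiment-emulating difference PDFs.
#' @return list of class `transform_config`.
#' @export
transform_config <- function(s_min = 0.5, s_max = 10.0, ds = 0.02,
                             damping_alpha = log(10) / s_max^2,
                             r_min = 0, r_max = 8, dr = 0.01,
                             excitation_fraction = 0.0156) {
  stopifnot(s_min < s_max, ds > 0, dr > 0, r_min < r_max,
            damping_alpha >= 0,
            excitation_fraction > 0, excitation_fraction <= 1)
  structure(list(s_min = s_min, s_max = s_max, ds = ds,
                 damping_alpha = damping_alpha,
                 r_min = r_min, r_max = r_max, dr = dr,
                 excitation_fraction = excitation_fraction),
            class = "transform_config")
}

#' Momentum-transfer and real-space grids of a transform configuration
#' @param config a [transform_config()].
#' @return numeric grid (1/Angstrom for s, Angstrom for r).
#' @export
config_s_grid <- function(config) seq(config$s_min, config$s_max, by = config$ds)

#' @rdname config_s_grid
#' @export
config_r_grid <- function(config) seq(config$r_min, config$r_max, by = config$dr)

# trapezoidal quadrature weights for an ascending grid
trap_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Weighted-ensemble modified scattering intensity sM(s)
#'
#' Rotationally averaged Debye form for an isotropic gas:
#' \deqn{I_{mol}(s) = \sum_{i \ne j} f_i f_j \sin(s r_{ij})/(s r_{ij}),}
#' \eqn{sM(s) = s I_{mol}(s) / \sum_i f_i^2}, averaged over the supplied
#' geometries with normalized weights.  Invariant to uniform weight
#' rescaling.
#'
#' @param geometries list of [molecular_geometry()], identical atom lists.
#' @param weights nonnegative weights, sum > 0 (default uniform).
#' @param s_grid ascending momentum-transfer grid, 1/Angstrom.
#' @return list of class `scattering_curve` with `s_grid` and `values`.
#' @export
compute_sm <- function(geometries, weights = NULL,
                       s_grid = config_s_grid(transform_config())) {
  if (inherits(geometries, "molecular_geometry")) geometries <- list(geometries)
  if (!length(geometries)) stop("empty geometry list")
  if (is.null(weights)) weights <- rep(1, length(geometries))
  if (length(weights) != length(geometries))
    stop("weights must match geometries")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  if (is.unsorted(s_grid, strictly = TRUE)) stop("s_grid must be ascending")
  el <- geometries[[1]]$elements
  n <- length(el)
  for (g in geometries)
    if (!identical(g$elements, el)) stop("mismatched atom lists")
  w <- weights / sum(weights)

  f_el <- lapply(unique(el), form_factor, s = s_grid)
  names(f_el) <- unique(el)
  i_at <- Reduce(`+`, lapply(seq_len(n), function(i) f_el[[el[i]]]^2))
  if (n < 2)
    return(structure(list(s_grid = s_grid, values = numeric(length(s_grid))),
                     class = "scattering_curve"))

  # pair bookkeeping in dist() order (columnwise lower triangle)
  pi_idx <- unlist(lapply(seq_len(n - 1), function(j) seq(j + 1, n)))
  pj_idx <- rep(seq_len(n - 1), times = (n - 1):1)
  fprod <- mapply(function(i, j) f_el[[el[i]]] * f_el[[el[j]]],
                  pi_idx, pj_idx, SIMPLIFY = TRUE)  # |s| x npairs

  i_mol <- numeric(length(s_grid))
  for (k in seq_along(geometries)) {
    if (w[k] == 0) next
    r <- as.vector(stats::dist(geometries[[k]]$coords))
    sr <- outer(s_grid, r)
    sinc <- sin(sr) / sr
    sinc[sr == 0] <- 1
    i_mol <- i_mol + w[k] * 2 * rowSums(fprod * sinc)
  }
  structure(list(s_grid = s_grid, values = s_grid * i_mol / i_at),
            class = "scattering_curve")
}

#' Pair distribution function from sM(s)
#'
#' Damped sine transform \deqn{PDF(r) = \int sM(s) \sin(s r)
#' e^{-\alpha s^2} ds} evaluated by trapezoidal quadrature on the curve's
#' s-grid.  Linear in sM.
#'
#' @param curve a `scattering_curve`.
#' @param r_grid ascending real-space grid, Angstrom.
#' @param damping_alpha damping constant, Angstrom^2.
#' @param label `"static"` or `"delta"`.
#' @param delay pump-probe delay in fs (delta curves).
#' @return list of class `pdf_curve` with `r_grid`, `values`, `label`, `delay`.
#' @export
pdf_from_sm <- function(curve, r_grid = config_r_grid(transform_config()),
                        damping_alpha = transform_config()$damping_alpha,
                        label = "static", delay = NA_real_) {
  if (is.unsorted(r_grid, strictly = TRUE)) stop("r_grid must be ascending")
  if (is.unsorted(curve$s_grid, strictly = TRUE)) stop("s_grid must be ascending")
  kern <- curve$values * exp(-damping_alpha * curve$s_grid^2) *
    trap_weights(curve$s_grid)
  vals <- as.vector(sin(outer(r_grid, curve$s_grid)) %*% kern)
  structure(list(r_grid = r_grid, values = vals, label = label, delay = delay),
            class = "pdf_curve")
}

#' Difference PDF between an ensemble at a delay and a reference
#'
#' \eqn{\Delta PDF = f_{exc} (PDF_{excited} - PDF_{reference})} with a
#' common transform configuration.  The default excitation fraction for
#' experiment emulation is 1.56 percent.
#'
#' @param ensemble_at_t,reference lists with elements `geometries` (list)
#'   and `weights` (numeric), or `scattering_curve`s.
#' @param excitation_fraction in (0, 1].
#' @param config a [transform_config()].
#' @param delay delay in fs recorded on the output curve.
#' @return a `pdf_curve` with `label = "delta"`.
#' @export
delta_pdf <- function(ensemble_at_t, reference,
                      excitation_fraction = NULL,
                      config = transform_config(), delay = NA_real_) {
  if (is.null(excitation_fraction))
    excitation_fraction <- config$excitation_fraction
  if (excitation_fraction <= 0 || excitation_fraction > 1)
    stop("excitation_fraction must be in (0, 1]")
  s_grid <- config_s_grid(config)
  as_sm <- function(x) {
    if (inherits(x, "scattering_curve")) return(x)
    compute_sm(x$geometries, x$weights, s_grid)
  }
  sm_t <- as_sm(ensemble_at_t); sm_ref <- as_sm(reference)
  if (!isTRUE(all.equal(sm_t$s_grid, sm_ref$s_grid)))
    stop("ensemble and reference must share the transform configuration")
  pdf_t <- pdf_from_sm(sm_t, config_r_grid(config), config$damping_alpha)
  pdf_r <- pdf_from_sm(sm_ref, config_r_grid(config), config$damping_alpha)
  structure(list(r_grid = pdf_t$r_grid,
                 values = excitation_fraction * (pdf_t$values - pdf_r$values),
                 label = "delta", delay = delay),
            class = "pdf_curve")
}

#' Write a curve as two-column CSV with a commented configuration header
#'
#' @param curve a `scattering_curve` or `pdf_curve`.
#' @param path output file.
#' @param config optional [transform_config()] recorded in the header.
#' @export
write_curve <- function(curve, path, config = NULL) {
  hdr <- c(sprintf("# class: %s", class(curve)[1]))
  if (inherits(curve, "pdf_curve"))
    hdr <- c(hdr, sprintf("# label: %s", curve$label),
             sprintf("# delay_fs: %.17g", curve$delay))
  if (!is.null(config))
    hdr <- c(hdr, sprintf("# config: %s",
                          jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA)))
  x <- if (inherits(curve, "pdf_curve")) curve$r_grid else curve$s_grid
  xn <- if (inherits(curve, "pdf_curve")) "r_angstrom" else "s_inv_angstrom"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(xn, "value", sep = ","), con)
  writeLines(sprintf("%.17g,%.17g", x, curve$values), con)
}

#' Read a curve written by [write_curve()]
#'
#' @param path CSV file path.
#' @return the curve object; any recorded config is attached as attribute
#'   `"config"`.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  get_field <- function(key) {
    m <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, ": ?"), "", m[1])
  }
  cls <- get_field("class")
  out <- if (identical(cls, "pdf_curve")) {
    structure(list(r_grid = body[[1]], values = body[[2]],
                   label = get_field("label"),
                   delay = as.numeric(get_field("delay_fs"))),
              class = "pdf_curve")
  } else {
    structure(list(s_grid = body[[1]], values = body[[2]]),
              class = "scattering_curve")
  }
  cfg <- get_field("config")
  if (!is.null(cfg)) {
    parsed <- jsonlite::fromJSON(cfg)
    attr(out, "config") <- structure(parsed, class = "transform_config")
  }
  out
}
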