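# Region integration of difference PDFs, instrument-response convolution,
# error-function onset fitting, and trajectory-level bootstrap.

#' Difference-PDF integration regions
#'
#' Default alpha/beta/gamma regions, chosen from the coordination-sphere
#' structure of the static PDF: alpha spans the first-sphere (bond) peak,
#' beta the second-sphere peak, gamma the gap between the cis and trans
#' modes of the third sphere where out-of-plane motion first appears.
#'
#' The signal direction of each named region is known from the late-time
#' difference PDF: alpha and beta are depletions (negative), gamma is a
#' gain (positive); `expected_sign` records it and stabilizes the onset
#' fits downstream.
#'
#' @param name one of `"alpha"`, `"beta"`, `"gamma"`, `"custom"`.
#' @param r_lo,r_hi bounds in Angstrom (required for `"custom"`).
#' @param expected_sign -1, 0 or +1 (defaults: alpha/beta -1, gamma +1,
#'   custom 0).
#' @return list of class `region_definition`.
#' @export
region_definition <- function(name = c("alpha", "beta", "gamma", "custom"),
                              r_lo = NULL, r_hi = NULL,
                              expected_sign = NULL) {
  name <- match.arg(name)
  defaults <- list(alpha = c(1.2, 1.9), beta = c(2.2, 3.0),
                   gamma = c(3.2, 3.7))
  if (is.null(r_lo) || is.null(r_hi)) {
    if (name == "custom") stop("custom regions need r_lo and r_hi")
    r_lo <- defaults[[name]][1]; r_hi <- defaults[[name]][2]
  }
  if (is.null(expected_sign))
    expected_sign <- switch(name, alpha = -1, beta = -1, gamma = 1, 0)
  if (r_lo >= r_hi) stop("r_lo must be below r_hi")
  structure(list(name = name, r_lo = r_lo, r_hi = r_hi,
                 expected_sign = expected_sign),
            class = "region_definition")
}

#' Integrate difference PDFs over a region, per delay
#'
#' Trapezoidal integral of each curve over `[r_lo, r_hi]`.
#'
#' @param delta_pdfs list of `pdf_curve`s (one per delay).
#' @param region a [region_definition()].
#' @return data.frame with `delay_fs` and `value`.
#' @export
integrate_region <- function(delta_pdfs, region) {
  if (inherits(delta_pdfs, "pdf_curve")) delta_pdfs <- list(delta_pdfs)
  vapply(delta_pdfs, function(cv) {
    r <- cv$r_grid
    if (region$r_lo < min(r) || region$r_hi > max(r))
      stop("integrate_region: region [", region$r_lo, ", ", region$r_hi,
           "] outside the r-grid")
    sel <- r >= region$r_lo - 1e-12 & r <= region$r_hi + 1e-12
    sum(trap_weights(r[sel]) * cv$values[sel])
  }, numeric(1)) -> vals
  data.frame(delay_fs = vapply(delta_pdfs, function(cv) cv$delay, numeric(1)),
             value = vals)
}

#' Convolve a time series with a Gaussian instrument response function
#'
#' Discrete convolution with a unit-area Gaussian of the stated FWHM on a
#' uniform time grid.  Edge bins are renormalized by the truncated kernel
#' mass, so constant series are preserved exactly.
#'
#' @param series data.frame with `delay_fs` and `value` (uniform grid).
#' @param fwhm Gaussian full width at half maximum, fs (default 150, a
#'   typical MeV-UED response).
#' @return data.frame of the same shape.
#' @export
convolve_irf <- function(series, fwhm = 150) {
  t <- series$delay_fs
  dt <- diff(t)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
    stop("convolve_irf requires a uniform time grid")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma / dt[1])
  kern <- stats::dnorm((-half:half) * dt[1], sd = sigma)
  kern <- kern / sum(kern)
  y <- series$value
  n <- length(y)
  ypad <- c(rep(0, half), y, rep(0, half))
  mpad <- c(rep(0, half), rep(1, n), rep(0, half))
  out <- numeric(n); mass <- numeric(n)
  for (i in seq_len(n)) {
    win <- i:(i + 2 * half)
    out[i] <- sum(ypad[win] * rev(kern))
    mass[i] <- sum(mpad[win] * rev(kern))
  }
  data.frame(delay_fs = t, value = out / mass)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Fit an error-function onset to a time trace
#'
#' Least-squares fit of \deqn{S(t) = B + (A/2) [1 + erf((t - t_0) /
#' (\sqrt 2 w))]} by Levenberg-Marquardt.  `w` is the Gaussian sigma of
#' the underlying step response; the FWHM (2.355 w) is also reported.
#'
#' @param series data.frame with `delay_fs` and `value` (>= 6 points
#'   spanning the onset).
#' @param start optional named list of initial guesses `t0`, `w`, `A`, `B`.
#' @param sign `0` leaves the step amplitude free; `+1`/`-1` constrain its
#'   direction, and `"late"` constrains it to the sign of the late-time
#'   signal (mean of the last quarter of the trace minus the baseline).
#'   Constraining the direction stabilizes onset centers when a weak
#'   opposite-sign precursor leaks into an integration region.
#' @return object of class `onset_fit`: `t0`, `w`, `fwhm`, `A`, `B`,
#'   standard errors `se` (named), `residual_norm`, `step_detected`
#'   (whether the fitted step amplitude exceeds twice the residual noise;
#'   a fit without a detected step means no onset occurred within the
#'   analysis window), and the `fit` object.
#' @export
fit_erf_onset <- function(series, start = NULL, sign = 0) {
  t <- series$delay_fs; y <- series$value
  if (length(t) < 6) stop("need at least 6 points spanning the onset")
  # fit on a normalized ordinate for numerical conditioning
  yscale <- max(abs(y - mean(y)), .Machine$double.eps)
  ys <- y / yscale
  dat <- data.frame(t = t, y = ys)
  head_m <- mean(ys[seq_len(3)])
  n4 <- max(3, length(ys) %/% 4)
  tail_m <- mean(ys[seq(length(ys) - n4 + 1, length(ys))])
  a0 <- tail_m - head_m
  if (identical(sign, "late")) sign <- if (a0 >= 0) 1 else -1
  sign <- unname(sign)
  if (abs(a0) < 1e-8) a0 <- ys[which.max(abs(ys - head_m))] - head_m
  if (sign != 0) a0 <- sign * max(abs(a0), stats::sd(ys), 1e-6)
  half <- head_m + a0 / 2
  t0_guess <- t[which.min(abs(ys - half))]
  a_lo <- if (sign > 0) 0 else -Inf
  a_hi <- if (sign < 0) 0 else Inf
  starts <- list()
  if (!is.null(start)) {
    start$A <- start$A / yscale; start$B <- start$B / yscale
    starts <- list(start)
  }
  for (wv in diff(range(t)) / c(8, 3, 20))
    for (tv in unique(c(t0_guess, stats::quantile(t, c(0.35, 0.65)))))
      starts[[length(starts) + 1]] <- list(t0 = unname(tv), w = wv,
                                           A = a0, B = head_m)
  fit <- NULL; err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ B + (A / 2) * (1 + erf((t - t0) / (sqrt(2) * w))),
        data = dat, start = st,
        lower = c(t0 = -Inf, w = 1e-6, A = a_lo, B = -Inf)[names(st)],
        upper = c(t0 = Inf, w = Inf, A = a_hi, B = Inf)[names(st)],
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # fallback: coarse (t0, w) grid with linear least squares for (A, B)
    # under the sign constraint, then one more refinement attempt
    best <- NULL
    for (t0v in seq(min(t), max(t), length.out = 41))
      for (wv in exp(seq(log(max(diff(t))), log(diff(range(t))), length.out = 12))) {
        m <- 0.5 * (1 + erf((t - t0v) / (sqrt(2) * wv)))
        X <- cbind(1, m)
        ab <- tryCatch(stats::lm.fit(X, ys)$coefficients,
                       error = function(e) NULL)
        if (is.null(ab) || anyNA(ab)) next
        A <- ab[2]
        if (sign > 0 && A < 0) A <- 0
        if (sign < 0 && A > 0) A <- 0
        B <- mean(ys - A * m)
        rss <- sum((ys - (B + A * m))^2)
        if (is.null(best) || rss < best$rss)
          best <- list(t0 = t0v, w = wv, A = unname(A), B = unname(B),
                       rss = rss)
      }
    if (is.null(best)) stop("erf onset fit failed: ", err)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ B + (A / 2) * (1 + erf((t - t0) / (sqrt(2) * w))),
        data = dat,
        start = list(t0 = best$t0, w = best$w,
                     A = if (best$A == 0) sign * 1e-4 else best$A,
                     B = best$B),
        lower = c(t0 = -Inf, w = 1e-6, A = a_lo, B = -Inf),
        upper = c(t0 = Inf, w = Inf, A = a_hi, B = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      se <- stats::setNames(rep(NA_real_, 4), c("t0", "w", "A", "B"))
      resid_sd <- sqrt(best$rss / length(ys))
      return(structure(list(t0 = best$t0, w = best$w,
                            fwhm = 2 * sqrt(2 * log(2)) * best$w,
                            A = unname(best$A) * yscale,
                            B = unname(best$B) * yscale,
                            se = se,
                            residual_norm = sqrt(best$rss) * yscale,
                            step_detected = abs(best$A) > 2 * resid_sd,
                            fit = NULL),
                       class = "onset_fit"))
    }
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4),
                                                     names(cf)))
  se[c("A", "B")] <- se[c("A", "B")] * yscale
  resid_sd <- sqrt(mean(stats::resid(fit)^2))
  structure(list(t0 = unname(cf[["t0"]]), w = unname(cf[["w"]]),
                 fwhm = 2 * sqrt(2 * log(2)) * unname(cf[["w"]]),
                 A = unname(cf[["A"]]) * yscale,
                 B = unname(cf[["B"]]) * yscale,
                 se = se,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)) * yscale,
                 step_detected = abs(unname(cf[["A"]])) > 2 * resid_sd,
                 fit = fit),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("erf onset: t0 = %.1f fs (se %.1f), w = %.1f fs (FWHM %.1f), A = %.3g, B = %.3g\n",
              x$t0, x$se[["t0"]], x$w, x$fwhm, x$A, x$B))
  invisible(x)
}

#' Bootstrap a statistic over resampleable units
#'
#' Resamples whole units (trajectories or scans -- never individual
#' frames, which are serially correlated) with replacement, recomputes
#' the statistic, and reports the 16th-84th percentile (68 percent)
#' interval.
#'
#' @param statistic function taking a list of units and returning a
#'   number.
#' @param units list of at least 2 resampleable units.
#' @param n_resamples number of bootstrap resamples (default 1000).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return object of class `bootstrap_result`: `estimate`, `lower`,
#'   `upper`, `n_resamples`, `seed`, `resamples`.
#' @export
bootstrap <- function(statistic, units, n_resamples = 1000, seed) {
  if (length(units) < 2) stop("need at least 2 resampleable units")
  if (missing(seed)) stop("a seed is required")
  est <- statistic(units)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(n_resamples), function(i) {
    statistic(units[sample.int(length(units), replace = TRUE)])
  }, numeric(1))
  q <- unname(stats::quantile(reps, c(0.16, 0.84), type = 7))
  if (q[2] - q[1] <= 0)
    warning("degenerate statistic: zero-width bootstrap interval")
  structure(list(estimate = est, lower = min(q[1], est),
                 upper = max(q[2], est), n_resamples = n_resamples,
                 seed = seed, resamples = reps),
            class = "bootstrap_result")
}

#' Write an onset fit (plus optional bootstrap) as JSON
#'
#' @param fit an `onset_fit`.
#' @param path output file.
#' @param extra named list merged into the report (e.g. config hash).
#' @export
write_fit_report <- function(fit, path, extra = list()) {
  rep <- c(list(t0_fs = fit$t0, w_fs = fit$w, fwhm_fs = fit$fwhm,
                amplitude = fit$A, baseline = fit$B,
                se = as.list(fit$se), residual_norm = fit$residual_norm),
           extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
}
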