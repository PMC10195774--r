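# IAM forward model: Debye sM(s), sine-transform PDFs, difference PDFs.

test_that("form factors are positive and monotone non-increasing", {
  s <- seq(0, 12, by = 0.05)
  for (el in c("C", "H")) {
    f <- form_factor(el, s)
    expect_true(all(f > 0))
    expect_true(all(diff(f) <= 1e-12))
  }
  expect_gt(form_factor("C", 1)[1], form_factor("H", 1)[1])
  expect_error(form_factor("Xe", s), "no form factor")
})

test_that("sM of a single atom is identically zero", {
  g <- toy_geometry(matrix(0, 1, 3))
  sm <- compute_sm(list(g))
  expect_true(all(sm$values == 0))
})

test_that("homonuclear diatomic sM matches the closed form to 1e-10", {
  r0 <- 1.5
  s <- seq(0.5, 10, by = 0.02)
  sm <- compute_sm(list(diatomic(r0)), s_grid = s)
  expect_equal(sm$values, s * sin(s * r0) / (s * r0), tolerance = 1e-10)
})

test_that("Debye sum equals a Monte-Carlo orientational average on small toys", {
  # I_total(s ez) = |sum_i f_i exp(i s ez . R r_i)|^2 averaged over random
  # rotations R equals I_at + I_mol from the Debye formula
  set.seed(99)
  s_test <- c(1.0, 2.5, 5.0)
  for (geom in list(
    toy_geometry(rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.6, 1.2, 0))),
    toy_geometry(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.8, 1.3, 0.2),
                       c(-0.4, 0.5, 1.1)), elements = c("C", "C", "C", "H")))) {
    n <- nrow(geom$coords)
    f <- vapply(geom$elements, function(el) form_factor(el, s_test),
                numeric(length(s_test)))  # |s| x n
    nrot <- 2e4
    acc <- matrix(0, length(s_test), 1)
    for (m in seq_len(nrot)) {
      R <- random_rotation()
      z <- (geom$coords %*% t(R))[, 3]
      for (si in seq_along(s_test)) {
        amp <- sum(f[si, ] * exp(1i * s_test[si] * z))
        acc[si] <- acc[si] + Mod(amp)^2
      }
    }
    i_tot_mc <- acc / nrot
    i_at <- rowSums(f^2)
    sm <- compute_sm(list(geom), s_grid = s_test)
    i_mol_debye <- sm$values * i_at / s_test
    # MC standard error is well below 3% of the atomic intensity scale
    expect_lt(max(abs((as.vector(i_tot_mc) - i_at) - i_mol_debye)),
              0.03 * mean(i_at))
  }
})

test_that("sM is invariant to uniform weight rescaling and averages linearly", {
  g1 <- diatomic(1.4); g2 <- diatomic(2.2)
  s <- seq(0.5, 10, by = 0.1)
  a <- compute_sm(list(g1, g2), c(0.3, 0.7), s)
  b <- compute_sm(list(g1, g2), c(3, 7), s)
  expect_equal(a$values, b$values, tolerance = 1e-12)
  i1 <- compute_sm(list(g1), s_grid = s)$values
  i2 <- compute_sm(list(g2), s_grid = s)$values
  expect_equal(a$values, 0.3 * i1 + 0.7 * i2, tolerance = 1e-12)
  expect_error(compute_sm(list()), "empty")
  expect_error(compute_sm(list(g1, toy_geometry(matrix(0, 1, 3)))),
               "mismatched")
})

test_that("PDF transform: zero map, linearity to 1e-10, diatomic peak location", {
  cfg <- transform_config()
  s <- config_s_grid(cfg)
  zero <- structure(list(s_grid = s, values = numeric(length(s))),
                    class = "scattering_curve")
  expect_true(all(pdf_from_sm(zero)$values == 0))

  sm1 <- compute_sm(list(diatomic(1.5)), s_grid = s)
  sm2 <- compute_sm(list(diatomic(3.1)), s_grid = s)
  lin <- sm1; lin$values <- 2.5 * sm1$values - 1.3 * sm2$values
  p_lin <- pdf_from_sm(lin)
  expect_equal(p_lin$values,
               2.5 * pdf_from_sm(sm1)$values - 1.3 * pdf_from_sm(sm2)$values,
               tolerance = 1e-10)

  p1 <- pdf_from_sm(sm1)
  expect_lt(abs(p1$r_grid[which.max(p1$values)] - 1.5), 0.011)
})

test_that("delta PDF: null difference, linear scaling, ring-opening sign pattern", {
  g0 <- build_terpinene()
  ens <- list(geometries = list(g0), weights = 1)
  cfg <- transform_config()
  d0 <- delta_pdf(ens, ens, config = cfg)
  expect_true(all(abs(d0$values) < 1e-14))
  expect_error(delta_pdf(ens, ens, excitation_fraction = 0), "in \\(0, 1\\]")

  open_ens <- list(geometries = lapply(c("cZc", "cZt", "tZc", "tZt"),
                                       build_open_product),
                   weights = rep(0.25, 4))
  d1 <- delta_pdf(open_ens, ens, excitation_fraction = 0.01, config = cfg)
  d2 <- delta_pdf(open_ens, ens, excitation_fraction = 0.02, config = cfg)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  # ring-opening: bond loss near 1.5, gain near 3.4
  r <- d1$r_grid
  expect_lt(d1$values[which.min(abs(r - 1.5))], 0)
  expect_gt(d1$values[which.min(abs(r - 3.4))], 0)
})

test_that("hydrogens shift the static PDF peak positions by < 0.1 Angstrom", {
  g <- build_terpinene()
  keep <- g$elements == "C"
  cm <- g$carbon_map
  gc <- molecular_geometry(g$elements[keep], g$coords[keep, ],
                           stats::setNames(cumsum(keep)[cm], names(cm)))
  peaks <- function(geom) {
    p <- pdf_from_sm(compute_sm(list(geom)))
    v <- p$values; n <- length(v)
    im <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
    im <- im[v[im] > 0.2 * max(v)]
    p$r_grid[im]
  }
  pa <- peaks(g); pc <- peaks(gc)
  expect_identical(length(pa), length(pc))
  expect_true(all(abs(pa - pc) < 0.1))
})

test_that("curve CSV roundtrip is bit-exact and records the config", {
  cfg <- transform_config(s_min = 0.4, ds = 0.04, damping_alpha = 0.03)
  sm <- compute_sm(list(build_terpinene()), s_grid = config_s_grid(cfg))
  f <- tempfile(fileext = ".csv")
  write_curve(sm, f, config = cfg)
  back <- read_curve(f)
  expect_identical(back$s_grid, sm$s_grid)
  expect_identical(back$values, sm$values)
  expect_equal(attr(back, "config")$damping_alpha, 0.03)

  p <- pdf_from_sm(sm, label = "delta", delay = 125)
  write_curve(p, f)
  pb <- read_curve(f)
  expect_identical(pb$values, p$values)
  expect_identical(pb$delay, 125)
  unlink(f)
})
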