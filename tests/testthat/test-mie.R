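test_that("compute_mie matches the brute-force Bessel-series oracle", {
  # non-absorbing sphere, d = 1 um, lambda = 0.63 um, m = 1.5
  got <- compute_mie(1.0, 0.63, complex(real = 1.5), n_angles = 181)
  want <- mie_oracle(1.0, 0.63, 1.5)
  expect_equal(got$q_sca, want$q_sca, tolerance = 1e-6)
  expect_equal(got$q_ext, want$q_ext, tolerance = 1e-6)
  expect_equal(got$anisotropy_g, want$g, tolerance = 1e-6)
})

test_that("smoke-particle anisotropy reproduces the reference table values", {
  m <- complex(real = 1.57, imaginary = 0.4277)
  g1 <- compute_mie(0.2, 0.630, m)$anisotropy_g
  g2 <- compute_mie(6.0, 0.630, m)$anisotropy_g
  expect_equal(g1, 0.2052, tolerance = 0.01 / 0.2052)
  expect_equal(g2, 0.7324, tolerance = 0.01 / 0.7324)
})

test_that("Rayleigh limit gives fore-aft symmetric scattering", {
  r <- compute_mie(0.002, 0.630, complex(real = 1.5))
  expect_lt(abs(r$anisotropy_g), 0.01)
})

test_that("energy bookkeeping and phase-table invariants hold", {
  cases <- list(
    list(d = 0.2, m = complex(real = 1.57, imaginary = 0.4277), abs = TRUE),
    list(d = 6.0, m = complex(real = 1.57, imaginary = 0.4277), abs = TRUE),
    list(d = 1.0, m = complex(real = 1.5), abs = FALSE),
    list(d = 3.0, m = complex(real = 1.57), abs = FALSE)
  )
  for (cs in cases) {
    r <- compute_mie(cs$d, 0.630, cs$m, n_angles = 1801,
                     absorbing_sphere = cs$abs)
    expect_lt(abs(r$q_ext - r$q_sca - r$q_abs) / r$q_ext, 1e-9)
    S11 <- r$phase_matrix$S11
    expect_true(all(S11 >= 0))
    expect_true(all(abs(r$phase_matrix$S12) <= S11 + 1e-12))
    th <- r$angle_grid
    norm <- 2 * pi * sum(diff(th) * (head(S11 * sin(th), -1) +
                                       (S11 * sin(th))[-1]) / 2)
    expect_equal(norm, 1, tolerance = 1e-6)
    g_tab <- 2 * pi * sum(diff(th) *
                            (head(cos(th) * S11 * sin(th), -1) +
                               (cos(th) * S11 * sin(th))[-1]) / 2)
    expect_equal(g_tab, r$anisotropy_g, tolerance = 1e-4)
  }
})

test_that("angle-grid refinement has converged", {
  m <- complex(real = 1.57, imaginary = 0.4277)
  r1 <- compute_mie(6.0, 0.630, m, n_angles = 901)
  r2 <- compute_mie(6.0, 0.630, m, n_angles = 1801)
  expect_lt(abs(r1$anisotropy_g - r2$anisotropy_g), 1e-5)
})

test_that("compute_mie validates its domain", {
  expect_error(compute_mie(-1, 0.63, 1.5 + 0i), "diameter")
  expect_error(compute_mie(1, 0, 1.5 + 0i), "wavelength")
  expect_error(compute_mie(1, 0.63, 1.5 + 0i, medium_index = 0.5), "medium")
  expect_error(compute_mie(1, 0.63, 1.5 + 0i, n_angles = 1), "n_angles")
})

test_that("scattering_coefficient converts density to cm^-1", {
  m <- complex(real = 1.57, imaginary = 0.4277)
  r1 <- compute_mie(0.2, 0.630, m)
  r2 <- compute_mie(6.0, 0.630, m)
  expect_equal(scattering_coefficient(r1, 2e-3), 0.1737, tolerance = 0.05)
  expect_equal(scattering_coefficient(r2, 1e-6), 0.6230, tolerance = 0.05)
  expect_identical(scattering_coefficient(r1, 0), 0)
  expect_error(scattering_coefficient(r1, -1), "density")
})

test_that("gaussian_size_distribution behaves as documented", {
  d <- gaussian_size_distribution(3.0, 0.3, 1001)
  expect_length(d$diameters, 1001)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
  expect_true(all(d$diameters > 0))

  d0 <- gaussian_size_distribution(3.0, 0, 101)
  expect_identical(d0$diameters, 3.0)
  expect_identical(d0$weights, 1)

  # quadrature refinement: coarse and fine grids agree on the mean
  mean_d <- function(n) {
    s <- gaussian_size_distribution(3.0, 0.3, n)
    sum(s$diameters * s$weights)
  }
  expect_equal(mean_d(5), mean_d(1e5), tolerance = 0.01)

  expect_error(gaussian_size_distribution(3.0, 1.0), "cv")
  expect_error(gaussian_size_distribution(-1, 0.3), "mean_diameter")
})

test_that("polydisperse_mie reduces and combines correctly", {
  m <- complex(real = 1.57, imaginary = 0.4277)
  # degenerate distribution equals the single-size result
  d0 <- gaussian_size_distribution(2.0, 0, 1)
  p0 <- polydisperse_mie(d0, 0.630, m, n_angles = 91)
  s0 <- compute_mie(2.0, 0.630, m, n_angles = 91)
  expect_equal(p0$anisotropy_g, s0$anisotropy_g, tolerance = 1e-12)
  expect_equal(p0$sigma_sca, s0$sigma_sca, tolerance = 1e-12)

  # 3-point toy distribution equals the hand-rolled weighted sum
  dist <- structure(list(diameters = c(1, 2, 4), weights = c(0.2, 0.5, 0.3),
                         mean_diameter = 2.3, coefficient_of_variation = NA,
                         n_points = 3L), class = "size_distribution")
  p <- polydisperse_mie(dist, 0.630, m, n_angles = 91)
  parts <- lapply(dist$diameters, compute_mie, wavelength = 0.630,
                  particle_index = m, n_angles = 91)
  sig <- vapply(parts, `[[`, numeric(1), "sigma_sca")
  gs <- vapply(parts, `[[`, numeric(1), "anisotropy_g")
  qs <- vapply(parts, `[[`, numeric(1), "q_sca")
  w <- dist$weights
  expect_equal(p$sigma_sca, sum(w * sig), tolerance = 1e-12)
  expect_equal(p$q_sca, sum(w * qs), tolerance = 1e-12)
  expect_equal(p$anisotropy_g, sum(w * sig * gs) / sum(w * sig),
               tolerance = 1e-12)
  pn <- polydisperse_mie(dist, 0.630, m, n_angles = 91,
                         g_weighting = "number")
  expect_equal(pn$anisotropy_g, sum(w * gs), tolerance = 1e-12)
})

test_that("polydisperse anisotropy matches the reference table", {
  dist <- gaussian_size_distribution(3.0, 0.3, 1001)
  p <- polydisperse_mie(dist, 0.630, complex(real = 1.57, imaginary = 0.4277),
                        n_angles = 91)
  expect_equal(p$anisotropy_g, 0.7253, tolerance = 0.01 / 0.7253)
})

test_that("phase tables export as two-column text", {
  r <- compute_mie(0.5, 0.63, 1.5 + 0i, n_angles = 19)
  dir <- withr::local_tempdir()
  paths <- export_phase_table(r, dir)
  expect_length(paths, 4)
  tab <- utils::read.table(paths[1], header = TRUE)
  expect_equal(nrow(tab), 19)
  expect_equal(tab$angle_deg[c(1, 19)], c(0, 180))
})
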