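phase62 <- compute_mie(6.0, 0.630, complex(real = 1.57, imaginary = 0.4277),
                       n_angles = 721)
phase02 <- compute_mie(0.2, 0.630, complex(real = 1.57, imaginary = 0.4277),
                       n_angles = 721)

test_that("launch_photon starts at the beam axis with horizontal polarization", {
  b <- launch_photon(5, smoke_depth = 3)
  expect_equal(b$pos, cbind(0, 0, rep(3, 5)))
  expect_equal(b$dir[1, ], c(0, 0, -1))
  expect_equal(b$stokes[3, ], c(1, 1, 0, 0))
  expect_identical(b$weight, rep(1, 5))
  # frames orthonormal and right-handed
  expect_equal(rowSums(b$epar * b$eperp), rep(0, 5))
  expect_equal(b$epar[1, 2] * b$eperp[1, 3] - b$epar[1, 3] * b$eperp[1, 2],
               b$dir[1, 1])
})

test_that("free paths are exponential and absorption uses the albedo", {
  mu_s <- 0.1737; mu_a <- 0.0100
  med <- layered_medium(1e6, mu_s, mu_a, phase62)
  set.seed(4)
  b <- launch_photon(1e5, 1e6 - 1)
  step <- propagate_step(b, med)
  # mean free path of the scattered photons vs 1/(mu_s+mu_a) = 5.44 cm
  z_travel <- (1e6 - 1) - step$batch$pos[step$scattered, 3]
  mu_t <- mu_s + mu_a
  se <- (1 / mu_t) / sqrt(length(z_travel))
  expect_lt(abs(mean(z_travel) - 1 / mu_t), 2.5 * se)
  # single-scattering albedo applied to the weight
  expect_equal(unique(round(step$batch$weight[step$scattered], 10)),
               round(mu_s / mu_t, 10))
})

test_that("a vacuum slab is crossed ballistically", {
  med <- layered_medium(2, 0, 0, phase62)
  b <- launch_photon(10, 2)
  step <- propagate_step(b, med)
  expect_identical(step$at_tissue, 1:10)
  expect_equal(step$batch$pos[, 3], rep(0, 10))
  expect_identical(step$batch$weight, rep(1, 10))
})

test_that("scatter_photon reproduces the phase function statistics", {
  set.seed(11)
  # isotropic phase: cos(theta) uniform on [-1, 1]
  iso <- phase62
  iso$phase_matrix <- lapply(iso$phase_matrix, function(v) v * 0)
  iso$phase_matrix$S11 <- rep(1 / (4 * pi), length(iso$angle_grid))
  b <- launch_photon(1e5, 10)
  b$stokes <- matrix(rep(c(1, 0, 0, 0), each = 1e5), 1e5, 4)  # unpolarized
  b2 <- scatter_photon(b, iso)
  ct <- -b2$dir[, 3]  # cos scattering angle relative to straight-down
  h <- table(cut(ct, seq(-1, 1, length.out = 21)))
  p <- stats::chisq.test(as.numeric(h))$p.value
  expect_gt(p, 0.001)

  # Mie phase for the 6 um particle: empirical mean cosine = anisotropy g
  set.seed(12)
  b <- launch_photon(1e5, 10)
  b$stokes <- matrix(rep(c(1, 0, 0, 0), each = 1e5), 1e5, 4)
  b2 <- scatter_photon(b, phase62)
  ct <- -b2$dir[, 3]
  se <- stats::sd(ct) / sqrt(length(ct))
  expect_lt(abs(mean(ct) - phase62$anisotropy_g), 3 * se)

  # physics bounds after scattering of a polarized batch
  set.seed(13)
  b <- launch_photon(2e4, 10)
  b3 <- scatter_photon(b, phase62)
  dopv <- sqrt(rowSums(b3$stokes[, 2:4]^2))
  expect_true(all(dopv <= 1 + 1e-9))
  expect_true(all(abs(sqrt(rowSums(b3$dir^2)) - 1) < 1e-9))
  expect_error(scatter_photon(b, {
    z <- phase62; z$phase_matrix$S11 <- z$phase_matrix$S11 * 0; z
  }), "degenerate")
})

test_that("tissue interaction: Fresnel, Lambertian moment, depolarization", {
  set.seed(21)
  n <- 1e5
  # albedo 0: only the 4% specular Fresnel reflection survives
  med0 <- layered_medium(2, 0.1, 0.01, phase62, tissue_albedo = 0)
  b <- launch_photon(n, 2)
  b$pos[, 3] <- 0
  ti <- tissue_interaction(b, med0, seq_len(n))
  frac <- mean(ti$batch$alive)
  expect_lt(abs(frac - ((1.5 - 1) / (1.5 + 1))^2), 2.5 * sqrt(0.04 * 0.96 / n))

  # albedo 1, matched indices: all Lambertian, mean exit cosine 2/3
  set.seed(22)
  med1 <- layered_medium(2, 0.1, 0.01, phase62, tissue_albedo = 1,
                         n_tissue = 1.0, tissue_depolarization = 1)
  b <- launch_photon(n, 2)
  b$pos[, 3] <- 0
  ti <- tissue_interaction(b, med1, seq_len(n))
  expect_true(all(ti$batch$alive))
  ct <- ti$batch$dir[, 3]
  expect_true(all(ct > 0))
  expect_lt(abs(mean(ct) - 2 / 3), 2.5 * stats::sd(ct) / sqrt(n))
  # fully depolarizing tissue: re-emitted DOP is exactly zero
  expect_true(all(ti$batch$stokes[, 2:4] == 0))
  # frames stay orthonormal
  expect_lt(max(abs(rowSums(ti$batch$dir * ti$batch$epar))), 1e-9)
})

test_that("run_simulation conserves energy and is deterministic", {
  med <- layered_medium(NA, 0.6230, 0.0100, phase62)
  cfg <- mc_config(med, n_photons = 5000, heights = c(2, 6), seed = 99)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  for (k in 1:2) {
    expect_identical(r1[[k]]$co, r2[[k]]$co)        # bit-identical repeat
    expect_identical(r1[[k]]$cross, r2[[k]]$cross)
    expect_equal(sum(r1[[k]]$ledger), 5000, tolerance = 1e-6)
  }
})

test_that("backscattering trends match the layered-medium physics", {
  heights <- c(2, 4, 6, 8)
  for (p in list(list(phase = phase02, mu_s = 0.1737),
                 list(phase = phase62, mu_s = 0.6230))) {
    med <- layered_medium(NA, p$mu_s, 0.0100, p$phase)
    res <- run_simulation(mc_config(med, n_photons = 15000,
                                    heights = heights, seed = 7))
    co <- vapply(res, `[[`, numeric(1), "co_total")
    cross <- vapply(res, `[[`, numeric(1), "cross_total")
    expect_true(all(co > cross))             # co-polarized dominates
    central <- vapply(res, central_radiance, numeric(1), channel = "co")
    expect_true(all(diff(central) <= 0))     # central radiance decays
    dopt <- (co - cross) / (co + cross)
    # depolarization grows with medium depth (2 SE slack per step)
    se <- 2 / sqrt(15000)
    expect_true(all(diff(dopt) <= 2 * se))
  }
})

test_that("scatter-free depolarizing slab returns co ~ cross", {
  med <- layered_medium(NA, 0, 0, phase62, tissue_albedo = 1,
                        n_tissue = 1.0, tissue_depolarization = 1)
  res <- run_simulation(mc_config(med, n_photons = 20000, heights = 2,
                                  seed = 3))
  r <- res[[1]]
  tot <- r$co_total + r$cross_total
  expect_lt(abs(r$co_total - r$cross_total) / tot, 2 / sqrt(20000))
})
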