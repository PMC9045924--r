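#' Degree of polarization map
#'
#' Two-channel linear degree of polarization,
#' `DOP = (Ico - Icro) / (Ico + Icro)`, per pixel and colour channel,
#' clamped to `[0, 1]`. Pixels with `Ico + Icro = 0` are undefined: they
#' are returned as `NA` and flagged in the `"undefined"` attribute rather
#' than silently set to zero.
#'
#' @param pair A `polarimetric_pair`.
#' @return `H x W x 3` DOP array of class `dop_map` with logical
#'   attribute `"undefined"`.
#' @export
dop <- function(pair) {
  stopifnot(inherits(pair, "polarimetric_pair"))
  s <- pair$co + pair$cross
  d <- pair$co - pair$cross
  undef <- s == 0
  out <- array(NA_real_, dim(s))
  out[!undef] <- pmin(pmax(d[!undef] / s[!undef], 0), 1)
  structure(out, class = c("dop_map", "array"), undefined = undef)
}

# scalar (channel-averaged) DOP map
dop_scalar <- function(pair) {
  m <- dop(pair)
  (m[, , 1] + m[, , 2] + m[, , 3]) / 3
}

mask_index <- function(x, mask) {
  if (is.null(mask)) return(rep(TRUE, prod(dim(x)[1:2])))
  stopifnot(all(dim(mask) == dim(x)[1:2]))
  as.vector(mask) > 0
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` over the masked pixels. Identical images
#' (zero MSE) return the documented cap. With `peak = 255` the value
#' matches the 8-bit convention used when PSNR is reported in the 55-67
#' dB range; `peak = 1` (default) is the normalized-image convention.
#'
#' @param reference,test Arrays of identical shape, values in `[0, 1]`.
#' @param mask Optional `H x W` logical/0-1 matrix selecting pixels.
#' @param peak Peak signal value (default 1).
#' @param cap Value returned for zero MSE (default 100 dB).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, mask = NULL, peak = 1, cap = 100) {
  stopifnot(identical(dim(reference), dim(test)))
  sel <- mask_index(reference, mask)
  if (!any(sel)) stop("empty mask")
  nc <- if (length(dim(reference)) == 3L) dim(reference)[3] else 1L
  selc <- rep(sel, nc)
  mse <- mean((as.vector(reference)[selc] - as.vector(test)[selc])^2)
  if (mse == 0) return(cap)
  min(10 * log10(peak^2 / mse), cap)
}

# separable Gaussian filtering, valid region only
gauss_filter_valid <- function(m, kernel) {
  k <- length(kernel)
  out <- apply(m, 2, function(col) stats::filter(col, kernel))
  out <- t(apply(t(out), 2, function(row) stats::filter(row, kernel)))
  half <- (k - 1) / 2
  out[(half + 1):(nrow(m) - half), (half + 1):(ncol(m) - half), drop = FALSE]
}

#' Structural similarity index
#'
#' Standard single-scale SSIM: 11 x 11 Gaussian window (sigma 1.5),
#' stability constants `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 1`.
#' Colour images are converted to luma (Rec. 601 weights) first. The
#' SSIM map is computed on the valid (fully windowed) region and averaged
#' over the mask.
#'
#' @param reference,test Images of identical shape, values in `[0, 1]`.
#' @param mask Optional `H x W` mask (cropped to the valid region).
#' @return Mean SSIM, dimensionless in `[-1, 1]`.
#' @export
ssim <- function(reference, test, mask = NULL) {
  stopifnot(identical(dim(reference), dim(test)))
  to_gray <- function(x) {
    if (length(dim(x)) == 3L)
      0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    else x
  }
  a <- to_gray(reference); b <- to_gray(test)
  win <- 11L
  if (nrow(a) < win || ncol(a) < win)
    stop("image smaller than the 11 x 11 SSIM window")
  g <- stats::dnorm(seq(-5, 5), 0, 1.5)
  g <- g / sum(g)
  C1 <- (0.01 * 1)^2
  C2 <- (0.03 * 1)^2
  mu_a <- gauss_filter_valid(a, g)
  mu_b <- gauss_filter_valid(b, g)
  saa <- gauss_filter_valid(a * a, g) - mu_a^2
  sbb <- gauss_filter_valid(b * b, g) - mu_b^2
  sab <- gauss_filter_valid(a * b, g) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(a)))
    half <- (win - 1) / 2
    mk <- mask[(half + 1):(nrow(a) - half), (half + 1):(ncol(a) - half)]
    if (!any(mk > 0)) stop("empty mask")
    mean(map[mk > 0])
  } else mean(map)
}

# sRGB (gamma-encoded, D65) -> CIE Lab
srgb_to_lab <- function(rgb) {
  v <- pmin(pmax(rgb, 0), 1)
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.0, 1.08883)
  r <- sweep(xyz, 2, white, "/")
  f <- ifelse(r > (6 / 29)^3, r^(1 / 3), r / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' CIEDE2000 colour difference between Lab pairs
#'
#' Full CIEDE2000 formula including the lightness/chroma/hue weighting
#' functions and the rotation term, with unit weighting factors
#' (`kL = kC = kH = 1`). Vectorized over rows.
#'
#' @param lab1,lab2 `n x 3` matrices of CIE Lab coordinates.
#' @return Numeric vector of `n` colour differences.
#' @export
delta_e2000 <- function(lab1, lab2) {
  lab1 <- rbind(lab1); lab2 <- rbind(lab2)
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) * 180 / pi) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) * 180 / pi) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
                ifelse(abs(dh) <= 180, dh,
                       ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
                ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                       ifelse(hsum < 360, (hsum + 360) / 2,
                              (hsum - 360) / 2)))
  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * pi / 180) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

#' Mean CIEDE2000 colour difference between two RGB images
#'
#' Converts both images from sRGB (companded, D65 white) to CIE Lab and
#' returns the mean per-pixel CIEDE2000 difference over the mask.
#'
#' @param reference,test `H x W x 3` RGB images in `[0, 1]`.
#' @param mask Optional `H x W` mask.
#' @return Mean colour difference (dimensionless, >= 0).
#' @export
ciede2000 <- function(reference, test, mask = NULL) {
  reference <- as_image3(reference); test <- as_image3(test)
  stopifnot(identical(dim(reference), dim(test)))
  sel <- mask_index(reference, mask)
  if (!any(sel)) stop("empty mask")
  flat <- function(x) cbind(as.vector(x[, , 1]), as.vector(x[, , 2]),
                            as.vector(x[, , 3]))[sel, , drop = FALSE]
  mean(delta_e2000(srgb_to_lab(flat(reference)), srgb_to_lab(flat(test))))
}

#' Joint image and polarimetric evaluation report
#'
#' Computes PSNR, SSIM and CIEDE2000 between a reference and a test
#' image, and -- when polarimetric pairs are supplied -- the same metrics
#' between their degree-of-polarization maps (channel-averaged DOP
#' treated as a grayscale image).
#'
#' @param reference,test `H x W x 3` images in `[0, 1]` (clamped for the
#'   metrics).
#' @param pair_reference,pair_test Optional `polarimetric_pair`s for DOP
#'   evaluation.
#' @param mask Optional `H x W` region-of-interest mask.
#' @param peak PSNR peak convention (default 1).
#' @return An object of class `metric_report`: list with `psnr`, `ssim`,
#'   `ciede2000` and, if pairs were given, `dop_psnr`, `dop_ssim`,
#'   `dop_ciede2000`.
#' @export
evaluate <- function(reference, test, pair_reference = NULL,
                     pair_test = NULL, mask = NULL, peak = 1) {
  clamp <- function(x) pmin(pmax(x, 0), 1)
  reference <- clamp(reference); test <- clamp(test)
  rep_ <- list(psnr = psnr(reference, test, mask, peak = peak),
               ssim = ssim(reference, test, mask),
               ciede2000 = ciede2000(reference, test, mask))
  if (!is.null(pair_reference) && !is.null(pair_test)) {
    dr <- dop_scalar(pair_reference)
    dt <- dop_scalar(pair_test)
    dr[is.na(dr)] <- 0; dt[is.na(dt)] <- 0
    rep_$dop_psnr <- psnr(dr, dt, mask, peak = peak)
    rep_$dop_ssim <- ssim(dr, dt, mask)
    rep_$dop_ciede2000 <- ciede2000(as_image3(dr), as_image3(dt), mask)
  }
  structure(rep_, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report\n")
  cat(sprintf("  PSNR      = %.4f dB\n", x$psnr))
  cat(sprintf("  SSIM      = %.4f\n", x$ssim))
  cat(sprintf("  CIEDE2000 = %.4f\n", x$ciede2000))
  if (!is.null(x$dop_psnr)) {
    cat(sprintf("  DOP PSNR  = %.4f dB, DOP SSIM = %.4f, DOP dE00 = %.4f\n",
                x$dop_psnr, x$dop_ssim, x$dop_ciede2000))
  }
  invisible(x)
}
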