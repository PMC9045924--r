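#' Polarimetric image pair
#'
#' The pipeline's central container: registered co-polarized and
#' cross-polarized RGB radiance images of the same scene. Values live in
#' `[0, 1]` by convention but are kept unclamped internally; clamping
#' happens only at export ([write_image()]).
#'
#' @param co,cross `H x W x 3` numeric arrays.
#' @param tag One of `"ground-truth"`, `"degraded"`, `"restored"`.
#' @return An object of class `polarimetric_pair`.
#' @export
polarimetric_pair <- function(co, cross,
                              tag = c("ground-truth", "degraded", "restored")) {
  tag <- match.arg(tag)
  co <- as_image3(co); cross <- as_image3(cross)
  if (!identical(dim(co), dim(cross)))
    stop("co and cross images must have identical dimensions")
  structure(list(co = co, cross = cross, tag = tag),
            class = "polarimetric_pair")
}

#' @export
print.polarimetric_pair <- function(x, ...) {
  d <- dim(x$co)
  cat(sprintf("Polarimetric image pair [%s], %d x %d x %d\n",
              x$tag, d[1], d[2], d[3]))
  cat(sprintf("  co in [%.3f, %.3f], cross in [%.3f, %.3f]\n",
              min(x$co), max(x$co), min(x$cross), max(x$cross)))
  invisible(x)
}

# Coerce a matrix or 3-plane array to H x W x 3.
as_image3 <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3))
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("expected an H x W x 3 array (or an H x W matrix)")
  x
}

#' Ambient light (airlight) at infinite optical depth
#'
#' The colour an infinitely thick smoke layer presents to the camera, one
#' RGB triple per polarization channel.
#'
#' @param co_rgb,cross_rgb Length-3 numeric vectors in `[0, 1]`.
#' @return An object of class `airlight`.
#' @export
airlight <- function(co_rgb, cross_rgb) {
  stopifnot(length(co_rgb) == 3, length(cross_rgb) == 3,
            all(co_rgb >= 0 & co_rgb <= 1),
            all(cross_rgb >= 0 & cross_rgb <= 1))
  structure(list(co_rgb = as.numeric(co_rgb),
                 cross_rgb = as.numeric(cross_rgb)),
            class = "airlight")
}

# smooth white noise with a separable box kernel, wrap-around
smooth_noise <- function(h, w, radius) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (radius < 1) return(z)
  k <- rep(1, 2 * radius + 1)
  circ_filter <- function(m, k) {
    pad <- (length(k) - 1) / 2
    mm <- rbind(m[(nrow(m) - pad + 1):nrow(m), , drop = FALSE], m,
                m[1:pad, , drop = FALSE])
    out <- apply(mm, 2, function(col) stats::filter(col, k / sum(k)))
    out[(pad + 1):(pad + nrow(m)), , drop = FALSE]
  }
  z <- circ_filter(z, k)
  t(circ_filter(t(z), k))
}

rescale01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0 + 0.5)
  (m - r[1]) / diff(r)
}

#' Generate a smoke-free polarimetric ground-truth scene
#'
#' Produces a synthetic scene radiance `J` and splits it into polarization
#' channels as `Jco = J (1 + p)/2`, `Jcro = J (1 - p)/2`, so the
#' two-channel degree of polarization of the ground truth equals the
#' requested `scene_dop` at every pixel (or the per-pixel `dop_map`).
#'
#' Scene kinds: `"checker"` is a colour-checker-style grid of flat
#' patches including near-black, near-white, grey and saturated primaries
#' (a stand-in for a physical colour checker card); `"blobs"` overlays
#' soft Gaussian colour blobs on a grey ramp; `"tissue-texture"` is a
#' smooth reddish texture with vessel-like streaks emulating an organ
#' surface.
#'
#' @param kind `"checker"`, `"blobs"` or `"tissue-texture"`.
#' @param height,width Image size in pixels, >= 16.
#' @param scene_dop Scalar degree of polarization in `[0, 1)`.
#' @param rng_seed Integer seed; the scene is reproducible bit-for-bit.
#' @param dop_map Optional `H x W` matrix of per-pixel DOP values in
#'   `[0, 1)`, overriding `scene_dop`.
#' @return A `polarimetric_pair` tagged `"ground-truth"` with attribute
#'   `"J"` (the scene radiance) and `"dop"` (the DOP used).
#' @export
generate_scene <- function(kind = c("checker", "blobs", "tissue-texture"),
                           height = 256L, width = 256L, scene_dop = 0,
                           rng_seed = 1L, dop_map = NULL) {
  kind <- match.arg(kind)
  if (height < 16 || width < 16) stop("scene dimensions must be >= 16")
  if (is.null(dop_map)) {
    if (scene_dop < 0 || scene_dop >= 1)
      stop("`scene_dop` must be in [0, 1)")
  } else {
    stopifnot(all(dim(dop_map) == c(height, width)),
              all(dop_map >= 0 & dop_map < 1))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)

  J <- array(0, c(height, width, 3))
  if (kind == "checker") {
    # fixed palette: primaries, secondaries, grey steps, near-black/white
    pal <- rbind(c(0.02, 0.02, 0.02), c(0.98, 0.98, 0.98),
                 c(0.85, 0.1, 0.1), c(0.1, 0.8, 0.15), c(0.12, 0.2, 0.85),
                 c(0.9, 0.85, 0.1), c(0.1, 0.8, 0.8), c(0.8, 0.1, 0.8),
                 c(0.25, 0.25, 0.25), c(0.5, 0.5, 0.5), c(0.75, 0.75, 0.75),
                 c(0.6, 0.4, 0.2), c(0.4, 0.55, 0.3), c(0.7, 0.5, 0.6),
                 c(0.35, 0.3, 0.6), c(0.9, 0.6, 0.3))
    nrp <- 6L; ncp <- 6L
    idx <- matrix(sample.int(nrow(pal), nrp * ncp, replace = TRUE), nrp, ncp)
    idx[1, 1] <- 1L; idx[1, 2] <- 2L    # always include black and white
    ri <- pmin(ceiling(seq_len(height) / (height / nrp)), nrp)
    ci <- pmin(ceiling(seq_len(width) / (width / ncp)), ncp)
    for (c in 1:3) J[, , c] <- matrix(pal[idx[cbind(rep(ri, times = width),
                                                    rep(ci, each = height))],
                                          c], height, width)
  } else if (kind == "blobs") {
    base <- matrix(rep(seq(0.15, 0.85, length.out = width), each = height),
                   height, width)
    for (c in 1:3) J[, , c] <- base
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), times = width), height, width)
    for (b in 1:8) {
      cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
      rad <- stats::runif(1, 0.05, 0.2) * min(height, width)
      col <- stats::runif(3, 0.1, 0.95)
      g <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * rad^2))
      for (c in 1:3) J[, , c] <- J[, , c] * (1 - g) + col[c] * g
    }
  } else {                              # tissue-texture
    base <- rescale01(smooth_noise(height, width, 12))
    fine <- rescale01(smooth_noise(height, width, 3))
    tex <- 0.55 + 0.3 * base + 0.12 * fine
    ys <- matrix(rep(seq_len(height), times = width), height, width)
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    vessels <- exp(-((sin(xs / width * 6 * pi + 4 * base) *
                        cos(ys / height * 3 * pi))^2) / 0.02)
    J[, , 1] <- pmin(tex * 0.95, 1)
    J[, , 2] <- tex * 0.45 * (1 - 0.5 * vessels)
    J[, , 3] <- tex * 0.40 * (1 - 0.5 * vessels)
  }

  p <- if (is.null(dop_map)) array(scene_dop, c(height, width))
       else dop_map
  pco <- array(rep((1 + p) / 2, 3), c(height, width, 3))
  pcr <- array(rep((1 - p) / 2, 3), c(height, width, 3))
  pair <- polarimetric_pair(J * pco, J * pcr, "ground-truth")
  attr(pair, "J") <- J
  attr(pair, "dop") <- p
  pair
}

#' Generate a spatially varying optical-depth map
#'
#' The per-pixel dimensionless optical thickness \eqn{u(x) = \beta\tau(x)}
#' driving the forward degradation model (`t = exp(-u)`). `"uniform"`
#' returns a constant map; `"gaussian-blob"` superimposes a few smooth
#' plumes; `"multiscale-noise"` sums smoothed noise octaves and
#' exponentiates, emulating patchy drifting smoke. Inhomogeneous kinds
#' are rescaled so their spatial mean equals `level` exactly.
#'
#' @param kind `"uniform"`, `"gaussian-blob"` or `"multiscale-noise"`.
#' @param level Mean optical depth, >= 0 (dimensionless).
#' @param height,width Map size in pixels.
#' @param rng_seed Integer seed.
#' @return An object of class `optical_depth_map`: an `H x W` matrix with
#'   attribute `level`.
#' @export
generate_optical_depth <- function(kind = c("uniform", "gaussian-blob",
                                            "multiscale-noise"),
                                   level, height = 256L, width = 256L,
                                   rng_seed = 1L) {
  kind <- match.arg(kind)
  if (level < 0) stop("`level` must be >= 0")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  if (kind == "uniform") {
    u <- matrix(level, height, width)
  } else if (kind == "gaussian-blob") {
    xs <- matrix(rep(seq_len(width), each = height), height, width)
    ys <- matrix(rep(seq_len(height), times = width), height, width)
    u <- matrix(0.25, height, width)    # thin ambient haze under the plumes
    for (b in 1:4) {
      cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
      rad <- stats::runif(1, 0.15, 0.4) * min(height, width)
      u <- u + exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * rad^2))
    }
    if (level > 0) u <- u * (level / mean(u)) else u <- u * 0
  } else {
    f <- smooth_noise(height, width, 16) + 0.5 * smooth_noise(height, width, 6) +
      0.25 * smooth_noise(height, width, 2)
    f <- f / stats::sd(f)
    u <- exp(0.5 * f)
    if (level > 0) u <- u * (level / mean(u)) else u <- u * 0
  }
  structure(u, class = c("optical_depth_map", "matrix"), level = level)
}

#' Apply the two-term smoke degradation model
#'
#' Degrades a ground-truth polarimetric pair with the scattering model
#' `I = J exp(-u) + A (1 - exp(-u))`, applied per pixel, per colour
#' channel and per polarization channel with that channel's airlight.
#' Optionally adds i.i.d. Gaussian sensor noise.
#'
#' @param truth A `polarimetric_pair` (ground truth).
#' @param u An `optical_depth_map` (`H x W`, shared by colour channels)
#'   or an `H x W x 3` array for chromatic smoke.
#' @param A An [airlight()].
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0, noise-free).
#' @param rng_seed Seed used when `noise_sd > 0`.
#' @return A `polarimetric_pair` tagged `"degraded"`.
#' @export
degrade <- function(truth, u, A, noise_sd = 0, rng_seed = 1L) {
  stopifnot(inherits(truth, "polarimetric_pair"), inherits(A, "airlight"))
  d <- dim(truth$co)
  uu <- if (length(dim(u)) == 3L) unclass(u) else
    array(rep(unclass(u), 3), c(dim(u), 3))
  if (!identical(dim(uu), d))
    stop("optical-depth map dimensions do not match the image")
  if (any(uu < 0) || any(!is.finite(uu)))
    stop("optical depth must be finite and >= 0")
  tr <- exp(-uu)
  Aco <- array(rep(A$co_rgb, each = d[1] * d[2]), d)
  Acr <- array(rep(A$cross_rgb, each = d[1] * d[2]), d)
  co <- truth$co * tr + Aco * (1 - tr)
  cross <- truth$cross * tr + Acr * (1 - tr)
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(rng_seed)
    co <- co + array(stats::rnorm(prod(d), 0, noise_sd), d)
    cross <- cross + array(stats::rnorm(prod(d), 0, noise_sd), d)
  }
  polarimetric_pair(co, cross, "degraded")
}
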