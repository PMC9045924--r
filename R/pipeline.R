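#' Estimate the ambient light at infinite optical depth (haze lines)
#'
#' Three-step haze-line airlight estimation: (i) quantize the image to 64
#' representative colours (deterministic k-means) with per-cluster pixel
#' counts; (ii) project the cluster centres onto the three 2-D colour
#' planes RB, GB and RG; (iii) Hough-vote on a candidate grid per plane
#' for the point that maximizes the count-weighted collinearity of haze
#' lines through it, i.e. the point where the lines traced by scene
#' colours under varying transmission converge. Each colour channel's
#' estimate is the average of its two plane winners.
#'
#' @param image `H x W x 3` radiance array in `[0, 1]`.
#' @param n_clusters Number of colour clusters (default 64).
#' @param grid_n Candidate-grid resolution per axis (default 64); the
#'   grid spans `[0, 1.1 * max(image)]`.
#' @param n_angle_bins Number of haze-line angle bins (default 90).
#' @param seed Seed for the clustering initialisation (fixed default 1
#'   makes repeated calls identical).
#' @return Length-3 numeric airlight estimate, with attribute `"votes"`
#'   (per-plane `hazeline_vote` detail: candidate grids, accumulators and
#'   winners).
#' @export
estimate_airlight <- function(image, n_clusters = 64L, grid_n = 64L,
                              n_angle_bins = 90L, seed = 1L) {
  image <- as_image3(image)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  if (max(apply(px, 2, stats::sd)) < 1e-3) {
    warning("near-constant image: returning the mean colour as airlight")
    return(colMeans(px))
  }
  # deterministic subsample keeps the clustering cheap on large frames
  if (nrow(px) > 20000L)
    px <- px[seq(1L, nrow(px), length.out = 20000L), , drop = FALSE]
  uniq <- unique(px)
  k <- min(n_clusters, nrow(uniq))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (nrow(uniq) <= n_clusters) {
    centers <- uniq
    counts <- as.numeric(table(factor(match(
      paste(px[, 1], px[, 2], px[, 3]),
      paste(uniq[, 1], uniq[, 2], uniq[, 3])), levels = seq_len(k))))
  } else {
    km <- suppressWarnings(stats::kmeans(px, centers = k, iter.max = 100,
                                         nstart = 1))
    centers <- km$centers
    counts <- as.numeric(km$size)
  }

  hi <- 1.1 * max(image)
  # the airlight cannot be darker than the bulk of a smoky frame: floor
  # the candidate set at the per-channel pixel median
  med <- apply(px, 2, stats::median)
  planes <- list(RB = c(1, 3), GB = c(2, 3), RG = c(1, 2))
  votes <- lapply(planes, function(ch)
    hazeline_vote_plane(centers[, ch, drop = FALSE], counts, hi, grid_n,
                        n_angle_bins, floor_xy = med[ch]))
  # joint argmax over the RGB grid: each channel is constrained by the
  # two planes it appears in, which stabilises the vote against a single
  # degenerate plane
  nrm <- function(a) a / max(a, 1e-12)
  aRB <- nrm(votes$RB$accumulator)      # [R, B]
  aGB <- nrm(votes$GB$accumulator)      # [G, B]
  aRG <- nrm(votes$RG$accumulator)      # [R, G]
  best <- c(1L, 1L, 1L); bestv <- -Inf
  for (b in seq_len(grid_n)) {          # total score: RB[r,b]+GB[g,b]+RG[r,g]
    tot <- outer(aRB[, b], aGB[, b], "+") + aRG
    m <- which.max(tot)
    if (tot[m] > bestv) {
      bestv <- tot[m]
      best <- c((m - 1L) %% grid_n + 1L, (m - 1L) %/% grid_n + 1L, b)
    }
  }
  # sub-grid refinement: vote-weighted centroid of the 3 x 3 window
  # around each plane's winning cell, averaged over the two planes each
  # channel appears in
  g <- votes$RB$candidate_grid
  centroid <- function(a, i, j) {
    ii <- pmax(1, i - 1):pmin(grid_n, i + 1)
    jj <- pmax(1, j - 1):pmin(grid_n, j + 1)
    win <- a[ii, jj, drop = FALSE]
    s <- sum(win)
    if (s == 0) return(c(g[i], g[j]))
    c(sum(g[ii] * rowSums(win)) / s, sum(g[jj] * colSums(win)) / s)
  }
  cRB <- centroid(aRB, best[1], best[3])
  cGB <- centroid(aGB, best[2], best[3])
  cRG <- centroid(aRG, best[1], best[2])
  est <- c(R = (cRB[1] + cRG[1]) / 2,
           G = (cGB[1] + cRG[2]) / 2,
           B = (cRB[2] + cGB[2]) / 2)
  attr(est, "votes") <- votes
  est
}

# Hough vote in one 2-D colour plane. A haze line is traced by one scene
# colour under varying transmission, so two clusters sampling the same
# haze line are collinear with the airlight: every cluster *pair* votes
# for the candidates from which both members are seen under the same
# quantized angle (within half an angle bin, i.e. the pair's line passes
# through the candidate, with the candidate outside the segment). Votes
# are weighted by the product of cluster pixel counts; ties go to the
# brighter candidate.
hazeline_vote_plane <- function(pts, counts, hi, grid_n, n_angle_bins,
                                floor_xy = c(0, 0)) {
  g <- seq(0, hi, length.out = grid_n)
  cand <- cbind(rep(g, times = grid_n), rep(g, each = grid_n))
  delta <- hi / (grid_n - 1)
  w <- counts / sum(counts)
  n <- nrow(pts)
  # the airlight is not darker than the bulk of a smoky frame; flooring
  # the candidates also removes the false convergence point that shading
  # lines of a smooth scene create near the origin
  allowed <- cand[, 1] >= floor_xy[1] & cand[, 2] >= floor_xy[2]
  if (!any(allowed)) allowed <- rep(TRUE, nrow(cand))
  # Every sufficiently separated cluster pair defines a candidate haze
  # line. A candidate accumulates the pair's weight when it lies within
  # half a grid cell of that line, outside the segment (the airlight is
  # the convergence point of haze lines, not an interior point). Votes
  # are binned by each line's direction and the score sums sqrt(bin
  # mass): many *distinct* converging directions beat one heavily
  # populated line (e.g. the neutral axis of a colour chart, or the
  # near-parallel shading lines of a smooth scene).
  nc <- nrow(cand)
  accW <- matrix(0, nc, n_angle_bins)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      dx <- pts[j, 1] - pts[i, 1]
      dy <- pts[j, 2] - pts[i, 2]
      len <- sqrt(dx^2 + dy^2)
      if (len < 2 * delta) next
      bin <- floor(((atan2(dy, dx) %% pi) / pi) * n_angle_bins) %% n_angle_bins
      ax <- cand[, 1] - pts[i, 1]
      ay <- cand[, 2] - pts[i, 2]
      perp <- abs(dx * ay - dy * ax) / len
      outside <- (ax * (cand[, 1] - pts[j, 1]) +
                    ay * (cand[, 2] - pts[j, 2])) > 0
      hit <- which(perp < delta / 2 & outside & allowed)
      if (length(hit)) accW[hit, bin + 1L] <- accW[hit, bin + 1L] +
          w[i] * w[j] * (len / delta)
    }
  }
  acc <- rowSums(sqrt(accW))
  best <- which(acc == max(acc))
  best <- best[which.max(cand[best, 1] + cand[best, 2])]
  structure(list(candidate_grid = g, accumulator = matrix(acc, grid_n, grid_n),
                 winner = cand[best, ]),
            class = "hazeline_vote")
}

#' Polarization-difference image
#'
#' Per-pixel, per-channel `Ico - Icro`. Under the degradation model the
#' object radiance cancels for depolarized scenes and the difference
#' isolates the smoke term `Aco (1 - exp(-u))`. Negative values (sensor
#' noise) are clamped to zero.
#'
#' @param pair A `polarimetric_pair`.
#' @return `H x W x 3` difference array.
#' @export
polarization_difference <- function(pair) {
  stopifnot(inherits(pair, "polarimetric_pair"))
  pmax(pair$co - pair$cross, 0)
}

#' Estimate the per-channel transmission map
#'
#' `t_c(x) = 1 - diff_c(x) / Aco_c`, computed independently for the R, G
#' and B channels (colours are attenuated by smoke to different degrees,
#' so a single scalar per pixel would bias the reconstruction), then
#' clamped to `[t_min, 1]`.
#'
#' @param difference `H x W x 3` polarization-difference image.
#' @param airlight_co Length-3 co-channel airlight; all components must
#'   be positive.
#' @param t_min Lower clamp for the transmission (default 0.05); bounds
#'   the division in the reconstruction step.
#' @return An object of class `transmission_map` (`H x W x 3` array with
#'   attribute `t_min`).
#' @export
estimate_transmission <- function(difference, airlight_co, t_min = 0.05) {
  stopifnot(length(airlight_co) == 3, t_min > 0, t_min <= 1)
  if (any(airlight_co <= 0))
    stop("all co-channel airlight components must be > 0")
  difference <- as_image3(difference)
  d <- dim(difference)
  Aco <- array(rep(airlight_co, each = d[1] * d[2]), d)
  t <- pmin(pmax(1 - difference / Aco, t_min), 1)
  structure(t, class = c("transmission_map", "array"), t_min = t_min)
}

#' Reconstruct the smoke-free image
#'
#' Doubles the restored cross-polarized radiance:
#' `J = 2 (Icro - Acro) / t + 2 Acro`, per pixel and colour channel. The
#' result is left unclamped; clamping to `[0, 1]` happens at export.
#'
#' @param pair A `polarimetric_pair` (degraded).
#' @param t A `transmission_map`.
#' @param airlight_cross Length-3 cross-channel airlight.
#' @return `H x W x 3` restored radiance.
#' @export
reconstruct <- function(pair, t, airlight_cross) {
  stopifnot(inherits(pair, "polarimetric_pair"), length(airlight_cross) == 3)
  d <- dim(pair$cross)
  Acr <- array(rep(airlight_cross, each = d[1] * d[2]), d)
  tt <- array(as.numeric(t), d)
  2 * (pair$cross - Acr) / tt + 2 * Acr
}

#' Run the full polarization-difference desmoking pipeline
#'
#' Estimates the airlight of each polarization channel (haze-line voting,
#' unless supplied), forms the polarization difference, estimates the
#' per-channel transmission, reconstructs the smoke-free image, and also
#' restores each polarization channel separately
#' (`Jch = (Ich - Ach) / t + Ach`) so the degree of polarization of the
#' restored scene can be evaluated downstream.
#'
#' @param pair A `polarimetric_pair` of the smoky scene.
#' @param airlight_co,airlight_cross Optional length-3 overrides. When
#'   `NULL`, the co-channel airlight comes from [estimate_airlight()]
#'   (haze-line voting); the cross-channel airlight is then read off the
#'   smokiest pixels -- the `(1 - t)^4`-weighted mean of the cross image,
#'   which converges to the ambient light at infinite optical depth.
#'   Haze-line voting is unreliable on the cross channel because its
#'   airlight is dim (the smoke backscatter is strongly co-polarized) and
#'   typically darker than the scene content.
#' @param t_min Transmission lower bound (default 0.05).
#' @param verbose Log each stage to the console.
#' @return An object of class `desmoke_result`: list with `restored`
#'   (`H x W x 3`), `transmission` (`transmission_map`), `airlight`
#'   ([airlight()]), `difference`, and `restored_pair` (a
#'   `polarimetric_pair` tagged `"restored"`).
#' @export
desmoke <- function(pair, airlight_co = NULL, airlight_cross = NULL,
                    t_min = 0.05, verbose = FALSE) {
  stopifnot(inherits(pair, "polarimetric_pair"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(airlight_co)) {
    say("estimating co-channel airlight (haze lines)")
    airlight_co <- as.numeric(estimate_airlight(pair$co))
  }
  diff <- polarization_difference(pair)
  t <- estimate_transmission(diff, airlight_co, t_min)
  if (is.null(airlight_cross)) {
    say("estimating cross-channel airlight from the smokiest pixels")
    smoke_w <- (1 - (t[, , 1] + t[, , 2] + t[, , 3]) / 3)^4
    if (sum(smoke_w) < 1e-8) {
      # essentially smoke-free frame: the cross airlight is unobservable
      # and also irrelevant (t ~ 1); any bounded value works
      airlight_cross <- c(0, 0, 0)
    } else {
      airlight_cross <- vapply(1:3, function(c)
        sum(smoke_w * pair$cross[, , c]) / sum(smoke_w), numeric(1))
    }
  }
  say("airlight co = (%.3f, %.3f, %.3f), cross = (%.3f, %.3f, %.3f)",
      airlight_co[1], airlight_co[2], airlight_co[3],
      airlight_cross[1], airlight_cross[2], airlight_cross[3])
  say("transmission in [%.3f, %.3f]", min(t), max(t))
  restored <- reconstruct(pair, t, airlight_cross)
  d <- dim(pair$co)
  Aco <- array(rep(airlight_co, each = d[1] * d[2]), d)
  Acr <- array(rep(airlight_cross, each = d[1] * d[2]), d)
  tt <- array(as.numeric(t), d)
  rp <- polarimetric_pair((pair$co - Aco) / tt + Aco,
                          (pair$cross - Acr) / tt + Acr,
                          "restored")
  structure(list(restored = restored, transmission = t,
                 airlight = airlight(pmin(pmax(airlight_co, 0), 1),
                                     pmin(pmax(airlight_cross, 0), 1)),
                 difference = diff, restored_pair = rp,
                 t_min = t_min),
            class = "desmoke_result")
}

#' @export
print.desmoke_result <- function(x, ...) {
  cat("Desmoke result\n")
  cat(sprintf("  airlight co    = (%.3f, %.3f, %.3f)\n",
              x$airlight$co_rgb[1], x$airlight$co_rgb[2], x$airlight$co_rgb[3]))
  cat(sprintf("  airlight cross = (%.3f, %.3f, %.3f)\n",
              x$airlight$cross_rgb[1], x$airlight$cross_rgb[2],
              x$airlight$cross_rgb[3]))
  cat(sprintf("  transmission in [%.3f, %.3f] (t_min = %g)\n",
              min(x$transmission), max(x$transmission), x$t_min))
  invisible(x)
}
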