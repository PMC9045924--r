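#' Layered smoke-over-tissue medium
#'
#' Describes the two-layer scene used by the polarized Monte Carlo
#' simulator: a slab of smoke (scattering particles in air) of thickness
#' `smoke_depth` resting on a diffusely reflecting tissue surface.
#'
#' @param smoke_depth Smoke-layer thickness, cm.
#' @param mu_s Scattering coefficient of the smoke, cm^-1.
#' @param mu_a Absorption coefficient of the smoke, cm^-1.
#' @param phase A `mie_result` providing the single-scattering phase
#'   matrix of the smoke particles.
#' @param n_smoke Real refractive index of the smoke layer (default 1.0).
#' @param tissue_albedo Probability that a photon reaching the tissue is
#'   diffusely re-emitted rather than absorbed (default 0.6).
#' @param n_tissue Real refractive index of the tissue (default 1.50).
#' @param tissue_depolarization Fraction of the incident polarization lost
#'   at each diffuse tissue bounce, in `[0, 1]`. `1` makes the tissue a
#'   fully depolarizing reflector; the default 0.3 keeps most of the
#'   polarization, reflecting that directly reflected illumination
#'   retains its polarization state and that depth-dependent
#'   depolarization is accrued in the smoke, not at the surface.
#' @return A list of class `layered_medium`.
#' @export
layered_medium <- function(smoke_depth, mu_s, mu_a, phase,
                           n_smoke = 1.0, tissue_albedo = 0.6,
                           n_tissue = 1.50, tissue_depolarization = 0.3) {
  stopifnot(mu_s >= 0, mu_a >= 0,
            tissue_albedo >= 0, tissue_albedo <= 1,
            tissue_depolarization >= 0, tissue_depolarization <= 1,
            inherits(phase, "mie_result"))
  structure(list(smoke_depth = smoke_depth, mu_s = mu_s, mu_a = mu_a,
                 phase = phase, n_smoke = n_smoke,
                 tissue_albedo = tissue_albedo, n_tissue = n_tissue,
                 tissue_depolarization = tissue_depolarization),
            class = "layered_medium")
}

#' Monte Carlo run configuration
#'
#' @param medium A [layered_medium()]. Its `smoke_depth` may be `NA`, in
#'   which case each detector height doubles as the smoke depth (the
#'   receiving plane sits on top of the smoke, so greater height means a
#'   deeper medium).
#' @param n_photons Photons per height (default 50000).
#' @param heights Detector-plane heights above the tissue, cm
#'   (default `c(2, 4, 6, 8)`).
#' @param extent Lateral size of the square detector, cm (default 25).
#' @param bins Sampling points per side of the detector (default 100).
#' @param seed Integer master seed.
#' @param roulette_threshold,roulette_survival Russian-roulette weight
#'   threshold and survival probability.
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(medium, n_photons = 50000L,
                      heights = c(2, 4, 6, 8), extent = 25, bins = 100L,
                      seed = 1L, roulette_threshold = 1e-4,
                      roulette_survival = 0.1) {
  stopifnot(inherits(medium, "layered_medium"), n_photons >= 0,
            all(heights > 0), extent > 0, bins >= 1)
  structure(list(medium = medium, n_photons = as.integer(n_photons),
                 heights = heights, extent = extent, bins = as.integer(bins),
                 seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "mc_config")
}

#' Launch a batch of photons
#'
#' All photons start at the centre of the illuminated plane (top of the
#' smoke layer), heading straight down, with unit weight and horizontal
#' linear polarization, Stokes vector (1, 1, 0, 0) referenced to the
#' laboratory x axis.
#'
#' @param n Number of photons.
#' @param smoke_depth Launch height (top of the smoke layer), cm.
#' @return A photon batch: list of matrices `pos` (n x 3, cm), `dir`,
#'   `epar`, `eperp` (n x 3 unit vectors; `(epar, eperp, dir)` is a
#'   right-handed orthonormal triad), `stokes` (n x 4, `s0 = 1`),
#'   `weight` (length n), `alive` (logical n).
#' @export
launch_photon <- function(n, smoke_depth) {
  n <- as.integer(n)
  list(
    pos = cbind(numeric(n), numeric(n), rep(smoke_depth, n)),
    dir = matrix(rep(c(0, 0, -1), each = n), n, 3),
    epar = matrix(rep(c(1, 0, 0), each = n), n, 3),
    eperp = matrix(rep(c(0, -1, 0), each = n), n, 3),
    stokes = matrix(rep(c(1, 1, 0, 0), each = n), n, 4),
    weight = rep(1, n),
    alive = rep(TRUE, n)
  )
}

# Linear interpolation of a phase-table element at arbitrary angles.
phase_lookup <- function(theta_grid, values, theta) {
  stats::approx(theta_grid, values, xout = theta, rule = 2)$y
}

# Tabulated inverse CDF of the azimuth-integrated phase function
# S11(theta) sin(theta); used to draw scattering angles.
make_theta_sampler <- function(phase) {
  th <- phase$angle_grid
  dens <- phase$phase_matrix$S11 * sin(th)
  cdf <- c(0, cumsum((head(dens, -1) + dens[-1]) / 2 * diff(th)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  th <- th[keep]; cdf <- cdf[keep]
  function(u) stats::approx(cdf, th, xout = u, rule = 2)$y
}

#' Scatter a batch of photons off smoke particles
#'
#' Draws the scattering angle from the azimuth-integrated phase function
#' (inverse-CDF on the S11 table) and the azimuth from the
#' polarization-dependent conditional density
#' \eqn{1 + (S_{12}/S_{11})(s_1\cos 2\phi + s_2\sin 2\phi)} by rejection
#' (envelope 2, acceptance >= 1/2). The Stokes vector is rotated into the
#' scattering meridian, multiplied by the scattering matrix, renormalized
#' to `s0 = 1` (weight bookkeeping is carried separately), and the
#' direction and reference frame are updated.
#'
#' @param batch A photon batch (see [launch_photon()]); only rows with
#'   `batch$alive` are scattered.
#' @param phase A `mie_result`.
#' @return The updated batch.
#' @export
scatter_photon <- function(batch, phase) {
  if (all(phase$phase_matrix$S11 == 0))
    stop("degenerate phase table: S11 is identically zero")
  idx <- which(batch$alive)
  n <- length(idx)
  if (n == 0L) return(batch)
  sampler <- make_theta_sampler(phase)
  theta <- sampler(stats::runif(n))
  s11 <- phase_lookup(phase$angle_grid, phase$phase_matrix$S11, theta)
  s12 <- phase_lookup(phase$angle_grid, phase$phase_matrix$S12, theta)
  s33 <- phase_lookup(phase$angle_grid, phase$phase_matrix$S33, theta)
  s34 <- phase_lookup(phase$angle_grid, phase$phase_matrix$S34, theta)
  ratio <- ifelse(s11 > 0, s12 / s11, 0)
  ratio <- pmax(pmin(ratio, 1), -1)
  st <- batch$stokes[idx, , drop = FALSE]

  # azimuth by rejection against a flat envelope of height 2
  phi <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    cand <- stats::runif(length(todo), 0, 2 * pi)
    dens <- 1 + ratio[todo] *
      (st[todo, 2] * cos(2 * cand) + st[todo, 3] * sin(2 * cand))
    acc <- stats::runif(length(todo)) * 2 <= dens
    phi[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }

  c2 <- cos(2 * phi); s2 <- sin(2 * phi)
  s1r <- st[, 2] * c2 + st[, 3] * s2      # rotate reference by phi
  s2r <- -st[, 2] * s2 + st[, 3] * c2
  s0n <- s11 * st[, 1] + s12 * s1r        # apply scattering matrix
  s1n <- s12 * st[, 1] + s11 * s1r
  s2n <- s33 * s2r + s34 * st[, 4]
  s3n <- -s34 * s2r + s33 * st[, 4]
  f <- ifelse(s0n > 0, 1 / s0n, 0)        # renormalize to s0 = 1
  batch$stokes[idx, ] <- cbind(1, s1n * f, s2n * f, s3n * f)

  cphi <- cos(phi); sphi <- sin(phi)
  epar <- batch$epar[idx, , drop = FALSE]
  eperp <- batch$eperp[idx, , drop = FALSE]
  dirv <- batch$dir[idx, , drop = FALSE]
  epar2 <- cphi * epar + sphi * eperp     # frame rotated into meridian
  eperp2 <- -sphi * epar + cphi * eperp
  ct <- cos(theta); stn <- sin(theta)
  dir_new <- ct * dirv + stn * epar2
  epar_new <- ct * epar2 - stn * dirv
  nrm <- sqrt(rowSums(dir_new^2))
  batch$dir[idx, ] <- dir_new / nrm
  batch$epar[idx, ] <- epar_new / sqrt(rowSums(epar_new^2))
  batch$eperp[idx, ] <- eperp2 / sqrt(rowSums(eperp2^2))
  batch
}

# Unpolarized Fresnel reflectance at a planar interface.
fresnel_reflectance <- function(cos_i, n1, n2) {
  cos_i <- pmin(pmax(cos_i, 0), 1)
  sin_t2 <- (n1 / n2)^2 * (1 - cos_i^2)
  r <- rep(1, length(cos_i))          # total internal reflection
  ok <- sin_t2 < 1
  cos_t <- sqrt(1 - sin_t2[ok])
  ci <- cos_i[ok]
  rs <- ((n1 * ci - n2 * cos_t) / (n1 * ci + n2 * cos_t))^2
  rp <- ((n1 * cos_t - n2 * ci) / (n1 * cos_t + n2 * ci))^2
  r[ok] <- (rs + rp) / 2
  r
}

#' Interact a batch of photons with the tissue surface
#'
#' Photons arriving at the tissue surface (z = 0, moving downward) first
#' see the Fresnel specular reflection of the smoke/tissue interface
#' (direction mirrored, polarization kept). Transmitted photons are
#' either diffusely re-emitted with probability `tissue_albedo` --
#' Lambertian direction -- or absorbed (terminated). A re-emitted photon
#' keeps a fraction `1 - tissue_depolarization` of its incident
#' polarization (orientation carried over in the laboratory frame); with
#' `tissue_depolarization = 1` the tissue is a fully depolarizing
#' reflector emitting Stokes (1, 0, 0, 0).
#'
#' @param batch Photon batch; rows in `at_tissue` must sit at z = 0 with
#'   downward direction.
#' @param medium A [layered_medium()].
#' @param at_tissue Integer indices of the photons to process.
#' @return List with the updated `batch` and `absorbed`, the total weight
#'   terminated in the tissue.
#' @export
tissue_interaction <- function(batch, medium, at_tissue) {
  n <- length(at_tissue)
  if (n == 0L) return(list(batch = batch, absorbed = 0))
  cos_i <- -batch$dir[at_tissue, 3]
  refl <- fresnel_reflectance(cos_i, medium$n_smoke, medium$n_tissue)
  u <- stats::runif(n)
  spec <- u < refl
  dif <- !spec & (stats::runif(n) < medium$tissue_albedo)
  dead <- !spec & !dif

  if (any(spec)) {                     # mirror reflection
    i <- at_tissue[spec]
    batch$dir[i, 3] <- -batch$dir[i, 3]
    batch$epar[i, 3] <- -batch$epar[i, 3]
    batch$eperp[i, 3] <- -batch$eperp[i, 3]
  }
  if (any(dif)) {                      # Lambertian re-emission
    i <- at_tissue[dif]
    k <- length(i)
    depol <- medium$tissue_depolarization
    if (is.null(depol)) depol <- 1
    if (depol < 1) {                   # incident polarization in lab frame
      ro <- frame_rotation(batch, i)
      st <- batch$stokes[i, , drop = FALSE]
      s1lab <- st[, 2] * ro$c2 + st[, 3] * ro$s2
      s2lab <- -st[, 2] * ro$s2 + st[, 3] * ro$c2
      s3old <- st[, 4]
    }
    ct <- sqrt(stats::runif(k))
    st <- sqrt(1 - ct^2)
    ph <- stats::runif(k, 0, 2 * pi)
    d <- cbind(st * cos(ph), st * sin(ph), ct)
    batch$dir[i, ] <- d
    # rebuild an orthonormal frame around the new direction
    ref <- cbind(rep(1, k), 0, 0)
    swap <- abs(d[, 1]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    ep <- ref - d * rowSums(ref * d)
    ep <- ep / sqrt(rowSums(ep^2))
    eq <- cbind(d[, 2] * ep[, 3] - d[, 3] * ep[, 2],
                d[, 3] * ep[, 1] - d[, 1] * ep[, 3],
                d[, 1] * ep[, 2] - d[, 2] * ep[, 1])
    batch$epar[i, ] <- ep
    batch$eperp[i, ] <- -eq            # keep (epar, eperp, dir) right-handed
    if (depol < 1) {                   # rotate retained part into new frame
      rn <- frame_rotation(batch, i)
      keep_f <- 1 - depol
      batch$stokes[i, ] <- cbind(
        rep(1, k),
        keep_f * (s1lab * rn$c2 - s2lab * rn$s2),
        keep_f * (s1lab * rn$s2 + s2lab * rn$c2),
        keep_f * s3old)
    } else {
      batch$stokes[i, ] <- cbind(rep(1, k), 0, 0, 0)
    }
  }
  absorbed <- 0
  if (any(dead)) {
    i <- at_tissue[dead]
    absorbed <- sum(batch$weight[i])
    batch$alive[i] <- FALSE
  }
  list(batch = batch, absorbed = absorbed)
}

#' Propagate a batch of photons one step
#'
#' Samples an exponential free path with attenuation `mu_s + mu_a`, moves
#' each photon, and classifies the outcome: exit through the top of the
#' smoke layer, arrival at the tissue surface, escape through the lateral
#' boundary, or a scattering event inside the slab (absorption handled by
#' multiplying the weight with the single-scattering albedo
#' `mu_s / (mu_s + mu_a)`). In a vacuum slab (`mu_s + mu_a = 0`) photons
#' travel ballistically to the nearest boundary.
#'
#' @param batch Photon batch.
#' @param medium A [layered_medium()] (its `smoke_depth` is the top
#'   boundary).
#' @param extent Lateral half-extent is `extent/2`; photons beyond it are
#'   terminated as side escapes.
#' @return List: updated `batch`, index vectors `exit_top`, `at_tissue`,
#'   `scattered`, and the weights `side_escaped` and `absorbed` removed
#'   from the batch this step.
#' @export
propagate_step <- function(batch, medium, extent = 25) {
  idx <- which(batch$alive)
  out <- list(batch = batch, exit_top = integer(0), at_tissue = integer(0),
              scattered = integer(0), side_escaped = 0, absorbed = 0)
  if (length(idx) == 0L) return(out)
  mu_t <- medium$mu_s + medium$mu_a
  n <- length(idx)
  s <- if (mu_t > 0) -log(stats::runif(n)) / mu_t else rep(Inf, n)

  z <- batch$pos[idx, 3]
  dz <- batch$dir[idx, 3]
  d_top <- ifelse(dz > 0, (medium$smoke_depth - z) / dz, Inf)
  d_bot <- ifelse(dz < 0, -z / dz, Inf)
  d_bound <- pmin(d_top, d_bot)
  hits_boundary <- s >= d_bound
  travel <- pmin(s, d_bound)
  travel[is.infinite(travel)] <- 0     # horizontal photon in vacuum slab

  batch$pos[idx, ] <- batch$pos[idx, ] + batch$dir[idx, ] * travel
  # clean up boundary coordinates against roundoff
  top_hit <- hits_boundary & (d_top <= d_bot)
  bot_hit <- hits_boundary & (d_bot < d_top)
  batch$pos[idx[top_hit], 3] <- medium$smoke_depth
  batch$pos[idx[bot_hit], 3] <- 0

  # lateral escape check after the move
  half <- extent / 2
  outside <- abs(batch$pos[idx, 1]) > half | abs(batch$pos[idx, 2]) > half
  stuck <- is.infinite(s) & !hits_boundary   # vacuum + horizontal: no event
  side <- outside | stuck
  if (any(side)) {
    out$side_escaped <- sum(batch$weight[idx[side]])
    batch$alive[idx[side]] <- FALSE
  }
  keep <- !side
  out$exit_top <- idx[top_hit & keep]
  out$at_tissue <- idx[bot_hit & keep]
  scat <- idx[!hits_boundary & keep & !stuck]
  if (mu_t > 0 && length(scat) > 0) {
    albedo <- medium$mu_s / mu_t
    out$absorbed <- sum(batch$weight[scat]) * (1 - albedo)
    batch$weight[scat] <- batch$weight[scat] * albedo
  }
  out$scattered <- scat
  out$batch <- batch
  out
}

# Rotation (cos 2psi, sin 2psi) taking each photon's reference frame onto
# the laboratory frame whose x axis is the launch polarization, projected
# perpendicular to the propagation direction.
frame_rotation <- function(batch, idx) {
  d <- batch$dir[idx, , drop = FALSE]
  ex <- cbind(1 - d[, 1]^2, -d[, 1] * d[, 2], -d[, 1] * d[, 3])
  nrm <- sqrt(rowSums(ex^2))
  degen <- nrm < 1e-12                  # photon travelling along x
  if (any(degen))
    ex[degen, ] <- matrix(rep(c(0, 0, 1), each = sum(degen)), ncol = 3)
  nrm[degen] <- 1
  ex <- ex / nrm
  cpsi <- rowSums(ex * batch$epar[idx, , drop = FALSE])
  spsi <- rowSums(ex * batch$eperp[idx, , drop = FALSE])
  list(c2 = cpsi^2 - spsi^2, s2 = 2 * cpsi * spsi)
}

# Rotate detected Stokes vectors into the laboratory frame, then split
# into co/cross components.
detect_co_cross <- function(batch, idx) {
  r <- frame_rotation(batch, idx)
  st <- batch$stokes[idx, , drop = FALSE]
  s1lab <- st[, 2] * r$c2 + st[, 3] * r$s2
  w <- batch$weight[idx]
  list(co = w * (1 + s1lab) / 2, cross = w * (1 - s1lab) / 2)
}

#' Run the polarized Monte Carlo backscattering simulation
#'
#' Simulates `n_photons` linearly polarized pencil-beam photons per
#' detector height. The receiving plane sits at the top of the smoke
#' layer (height above the tissue = smoke depth, unless the medium fixes
#' `smoke_depth`, in which case photons exiting the smoke continue
#' ballistically up to each plane). Upward-crossing photons are binned on
#' the detector grid; the co-polarized channel accumulates
#' \eqn{(s_0+s_1)/2} and the cross-polarized channel \eqn{(s_0-s_1)/2},
#' both referenced to the launch polarization.
#'
#' @param config An [mc_config()].
#' @return A list of class `mc_result`, one element per height, each of
#'   class `detector_grid` with `co`/`cross` accumulators (`bins x bins`
#'   matrices), totals, an energy `ledger`
#'   (detected/absorbed/side-escaped/terminated weights), and metadata.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  if (config$n_photons == 0L) warning("zero photons requested: empty grids")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  results <- vector("list", length(config$heights))
  names(results) <- paste0("h", config$heights)
  for (k in seq_along(config$heights)) {
    set.seed(config$seed + k - 1L)
    results[[k]] <- mc_run_one_height(config, config$heights[k])
  }
  structure(results, class = "mc_result", config = config)
}

mc_run_one_height <- function(config, height) {
  med <- config$medium
  depth <- if (is.na(med$smoke_depth)) height else med$smoke_depth
  med$smoke_depth <- depth
  n <- config$n_photons
  bins <- config$bins
  half <- config$extent / 2
  co_acc <- matrix(0, bins, bins)
  cross_acc <- matrix(0, bins, bins)
  ledger <- c(detected = 0, absorbed = 0, side_escaped = 0, terminated = 0)

  batch <- launch_photon(n, depth)
  iter <- 0L
  while (any(batch$alive) && iter < 10000L) {
    iter <- iter + 1L
    step <- propagate_step(batch, med, config$extent)
    batch <- step$batch
    ledger["side_escaped"] <- ledger["side_escaped"] + step$side_escaped
    ledger["absorbed"] <- ledger["absorbed"] + step$absorbed

    if (length(step$exit_top) > 0) {
      idx <- step$exit_top
      pos <- batch$pos[idx, , drop = FALSE]
      dirv <- batch$dir[idx, , drop = FALSE]
      if (height > depth) {             # free flight up to the plane
        t_up <- (height - pos[, 3]) / dirv[, 3]
        pos <- pos + dirv * t_up
      }
      inb <- abs(pos[, 1]) <= half & abs(pos[, 2]) <= half
      cc <- detect_co_cross(batch, idx)
      ix <- pmin(pmax(floor((pos[inb, 1] + half) / config$extent * bins) + 1, 1), bins)
      iy <- pmin(pmax(floor((pos[inb, 2] + half) / config$extent * bins) + 1, 1), bins)
      flat <- cbind(ix, iy)
      co_in <- cc$co[inb]; cross_in <- cc$cross[inb]
      for (j in seq_along(co_in)) {     # few collisions; simple accumulate
        co_acc[flat[j, 1], flat[j, 2]] <- co_acc[flat[j, 1], flat[j, 2]] + co_in[j]
        cross_acc[flat[j, 1], flat[j, 2]] <- cross_acc[flat[j, 1], flat[j, 2]] + cross_in[j]
      }
      ledger["detected"] <- ledger["detected"] + sum(cc$co + cc$cross)
      ledger["side_escaped"] <- ledger["side_escaped"] +
        sum(cc$co[!inb] + cc$cross[!inb])
      ledger["detected"] <- ledger["detected"] - sum(cc$co[!inb] + cc$cross[!inb])
      batch$alive[idx] <- FALSE
    }
    if (length(step$at_tissue) > 0) {
      ti <- tissue_interaction(batch, med, step$at_tissue)
      batch <- ti$batch
      ledger["absorbed"] <- ledger["absorbed"] + ti$absorbed
    }
    if (length(step$scattered) > 0) {
      live_scat <- step$scattered[batch$alive[step$scattered]]
      sub <- batch$alive & FALSE
      sub[live_scat] <- TRUE
      tmp_alive <- batch$alive
      batch$alive <- sub
      batch <- scatter_photon(batch, med$phase)
      batch$alive <- tmp_alive
      # Russian roulette on low-weight photons
      rr <- live_scat[batch$weight[live_scat] < config$roulette_threshold]
      if (length(rr) > 0) {
        surv <- stats::runif(length(rr)) < config$roulette_survival
        killw <- sum(batch$weight[rr[!surv]])
        ledger["terminated"] <- ledger["terminated"] + killw
        batch$alive[rr[!surv]] <- FALSE
        boost <- batch$weight[rr[surv]] * (1 / config$roulette_survival - 1)
        ledger["terminated"] <- ledger["terminated"] - sum(boost)
        batch$weight[rr[surv]] <- batch$weight[rr[surv]] / config$roulette_survival
      }
    }
  }
  structure(list(height = height, smoke_depth = depth,
                 co = co_acc, cross = cross_acc,
                 co_total = sum(co_acc), cross_total = sum(cross_acc),
                 ledger = ledger, n_photons = n,
                 extent = config$extent, bins = bins),
            class = "detector_grid")
}

#' @export
print.detector_grid <- function(x, ...) {
  cat(sprintf("Detector grid at height %g cm (smoke depth %g cm)\n",
              x$height, x$smoke_depth))
  cat(sprintf("  co total = %.4f, cross total = %.4f (of %d photons)\n",
              x$co_total, x$cross_total, x$n_photons))
  cat(sprintf("  ledger: detected %.4f, absorbed %.4f, side %.4f, terminated %.4f\n",
              x$ledger["detected"], x$ledger["absorbed"],
              x$ledger["side_escaped"], x$ledger["terminated"]))
  invisible(x)
}

#' Central-region radiance of a detector grid
#'
#' Mean radiance in the central `frac` x `frac` region of the grid,
#' mirroring the "brightest central region" readout of backscattering
#' simulations.
#'
#' @param grid A `detector_grid`.
#' @param channel `"co"` or `"cross"`.
#' @param frac Side fraction of the central window (default 0.1).
#' @return Scalar mean radiance per bin.
#' @export
central_radiance <- function(grid, channel = c("co", "cross"), frac = 0.1) {
  channel <- match.arg(channel)
  b <- grid$bins
  w <- max(1L, round(b * frac))
  lo <- floor((b - w) / 2) + 1L
  sel <- lo:(lo + w - 1L)
  mean(grid[[channel]][sel, sel])
}
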