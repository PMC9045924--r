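#' Mie scattering solution for a homogeneous sphere
#'
#' Computes scattering and extinction efficiencies, the asymmetry parameter
#' \eqn{g} (mean cosine of the scattering angle), the scattering
#' cross-section, and tabulated scattering-matrix elements for a sphere of
#' given diameter illuminated at a given wavelength, using the
#' Bohren--Huffman recurrences with the Wiscombe series truncation
#' \eqn{N = x + 4x^{1/3} + 2}.
#'
#' Smoke-particle optical tables in the surgical-smoke literature are
#' usually produced with the particle treated as non-absorbing in the Mie
#' call (absorption is specified separately as a bulk absorption
#' coefficient of the medium). `absorbing_sphere = FALSE`, the default,
#' follows that convention and runs the series with `Re(particle_index)`
#' only; set it to `TRUE` for the full absorbing-sphere solution, in which
#' case `q_abs > 0`.
#'
#' @param diameter Sphere diameter in micrometres. Must be positive.
#' @param wavelength Vacuum wavelength in micrometres. Must be positive.
#' @param particle_index Complex refractive index of the particle
#'   (e.g. `complex(real = 1.57, imaginary = 0.4277)`).
#' @param medium_index Real refractive index of the host medium
#'   (default 1.0, air). Must be >= 1.
#' @param n_angles Number of scattering angles tabulated uniformly on
#'   \eqn{[0, \pi]} (default 181). Must be >= 2.
#' @param absorbing_sphere Logical; run the series with the full complex
#'   index (`TRUE`) or its real part only (`FALSE`, default; see Details).
#'
#' @return An object of class `mie_result`: a list with elements
#'   `size_parameter`, `q_sca`, `q_abs`, `q_ext`, `anisotropy_g`,
#'   `sigma_sca` (um^2), `angle_grid` (radians), and `phase_matrix`, a
#'   list of numeric vectors `S11`, `S12`, `S33`, `S34` on `angle_grid`,
#'   normalized so that \eqn{2\pi \int S_{11}(\theta)\sin\theta\,
#'   d\theta = 1}.
#'
#' @examples
#' m <- compute_mie(0.2, 0.630, complex(real = 1.57, imaginary = 0.4277))
#' m$anisotropy_g
#' @export
compute_mie <- function(diameter, wavelength, particle_index,
                        medium_index = 1.0, n_angles = 181L,
                        absorbing_sphere = FALSE) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("`diameter` must be a single positive number (um)")
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("`wavelength` must be a single positive number (um)")
  if (!is.numeric(medium_index) || medium_index < 1)
    stop("`medium_index` must be a real number >= 1")
  if (n_angles < 2) stop("`n_angles` must be >= 2")
  m_full <- as.complex(particle_index) / medium_index
  m <- if (absorbing_sphere) m_full else complex(real = Re(m_full))

  x <- pi * diameter * medium_index / wavelength
  co <- mie_coefficients(x, m)
  eff <- mie_efficiencies(x, co$a, co$b)

  theta <- seq(0, pi, length.out = n_angles)
  amp <- mie_amplitudes(theta, co$a, co$b)
  S11 <- 0.5 * (Mod(amp$S2)^2 + Mod(amp$S1)^2)
  S12 <- 0.5 * (Mod(amp$S2)^2 - Mod(amp$S1)^2)
  S33 <- Re(amp$S2 * Conj(amp$S1))
  S34 <- Im(amp$S2 * Conj(amp$S1))
  # normalize so the phase function integrates to 1 over the sphere
  norm <- 2 * pi * trapz(theta, S11 * sin(theta))
  phase <- lapply(list(S11 = S11, S12 = S12, S33 = S33, S34 = S34),
                  function(v) v / norm)

  structure(list(
    size_parameter = x,
    q_sca = eff$q_sca,
    q_abs = eff$q_ext - eff$q_sca,
    q_ext = eff$q_ext,
    anisotropy_g = eff$g,
    sigma_sca = eff$q_sca * pi * (diameter / 2)^2,
    angle_grid = theta,
    phase_matrix = phase,
    diameter = diameter,
    wavelength = wavelength,
    particle_index = m_full * medium_index,
    medium_index = medium_index,
    n_terms = co$n_terms
  ), class = "mie_result")
}

# Mie series coefficients a_n, b_n (Bohren & Huffman, logarithmic
# derivative by downward recurrence). x: size parameter; m: relative index.
mie_coefficients <- function(x, m, nmax = NULL) {
  if (is.null(nmax)) nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  nmax <- as.integer(nmax)
  nmx <- as.integer(max(nmax, ceiling(Mod(m * x))) + 16L)
  mx <- m * x
  D <- complex(length.out = nmx + 1L)
  for (n in nmx:1) D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)

  a <- complex(length.out = nmax)
  b <- complex(length.out = nmax)
  psi_nm1 <- cos(x); chi_nm1 <- -sin(x)   # order -1
  psi_n <- sin(x);   chi_n <- cos(x)      # order 0
  for (k in seq_len(nmax)) {
    psi_k <- (2 * k - 1) / x * psi_n - psi_nm1
    chi_k <- (2 * k - 1) / x * chi_n - chi_nm1
    xi_k <- complex(real = psi_k, imaginary = -chi_k)
    xi_km1 <- complex(real = psi_n, imaginary = -chi_n)
    Dk <- D[k + 1L]
    fa <- Dk / m + k / x
    fb <- Dk * m + k / x
    a[k] <- (fa * psi_k - psi_n) / (fa * xi_k - xi_km1)
    b[k] <- (fb * psi_k - psi_n) / (fb * xi_k - xi_km1)
    psi_nm1 <- psi_n; chi_nm1 <- chi_n
    psi_n <- psi_k; chi_n <- chi_k
  }
  if (any(!is.finite(Re(a))) || any(!is.finite(Re(b))))
    stop("Mie series failed to converge after ", nmax, " terms")
  list(a = a, b = b, n_terms = nmax)
}

mie_efficiencies <- function(x, a, b) {
  n <- seq_along(a)
  q_sca <- (2 / x^2) * sum((2 * n + 1) * (Mod(a)^2 + Mod(b)^2))
  q_ext <- (2 / x^2) * sum((2 * n + 1) * Re(a + b))
  nm1 <- n[-length(n)]
  cross <- sum(nm1 * (nm1 + 2) / (nm1 + 1) *
                 Re(a[nm1] * Conj(a[nm1 + 1]) + b[nm1] * Conj(b[nm1 + 1])))
  self <- sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- (4 / (x^2 * q_sca)) * (cross + self)
  list(q_sca = q_sca, q_ext = q_ext, g = g)
}

# Amplitude functions S1(theta), S2(theta) via pi_n/tau_n recurrences,
# vectorized over angles.
mie_amplitudes <- function(theta, a, b) {
  mu <- cos(theta)
  nmax <- length(a)
  S1 <- complex(length.out = length(mu))
  S2 <- complex(length.out = length(mu))
  pi_nm1 <- rep(0, length(mu))  # pi_0
  pi_n <- rep(1, length(mu))    # pi_1
  for (n in seq_len(nmax)) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    f <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + f * (a[n] * pi_n + b[n] * tau_n)
    S2 <- S2 + f * (a[n] * tau_n + b[n] * pi_n)
    pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
    pi_nm1 <- pi_n
    pi_n <- pi_np1
  }
  list(S1 = S1, S2 = S2)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' @export
print.mie_result <- function(x, ...) {
  cat("Mie scattering result\n")
  cat(sprintf("  d = %g um, lambda = %g um, x = %.4f, m = %g%+gi (medium %g)\n",
              x$diameter, x$wavelength, x$size_parameter,
              Re(x$particle_index), Im(x$particle_index), x$medium_index))
  cat(sprintf("  Qsca = %.6f  Qabs = %.6f  Qext = %.6f\n",
              x$q_sca, x$q_abs, x$q_ext))
  cat(sprintf("  g = %.4f  sigma_sca = %.6g um^2  (%d series terms, %d angles)\n",
              x$anisotropy_g, x$sigma_sca, x$n_terms, length(x$angle_grid)))
  invisible(x)
}

#' Scattering coefficient of a particle suspension
#'
#' Multiplies the Mie scattering cross-section by the particle number
#' density and converts to cm^-1 (1 um^-1 = 1e4 cm^-1).
#'
#' @param result A `mie_result` from [compute_mie()] or
#'   [polydisperse_mie()].
#' @param number_density Particles per cubic micrometre. Must be >= 0.
#' @return Scattering coefficient \eqn{\mu_s} in cm^-1.
#' @examples
#' m <- compute_mie(0.2, 0.630, 1.57 + 0.4277i)
#' scattering_coefficient(m, 2e-3)
#' @export
scattering_coefficient <- function(result, number_density) {
  stopifnot(inherits(result, "mie_result"))
  if (!is.numeric(number_density) || number_density < 0)
    stop("`number_density` must be >= 0 (particles/um^3)")
  result$sigma_sca * number_density * 1e4
}

#' Truncated Gaussian particle-size distribution
#'
#' Samples a Gaussian number distribution of sphere diameters on a uniform
#' grid spanning mean +/- 4 standard deviations, truncated below at
#' `max(mean - 4 sd, mean/100)` so all diameters stay positive, with
#' weights proportional to the Gaussian density and renormalized to sum
#' to 1.
#'
#' @param mean_diameter Mean diameter, um. Must be positive.
#' @param cv Coefficient of variation (sd/mean), in `[0, 1)`. `cv = 0`
#'   collapses to a single diameter.
#' @param n_points Number of sampled diameters (default 1001).
#' @return An object of class `size_distribution`: list with `diameters`,
#'   `weights`, `mean_diameter`, `coefficient_of_variation`, `n_points`.
#' @examples
#' d <- gaussian_size_distribution(3.0, 0.3, 1001)
#' sum(d$weights)
#' @export
gaussian_size_distribution <- function(mean_diameter, cv, n_points = 1001L) {
  if (!is.numeric(mean_diameter) || mean_diameter <= 0)
    stop("`mean_diameter` must be positive")
  if (!is.numeric(cv) || cv < 0 || cv >= 1)
    stop("`cv` must be in [0, 1): cv >= 1 makes negative diameters unavoidable")
  if (n_points < 1) stop("`n_points` must be >= 1")
  if (cv == 0 || n_points == 1L) {
    d <- mean_diameter
    w <- 1
  } else {
    sd <- mean_diameter * cv
    lo <- max(mean_diameter - 4 * sd, mean_diameter / 100)
    hi <- mean_diameter + 4 * sd
    d <- seq(lo, hi, length.out = n_points)
    w <- stats::dnorm(d, mean_diameter, sd)
    w <- w / sum(w)
  }
  structure(list(diameters = d, weights = w,
                 mean_diameter = mean_diameter,
                 coefficient_of_variation = cv,
                 n_points = length(d)),
            class = "size_distribution")
}

#' Effective Mie properties of a polydisperse suspension
#'
#' Combines per-diameter Mie solutions over a [gaussian_size_distribution()]
#' (or any `size_distribution`). Efficiencies and the scattering
#' cross-section are number-weighted means; the effective anisotropy `g`
#' and the phase-matrix tables are weighted by each size's scattering
#' cross-section (the radiative-transfer convention: large particles
#' scatter more light, so they dominate the angular distribution).
#'
#' @param dist A `size_distribution`.
#' @param wavelength,particle_index,medium_index,n_angles,absorbing_sphere
#'   As in [compute_mie()].
#' @param g_weighting `"scattering"` (default, sigma_sca-weighted) or
#'   `"number"` for a plain number-weighted mean of per-size `g`.
#' @return A `mie_result` with effective properties; `size_parameter` is
#'   the number-weighted mean size parameter.
#' @examples
#' d <- gaussian_size_distribution(3.0, 0.3, 101)
#' p <- polydisperse_mie(d, 0.630, 1.57 + 0.4277i, n_angles = 91)
#' p$anisotropy_g
#' @export
polydisperse_mie <- function(dist, wavelength, particle_index,
                             medium_index = 1.0, n_angles = 181L,
                             absorbing_sphere = FALSE,
                             g_weighting = c("scattering", "number")) {
  stopifnot(inherits(dist, "size_distribution"))
  g_weighting <- match.arg(g_weighting)
  n <- length(dist$diameters)
  q_sca <- q_ext <- g <- sig <- xs <- numeric(n)
  nterms <- 0L
  phase_acc <- NULL
  theta <- NULL
  for (i in seq_len(n)) {
    r <- compute_mie(dist$diameters[i], wavelength, particle_index,
                     medium_index, n_angles, absorbing_sphere)
    q_sca[i] <- r$q_sca; q_ext[i] <- r$q_ext
    g[i] <- r$anisotropy_g; sig[i] <- r$sigma_sca
    xs[i] <- r$size_parameter
    nterms <- max(nterms, r$n_terms)
    wph <- dist$weights[i] * sig[i]
    if (is.null(phase_acc)) {
      theta <- r$angle_grid
      phase_acc <- lapply(r$phase_matrix, function(v) v * wph)
    } else {
      phase_acc <- Map(function(acc, v) acc + v * wph, phase_acc,
                       r$phase_matrix)
    }
  }
  w <- dist$weights
  wsig <- w * sig
  phase <- lapply(phase_acc, function(v) v / sum(wsig))
  g_eff <- if (g_weighting == "scattering") sum(wsig * g) / sum(wsig)
           else sum(w * g)
  q_sca_eff <- sum(w * q_sca)
  q_ext_eff <- sum(w * q_ext)
  structure(list(
    size_parameter = sum(w * xs),
    q_sca = q_sca_eff,
    q_abs = q_ext_eff - q_sca_eff,
    q_ext = q_ext_eff,
    anisotropy_g = g_eff,
    sigma_sca = sum(wsig),
    angle_grid = theta,
    phase_matrix = phase,
    diameter = dist$mean_diameter,
    wavelength = wavelength,
    particle_index = as.complex(particle_index),
    medium_index = medium_index,
    n_terms = nterms,
    distribution = dist
  ), class = "mie_result")
}

#' Export phase-matrix tables as plain text
#'
#' Writes one two-column (angle in degrees, value) whitespace-separated
#' file per scattering-matrix element, for external inspection.
#'
#' @param result A `mie_result`.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix (default `"phase"`).
#' @return Invisibly, the paths written.
#' @export
export_phase_table <- function(result, dir, prefix = "phase") {
  stopifnot(inherits(result, "mie_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  deg <- result$angle_grid * 180 / pi
  paths <- character(0)
  for (el in names(result$phase_matrix)) {
    p <- file.path(dir, sprintf("%s_%s.txt", prefix, el))
    utils::write.table(data.frame(angle_deg = deg,
                                  value = result$phase_matrix[[el]]),
                       p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
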