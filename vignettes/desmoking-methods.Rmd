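---
title: "Polarization-difference smoke removal: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarization-difference smoke removal: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desmokeR)
```

## The problem and the model

Electrocautery smoke sits between the camera and the tissue at an almost
constant working distance, so the classic outdoor haze model
`t = exp(-beta d)` (attenuation growing with scene *depth* `d`) is the
wrong parameterization: depth barely varies, while the smoke density
varies a lot. desmokeR therefore drives the attenuation with the smoke's
optical depth. Writing `u(x) = beta * tau(x)` for the per-pixel optical
thickness, every polarization channel degrades as

    I(x) = J(x) exp(-u(x)) + A (1 - exp(-u(x)))

where `J` is the smoke-free radiance and `A` is the ambient light at
infinite optical depth — the colour an infinitely thick smoke layer
presents to the camera.

Under linearly polarized illumination the scene is a two-layer medium:
the smoke layer backscatters light that largely keeps the illumination
polarization, while light that reaches the tissue and returns has been
scrambled by multiple scattering. Writing `Ico`/`Icro` for the co- and
cross-polarized channels and assuming (i) the object radiance is nearly
unpolarized (`Jco ~ Jcro`) and (ii) the smoke's ambient term is strongly
co-polarized (`Acro << Aco`), the polarization difference

    Ico(x) - Icro(x) = Aco (1 - exp(-u(x)))

isolates the smoke term, so the per-pixel transmission is

    t(x) = 1 - (Ico(x) - Icro(x)) / Aco

computed independently per colour channel (smoke attenuates the three
channels differently), and the restored image doubles the restored
cross channel:

    J(x) = 2 (Icro(x) - Acro) / t(x) + 2 Acro.

When assumptions (i)–(ii) hold exactly — a depolarized scene and a fully
co-polarized smoke ambient light — this chain is the algebraic inverse
of the degradation and the round trip is exact to numerical precision
(the package tests assert `< 1e-10`). On polarized scenes (`Jco != Jcro`)
the difference picks up a scene term and the recovered `t` is biased;
this is the method's intrinsic approximation, and the DOP-restoration
tests measure exactly how much of the polarization structure survives it.

## Why the assumptions are reasonable: the polarized Monte Carlo module

`run_simulation()` is a Stokes-vector Monte Carlo simulation of a pencil
beam of horizontally polarized light (Stokes `(1, 1, 0, 0)`) incident on
a smoke slab over tissue. Photons carry an explicit orthonormal
reference frame; scattering draws the polar angle from the
azimuth-integrated phase function `S11(theta) sin(theta)` by inverse
CDF and the azimuth from the polarization-dependent conditional density
`1 + (S12/S11)(s1 cos 2phi + s2 sin 2phi)` by rejection (envelope 2).
The Stokes vector is rotated into the scattering meridian, multiplied by
the sphere scattering matrix `(S11, S12, S33, S34)`, and renormalized so
that `s0 = 1` with radiometric weight carried separately — the draw is
from the correct joint density, so renormalization is the unbiased
update. Detection rotates each exiting photon's frame onto the
laboratory frame of the launch polarization and accumulates
`(s0 + s1)/2` (co) and `(s0 - s1)/2` (cross) on a 25 cm x 25 cm,
100 x 100 grid.

Smoke optics come from the Mie module. For the two reference particle
sizes (0.2 um and 6.0 um at 0.630 um, particle index 1.57 + 0.4277i in
air) the simulated slab reproduces the qualitative behaviour the model
needs: the co-polarized channel dominates the backscattered radiance at
every depth, the central co radiance decays with medium depth, and the
total degree of polarization of the detected light decreases as the
slab deepens.

**Tissue model.** The authors' exact tissue treatment is not public, so
the tissue is a stand-in: a Fresnel specular pre-step at the
smoke/tissue interface (n = 1.50) followed, with probability
`tissue_albedo` (default 0.6), by Lambertian re-emission. A fully
depolarizing re-emission turned out to contradict the physics the
simulation is supposed to demonstrate: if every tissue bounce erases
polarization, the depolarized tissue return fades with depth *faster*
than the polarization-maintaining smoke backscatter, and the total DOP
*rises* with smoke depth instead of falling. Directly reflected
illumination in the real system keeps most of its polarization, so
`layered_medium()` exposes `tissue_depolarization` (fraction of the
polarization lost per diffuse bounce), default 0.3; depth-dependent
depolarization is then accrued in the smoke, as observed. Setting
`tissue_depolarization = 1` recovers the fully depolarizing reflector.

Side boundaries terminate photons (counted as side escapes); Russian
roulette below weight 1e-4 (survival 0.1) bounds the runtime; the energy
ledger (detected + absorbed + side-escaped + terminated = launched) is
exact by construction and asserted to 1e-6. One seeded R RNG stream
drives a fully vectorized photon batch, so a fixed seed reproduces the
accumulators bit for bit.

## Mie scattering

`compute_mie()` implements the Bohren–Huffman recurrences (downward
logarithmic derivative, Wiscombe truncation `x + 4 x^(1/3) + 2`) and
tabulates the four independent scattering-matrix elements on a uniform
angle grid, normalized so `2 pi * integral(S11 sin theta) = 1`.

**Index convention.** The reference smoke tables list a complex particle
index *and* a separate bulk absorption coefficient. They are reproduced
only when the Mie series runs with the real part of the index (the
particle treated as non-absorbing, absorption specified separately):
that convention gives g = 0.2050 / 0.7245 and mu_s = 0.1729 / 0.6205
cm^-1 against the tabulated 0.2052 / 0.7324 and 0.1737 / 0.6230, all
inside the stated tolerances, whereas the full absorbing-sphere solution
gives g = 0.2197 / 0.9180. `absorbing_sphere = FALSE` is therefore the
default, with the full complex solution available behind the flag.

**Polydispersity.** `gaussian_size_distribution()` samples a Gaussian
number distribution of diameters on a uniform grid over mean +/- 4 sd,
truncated at `max(mean - 4 sd, mean/100)` to keep diameters positive.
`polydisperse_mie()` averages efficiencies and cross-sections with
number weights, and the anisotropy and phase matrix with
`sigma_sca`-weights — the radiative-transfer convention, since large
particles scatter disproportionately more light; a number-weighted `g`
is available via `g_weighting = "number"`. For the reference
distribution (mean 3.0 um, CV 0.3, 1001 points) this yields g = 0.7263
against the tabulated 0.7253.

## The synthetic world

`generate_scene()` emits a smoke-free polarimetric pair with exact
ground truth: scene radiance `J` split as `Jco = J (1 + p)/2`,
`Jcro = J (1 - p)/2` so the two-channel DOP returns `p` identically.
Scene kinds: a colour-checker-style patch grid (with guaranteed
near-black and near-white patches), soft colour blobs, and a reddish
vessel-textured surface emulating an organ. `generate_optical_depth()`
produces the per-pixel `u`: constant, Gaussian plumes over a thin
ambient haze, or exponentiated multiscale noise, the latter two rescaled
to an exact spatial mean. `degrade()` applies the two-term model per
pixel, channel, and polarization state, with optional additive Gaussian
sensor noise (default 0).

Default world parameters and why:

* airlight co `(0.62, 0.58, 0.55)` — a bright, slightly warm grey,
  typical of white-light illumination scattered by fog-like media;
* cross airlight `0.25 x` the co airlight (airlight DOP 0.6) — the MC
  module shows smoke backscatter is strongly co-polarized; the exact
  round-trip tests use a fully co-polarized airlight (cross = 0), the
  regime in which the difference model is exact;
* smoke levels `u in {2.0, 1.5, 1.0, 0.6, 0.3}` — spanning heavy to
  mild smoke, mirroring a five-level concentration series;
* images 128–256 px, enough for 64-colour clustering to be meaningful
  while keeping the tests fast.

What the generator does *not* emulate: forward-scattering blur
(the model treats smoke as a purely multiplicative/additive screen),
sensor nonlinearity and demosaicing, misregistration between the
polarization channels, and shot noise. A green test therefore
establishes correctness of the model chain and robustness of the
estimators within this world, not end-to-end camera fidelity. Images
are treated as linear radiance throughout; no gamma decoding is applied
at the I/O boundary (the CIEDE2000 metric, which is defined on sRGB,
applies the sRGB companding as part of its own colour conversion).

## Airlight estimation

`estimate_airlight()` follows the haze-line scheme: (1) quantize the
image to 64 colours (deterministic seeded k-means over at most 20000
deterministically subsampled pixels); (2) project cluster centres onto
the RB, GB, RG planes; (3) Hough-vote on a 64 x 64 candidate grid per
plane. The voting treats every sufficiently separated *pair* of cluster
centres as a candidate haze line: a candidate receives the pair's
count-product weight when it lies within half a grid cell of the line,
outside the segment. Votes are binned into 90 line-direction bins and
the score is the sum of `sqrt(bin mass)`, so many distinct converging
directions beat a single heavily populated line — without this, the
neutral axis of a colour chart or the near-parallel shading lines of a
smooth scene drown the true convergence point. Candidates darker than
the per-channel pixel median are excluded (thick smoke cannot present a
colour darker than the bulk of the frame; this also removes the false
convergence point of shading lines near the origin). The three planes
are combined by a joint RGB argmax over the normalized plane
accumulators (each channel is constrained by both planes containing
it), followed by a vote-weighted 3 x 3 centroid refinement.

Identifiability caveat: under *spatially uniform* smoke every scene
colour collapses to a single point, haze lines degenerate, and no
estimator of this family can recover the airlight; the tests use mildly
inhomogeneous smoke, which is also the realistic regime. On the
synthetic checker world the estimate lands within 0.01–0.04 per channel
of the true airlight at moderate smoke.

The cross-channel airlight is *not* estimated by haze lines: it is dim
(smoke backscatter is co-polarized) and usually darker than the scene,
which defeats the voting. `desmoke()` instead reads it off the
smokiest pixels — the `(1 - t)^4`-weighted mean of the cross image —
which converges to the ambient light at infinite optical depth, its
defining property.

## Numerical choices

* `t_min = 0.05` bounds the transmission from below (standard dehazing
  practice; caps the `1/t` amplification in the reconstruction).
* Negative polarization differences (possible with sensor noise) clamp
  to zero.
* A single transmission map drives the restoration of both polarization
  channels: in the model, smoke transmission is
  polarization-channel-agnostic.
* Radiance stays unclamped through the pipeline; clamping to `[0, 1]`
  happens at export (PNG quantization) and inside the metric suite.
* No smoothing is applied to the transmission map: each pixel is
  processed independently, which is what makes cropping commute with
  processing (asserted in the tests).
* PSNR uses peak 1.0 on normalized images by default with a 100 dB cap
  on identical inputs; a 255 peak is selectable to match 8-bit
  conventions. SSIM is the standard single-scale form (11 x 11 Gaussian
  window, sigma 1.5, K1 = 0.01, K2 = 0.03) on Rec. 601 luma, valid
  region only. CIEDE2000 implements the full formula (verified to 5e-5
  against the published 33-pair verification set and to 1e-10 against
  an independent step-by-step transcription in the test suite).
* DOP maps are computed per colour channel and averaged for scalar
  reporting; pixels with `Ico + Icro = 0` are flagged `NA`, never
  silently zeroed.

## Evaluating DOP restoration

A subtlety worth recording: with a *constant* ground-truth DOP map,
SSIM degenerates into a smoothness contest — its structure term
penalizes any variance against a zero-variance reference, so a smooth
degraded map can outscore a restoration that is demonstrably closer in
PSNR. The DOP-restoration tests therefore use the generator's
spatially varying DOP option (mean 0.3), which is also what a real
sample's polarization structure looks like and what SSIM is meant to
measure. Under moderate inhomogeneous smoke with known airlight the
restored DOP map beats the degraded one in both SSIM and PSNR
consistently across seeds.

## Known limitations

* Heavy smoke: the cross channel is itself increasingly contaminated,
  the polarization difference underestimates the smoke term, and
  residual haze survives restoration — reported, not corrected.
* Uniform smoke defeats haze-line airlight estimation (see above);
  supply `airlight_co`/`airlight_cross` explicitly in that regime.
* The MC tissue model is a documented stand-in validated against
  qualitative behaviour only.
* The PNG codec supports 8/16-bit grey/RGB non-interlaced files (alpha
  dropped on read); interlaced and paletted files are rejected.
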