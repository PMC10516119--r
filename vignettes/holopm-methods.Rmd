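---
title: "Methods: lensfree holographic particle sensing in holopm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lensfree holographic particle sensing in holopm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holopm)
```

# The measurement

A lensfree in-line holographic air-quality sensor has no imaging optics at
all: a partially coherent LED (528 ± 15 nm, spatially filtered by a
pinhole) illuminates aerosol particles that have settled onto a thin
vapor-condensed polyethylene-glycol (PEG) film resting ~1 mm above a
monochrome CMOS sensor with 1.67 µm pixels. The sensor records the
interference between the unscattered background and the light scattered by
each particle — an in-line hologram — at unit magnification over the whole
sensor area. Numerical back-propagation of that hologram reconstructs a
complex field at the object plane whose *phase* channel carries the
particle signal.

Two physical ideas make sub-pixel particles measurable:

* **Nanolensing.** A bare 100 nm sphere scatters far too weakly to register
  against sensor noise. On a liquid PEG film, however, surface tension pulls
  a meniscus up around each particle within seconds of landing. This
  "nanolens" enlarges the effective scattering cross section by orders of
  magnitude, lifting 100 nm particles above the noise floor.
* **Integrative sensing.** Particles remain on the film unless actively
  wiped off. Cumulative counts therefore only grow, and the instantaneous
  PM level each hour is the *difference* in counts against the previous
  hour.

The sizing observable is the **peak phase** φ_pk of a particle in the
focused reconstruction: larger particles (with their larger menisci) imprint
larger phase maxima, and a fitted calibration curve maps measured peak phase
to physical diameter.

# Forward model (the synthetic-data generator)

Every downstream stage is testable against ground truth because the package
generates its own data. The generator emulates the device's physics at the
level the processing chain actually consumes.

## Phase objects on an evaporating film

A scene of deposited particles is a unit-amplitude transmittance
`exp(i φ(x, y))`, where φ is a sum of radially symmetric, compactly
supported bumps (a cos² kernel), one per particle. Each bump peaks at the
particle's ground-truth phase and has lateral radius
`meniscus_width_factor × particle radius` (default factor 10), floored at
two pixels: the meniscus halo is what makes a sub-pixel particle visible,
and it never collapses below the sensor sampling. The full Young–Laplace
meniscus shape is deliberately not solved — the pipeline only consumes the
peak phase and lateral scale of the perturbation, so a parametric bump with
exactly controllable ground truth is the better test instrument.

The **ground-truth phase–diameter relation** is the invertible three-
parameter curve `D = A (φ_pk − C)^B` with defaults A = 1300 nm/rad, B = 1,
C = 0.02 rad — linear in diameter, because to first order the nanolens peak
optical path grows in proportion to particle size. It spans ~0.1 rad at
100 nm to ~1.9 rad at 2.5 µm (the PM2.5 range); particles approaching 10 µm
need a user-supplied curve, enforced by the (0, π) phase invariant at
construction. Using the same functional family as the sizing calibration
makes calibration recovery exactly testable.

## Film evaporation

PEG evaporates. The film thickness decays exponentially,
`h(t) = h₀ e^(−t/τ)`, with defaults h₀ = 110 nm (a 5-minute deposition) and
τ = 48 h, which holds the film near the ~50 nm optimum for a day or two. A
particle's signal retention is modeled as

```
retention(d, t) = (h(t)/h₀)^(s · (200 nm / d)²),    s = 8 by default
```

— a few nanometres of lost film is a large fraction of a small particle's
meniscus, so the smallest particles lose signal first. With the defaults,
200 nm particles fall below the detection floor after about one day
(retention 0.018 at 24 h), 500 nm particles fade around day six, and 1 µm
particles persist (retention 0.85 at 24 h). The film-age helper
`check_film_age()` warns when sub-200 nm sizing is attempted on a film older
than a day.

## Partial coherence, sensor noise

The hologram intensity is an incoherent average over 5 wavelengths spanning
the source FWHM (528 ± 15 nm), with the thin object's phase scaled by
λ₀/λ per wavelength. This is the cheapest model that reproduces the
fringe-contrast loss of an LED source. The detector applies a gain that
places the unit background at 45% of full scale, optional Poisson shot
noise, additive Gaussian read noise (default 1 count), and quantization to
8 or 16 bits. All randomness derives from explicit seeds; rendering is
bit-reproducible.

## Deposition over time

A field deployment draws air at Q = 4.5 L/min; a fraction η of the drawn
particles lands in the imaged area. Deposits per 10-minute epoch are Poisson
with mean `concentration / mean_mass × Q t_epoch × η` — linear in
concentration, which is the assumption behind converting captured to ambient
mass. Placement is uniform with a minimum center-to-center distance of one
particle footprint (10 px), keeping ground truth unambiguous; at full-device
particle counts (manifest-only runs) placement samples distinct footprint
cells instead of rejection sampling. Twenty frames are rendered per epoch
and averaged, as the device does.

The default field-day size distribution is lognormal with median 600 nm and
geometric standard deviation 1.6 — an accumulation-mode aerosol whose
mass-effective diameter (~830 nm) is consistent with a deposition rate of
order 10³ particles/h at 6 µg/m³ for η ≈ 1.9×10⁻⁴. Because η is the
fraction of drawn particles landing in the *imaged* area, simulations on a
desk-scale sensor scale η by the area ratio of the simulated frame to the
10-megapixel device sensor.

# Reconstruction

## Angular spectrum propagation

`propagate_asm()` is the exact spectral operator: FFT the field, multiply by
`exp(i z √(k² − kₓ² − k_y²))`, zero the evanescent band (kₓ² + k_y² > k²),
inverse FFT. Evanescent zeroing is a hard cut: at z ≈ 600 wavelengths the
evanescent content is numerically nil, and the cut keeps the operator
exactly unitary on the propagating band, so `propagate(+z)` followed by
`propagate(−z)` is an identity to machine precision — a property the test
suite asserts on random fields. (At the device sampling of 1.67 µm ≫ λ/2
the FFT band contains no evanescent components at all.)

The operator refuses distances beyond
`N·Δx²/λ · √(1 − (λ/2Δx)²)`, where the transfer-function phase would alias
on the N-point grid.

Rendering, back-propagation, and twin removal wrap this operator with 2×
zero-padding (constant background fill, cropped afterwards) to suppress
wrap-around fringes from particles near the frame edge. The padding lives
in the wrappers rather than in `propagate_asm()` itself because a pad+crop
inside a round trip would destroy the exact unitarity that the raw operator
guarantees.

## Back-propagation and autofocus

A single-shot in-line hologram records intensity only; the reconstruction
takes `√intensity` as the field amplitude with zero sensor-plane phase (the
standard assumption), propagates by −z, and references the phase to the
spatial mean so the background sits at zero.

`autofocus()` mirrors the device procedure of back-propagating until the
phase of a particle is maximized: a 25-step coarse scan over the search
range followed by bounded golden-section/Brent refinement to sub-2 µm
tolerance. The focus metric is the **mean of the 9 largest relative-phase
pixels**. A quantile-based metric (e.g. the 99.9th percentile) fails at
desk-scale frame sizes: on a 128² frame the top 0.1% spans ~16 pixels,
more than an in-focus particle core occupies, so the percentile is dominated
by defocused fringes and peaks *away* from focus. The top-9 mean is the same
robust-peak idea at the correct concentration scale — insensitive to a
single hot pixel, concentrated enough to peak sharply at focus.

**Accuracy and limitations.** Two systematic effects displace the
phase-maximum plane from the object plane:

* strong scatterers (φ_pk ≳ 0.5 rad, i.e. µm-size particles) break the
  weak-object approximation; twin-image interference and the √intensity
  nonlinearity shift the apparent focus by up to ~1% toward the sensor;
* on small simulated frames the interference rings (radius ~100 px at
  z = 1 mm) truncate at the frame edge, adding a position-dependent shift —
  an artifact of desk-scale frames that the 10-megapixel device does not
  have.

Autofocus accuracy is therefore specified in the weak-scattering regime on
fringe-containing frames (frame side ≳ 2.5× the fringe extent, particles
placed within the central half): there the recovered distance is within
0.35% of truth across z ∈ {600, 1000, 1600} µm, against a 0.5% target.
Sizing is insensitive to the residual shift because the bead calibration
passes through the same measurement chain, and the phase maximum is flat at
its own optimum.

# Detection and sizing

## Five-threshold iterative detection

Detection loops over five strictly decreasing phase thresholds. The default
schedule is geometric from 0.9× the maximum phase down to 3× the robust
noise level (the scaled median absolute deviation of the phase image, which
sparse particles barely perturb); an image whose maximum does not clear 5×
the MAD — about the expected extreme of pure Gaussian noise on these grids —
is rejected as "no signal".

Each pass: refocus near the distance hint, threshold the phase image, label
connected components (via `EBImage::bwlabel`), discard components touching
the border, record one detection per component (phase-weighted subpixel
centroid, component maximum as peak phase, the pass index at which it first
appeared), then *remove* each detected particle and its twin from the raw
hologram before the next, lower threshold. Removal is what lets faint
particles emerge: the fringes of a 1 µm particle would otherwise bury a
100 nm neighbour. Detections within one footprint of an already accepted one
are treated as residuals of the same particle (nearer-centroid
tie-breaking), so each particle is reported exactly once.

## Twin-image removal

The reconstruction of an in-line hologram contains each particle twice: the
focused image at +z and a conjugate "twin" focused at the mirror plane,
spread into defocused fringes at +z. Removing only the focused core would
leave half the particle's energy in the hologram. `remove_particle_and_twin()`
therefore inpaints at *both* conjugate planes: back-propagate to the object
plane and replace the particle's disk (radius 3× the component's equivalent
radius, minimum 5 px, feathered with a cos² taper to avoid ringing) by the
local background field (complex mean over a surrounding annulus); propagate
to the twin's focal plane and inpaint the conjugate image the same way;
return to the sensor and take the intensity. Because the sensor projection
to intensity discards the small residual phase, the sweep is applied twice
(a fixed-point iteration), after which re-applying the removal changes the
hologram by < 0.1%, pixels far from the detection change by well under 1%,
and the residual background variance is comparable to a particle-free
hologram.

## Phase-to-diameter calibration

The measured peak phase is systematically smaller than the object-plane
phase — the twin image carries half the signal energy and the finite source
bandwidth reduces fringe contrast, compressing measured phases to roughly a
third of ground truth. Exactly as with the physical device, the remedy is to
calibrate on beads of known size *through the same measurement chain*:
`calibrate_from_beads()` images a 100/200/300/500/1000 nm bead ladder on a
fresh film, measures each bead's focused peak phase, and fits
`D = A (φ_pk − C)^B` by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), refusing fits that are not strictly increasing on the
data's phase range. The functional form is pluggable (`form_id`;
an exponential alternative ships in the registry) since the power law is a
modeling choice, not a law. The power family is closed under multiplicative
phase compression, so a noiseless calibration recovers the generating
parameters exactly — one of the acceptance checks.

Phases outside the calibrated range are clamped to its ends and flagged.
In practice this affects ~100 nm particles, whose measured phase sits at the
edge of the calibrated range: they are reliably *detected*, but sized
coarsely. For d ≥ 200 nm the end-to-end RMS diameter error on simulated
scenes is ~7%.

Calibration phases are measured at film age zero and not drift-corrected;
sizing on films older than a day (for sub-200 nm work) is instead guarded by
the film-age warning.

# Quantification

Captured mass concentration over a collection window of t hours:

```
PM_cap = Σᵢ (π/6 · dᵢ³ · ρ) / (Q · t)      [µg/m³]
```

with ρ defaulting to polystyrene (1050 kg/m³) and d ≤ 2.5 µm for the
PM2.5-comparable value. The ambient concentration is `PM = PM_cap / η`.
η is assumed size-independent by default; `ambient_concentration()` accepts
a per-size-bin η vector for size-resolved matrices.

`estimate_eta()` fits η against a trusted reference series by the
through-origin criterion `min Σ(PM_cap/η − ref)²`, whose closed form is
`η̂ = Σ PM_cap² / Σ PM_cap·ref`. This is the natural estimator when the
reference carries the noise (e.g. ±0.5 µg/m³ rounding, which the reference
reader propagates as symmetric error bars); when the captured series itself
is noisy the estimator acquires an upward bias of order the captured
series' relative variance — negligible at full-device deposition rates
(~10³ particles/h), which is the scale the simulated field days use.

`sensor_capacity()` (total pixels over squared footprint) and
`saturation_forecast()` (linear accumulation anchored at a reference
condition) give the dynamic-range estimates: a 10-megapixel sensor at
10×10 px per particle holds 10⁵ particles; anchored at 10³ particles/h at
6 µg/m³ that is a 600 µg/m³ one-hour ceiling and 100 h to saturation at the
anchor concentration. `epa_metrics()` computes the air-sensor performance
measures: R² of the OLS fit of device against reference (target ≥ 0.70) and
the coefficient of variation over replicate readings (target ≤ 30%).

Hour alignment: epochs are 10 min, an hour is 6 consecutive epochs, epochs
belong to the hour containing their end time, and trailing partial hours are
dropped. The pipeline detects on the frame closing each hour (the
epoch-average, since the scene within an epoch is static up to noise) and
differences cumulative counts — and, for mass, differences per-particle
masses of newly appearing detections matched by position against the
previous hour.

# What the benchmarks do and do not show

The simulator covers: sub-pixel phase objects with size-dependent signal,
film-decay burial of small particles, partial coherence, shot/read noise and
quantization, Poisson deposition linear in concentration, integrative
accumulation, and reference rounding. Passing tests demonstrate the
*processing chain* is correct and self-consistent under these conditions.

It deliberately does not model: rigorous Mie scattering of sub-wavelength
spheres (the phase bump is parametric), vector fields, sensor MTF or color
filters, real-world debris and clumped deposits, flow-geometry
inhomogeneity of η, humidity effects on the film, or the film-rupture
reorganization occasionally seen on thick films after several days. Field
performance of a physical device — absolute η, R² against a regulatory
monitor, replicate CV — depends on exactly these unmodeled factors, so the
synthetic recoveries here validate the algorithms, not the hardware.

# Numerical choices and problem sizes

* Determinism: every stochastic step takes a seed; child seeds derive from
  a master seed; RNG state is restored after internal draws.
* Autofocus: 25-step coarse scan, Brent refinement with 0.5 µm tolerance;
  "no focusable signal" raised when the best metric does not clear 5× the
  phase MAD at the worst scanned distance.
* Calibration fit: `nlsLM` with tight (1e−15) tolerances, C bounded below
  the smallest observed phase, start values from a log-log regression.
* Degenerate inputs raise errors naming the offender: particles outside the
  field of view, decreasing cumulative counts, all-zero captured series,
  under-determined or single-diameter calibration data, RGB frames.
* Test and acceptance problem sizes (chosen to exercise the physics at
  desk scale): 128² px frames for detection scenes (10 particles,
  100 nm–1 µm), 192²–320² px fringe-containing frames for autofocus and
  sizing studies, 20 frames per epoch, 2–3 h rendered pipeline runs, and
  manifest-level 12 h field days at the full 10-megapixel device scale
  (~7,500 particles). The package itself has no size limits beyond memory
  and the ASM aliasing bound.
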