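---
title: "Conical whisker mechanics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conical whisker mechanics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conewhisk)
```

## The model

A whisker is an elastic truncated cone with no intrinsic curvature: base
radius `b`, conicity `α`, Young's modulus `E`, density `ρ`. Its untruncated
length is `L = b/α`, and positions along the shaft are expressed in the
dimensionless arc coordinate `s` — 0 at the *virtual* (untruncated) tip, 1 at
the base, with the physical tip at `s_tip`. The transverse displacement
`U(s, t)` obeys the Euler–Bernoulli equation for a cone,

$$\partial_s^2\!\left(s^4\, \partial_s^2 U\right) + k^2 s^2\, \partial_t^2 U = 0,
\qquad k = 2\,\frac{L}{\alpha}\sqrt{\rho/E},$$

and the sensory variable is the base torque
`M = E I(1) C = (Eπb⁴/4) · (1/L²) ∂²U/∂s²|₁`. `k` is the single timescale of
the free cone: all eigenvalues are dimensionless numbers `λᵢ` with
`ωᵢ = λᵢ/k`, so material properties enter the vibration spectrum only through
`k`. The displacement splits into a quasi-static equilibrium part plus a
dynamic part decomposed onto damped eigenmodes; everything is linear, so all
responses scale exactly with their drive.

Assumptions worth keeping in mind: small deflections (torque linear in
curvature), a rigid clamp at the base (no follicle compliance), uniform `E`
along the shaft, a single constant modal damping ratio, quasi point-like
frictionless contacts, and planar motion.

### Quasi-static solutions

For the two shock geometries (object translating at speed `V` into a fixed
whisker; whisker rotating at rate `γ` into a fixed object) the equilibrium
problem `(s⁴U″)″ = 0` has the closed forms implemented in
`qs_profile_fixed()` / `qs_profile_rotating()`. Their base-torque rates,

$$\frac{dM_{qs}}{d(Vt)} = \frac{3E\pi b^4}{4}\left(\frac{1}{d^2}-\frac{\alpha}{d\,b}\right),
\qquad
\frac{dM_{qs}}{d\varphi} = \frac{3E\pi b^4}{4}\left(\frac{1}{d}-\frac{\alpha}{b}\right),$$

are positive, strictly decreasing in the contact distance `d`, and vanish at
the virtual tip — hence invertible: `locate_radial()` recovers `d` from a
measured rate by bracketed bisection on `(10⁻⁶L, L(1−10⁻⁹))`, which is
guaranteed to converge because the forward map is monotone. In dimensionless
form every cone collapses onto `1/x² − 1/x` (`master_curve()`), which the
tests verify to 1e-10 for both presets: the identity is exact once `L = b/α`.
Both printed closed forms are sign-consistent: the rotating profile has base
slope `+Lγt` and *positive* base curvature `3ε/(1−ε)` per unit drive, so no
sign convention had to be imposed beyond "protraction into the object gives
positive torque".

### Eigenmodes

`(s⁴V″)″ = λ² s² V` is solved on `[ε, 1]` for a contact pinned at `ε`
(`V(ε) = V″(ε) = 0`, clamped base) and on `[s_tip, 1]` for the free tip
(`V″ = V‴ = 0` there). The pinned problem is posed on `[ε, 1]` only:
deflections distal to the contact do not load the base in this model, which
is also what the modal projection integrals (taken from `ε` to 1) imply.
Modes are normalised to `∫ s² Vᵢ² ds = 1` — the cone's mass weighting, the
only normalisation under which the modal projection formulas are
dimensionally consistent — with sign fixed by `V′ > 0` at the non-base end.

Two independent numerical routes are provided, and their agreement is itself
a test:

- **Direct spectral solver.** Differentiation-matrix collocation of the
  4th-order operator conditions like `N⁸` and, near the tip where `s⁴`
  degenerates, visibly corrupts the free-tip eigenvectors. The solver
  therefore works in *integration* form: with `u = V⁗` as the unknown, the
  expanded equation `s²V⁗ + 8sV‴ + 12V″ = λ²V` is discretised with Chebyshev
  antiderivative operators, and all four boundary conditions are absorbed
  into exact integration constants. Orthonormality and interior residuals
  come out at the 1e-9 level and the eigenvalues are independent of the grid
  (degree 140 by default).
- **Cylinder-basis Galerkin.** A Rayleigh–Ritz projection on the eigenmodes
  of the cylindrical rod with the same `L`, `E`, `ρ` and radius `b` (24 basis
  functions by default, stable closed-form evaluation of the large-argument
  hyperbolics). Each basis function satisfies all four boundary conditions,
  so the Ritz eigenvalues are upper bounds that decrease monotonically with
  basis size — asserted in the tests. This route stays robust for contacts
  close to the base, where direct solution of the conical problem has
  historically been fragile.

`whisker_modes()` dispatches: direct collocation for `ε ≤ 0.35` and free
tips, the cylinder basis closer to the base.

### Shock dynamics

A contact at `t = 0` kicks each pinned mode through the mass-weighted
projection of the quasi-static shape: `qᵢ(t) = −A (∫ s²Ū Vᵢ ds) G(t)` with
`A = V` or `Lγ` and `G` the damped Green's function (`G(0) = 0`,
`G′(0) = 1`). The base torque is the quasi-static ramp plus
`(Eπb⁴/4L²) Σ qᵢ V″ᵢ(1)`; its initial dynamic excursion opposes the ramp (the
incoming deflection wave bends the base the other way), then rings down with
envelope `e^{−ζω₁t}`.

Two operationalisations deserve explanation:

- **Mode count.** The idealised impulse has unbounded bandwidth, so the peak
  metrics of `dM/dt` do not converge with the number of modes — the physical
  cutoff is the measurement chain. `shock_response()` therefore keeps, by
  default, every mode with eigenfrequency below a third of the sampling rate
  of the requested time grid: three samples per period is the least that
  makes a discrete derivative meaningful, and it mirrors a 25,000 fps
  recording. At 25 kHz and `ε = 0.44` this keeps 6 modes.
- **The delay τ.** `dM/dt` swings between its extremes `Ṁ₊` and `Ṁ₋`;
  `ΔṀ = Ṁ₊ − Ṁ₋` and `τ` is the time, from contact, at which the *later* of
  the two extremes occurs — the completion of the swing. At the study
  conditions the positive peak precedes the negative one, so "time of the
  maximum" would not measure the completed variation; the two conventions
  differ by about half a mode period. `τ` is independent of `V` exactly (by
  linearity), and the analysis window is 10 ms, where the short-time
  modulations live.

Damping is ζ = 0.041 for both presets, assumed independent of the contact
position. The dimensional wave-speed scale `α√(E/ρ)` is exposed as
`wave_speed_scale()`.

### Free whisking and the contact simulation

Driving the base angle as `φ(t) = φ₀ sin(2πf_w t)` rotates the whisker
rigidly (no base curvature) but its inertia excites the free-tip modes; the
resulting base torque oscillates at `f_w` with amplitude ∝ `φ₀ω_w²`. The
modal convolutions (damped sinusoid × sinusoid) are evaluated in closed form
through complex exponentials — no quadrature, no time-step sensitivity — and
the tests compare them against a Simpson-rule oracle at 1e-6.

`whisking_contact_sim()` composes, by linear superposition: (i) the
steady-state free-whisking torque — the periodic particular solution, chosen
over the from-rest transient so the air-phase noise floor is well defined
from the first cycle; (ii) during contact (`φ ≥ φ_c`), the rotating-mode
quasi-static torque at the excess angle; (iii) a pinned-mode shock transient
launched at each onset with `A = Lφ̇(t_on)` — pinned rather than free modes
during sustained contact, since the contact constrains the shaft (a modelling
choice, not something the physical setup dictates uniquely); and (iv) at
release, a free-tip ring-down started from the instantaneous pinned modal
state projected onto the free modes (the quasi-static term vanishes
continuously at release since `φ(t_off) = φ_c`). Contacts are one-sided:
onsets are upward crossings of `φ_c`, releases downward crossings.

### Detection

The air-phase torque amplitude defines the threshold: `noise_floor()`
estimates `σ = √2 ×` RMS of the mean-removed signal over an integer number of
whisking periods — the exact amplitude of a sinusoid, insensitive to sampling
phase ("typical amplitude" is otherwise underspecified). Detection is a
first crossing of `|M| > 3σ` (rectified, since mechanoreceptors respond to
stress magnitude), with the end of the contact interval as deadline. The
band-passed channel uses a *causal* one-pole high-pass at 80 Hz cascaded with
a one-pole low-pass at 1000 Hz (bilinear transform, prewarped corners):
causality matters because a real-time detector cannot use zero-phase
filtering — a zero-phase variant would shift detection times by up to a
filter time constant. Its own noise floor `σ̃` is estimated the same way on
the filtered air signal. The premise of the comparison is spectral
decoupling: for the real whisker at mid-shaft contact the first pinned mode
falls inside the 80–1000 Hz band while the 15 Hz whisking line is attenuated
by ~15 dB.

`detection_map()` sweeps contact location `ε` and contact phase `φ_c/φ₀`,
simulating each cell and recording the detection delay on either channel.
One caveat the maps make visible: with the end-of-contact deadline,
early-protraction contacts near the tip are *detected late* on the filtered
channel (their shock is weak and the first pinned mode can fall below the
80 Hz corner) where the total channel simply misses them. Cell-wise the
filtered channel is never slower and misses far fewer contacts, and the bulk
of its delay distribution is flat; but the handful of late detections gives
its delay distribution a heavy tail, so a plain coefficient of variation
over each channel's own detected cells can come out *larger* for the
filtered channel. The package reports both the CV and the median/90th
percentile in `analysis/03_whisking_detection.R`.

### Video-profile analysis and the synthetic camera

`extract_profile()` takes the per-column intensity barycentre of the bright
whisker on its dark background, after median background subtraction and a
*soft* threshold at 20% of the column contrast (a hard cutoff biases the
centroid of off-centre ridges); columns below a contrast floor are flagged
missing, and multi-object columns are flagged ambiguous. Displacements are
referenced against either a static profile (fixed experiments) or per-column
sine fits of the air-phase motion (whisking experiments, with a slow
quasi-static twin run providing the solid-rotation amplitude), then smoothed
on a 10-pixel window and fitted with a cubic constrained to zero slope at the
base; the base curvature is twice the quadratic coefficient.

The constrained cubic is fitted, by default, over the *basal half* of the
profile. Base curvature is a local quantity; during the dynamic phase a
deflection wave travels through the distal half and is decidedly not cubic,
and restricting the span removes that bias while the quasi-static shapes are
near-cubic over the basal half anyway (≈ −2% residual bias). The span,
smoothing width and cubic order are configuration constants — the analysis is
deterministic given a stack and a configuration. For wave visualisation a
wider (41-pixel) smoothing can be requested via `smooth_px`; the 10-pixel
default matches the curvature pipeline.

`render_frames()` draws centerlines as Gaussian ridges (2 px cross-section)
with additive pixel noise; `render_stack()` adds the camera constants (60 μm
pixels, exposure box-averaged over the frame interval with 2 sub-samples by
default) and ships the noiseless ground truth. `track_wavefront()` locates
the per-frame minimum of the deflection (profile minus its shock-time
profile) with parabolic sub-column refinement and fits the front's distance
to base linearly in time.

## The synthetic generators and what passing tests mean

`gen_torque_trace()` adds i.i.d. Gaussian noise at the 1 μN·m torque-sensor
resolution to the simulated torque; `render_stack()` renders frames at a
default peak-to-noise ratio of 20. Named recipes pin the laboratory
conditions: `fig6_shock` (artificial whisker, `ε = 0.44`, `V = 0.689` m/s,
25 kHz) and `fig8_whisking` (real whisker, 15 Hz, 10°, object approaching at
a separation of 2.07/2.60/3.17 cm; the approach speed, 5 cm/s, and the stop
position, at half the whisking amplitude, are not printed anywhere and were
fixed once at values a translation stage would realistically use). One
consequence the generator makes explicit: the free-whisking torque
(~1e-7 N·m) sits *below* the sensor resolution, which is why that regime must
be analysed on the optically tracked signal.

What the generators do not emulate: slow sensor drift, lens distortion,
motion blur beyond the exposure box average, friction or stick-slip at the
contact, follicle compliance, intrinsic whisker curvature, and multi-whisker
interactions. Recovery tests passing on these synthetics therefore validate
the *analysis chain* — geometry, sub-pixel extraction, curvature estimation,
calibration — under controlled noise, not robustness to every artefact of
real video.

## Problem sizes and reproducibility

Defaults used throughout the tests and analysis scripts: spectral degree 140
(eigen-solves take ~50 ms), 24 Galerkin basis functions, 25 kHz shock
sampling over 10 ms, 20 kHz whisking sampling over 3–4 cycles, 20×20
detection maps (a full map pass takes a few seconds), and 40–60 rendered
frames of 160 × ~700 px for the video loop. Every stochastic step takes an
explicit seed and every generator is a pure function of its recipe; identical
inputs give bit-identical outputs, which the tests assert.

## Known limitations

- The shock metrics depend on the measurement bandwidth by construction; the
  `fs/3` mode-count rule makes that dependence explicit rather than hiding it
  behind an arbitrary fixed mode count.
- Contact release re-projects the pinned state onto five free modes; the
  truncation slightly breaks torque continuity at release.
- The contact phase `φ_c` is frozen at each onset even while the object is
  still translating, a quasi-static approximation of the approach.
- The detection maps inherit every simplification of the contact model
  (impulse shock + quasi-static ramp); their absolute delays should be read
  as model quantities, their *contrasts* between channels as the robust
  conclusion.
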