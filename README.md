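# conewhisk

Rodents localise objects with their whiskers by reading the mechanical
stresses at the whisker base. `conewhisk` models a whisker as a truncated
elastic cone (base radius `b`, conicity `α`, untruncated length `L = b/α`,
Young's modulus `E`, density `ρ`) and computes the two components of the base
torque that a contact produces:

- the **quasi-static** component, from the equilibrium beam equation
  `(s⁴ U″)″ = 0` on the dimensionless arc coordinate `s` (0 at the virtual
  tip, 1 at the base), whose rate of change with indentation,
  `dM_qs/d(Vt) = (3Eπb⁴/4)(1/d² − α/(db))`, decreases monotonically with the
  radial contact distance `d` and collapses for all whiskers onto the master
  curve `1/x² − 1/x` with `x = d/L`;
- the **dynamic** component, from the damped eigenmodes of the conical
  Euler–Bernoulli beam `(s⁴V″)″ = λ² s² V` (pinned-contact or free-tip
  boundary conditions), superposed through the Green's function
  `G(t) = e^{−ζωt} sin(√(1−ζ²) ω t)/(√(1−ζ²) ω)`.

On top of these the package provides: shock metrics (the swing `ΔṀ` of the
torque derivative and its delay `τ`), the inertial torque of free whisking
(`φ(t) = φ₀ sin 2πf_w t`) that sets the mechanical noise floor `σ_w`,
whisking-against-object simulations, a quasi-static vs band-passed
(80–1000 Hz, first-order) contact-detection comparison over contact location
and phase, and a sub-pixel video-profile analysis chain (intensity-barycentre
centerlines, constrained cubic curvature fits, torque–curvature calibration,
deflection-wave-front tracking) that operates on synthetically rendered
high-speed frames with known ground truth.

Two laboratory whiskers ship as presets (`whisker_preset("artificial")`,
`whisker_preset("real")`), with damping ratio ζ = 0.041.

## Worked example

```r
library(conewhisk)
art <- whisker_preset("artificial")

# shock against a fixed whisker at eps = 0.44, V = 0.689 m/s, 25 kHz
cc   <- contact_config(0.44, speed = 0.689, mode = "fixed", spec = art)
resp <- shock_response(art, cc, seq(0, 0.01, by = 1 / 25000))
shock_metrics(resp)
#> <shock_metrics> dMdot+ = 1.252, dMdot- = -0.739 N m/s; delta = 1.991; tau = 0.00042 s

# the torque-derivative swing grows with V (slope ~2.9 N here), while the
# delay tau ~ 0.42 ms is set by wave propagation alone and ignores V

# free whisking of the real whisker at 15 Hz / 10 deg: the noise floor
real <- whisker_preset("real")
t <- seq(0, 4 / 15, by = 1 / 20000)
fw <- free_whisking_response(real, 15, 10 * pi / 180, t, steady_state = TRUE)
noise_floor(torque_trace(t, fw$M), period = 1 / 15)
#> [1] 1.767356e-07     # N m — the ~1e-7 N m threshold scale for detection
```

`analysis/01_quasistatic.R` … `analysis/04_video_profiles.R` are narrative
drivers that run the four studies end to end (quasi-static rates and master
curve, shock dynamics, whisking + detection maps, synthetic-video recovery)
and write their tables under `results/`.

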