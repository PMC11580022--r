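---
title: "Models and methods behind memtide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memtide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtide)
```

memtide analyses optical-trap membrane-tether experiments that probe how
fast membrane tension propagates across a cell surface, and the cell
biology that tension propagation serves: coupling exocytosis to
compensatory endocytosis. This vignette is the package's own account of the
models it implements, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## Unit system

All quantities are in pN, µm and s: tension σ in pN/µm, bending modulus κ
in pN·µm, 2-D stretch modulus E in pN/µm, 2-D membrane viscosity η in
pN·s/µm, 3-D fluid viscosity in pN·s/µm², density in pN·s²/µm⁴. These units
make every constant used by the package a number of order 10⁻³–10².
`memtide_constants()` lists the defaults. One deliberate trap-avoidance
rule: bead *radii* are stored in calibration objects even though bead
batches are quoted by diameter — `drag_coefficient()` documents this to
prevent a silent factor-of-two error.

## Tether mechanics

A membrane tether behaves as a fluid lipid tube whose holding force
balances tension against bending rigidity:

$$f = 2\pi\sqrt{2\kappa\sigma}, \qquad f\,r = 2\pi\kappa.$$

`tension_from_force()`, `force_from_tension()` and `radius_from_force()`
implement the three faces of this relation and are exact inverses of each
other (property-tested to 10⁻¹² relative over σ from 10⁻³ to 10² pN/µm).
The default κ = 0.27 pN·µm is the value for neuronal growth cones, within
the 0.18–0.32 pN·µm range reported for other cells. The relation assumes a
cytoskeleton-free tether; applying it to tethers with actin content
overestimates tension.

Trap calibration follows the hydrodynamic oscillation method: the stage is
driven sinusoidally, the bead amplitude is linear in the hydrodynamic force
amplitude γω_dA_pp/2, and the stiffness is the reciprocal slope
(`calibrate_trap()`). The method requires ω_d·γ/k_trap ≪ 1
(`check_trap_regime()` warns above 0.1) and negligible inertia
(`reynolds_number()` is ~10⁻⁶ for µm beads at µm/s speeds). Force
uncertainty propagates from bead-tracking error: 17 nm RMS at a 75 pN/µm
trap gives δf ≈ 1.3 pN per frame, and through dσ/df = f/(4π²κ) a tension
detection threshold δσ = f·δf/(4π²κ) — about 1.2 pN/µm at a 10 pN resting
force (`tension_threshold()`). Where a test assesses detectability of a
noiseless model signal rather than of single raw frames, we use
δf/√30, the error of 1-s frame averages at 30 Hz; the single-frame value
stays the package default.

`fit_step_response()` characterizes the tether's own response to a step
extension as a constrained double exponential on the normalized force
(amplitudes ≥ 0, summing to at most 1.05, initialized from a
single-exponential tail fit — the constraint set and initialization are our
choices; nothing in the underlying method prescribes them). The fast
component of such fits motivates the ~1 s first-order "tether lag" used
elsewhere.

## Diffusive tension propagation

When immobile, cytoskeleton-anchored transmembrane proteins form a random
array of obstacles, membrane flow is a 2-D Darcy flow and tension obeys

$$\frac{\partial\sigma}{\partial t} = D_\sigma \nabla^2\sigma
  + E\,Q(t)\,\delta^2(x), \qquad D_\sigma = \frac{E\,k}{\eta},
  \qquad k = a^2 f(\phi).$$

For the permeability factor we adopt the dilute random-cylinder-array form

$$f(\phi) = \frac{-\ln\phi - 1.476 + 2\phi - 1.774\phi^2 + 4.076\phi^3}{8\phi},$$

enforced on φ ∈ (0, 0.3] (`permeability_factor()` refuses higher packing
where the expansion is invalid). The obstacle radius default a = 2.3 nm is
a *calibration*, not a measurement: it is the single value that maps the
measured obstacle fractions onto nm²-scale permeabilities consistently, and
it cancels in every cross-cell-type ratio the package reports. Likewise E
and η are unstated by the upstream measurements; the defaults (E = 40
pN/µm, η = 10⁻³ pN·s/µm) are order-of-magnitude configuration values, and
quantities intended for comparison across cell types are constructed so
that E, η and a cancel. The obstacle fraction itself comes from FRAP:
φ = (immobile fraction) × (25 % transmembrane-protein area coverage)
(`obstacle_fraction()`).

### Forward model

The pulling tether's piecewise-linear motion program (`pull_protocol()`;
default 1 µm/s out for 40 µm, 30 s hold, 1 µm/s back, ~110 s total)
extracts membrane area at rate Q(t) = 2π·r_t·dL/dt. Q uses a fixed tether
radius (default from `radius_from_force()` at 10 pN) rather than coupling
r_t to the local tension; this keeps the forward model linear, and the
coupling is noted as an extension point.

Two backends implement the response at a probe a distance d away:

- **Infinite plane (default).** The heat-kernel convolution has a closed
  form for piecewise-constant Q in terms of exponential integrals,
  $\Delta\sigma = \frac{EQ}{4\pi D}[E_1(\beta/s_{hi}) - E_1(\beta/s_{lo})]$
  with β = d²/4D — evaluated per protocol segment, it is exact up to E₁
  precision (the test suite checks it against direct adaptive quadrature to
  10⁻⁶).
- **Reflecting disc.** A finite-volume radial Crank–Nicolson solver
  (`geometry = "disc"`), whose flux form conserves ∫Δσ dA = E × (net
  extracted area) to machine precision by construction; the source injects
  exactly E·ΔA per step into the innermost cell. Default disc radius 5 µm
  (a terminal-scale domain), grid R/200, time step 0.02 s.

The two geometries bracket the physical situation (an isolated terminal is
neither infinite nor a perfect disc). On a 60 µm disc with a 0.2 µm grid
the two solutions differ by under 1 % of the peak response — we quantify
agreement as max_t|difference| / max_t|kernel| because pointwise relative
error is meaningless where the signal passes through zero.

`sense_time()` reports the first threshold crossing (linear interpolation)
measured from protocol start; `max_probe_amplitude()` the peak response.
Under pure diffusion the time to sense scales as d² — the package verifies
a log–log slope of 2 ± 0.1 on the closed-form impulse kernel with a small
absolute threshold, the regime in which the asymptotic statement holds
(at larger thresholds the crossing moves off the self-similar tail and the
apparent slope rises slightly above 2).

### Fitting

`fit_dsigma()` minimizes the sum of squared residuals over log₁₀D_σ (coarse
grid then golden-section refinement; the objective can be multi-modal when
the signal is weak), optionally freeing an *effective* distance as well —
the diagnostic for propagation with weak distance dependence, which shows
up as d_eff far below the geometric separation. A fit that fails to improve
on the flat-zero null model by at least 5 % of its sum of squares is
flagged `identifiable = FALSE` and should not be interpreted; this matters
because a slow-diffusivity trace at wide separation contains no usable
signal within a recording, while the same diffusivity at 5 µm produces a
large late-protocol ramp (the kernel prefactor EQ/4πD grows as D shrinks)
and is perfectly identifiable.

## FRAP

Recovery curves are normalized as F = (f − f₀)/(f_pre − f₀) and fit with
the hyperbolic model

$$F(t) = \frac{F_0 + F_\infty\,(t/t_{1/2})}{1 + t/t_{1/2}},$$

which passes through (F₀+F∞)/2 at t½ exactly. Initialization is
deterministic: F₀ from the first post-bleach point, F∞ from the tail mean,
t½ from the first midpoint crossing. The tracer diffusivity is
D_t = A_bleach/(4t½) with A_bleach defaulting to the 2.4 µm spot × 0.85 µm
optical section (2.04 µm²) — a configuration constant of the specific
microscope geometry, not hard-coded. Whether an effective circular area
would be more appropriate than the rectangle product is unresolved; the
default follows the printed product. The mobile fraction is F∞ − F₀,
clipped to [0, 1] with a warning if the fit strays outside.

## Tether drag

The tether membrane angle θ is measured between the contour normal at the
tether base and the base→bead segment. The contour is a periodic cubic
spline parameterized by chord length; the nearest contour point is found by
dense scan plus local refinement, and bases further than 0.5 µm from the
contour raise a geometry error. Angles are folded into [0, π/2] (the force
decomposition uses |sinθ|; the drag direction's sign is carried by the
trajectory). The tangential force is f·sinθ.

Kinematics deliberately smooth the *positions* before differencing: summing
raw frame-to-frame displacements of a stationary but jittery point
accumulates ~1 µm/s of spurious distance at 17 nm jitter and 30 Hz, which
would swamp the 0.5 µm/s stall criterion. The Gaussian kernel (width 1 s,
interpreted as σ by default with FWHM as an option, truncated at 4σ,
point-reflection padding so steady motion keeps its slope at the record
ends) is applied to x(t), y(t) and then to the cumulative distance;
velocity is its central difference. One known bias follows: on a curved
path the smoothing shortens chords, attenuating speed by about
exp(−ω²σ²/2) for angular speed ω (≈8 % for 2 µm/s on a 5 µm cell) — tests
account for it and users comparing absolute speeds on small cells should
too. Stalls are maximal runs with |v| below the 0.5 µm/s noise floor;
stalls shorter than three smoothing widths are reported but flagged
unreliable rather than silently merged.

## Activity-driven tension dynamics

The exo-endocytosis model is a deliberate minimal linear area balance — the
upstream observations supply time constants and fractions, not equations.
Stimulation adds a fraction of terminal area (default 10 % over 0.25 s); a
fraction ε of it enters a retrievable pool removed by first-order
endocytosis, the remainder stays; tension follows σ = σ₀ − E·(excess area
fraction), low-pass filtered by the ~1 s tether response. Exponential
stepping keeps added − endocytosed − residual at machine precision. The
endocytic time constant defaults to 10 s: the observed tension recovery
proceeds on a 10–20 s time scale and is complete within the 50 s
statistic window, which a 20–30 s capacitance-derived constant would
contradict (at τ = 20 s only ~92 % recovers within 50 s). The weak-stimulus
regime (~1 s) is available by configuration.

`recovered_fraction()` is (σ(t_on+50) − σ_min)/(σ_baseline − σ_min),
clipped to [0, 1.1]. By default the trace is smoothed (Gaussian σ = 2 s)
before the minimum and endpoint are read off — appropriate for noisy 1 Hz
single-frame tension estimates — and the baseline window stops 4 smoothing
widths before onset so the kernel cannot leak the dip into the baseline.
Whether to smooth, and the baseline extent, remain exposed because the
upstream convention is unknown. The statistic is invariant under affine
rescaling of the trace and returns NA (flagged) when no dip exceeds three
baseline standard deviations.

One subtlety ties the generator to the statistic: the 1 s tether lag erodes
the apparent dip depth by ~13 %, so a trace generated from retrievable-pool
fraction ε yields an observed recovered fraction below ε. Because
dose–response anchors are stated in observed units, `gen_stimulus()` takes
the *target observed fraction* and inverts the deterministic noiseless
mapping (by root finding) to choose the pool fraction; both values are
recorded in the truth block. The dose→efficiency mapping for endocytosis
inhibitors is a lookup in these observed units, not a pharmacological
model.

## Synthetic data: what it does and does not emulate

Generators are seeded (`generator_config()`), bit-reproducible, and return
the consumed data plus a ground-truth block. They emulate:

- tracking noise as additive Gaussian position error (17 nm default), so
  probe force traces carry per-sample force noise k_trap × 17 nm ≈ 1.3 pN;
- the acquisition schedules (30/14/4.2/1 Hz; the FRAP two-phase schedule of
  30 frames at 1.29 s then per-minute frames);
- cell-type contrasts as parameter presets (`scenario_presets()`): immobile
  fractions 0.39/0.37/0.60 and tracer diffusivities for terminal, soma and
  chromaffin cells; drag onset forces ~8 vs ~24 pN; D_σ *regimes* — 24
  µm²/s for rapidly equilibrating terminals (a response within seconds at
  8 µm) versus 0.01 µm²/s for chromaffin cells (no detectable response
  within a protocol). The D_σ presets are regime choices, not measured
  values.

They do not emulate: image formation (everything starts from tracked
coordinates and intensities), registration drift beyond an optional linear
term, heterogeneous obstacle spatial arrangements, stochastic single-vesicle
fusion, or calcium-channel gating. Passing recovery tests on these
generators therefore demonstrates correctness of the analysis chain under
its own noise model, not robustness to all failure modes of real imaging
data.

## Problem sizes and tolerances

The test suite runs the finite-difference/kernel comparison on a 60 µm
disc (300 cells, 0.05 s steps over 130 s), diffusivity recovery on 20
seeded double-tether experiments across D_σ ∈ {0.024, 0.24, 2.4, 24}
µm²/s, FRAP recovery over a 12-point parameter grid at noise SD 0.03, and
drag/stimulus recovery on single generated records per motif — sizes chosen
so the full suite completes in about a minute while leaving each estimate's
error comfortably inside its tolerance. Quadrature agreement is asserted at
10⁻⁶ relative, solver agreement and area conservation at 1 %, parameter
recovery at the 10–20 % level appropriate to each noise model.

## Known limitations

- The diffusive forward model is linear: tether radius does not respond to
  the local tension, and sources superpose. Strong perturbations violate
  this.
- The disc backend places the source at the disc center; off-center source
  geometries (and hence angular structure) are not implemented.
- The σ ∝ 1/I² fluorescence route assumes the tether is thinner than the
  optical section and uniformly labeled.
- The exo-endo model's linear σ–area mapping needs E·(added fraction) <
  σ₀; `simulate_exo_endo()` warns when tension would cross zero.
- `fit_dsigma()` treats measurement noise as i.i.d.; correlated drift is
  not modeled (generators can add a linear drift for robustness checks).

```{r example, eval = FALSE}
# end-to-end demo of all four synthetic experiments
res <- run_pipeline(run_config(seed = 1))
str(res, max.level = 2)
```
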