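# memtide

Analysis toolkit for membrane-tension propagation experiments on secretory
cells. It implements the quantitative chain used to ask how fast a local
change in plasma-membrane tension spreads across a cell — a question that
decides whether tension can couple exocytosis to compensatory endocytosis at
neuronal presynaptic terminals, where the two occur at different places.

The package is aimed at biophysicists analysing optical-trap tether
recordings, FRAP curves and tracked tether-drag movies, and at modellers who
want a tested forward model of diffusive tension propagation to compare such
data against. All experiment types come with seeded synthetic generators
carrying known ground truth, so every stage of the chain is testable without
any microscope.

## The physics in brief

A membrane tether of radius *r* pulled from a cell at force *f* reports the
local membrane tension σ (pN/µm):

    f = 2π √(2κσ),   f·r = 2πκ,

with κ ≈ 0.27 pN·µm the bending modulus. When the membrane flows past a
random array of immobile transmembrane obstacles (area fraction φ, radius
*a*), tension perturbations spread diffusively,

    ∂σ/∂t = D_σ ∇²σ + E·Q(t)·δ²(x),   D_σ = E·k/η,   k = a²·f(φ),

where *E* is the 2-D stretch modulus, η the 2-D membrane viscosity, *k* the
Darcy permeability of the obstacle array, and Q(t) = 2π·r_t·dL/dt the rate at
which an extending tether extracts membrane area. φ is estimated from the
FRAP immobile fraction times the ~25 % of membrane area occupied by
transmembrane proteins. The package provides:

- **core mechanics** — force/tension/radius conversions, trap-stiffness
  calibration from hydrodynamic oscillation records, step-response fits,
  fluorescence-based tension (σ ∝ 1/I²);
- **tension diffusion** — the permeability model, an exact heat-kernel
  forward solver on the plane (exponential integrals), a conservative
  finite-difference solver on a reflecting disc, time-to-sense and
  amplitude-versus-distance predictions, and least-squares D_σ fitting;
- **FRAP** — normalization, hyperbolic recovery fits, D_t = A/(4·t½),
  mobile/immobile fractions;
- **drag kinematics** — tether membrane angle from tracked contours,
  tangential force f·sinθ, base velocity, stall detection with per-stall
  peak forces;
- **activity** — ΔF/F processing, an exo-endocytosis area-balance model of
  stimulus-evoked tension dips, the 50-s recovered-fraction statistic, and
  calcium–tension anticorrelation;
- **synthetic data** — seeded generators for all four experiment types with
  cell-type presets (bipolar terminal / soma, chromaffin, HeLa-like).

## Worked example

Fit a synthetic chromaffin-cell FRAP curve, derive the obstacle fraction,
and ask whether the implied diffusivity could carry a tension signal between
two tethers 8 µm apart:

```r
library(memtide)

frap <- gen_frap(generator_config(seed = 7, scenario = "chromaffin"))
fit  <- fit_recovery(frap$curve)
fit
#> <frap_fit>
#>   F0 = 0.0575, F_inf = 0.447, t_half = 46.36 s
#>   mobile = 0.389, immobile = 0.611
#>   D_t = 0.011 um^2/s (A_bleach = 2.04 um^2)

phi <- obstacle_fraction(fit$immobile_fraction)  # 0.153
membrane_model(phi = phi)
#> <membrane_model>
#>   E = 40 pN/um, eta = 0.001 pN s/um
#>   phi = 0.15268, a = 0.0023 um
#>   k = 2.95337e-06 um^2 (2.95 nm^2)
#>   D_sigma = 0.118135 um^2/s
```

The fitted immobile fraction (0.61) times the 25 % protein coverage gives
φ ≈ 0.15, a Darcy permeability of ~3 nm², and a tension diffusivity far too
small for a probe tether 8 µm away to sense anything during a ~110 s pulling
protocol. A rapidly-equilibrating terminal behaves differently:

```r
resp <- simulate_probe_response(pull_protocol(), membrane_model(D_sigma = 24), d = 8)
sense_time(resp, threshold = tension_threshold(10, delta_f = 1.3 / sqrt(30)))
#> # A tibble: 1 × 3
#>   t_sense threshold max_amplitude
#>     <dbl>     <dbl>         <dbl>
#> 1    5.05     0.223         0.500
```

i.e. with D_σ three orders of magnitude above the HeLa-derived literature
value the probe senses the pull after ~5 s, with a maximum tension change of
0.5 pN/µm. Every result object has `tidy()`/`glance()` methods and an
`autoplot()`; `run_pipeline(run_config(seed = 1))` runs one instance of all
four synthetic experiments end to end.

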