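# larynxsim

Voice scientists and speech engineers often need to ask: *if the brain
raises cricothyroid activity by this much, what happens to pitch,
loudness, brightness and roughness?* Direct measurement (electromyography,
excised-larynx stimulation) is invasive and sparse. `larynxsim` answers
the question computationally: it is a muscle-activation-controlled
simulator of voice production that maps intrinsic laryngeal muscle
activations to vocal fold posture, flow-induced self-sustained
oscillation, a radiated pressure signal, and the acoustic features of
that signal — and it sweeps the thyroarytenoid (TA) × cricothyroid (CT)
activation plane to produce muscle activation maps of each feature.

## The model in brief

- **Posture.** Activations (fractions of maximum) set a quasi-static
  strain ε by a calibrated force balance; empirical rules then give
  length *L* = L₀(1+ε), thickness *T* = T₀/(1+ε), the adduction
  half-widths ξ₀₁, ξ₀₂ and medial bulge ξ_b, and a half-width surface
  ξ₀(y,z) = (1−y/L)[ξ₀₂ + (ξ₀₁−ξ₀₂−4ξ_b z/T)(1−z/T)].
- **Tissue.** Each layer (SLLP cover, ligament, muscle) follows a
  linear-plus-exponential passive fiber stress
  σ_y(ε) = −(σ₀/ε₁)(ε−ε₁) + σ₂[e^{B(ε−ε₂)} −1 −B(ε−ε₂)], muscles add an
  active stress a·σ_m·FL(ε); tensile stress becomes a fiber shear
  modulus μ′ = max(0, σ_y) on top of the gel (μ = 0.5 kPa,
  η = 0.1 Pa·s).
- **Vibration.** 15 coronal slices × 120 triangular elements of
  fiber-gel tissue, fixed at anterior/posterior/lateral boundaries,
  pressure-driven on the glottal surfaces, with midline collision and
  inter-slice fiber strings; explicit central-difference stepping at
  44.1 kHz.
- **Aeroacoustics.** Bernoulli flow up to the minimum glottal diameter,
  jet beyond; a quadratic glottal junction couples the fold to
  wave-reflection subglottal (36 sections) and supraglottal (44
  sections, /ɑ/) airways with a radiation load at the lips.
- **Features.** fo (autocorrelation), SPL at 30 cm, normalized spectral
  centroid, and approximate entropy ApEn(m = 2, r = 0.2·SD).
- **Sweep.** Lung pressure and LCA/IA adduction are tied to the grid by
  the constraint rules P_L = 0.8 + 0.025 a_CT + 0.01 a_TA kPa and
  a_LC = a_IA = 30 + 0.3 a_CT − 0.1 a_TA (percent); PCA is 0.

See the methods vignette (`vignettes/activation-maps.Rmd`) for the full
account, including every numerical and calibration choice.

## Worked example

Simulate one grid point (20% CT, 20% TA — lung pressure and adduction
from the constraint rules) and read off its features:

```r
library(larynxsim)
cfg <- vp_config()
res <- run_point(aCT_pct = 20, aTA_pct = 20, cfg)
as.data.frame(res)
#>   aTA_pct aCT_pct PL_kPa aLC_pct      status fo_Hz SPL_dB   NSC   ApEn  L_cm
#> 1      20      20    1.5      34 oscillating 253.1  76.79 12.25 0.3668 1.711
#>   sigma_SLLP sigma_lig sigma_mus
#> 1      47188   2196897    897901
```

The cell self-oscillates at 253 Hz and radiates 76.8 dB SPL at 30 cm;
the fold is stretched to 1.71 cm, and the ligament carries the largest
fiber stress (2.2 MPa in CGS units, dyn/cm²), as expected from its
steep exponential law. The phonation threshold pressure at this posture
is about 0.62 kPa — comfortably below the 1.5 kPa the lung-pressure
rule supplies:

```r
phonation_threshold(fold_system(grid_activation(20, 20), cfg))
#> [1] 0.6236328
```

A reduced activation map and its contour plots:

```r
map <- run_sweep(grid_step_pct = 25, cfg)   # 5 x 5 grid, ~40 s
glance(map)
#>   n_cells n_oscillating n_failed   fo_min   fo_max  SPL_min  SPL_max
#> 1      25            12        0 161.2296 349.5134 63.21344 88.72466
autoplot(map, "fo_Hz")                       # TA (x) vs CT (y) contours
export_maps(map, "maps/")                    # tidy CSVs + PNGs per feature
```

At zero TA, fo climbs monotonically with CT (181 → 350 Hz across the
grid) while SPL rises with lung pressure and saturates as collision
limits the vibration amplitude. A command-line interface wraps the same
functions: `larynxsim simulate --act 20,20`, `larynxsim sweep --step 5`,
`larynxsim features in.wav`.

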