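---
title: "From laryngeal muscle activation to voice: the model behind larynxsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From laryngeal muscle activation to voice: the model behind larynxsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larynxsim)
```

larynxsim maps the activation levels of the intrinsic laryngeal muscles —
cricothyroid (CT), thyroarytenoid (TA), lateral cricoarytenoid (LCA),
interarytenoid (IA), posterior cricoarytenoid (PCA) — together with lung
pressure to a radiated voice signal, and from that signal to four acoustic
features: fundamental frequency (fo), sound pressure level (SPL),
normalized spectral centroid (NSC), and approximate entropy (ApEn). This
vignette explains the model stage by stage, the constants a user may want
to touch, the numerical choices, and what the package's tests do and do
not establish.

## Posture: from activations to prephonatory geometry

The vocal fold at rest is L0 = 1.6 cm long and T0 = 0.7 cm thick (average
male dimensions). Muscle activation sets a quasi-static strain
$\epsilon$, and empirical rules then give the full prephonatory geometry:

$$L = L_0(1+\epsilon), \qquad T = T_0/(1+\epsilon)$$
$$\xi_{01} = \xi_{02} + \max(0,\ 0.1\,T\,(1-1.5\,a_{TA})), \qquad
  \xi_b = 0.05\,T\,(1-a_{TA})$$

so that length and thickness trade off isochorically ($LT = L_0T_0$
exactly), and TA activation flattens the convergent entry profile and the
medial bulge. The glottal half-width anywhere on the medial surface is

$$\xi_0(y,z) = (1-y/L)\left[\xi_{02} +
  \left(\xi_{01}-\xi_{02}-4\xi_b z/T\right)(1-z/T)\right]$$

with $y$ running from the vocal-process end ($\xi_0$ interpolating
$\xi_{01}$ inferiorly to $\xi_{02}$ superiorly) to the zero-width
commissure at $y=L$, and $z$ from the inferior to the superior surface.

**Strain balance.** The cartilage-framework mechanics that in the full
physiology determine $\epsilon$ from all five muscles are replaced here by
a deliberately simple one-degree-of-freedom quasi-static balance: a
constant CT pulling force $a_{CT} G_{CT} \sigma_m^{CT} A_{CT}$ against a
TA shortening force $a_{TA} G_{TA} \sigma_m^{TA} A_{TA}$ and the
area-weighted passive fiber stresses of the three fold layers, measured
from their rest values. Because the passive sum is strictly increasing in
strain, the root is unique; it is found by bisection on
$[-0.45, 0.45]$ to a $10^{-9}$ relative force tolerance. The two gains
$G_{CT}, G_{TA}$ have closed-form calibrations (the balance is affine in
each) fixed so that full CT alone gives $\epsilon = +0.1875$
($L = 1.9$ cm) and full TA alone $\epsilon = -0.375$ ($L = 1.0$ cm), the
length extremes of the male fold. This stand-in inherits the passive
laws' exponential stiffening, which is why length gains saturate at high
CT — an emergent behaviour, not a fitted one.

**Adduction.** The vocal-process half-width follows a saturating rule

$$\xi_{02} = \xi_{02}^{rest}\, e^{-k_{LC}(a_{LC}+a_{IA})/2 - k_{TA} a_{TA}}$$

with $\xi_{02}^{rest} = 0.15$ cm, $k_{LC} = 3.7$, $k_{TA} = 0.4$. The
exponential form was chosen over a linear ramp because no linear rule can
simultaneously bring the half-gap below 0.05 cm at 30% adductor
activation (needed to make phonation threshold reachable at 0.8 kPa) and
keep the processes from crossing at 60%; the saturating form does both,
is strictly decreasing, and closes asymptotically at maximal adduction,
which is also the physiologically expected shape of cartilage approach.

## Tissue: the fiber-gel constitutive law

Each layer (superficial lamina propria SLLP, ligament, TA muscle — and
the other muscles for the strain balance) carries a passive fiber stress

$$\sigma_y(\epsilon) = -\frac{\sigma_0}{\epsilon_1}(\epsilon-\epsilon_1)
 + \sigma_2\left[e^{B(\epsilon-\epsilon_2)} - 1 - B(\epsilon-\epsilon_2)\right]$$

with per-layer constants shipped as a plain-text table
(`inst/extdata/layer_params.tsv`). Two reading decisions are built in.
First, the linear term is implemented with slope $-\sigma_0/\epsilon_1$
(positive, since $\epsilon_1 = -0.9$), so that $\sigma_0$ plays its
stated role as a scale factor and the law is increasing over the working
range; the literal negative-slope variant is available via
`vp_config(as_printed = TRUE)` for comparison. Second, table entries
printed as ".2e4" are read as 0.2e4. The exponential bracket is zeroed
for $\epsilon \le \epsilon_2$, which keeps the law $C^1$ there. Muscles
add an active stress $a\,\sigma_m\,FL(\epsilon)$ with a Gaussian
force–length factor peaking at $\epsilon = 0.4$. The default width 1.4
is broad: with a narrow factor the active term at full TA shortening
($\epsilon = -0.375$) is penalized so hard that muscle fiber stress would
*fall* from 75% to 100% TA at low CT, contradicting the expected monotone
rise of $\sigma_{mus}$ with both activations; a broad factor — defensible
for a muscle abstraction that bundles fiber recruitment — restores it.

Tensile fiber stress converts to a transverse fiber shear modulus
$\mu' = \max(0, \sigma_y)$ (a taut string resists transverse displacement
in proportion to its tension; a slack fiber not at all), which is added
to the isotropic gel modulus $\mu$ = 0.5 kPa with viscosity $\eta$ = 0.1
Pa·s, the same in all layers.

## Vibration: layered finite-element fold

The right fold is discretized into 15 coronal slices, each a 10×6 grid of
cells split into 120 linear triangles (77 nodes per slice). Cell columns
are assigned medially→laterally as 1 SLLP / 2 ligament / 7 muscle.
Anterior, posterior and lateral boundaries are fixed; medial, inferior
and superior surfaces are pressure-loaded. In-plane (plane-strain)
stiffness comes from the gel, with near-incompressibility enforced by a
penalty bulk modulus of 50 µ — triangles lock somewhat under such a
penalty, stiffening the mesh modestly, which we accept for the robustness
of an analytic-shape-function element. Fibers act as linear strings
between corresponding nodes of adjacent slices with stiffness
$\mu' A_{fib} / \Delta y$. The fiber cross-section uses an effective
fiber volume fraction of 0.45 (fibrous protein occupies roughly half the
tissue volume); this single constant sets the absolute scale of the
fiber stiffness and thereby centres the model's fo range on the male
70–400 Hz span. Tissue density is 1.04 g/cm³. The left fold is the
mirror image, so the glottal width is twice the simulated half-width.

Time integration is explicit central difference at the acoustic sampling
rate (44.1 kHz), keeping tissue and airway synchronous. The gel's
Kelvin–Voigt damping $C = (\eta/\mu) K$ is unstable for the highest
penalty modes under explicit integration, so the stiffness-proportional
factor is capped at its stable value (estimated per assembly by power
iteration) and the remainder is carried by a mass-proportional term
matched to the physical damping at 150 Hz — a standard Rayleigh split.
With $\eta = 0$ both terms vanish and the scheme conserves its discrete
energy invariant to machine precision, which the tests exploit.

Collision with the midplane uses a one-sided penalty spring (3× the
local medial-column stiffness) plus extra contact damping (damping ratio
0.5) while penetrating. A run whose displacement exceeds 1 cm or goes
non-finite is aborted and reported as a failed cell, never as an error
of the sweep. A tiny seeded random nodal velocity (10⁻⁴ cm/s) breaks the
symmetric equilibrium so that flow-induced oscillation can start; the
steady state is insensitive to this seed.

## Aeroacoustics: glottal flow and wave-reflection airways

Glottal flow solves the junction quadratic equating the transglottal
driving pressure to the kinetic loss $(\rho/2)(u_g/A_g)^2$ plus the
characteristic-impedance loading of the subglottal and supraglottal
tubes; the positive root is taken and flow is rectified at zero. With no
acoustic loading this reduces to the Bernoulli orifice law
$u_g = A_g\sqrt{2P/\rho}$, and flow vanishes continuously as the glottis
closes. Surface pressures are energy-conserving Bernoulli values
referenced to the subglottal pressure below the minimum glottal
diameter and the supraglottal (jet, no recovery) pressure at and above
it; when the glottis is closed, everything below the closure — including
the closure's upstream face — sees the stagnation pressure, which is
what reopens it.

The airways are Kelly–Lochbaum wave-reflection tubes: 36 subglottal and
44 supraglottal sections of $c/(2 f_s) = 0.3968$ cm. Because a section
is half the distance sound travels per sample, waves traverse two
sections per sample; the implementation performs two scattering
half-passes per sample. Losses are a per-section amplitude factor
(0.996) standing in for viscous and wall losses; the kinetic loss acts
only at the glottal junction. The lung end is a matched termination with
a constant pressure source (forward wave $P_L/2$), the lip end a
first-order reflection filter from the parallel resistance/inertance
radiation load (bilinear transform at the half-pass rate; reflection
$\to -1$ at DC). The supraglottal area profile is a stylized male /ɑ/
(narrow epilarynx and pharynx opening into a wide oral cavity), shipped
as `areas_aa_synthetic.tsv` and validated by its resonance behaviour
(a uniform-tube configuration reproduces the quarter-wave formant within
5%) rather than by comparison to a measured table, which is not
redistributed here.

## Features

- **fo**: normalized autocorrelation over the final 0.2 s, search range
  50–600 Hz, parabolic peak interpolation, periodicity-confidence gate
  0.3 (aperiodic signals report no pitch). This is a deliberate,
  documented replacement of a spectral pitch tracker; on clean periodic
  signals the two agree to within 1 Hz.
- **SPL**: $10\log_{10}[\bar p_o^2 A_m / (\rho c\, 4\pi R^2 R_m I_0)]
  + \Delta_{cal}$ at R = 30 cm with $I_0 = 10^{-12}$ W/m² — the
  dimensionally consistent reading of the radiated-intensity formula,
  with the mouth-opening area $A_m$ converting the oral pressure to a
  radiated power. The additive calibration $\Delta_{cal}$ (default
  −7 dB) is the single absolute-level constant; it absorbs the
  difference between the mouth-pressure proxy and a true far-field
  measurement.
- **NSC**: magnitude-spectrum centroid (Hann window, final 0.2 s, bins
  to Nyquist) divided by fo. Anchors: 1 for a pure tone, 1.5 for equal
  tones at $f$ and $2f$, 3 for equal harmonics 1–5.
- **ApEn**: $\Phi^m - \Phi^{m+1}$ with $m=2$, $\tau=1$, Chebyshev
  distance, self-matches included. The tolerance defaults to
  $r = 0.2\,\mathrm{SD}(x)$ — the scale-invariant convention — with
  `apen_r_mode = "variance"` available for the variance-scaled reading,
  since primary sources are ambiguous between the two. Signals are
  decimated to 4.41 kHz first ($O(N^2)$ at the full rate buys nothing).
- **Postural steady state**: arithmetic means over the final 100 ms.

A deterministic fixture generator (`make_fixture()`) produces the pure
tones, harmonic complexes, period-jittered tones and white noise used to
test these extractors. The jittered tone redraws the instantaneous
frequency each nominal cycle with a 5% SD. These fixtures exercise the
extractors' algebra (known centroids, known periods, known orderings);
they do not emulate glottal source spectra, formant structure or
additive turbulence noise, so feature tests passing on fixtures says
nothing about perceptual validity on real voices — the simulator-level
tests address the physical signal path instead.

## The activation sweep

The experiment design fixes PCA at 0 and ties the remaining controls to
the TA–CT grid through two constraint rules (activations in percent):

$$P_L = 0.8 + 0.025\,a_{CT} + 0.01\,a_{TA} \ \text{kPa}, \qquad
  a_{LC} = a_{IA} = 30 + 0.3\,a_{CT} - 0.1\,a_{TA}$$

spanning 0.8–4.3 kPa and 20–60%. The default 5% step gives 441 cells of
0.4 s each; every cell reports the acoustic features, steady-state
length and per-layer fiber stresses, plus an
oscillating / non-oscillating / failed status. A cell counts as
oscillating when the glottal-area oscillation amplitude over the final
100 ms exceeds 5×10⁻³ cm² and holds at least 95% of the preceding
window's amplitude (self-sustainment). Results are cached per cell so an
interrupted sweep resumes, and runs are bit-identical for a given
configuration and seed.

Maps are exported as tidy CSVs and filled-contour plots (TA on the x
axis, CT on the y axis); non-oscillating cells are blank, not zero. The
test suite and the acceptance script use a reduced 5×5 grid (25% steps)
and single 0.4 s runs — large enough to exhibit the map-level trends
(fo rising with CT, SPL–lung-pressure saturation, monotone length and
stress maps) at a desk-scale cost; the full 441-cell map is a
`run_sweep(5, ...)` call away.

## Known limitations

- The strain balance and adduction rule are stand-ins for unpublished
  cartilage mechanics; they are calibrated at the length extremes and
  validated by behaviour (oscillation onset, monotone maps), not derived.
- Fiber stresses are reported at the quasi-static posture, so the
  per-layer stress ratio depends directly on the stand-in strain model;
  only the ordering (ligament > muscle > SLLP) is asserted.
- No turbulence/aspiration noise, nasal tract, or articulation change;
  the vowel is fixed.
- Plane-strain slices with string coupling exclude anterior–posterior
  node motion and 3-D cartilage dynamics.
- Several cells of the activation grid — notably high TA with low CT —
  remain below phonation threshold under the constraint rules; they are
  reported as non-oscillating rather than forced.
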