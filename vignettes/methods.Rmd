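---
title: "Methods: spectral extinction modelling of hemoglobin microparticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral extinction modelling of hemoglobin microparticles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hboptics)
```

## The measurement and its model

Hemoglobin microparticles (HbMPs) are ~750 nm cross-linked
hemoglobin/albumin particles developed as artificial oxygen carriers.
Their quality hinges on how much of the hemoglobin is functional:
methemoglobin (ferric, metHb) binds no oxygen, and the ratio of
oxygenated to deoxygenated hemoglobin tracks the oxygen loading. None of
these are accessible by standard hemoglobin photometry because the
particles cannot be lysed and scatter light strongly.

The package models a collimated transmittance measurement of a dilute
suspension. Because the detector accepts only the unscattered forward
beam, Beer–Lambert inversion of $T(\lambda)$ yields the *extinction*
(absorption plus scattering) of the particle ensemble. Working with the
volume-specific extinction cross section
$Z(\lambda) = -\ln T(\lambda) / (\ell \cdot \mathrm{PPV} \cdot \varphi)$
removes the particle concentration — known only to within a factor of a
few for this system — in favour of the packed particle volume, which is
measured to four digits by hematocrit-style centrifugation.

The forward model composes three layers:

1. **Complex refractive index.** The particle interior is an aqueous
   protein solution: $n + i\kappa$ is the water index plus
   concentration-weighted specific increments (mL/g) of total hemoglobin
   and of heme-free globin/HSA. The hemoglobin increment is the
   mass-fraction-weighted sum over oxyHb, deoxyHb and metHb — the key
   linearity that makes composition fitting possible. Imaginary
   increments follow from molar extinction spectra via
   $\gamma = \ln\!10\,\epsilon\lambda/(4\pi M)$ with $M$ the Hb monomer
   mass (16114.5 g/mol); real increments are tied to absorption by
   causality (Kramers–Kronig).
2. **Single-sphere optics.** Lorenz–Mie theory gives
   $C_{ext}(\lambda; D)$ for a homogeneous sphere in water. Treating the
   peanut-shaped particles as volume-equivalent spheres is adopted as an
   explicit approximation; shape effects on extinction are small for
   this size and index contrast.
3. **Ensemble average.** $C_{ext}$ is averaged over a log-normal
   diameter distribution and divided by the mean particle volume to give
   $Z(\lambda)$.

The inverse problem — which (oxy, deoxy, met) composition explains a
measured $Z(\lambda)$ — is posed as least squares over the unit simplex,
optionally with one free multiplicative scale. The free scale is
deliberate: measured spectra sit systematically below simulations
(pipetting losses, agglomeration, trapped volume inflating the PPV), and
these mechanisms move the whole curve without changing its shape, which
is where the composition information lives (Soret band position and
width, Q-band structure).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| intra-particle $\beta_{Hb}$ | 120 | g/L | densitometry result for the reference batch |
| intra-particle $\beta_{Gl/HSA}$ | 130 | g/L | densitometry result; held fixed during fitting |
| PSD median $\mu_D$ | 760 | nm | DLS median of the reference batch |
| PSD width $w(16\text{–}84\%)$ | 395 | nm | DLS width; $\sigma_D$ = 25.8% via the exact-quantile convention |
| fit window | 300–800 | nm | spectrometer range with informative Hb bands |
| simplex grid step | 0.025 | – | resolves compositions well below the 0.05 reporting uncertainty |
| diameter quadrature step | ≤ 20 (default 10) | nm | grid-convergence of $Z$ to < 1e-4 |
| dilution QC threshold | $T \ge 0.30$ | – | onset of multiple-scattering effects |
| log-shift RMS tolerance | 0.02 | – | package choice; the underlying consistency criterion is qualitative |

Two conventions deserve emphasis because both alternatives appear in the
wild:

* **Quantile width.** Sizing instruments report
  $w = Q(84\%) - Q(16\%)$. We convert with the *exact* normal quantile
  $z_{84} \approx 0.9945$, i.e.
  $\sigma_D = \operatorname{asinh}(w/2\mu_D)/z_{84}$, not the $z = 1$
  shortcut; only the exact convention reproduces the reference values
  $\sigma_D = 25.8\%$ (DLS) and $15.1\%$ (AC) from the tabulated
  medians and widths.
* **Unrounded chaining.** The densitometry solve (heme-free protein in
  suspension → hemoglobin in supernatant → hemoglobin in particles) is
  evaluated without intermediate rounding; the printed-precision values
  (27.7, 2.0, 120.1 g/L) emerge only when rounding is deferred to the
  reporting layer.

The DLS summary is the default size input; analytical-centrifugation
parameters can be supplied instead. DLS medians are intensity-weighted
while the model's $p(D)$ is number-weighted; the package follows the
source convention of feeding the summary in directly, and flags the
caveat here.

## Numerical choices

**Mie series.** Wiscombe truncation
$N = \lceil x + 4x^{1/3} + 2 \rceil$; logarithmic derivatives by
downward recurrence started 15 orders above $N$; Riccati–Bessel
functions of the real argument by upward recurrence. The engine is
vectorized over (diameter, wavelength) pairs, which makes the
ensemble-averaged spectrum a single call. Validation is against an
independently coded oracle (Lentz continued fractions plus half-integer
Bessel functions), the Rayleigh closed form at $x \le 0.01$, the
optical theorem ($C_{ext} = C_{sca}$ exactly when $\kappa = 0$) and
truncation-order doubling.

**Kramers–Kronig.** A singly subtractive transform anchored to a known
reference increment: the principal-value integral runs over
$\Delta\gamma = \gamma_{target} - \gamma_{ref}$, which is confined to
the absorption bands that differ, so a finite grid with ≥ 50 nm padding
beyond the 300–800 nm output window suffices. The pole is handled by
subtracting the integrand value at the singularity (trapezoidal rule on
the regularized integrand, the excised node replaced by the numerical
derivative, plus the analytic log boundary term). Against analytic
Lorentz-oscillator pairs the transform is accurate to better than 1e-3
relative beyond two half-widths from band centers.

**PSD quadrature.** $Z$ integrals use an equidistant diameter grid from
the 0.1% to the 99.9% quantile with at least 51 nodes; numerator and
denominator share nodes, so tail truncation cancels in the ratio. The
standalone mean-volume quadrature instead substitutes
$D = \mu_D e^{\sigma_D z}$ and integrates in $z \in [-10, 10]$, because
the $D^3$-weighted tail extends three sigma beyond the number-weighted
one. A monodisperse PSD ($\sigma_D = 0$) short-circuits to the
single-sphere ratio rather than attempting quadrature on a delta
function.

**Fitting.** Grid-then-refine: closed-form per-candidate scale on the
simplex grid, followed by Nelder–Mead refinement in
$(\phi_{deoxy}, \phi_{met})$ with constraint violations penalized. The
refinement is only accepted if it improves the grid optimum. The metHb
uncertainty is the curvature of the one-dimensional metHb profile of
the grid objective ($\mathrm{Var} \approx 2\hat\sigma^2 / \partial^2
\mathrm{RSS}$); a non-positive curvature (flat objective) is reported
as an ill-posedness flag rather than a number. Residuals are unweighted
in linear $Z$: the least-squares rescaling convention is linear-space,
and no wavelength weighting is imposed absent a stated noise model.

## The synthetic generator

No public tabulated increment spectra ship with the package, so the
synthetic module generates species optics from Gaussian band models:
oxyHb with the Soret band at 413 nm and Q bands at 543/578 nm, deoxyHb
at 430 nm, metHb at 409 nm with its 640 nm marker, and a band-free
Gl/HSA. Real increments are derived from these bands by the package's
own Kramers–Kronig transform on top of flat baselines (0.200 mL/g for
heme proteins, 0.185 mL/g for Gl/HSA — typical protein refraction
increments). A broad low-amplitude component keeps the 450–520 nm
valley at a realistic level; with the reference composition this puts
the particle index near 1.387 + 4e-4 i at 488 nm, in the range expected
for such particles. Amplitudes give a roughly 10:1 Soret-to-Q ratio.

The generator emulates: the Beer–Lambert geometry (10 mm cuvette), the
six-step dilution series of a 100-fold pre-diluted stock (10–670 µL
into 2.2 mL), multiplicative log-normal photometric noise, and — for QC
testing — a saturating multiple-scattering artefact that fills in
transmitted light where extinction is strong. It does *not* emulate
instrument straylight, dark current, wavelength calibration error,
particle-shape effects, or the systematic offset between measured and
simulated spectra; consequently, passing round-trip tests demonstrate
the self-consistency and conditioning of the inversion, not the
absolute accuracy of composition estimates on real instruments with
real literature optics.

All randomness flows through explicit seeds; noiseless synthesis
inverts exactly (to 1e-12) through the transmittance-to-$Z$ conversion.

## Problem sizes used by the test suite

Tests synthesize and fit spectra on a 10 nm wavelength grid (51 points
over 300–800 nm) with a 20 nm diameter quadrature step, and use the
0.025 simplex grid for the round-trip and noise-replicate studies; the
monodisperse, grid-convergence and oracle comparisons use the finer
defaults. These sizes are the package's reference configuration for
desk-scale validation; production fits on measured spectra can use the
native instrument sampling unchanged.

## Known limitations

* The bundled optics are synthetic stand-ins; quantitative work on real
  spectra requires measured increment tables
  (`read_species_optics()`).
* Only three hemoglobin states are modelled; carboxy- and
  sulf-hemoglobin are out of scope.
* Intra-particle concentrations are fixed during fraction fitting;
  joint fitting of $\beta$'s and fractions is not attempted.
* The PSD is an input, not inferred from the spectrum.
* The homogeneous-sphere approximation ignores the particles' waist and
  surface fine structure.
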