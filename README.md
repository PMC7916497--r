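# hboptics

Optical and densitometric characterization of hemoglobin-based
oxygen-carrier microparticles (HbMPs) in suspension, for researchers
developing artificial blood substitutes who need a rapid, non-destructive
quality control of particle function.

Sub-micrometer hemoglobin/albumin particles cannot be lysed and measured
in a blood-gas analyzer, and plain photometry is confounded by light
scattering. `hboptics` instead works with **collimated transmittance
spectra** of dilute suspensions: it models the particles as homogeneous
spheres whose complex refractive index is a superposition of the protein
constituents, predicts the ensemble-averaged extinction spectrum by
Lorenz–Mie theory, and inverts measured spectra to the mass fractions of
the three hemoglobin states — oxygenated (oxyHb), deoxygenated (deoxyHb)
and non-functional methemoglobin (metHb).

## The model

From a transmittance spectrum *T*(λ) measured over 300–800 nm in a
cuvette of path length ℓ at stock volume fraction φ, the
concentration-free **volume-specific extinction cross section** is

> *Z*(λ) = −ln *T*(λ) / (ℓ · PPV · φ)   [µm⁻¹]

where PPV is the packed particle volume of the stock. The forward model
predicts *Z*(λ) as

> *Z*(λ) = ∫ C_ext(λ; D) p(D) dD / ∫ (π/6) D³ p(D) dD

with C_ext from the Lorenz–Mie series for a sphere of diameter *D* and
complex refractive index

> n(λ) + iκ(λ) = n_H₂O(λ) + β_Hb [α_Hb(λ) + iγ_Hb(λ)]
>   + β_Gl/HSA [α_HSA(λ) + iγ_HSA(λ)],

where the hemoglobin increments α_Hb, γ_Hb are the fraction-weighted sums
over the three Hb states, the imaginary increments follow from molar
extinction coefficients via γ = ln10·ε·λ/(4πM), real increments are
derived from absorption by Kramers–Kronig transforms, and p(D) is a
log-normal size distribution (median µ_D, log-width σ_D). Composition
fitting minimizes Σ_λ (s·Z_model − Z_meas)² over the (oxy, deoxy, met)
simplex, optionally with a free scale *s*.

A companion densitometry module decomposes high-accuracy density
measurements into hemoglobin versus heme-free globin/HSA content via
density increments (DI = ∂ρ/∂β), yielding the intra-particle protein
concentrations that parameterize the optical model.

## Worked example

```r
library(hboptics)

# densitometry: decompose the measured density panel
panel <- density_panel(rho_sus = 1.01639, rho_sup = 1.00422,
                       rho_rac = 1.00320, ppv = 0.1992,
                       di_hb = 0.2450, di_glhsa = 0.2505)
particle_density(panel)
#> [1] 1.065314
solve_composition(panel, beta_hb_sus = 25.5)[, 1:5]
#> # A tibble: 1 × 5
#>   beta_hb_sus beta_glhsa_sus ratio_glhsa_hb beta_hb_sup beta_hb_hbmp
#>         <dbl>          <dbl>          <dbl>       <dbl>        <dbl>
#> 1        25.5           27.7           1.09        1.97         120.

# optical inversion of a (synthetic) measurement
psd <- lognormal_from_summary(median = 760, width_16_84 = 395)  # sigma_d 25.8%
m   <- synthesize_transmittance(hb_fractions(0.65, 0, 0.35), psd,
                                noise_sigma = 0.01, seed = 42)
z   <- transmittance_to_vsecs(m)
fit <- fit_fractions(z, psd, grid_step = 0.05)
tidy(fit)
#> # A tibble: 3 × 3
#>   term      estimate std.error
#>   <chr>        <dbl>     <dbl>
#> 1 phi_oxy   6.62e- 1   NA
#> 2 phi_deoxy 3.45e-10   NA
#> 3 phi_met   3.38e- 1    0.0669
```

The density panel yields a particle density of 1.0653 g/mL and, via the
density-increment balance, 120.1 g/L hemoglobin and ≈130 g/L heme-free
protein inside the particles — about half the intra-particle protein
carries no heme. The fit recovers the generating fractions of the
noisy synthetic spectrum (0.65/0/0.35) to about 0.01, with a
profile-curvature uncertainty on the metHb fraction consistent with the
±0.05 spread observed across noise replicates.

A thin command-line wrapper is installed under `exec/`:

```sh
hboptics density --panel panel.json
hboptics synth --phi-oxy 0.65 --phi-deoxy 0 --phi-met 0.35 --noise 0.01 --seed 42 --out t.csv
hboptics fit --spectrum z.csv
```

## Limitations

The bundled species optics are synthetic Gaussian-band stand-ins for
literature increment tables (see the methods vignette); substitute
measured tables via `read_species_optics()` for real analyses. Particles
are treated as optically homogeneous spheres; non-spherical shape,
porosity and coatings are not modelled.
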