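---
title: "Methods: modelling and detecting the liana spectral signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and detecting the liana spectral signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lianasignal)
```

This vignette is the package's account of its science: the models, the
assumptions behind them, the parameters that matter, the numerical
choices that were genuinely open, and what the synthetic-data tests do
and do not demonstrate about real data.

## The problem

Lianas are structural parasites: they climb host trees and deploy a
leaf layer on top of the host crown. Their leaves are built cheaply —
lower dry mass, water mass, chlorophyll and carotenoid content per unit
area, fewer mesophyll air–cell-wall interfaces (thinner leaves) — and
are held markedly flatter (mean inclination near 28° from zenith versus
37° for trees). Flat leaves project more area toward a near-nadir sun
and sensor, and cheap leaves absorb less and transmit more, so multiple
scattering inside the canopy increases. Both mechanisms brighten
infested canopies, most strongly in the NIR and SWIR. The package
provides the forward physics of that signal, Bayesian machinery to
invert it, an information-theoretic measure of how separable it is, and
simulations of how sensor spatial and spectral design limit its
detection.

## Leaf model

`prospect_forward()` implements the generalized plate model: the leaf
is one elementary plate (upper interface illuminated within a fixed
40° cone — a model constant, not a configuration knob) stacked on
`N − 1` identical internal layers, solved with the classical
closed form for a pile of identical plates. The per-plate absorption
argument is `k(λ) = Σ c_i a_i(λ) / N` over the constituents of the
chosen variant (`5`: chlorophyll, carotenoids, water, dry matter;
`5b`: + brown pigments; `D`: + anthocyanins), and the plate
transmissivity is `(1−k)e^{−k} + k²E₁(k)`.

Two numerical points. First, the closed form for the layer pile fails
gracefully in the conservative limit (`ρ + τ → 1`), where the analytic
limit `T = t/(t + (1−t)m)` is substituted. Second, `N` may be
non-integer; the closed form is verified in the tests against two
independent routes — iterative one-layer-at-a-time adding for integer
piles, and an eigendecomposition of the two-flux transfer matrix raised
to a real power for fractional piles — and the interface transmissivity
against direct quadrature of the Fresnel coefficients.

**Coefficient tables.** The bundled specific-absorption and
refractive-index curves are *synthetic*: smooth analytic spectra with
features at the documented positions (chlorophyll at 430/662 nm with a
sharp red-edge cutoff near 715 nm, carotenoids below ~550 nm,
anthocyanins near 546 nm, liquid-water overtones at 970/1200/1450/1940
nm and a rising tail toward 2500 nm, dry-matter features in the SWIR),
with magnitudes chosen so typical leaf parameters yield realistic
vegetation spectra. They are public-constant stand-ins, not a published
calibration — users with a calibrated table supply it via
`read_coefficient_table()`. For this reason no test pins absolute
reflectance values to the bundled table; tests assert invariants
(energy conservation, linearity, monotonicity) and cross-derivations on
whatever table is loaded.

## Canopy model

`foursail2_forward()` solves the two-layer four-stream problem: direct
solar flux, downward and upward diffuse flux, and radiance toward the
observer, in two homogeneous layers over a Lambertian soil. The liana
layer sits on top with leaf area `LAI·L·(1−f₂)`; the tree layer carries
the remainder, so total leaf area is conserved and `L = 0` reduces the
canopy to a single tree layer (the reduction is bit-exact, which the
tests assert). Each layer has its own particle mix and its own
ellipsoidal leaf-inclination distribution, discretized into the 13
conventional angle classes; the one-parameter ellipsoidal family is
used because only a mean angle is specified per layer. The dissociation
parameter `D` interpolates the top layer's composition between pure
liana (`D = 1`, the default and the study condition) and the global
mixture (`D = 0`), with the bottom layer balancing so liana leaf area
is conserved.

Multiple-scattering operators of the two layers compose by the exact
adding equations of the linear four-stream system. The
single-scattering bidirectional term — the one carrying the hotspot —
does *not* compose layer by layer: the sun-path/view-path gap
correlation spans the layer boundary. It is therefore computed jointly
over the whole stack with a piecewise-analytic correlation kernel
(decorrelation rate `2 d_so / (κ (k_s + k_o))` per layer, the classical
single-layer form), integrated by Gauss–Legendre quadrature. This makes
a homogeneous canopy split into two identical layers agree with the
single-layer solution to machine precision, which is the structural
test of the whole assembly.

The production path of the four-stream core and the plate kernel is
compiled (Rcpp), as is conventional for radiative-transfer packages
that sit inside MCMC loops; the pure-R reference implementations are
kept in the package and the two are compared at 1e-12 in the tests.

Verification against an independent solver: a slab-discretization
oracle (bottom-up adding of hundreds of first-order thin slabs, with
Richardson extrapolation) reproduces the analytic two-layer solution
within 1% on a dense black-soil configuration with the hotspot
disabled.

Surface reflectance mixes the direct-beam and diffuse-incidence terms
with a diffuse skylight fraction `S(λ, θ_s)`. The built-in `S` table is
a documented stand-in (Rayleigh-like `(400/λ)⁴` component plus a weak
aerosol tail, scaled with air mass), monotone non-increasing over
400–1000 nm and fully replaceable by a user table.

One physical subtlety: with the hotspot parameter `κ = b/H` held fixed,
the single-scattering hotspot term converges slowly as LAI grows,
because the decorrelation depth in leaf-area units scales with LAI
under the classical parametrization. The saturation test therefore
scales `κ` inversely with LAI (fixed leaf size `b`, canopy height `H`
growing with leaf area), under which reflectance changes by less than
0.5% between LAI 15 and 20 over black soil.

## Bayesian inversion

The likelihood is independent Gaussian per wavelength (or per sensor
band after response convolution) with a single residual standard
deviation `σ`, itself a model parameter. Priors: normal for leaf
parameters (means and variances from leaf-scale fits, via
`derive_priors()`), flat over physical ranges for canopy structure,
fixed for the design parameters (`L`, `D`, `Cv`, `ζ`, geometry).
Sensors with fewer than 10 bands are refused by default, because
parameter uncertainty degrades sharply at low spectral resolution; an
override flag exists.

`run_demc()` is a differential-evolution MCMC with a thinned history
archive: proposals are differences of archived states scaled by
`2.38/√(2d)` (jittered, with γ = 1 every tenth iteration for mode
jumps), 10% snooker updates along the direction to an archived state,
and 20% adaptive-covariance moves estimated from the archive tail. The
archive is seeded with prior draws and appended every ten iterations;
the first half of every chain is burn-in. Runs are bit-reproducible
from the seed. The convergence diagnostic uses the conservative form
`R̂ = √(1 + B/(nW))`, which is exactly 1 for identical chains and ≥ 1
by construction.

Per-leaf fitting at scale uses MAP with multi-start L-BFGS-B
(`invert_leaf()`), with two conditioning choices that matter in
practice: `σ` is profiled out analytically (the concentrated
log-likelihood is smooth in `log SSR` even near a perfect fit), and
`optim`'s `parscale` is set from the prior ranges (the parameters span
five orders of magnitude). Non-convergence and non-physical inputs are
flagged in the returned row, not raised as errors, since the intended
use is batch inversion of thousands of leaves.

The hierarchical trait decomposition
`T_ijk = β₀ + β_i + β_jk + β_k + ε` (growth form `i`, species `j`
nested in study `k`) is fitted with JAGS: weakly-informed growth-form
group means, exchangeable normal species and study effects with uniform
hyperpriors on their standard deviations, and the liana-minus-tree
contrast as the target quantity. The fit consumes trait point
estimates; feeding per-leaf posterior draws instead would be a natural
extension but the model is written on trait values. The
"overlap with zero" statistic is twice the smaller posterior tail
probability of the contrast — the two-sided convention, which centres
on 0.5 under a null effect and approaches 0 for a decisive one.

## Spectral divergence

Spectral distributions are summarized per wavelength by `(μ_λ, σ_λ)`.
The divergence of the focal distribution from the liana reference is
the Gaussian Kullback–Leibler divergence per wavelength,
`log(σ₀/σ_k) + (σ_k² + (μ_k−μ₀)²)/(2σ₀²) − ½`, integrated over
400–2500 nm by trapezoid (nats; per-nm normalization by flag). The
defining double-integral form is retained (`numeric_kld()`) purely as
the quadrature oracle; the closed form agrees with it to 1e-7 over
random parameter draws. Note the middle term carries the *focal*
variance `σ_k²` in its numerator — the only orientation that is
non-negative and that matches the defining integral; tests enforce
this.

For sensors, `sensor_cumulative_kld()` maps both distributions to bands
by response-weighted averaging of both the mean *and* the standard
deviation curves, then sums the per-band divergences. The σ convention
is deliberate: the spread of a canopy reflectance ensemble is dominated
by canopy-to-canopy variability, which is spectrally coherent, so a
band's spread is the averaged σ — it does not shrink with bandwidth the
way independent noise would. Under the alternative
(independence) propagation, wide bands acquire artificially small σ and
a six-band broadband sensor would outscore a hyperspectral one, which
inverts the physically meaningful ranking. Each band then scores
roughly the average per-wavelength divergence it samples, so cumulative
divergence rewards sensors that place more bands in the informative
NIR/SWIR region; band aggregation by mean is available as an option.
`band_convolve()` keeps the independence-variance contract, which is
the correct propagation for the iid measurement-noise likelihood.

## Trait-swap sensitivity

`trait_swap_experiment()` parameterizes the top canopy layer with tree
traits, measures the integrated divergence from the liana-parameterized
reference (`d_base`), then swaps parameter subsets to their liana
values; the impact of a swap is `d_base − d_swap`, positive when the
swap moves the prediction toward the liana signal. Model
configurations define spectral distributions with μ = predicted
reflectance and a constant σ equal to the inversion residual. Pairwise
interactive components are reported both as raw pair impacts and as
`impact(pair) − impact(a) − impact(b)`, since either convention
appears in practice. Per-wavelength impact curves are evaluated the
same way wavelength by wavelength.

One expectation worth stating precisely: the chlorophyll swap's
per-wavelength impact peaks at the *red edge* (~705–720 nm), not below
700 nm — that is where reflectance is steepest in chlorophyll content
under any realistic absorption coefficient — while remaining negligible
(<10% of impact mass) beyond 800 nm. The leaf-angle swap, by contrast,
acts through projected area, which is wavelength-neutral, and shows
impact across VIS, NIR and SWIR alike.

## Scene detectability simulations

`generate_scene()` produces clustered infestation maps: Gaussian white
noise smoothed by an isotropic Gaussian kernel (periodic boundaries,
FFT), thresholded at the sample quantile so the target prevalence
(default 0.5, roughly equal infested and uninfested area) is met
exactly. The kernel scale is set from the target mean cluster area by a
pre-computed power law, `area ≈ e^{4.61} σ^{1.93}`, fitted on
1000×1000 scenes at prevalence 0.5 (mean connected-component area,
4-connectivity); realized mean cluster areas track targets within 25%
at the 350 and 2000 m² scales on grids large enough to hold many
clusters. `cluster_area = 1` skips smoothing and gives spatially
independent placement — the random baseline.

Rendering draws each 1-m² pixel independently from its class endmember
distribution; coarsening is the block mean of reflectance (linear
area-weighted mixing within a sensor footprint — the nonlinear mixing
of the canopy model applies within a canopy, not across footprints),
with edge remainders cropped. Coarse pixels are labelled feature by
majority rule (feature fraction ≥ 0.5; an any-feature rule is available
since the convention is not uniquely determined).

The divergence reported at each resolution is the *expected* KLD
between the feature-labelled and background-labelled areas: class means
are the empirical group means of the coarse pixels — diluted by
sub-pixel mixing as resolution degrades — while class standard
deviations are held at the endmember values. Two alternatives were
rejected for cause. Fully empirical group moments let block averaging
shrink the iid rendering noise, so pure-class blocks become *more*
separable with coarsening — an artifact, since real canopy-to-canopy
variability is spatially coherent and does not average out within a
footprint. And the plug-in estimator carries a positive O(1/n) bias
that floors the curve once groups shrink to a handful of coarse pixels.
The implementation debiases the squared mean separation by the sampling
variance of the group means, so curves decay toward zero as they
should. Under these conventions the simulations reproduce the expected
phenomenology: curves start at the endmember divergence at 1 m, decay
monotonically with aggregation, extensive (30,000 m²) clusters hold
signal at or above the random-placement baseline, and crown-scale
(350 m²) clusters lose most of their signal by ~25–30 m resolution.

## Synthetic study conditions

The generator defaults define the study conditions everywhere
(tests, acceptance runs, examples):

| Trait | Tree | Liana | Units |
|---|---|---|---|
| N | 1.9 ± 0.30 | 1.6 ± 0.20 | interfaces |
| C_ab | 42 ± 8 | 34 ± 7 | µg/cm² |
| C_ar | 11 ± 2.5 | 8.5 ± 2.0 | µg/cm² |
| C_an | 1.0 ± 0.5 | 0.8 ± 0.4 | µg/cm² |
| C_br | 0.10 ± 0.05 | 0.10 ± 0.05 | arbitrary |
| C_w | 0.012 ± 0.003 | 0.009 ± 0.0025 | g/cm² |
| C_m | 0.010 ± 0.0025 | 0.0075 ± 0.002 | g/cm² |
| angle | 37.1 ± 10 | 27.9 ± 8 | degrees |

Angle means are the field-measured values; the other contrasts encode
the documented direction of every liana–tree difference at 15–30%
relative magnitude, with liana and tree means within one standard
deviation of each other (the leaf-level overlap property). Draws are
truncated normals over the physical ranges — truncated rather than
log-normal for simple moment control, consistent with normal priors at
canopy scale. Canopy conditions: LAI 5.5, `f₂ = 0.66`, `L ∈ {0, 1}`
for the endmember classes, `D = 1`, `Cv = 1` (making crown shape `ζ`
inert), hotspot 0.05, soil moisture 0.5, sun at 30° zenith, nadir view.
Residual reflectance noise is 0.01 at canopy scale and 0.005 at leaf
scale.

What passing tests show — and do not. The generators draw iid traits
and iid residual noise from the very families the models assume, so the
recovery and coverage results demonstrate the *internal* correctness of
the inversion machinery (no bias, honest credible intervals, correct
information accounting), not robustness to real-data pathologies:
correlated residuals, instrument artifacts, mis-specified leaf-angle
families, within-crown trait gradients or atmospheric effects are all
outside what these tests can certify. The detectability simulations
likewise exclude sensor noise floors and atmospheric transfer — they
are best-case bounds by construction.

## Problem sizes used in the packaged runs

The packaged test and acceptance runs use deliberately modest sizes,
chosen so the full pipeline demonstrates its properties at desk scale:
canopy inversion coverage at 20 replicates (4 chains × 8000 DE-MC
iterations on a 15-nm grid, leaf parameters fixed at their prior means
so the sampled dimensions are LAI, Ω₁, Ω₂, f₂ and σ); hierarchical
recovery at 3 studies × 40 species; endmember ensembles of 100 canopies
per class for the sensor comparison; and scene curves at 50 replicates
on 200×200-m scenes across cluster areas 350 / 2,000 / 30,000 m² with
resolutions 1–50 m. Larger runs (1000×1000 scenes to 250 m, more
replicates, sampled leaf parameters) are a matter of passing different
arguments to the same functions.

## Known limitations

* One-dimensional turbid-medium canopy: no crown geometry (`Cv` is
  fixed at 1), no topographic or 3-D effects.
* A single residual σ across wavelengths; heteroscedastic errors are
  not modelled.
* The bundled coefficient, soil and skylight tables are synthetic
  stand-ins; absolute reflectance values depend on them even though the
  package's qualitative and structural results do not.
* The scene generator controls mean cluster area and prevalence but not
  cluster shape statistics; on small grids very large cluster targets
  are limited by the scene extent.
* Leaf-angle distributions are the one-parameter ellipsoidal family;
  bimodal or plagiophile canopies are outside it.
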