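# lianasignal

Mechanistic modelling and detectability analysis of the liana spectral
signal in tropical forest canopies.

Lianas (woody vines) overtop their host trees with a layer of cheaply
constructed leaves — thinner, with lower pigment, water and dry-mass
content per area — held about 25% flatter than tree leaves. Both traits
push canopy reflectance up, most strongly in the near- and short-wave
infrared, which is why liana-infested canopies look consistently
brighter to airborne and satellite sensors. `lianasignal` implements the
full modelling chain needed to study, invert and exploit that signal,
for remote-sensing ecologists who want to test liana-detection ideas
without assembling field campaigns first.

## What is inside

The forward model is the classical coupled leaf–canopy chain

```
tau_i, rho_i = PROSPECT(lambda, N_i, C_ab, C_ar, C_an, C_br, C_w, C_m)      i = 1 (liana), 2 (tree)
rho_d, rho_s = 4SAIL2-type two-layer four-stream model(
                 tau_1, rho_1, tau_2, rho_2, LAI, L(1 - f2),
                 Omega_1, Omega_2, D, kappa, theta_s, theta_o, psi, soil)
rho(lambda)  = S(lambda, theta_s) rho_d + (1 - S) rho_s
```

with the liana layer on top carrying the LAI share `L (1 - f2)` (`L` =
infestation index, `f2` = tree fraction at full infestation), so the
canopy collapses to a pure tree layer at `L = 0`. Around it:

* **Leaf model** — generalized plate model (Stokes closed form for the
  internal layer pile), any of the 5 / 5b / D constituent sets,
  energy-conserving to 1e-10.
* **Canopy model** — two-layer four-stream solution with per-layer
  ellipsoidal leaf-angle distributions, hotspot correction computed
  jointly across both layers, and a Lambertian dry/wet-mixed soil.
* **Bayesian inversion** — Gaussian spectral likelihood, leaf-informed
  priors, differential-evolution MCMC with snooker updates
  (`run_demc()`), fast multi-start MAP for per-leaf fitting
  (`invert_leaf()`), and Gelman–Rubin diagnostics.
* **Hierarchical trait model** — `T_ijk = beta0 + beta_i + beta_jk +
  beta_k + eps` for growth form `i`, species `j` nested in study `k`,
  fitted with JAGS (`fit_leaf_hierarchy()`).
* **Spectral divergence** — per-wavelength, integrated and sensor-band
  Gaussian Kullback–Leibler divergence between liana and tree spectral
  distributions (`gaussian_kld()`, `sensor_cumulative_kld()`), with
  built-in Landsat-5 TM, WorldView-2 and Hyperion band models.
* **Trait-swap sensitivity** — swap single traits or pairs from tree to
  liana values and measure the divergence moved toward the liana signal
  (`trait_swap_experiment()`, `interaction_effect()`).
* **Scene simulation** — clustered infestation maps at controlled mean
  cluster area, reflectance rendering, block-mean coarsening from 1 m to
  coarse satellite footprints, and divergence-versus-resolution curves
  against a random-placement baseline (`generate_scene()`,
  `scene_kld_curve()`).
* **Synthetic data** — trait, leaf-spectra, canopy-ensemble and
  trait-table generators with known ground truth, so every stage of the
  pipeline is testable end to end.

## Worked example

Simulate a fully infested canopy over its host-tree counterpart:

```r
library(lianasignal)

ref <- couple_prosail2(
  liana_leaf = leaf_params(N = 1.6, C_ab = 34, C_ar = 8.5, C_w = 0.009, C_m = 0.0075),
  tree_leaf  = leaf_params(N = 1.9, C_ab = 42, C_ar = 11,  C_w = 0.012, C_m = 0.010),
  canopy     = canopy_config(lai = 5.5, omega1 = 27.9, omega2 = 37.1,
                             f2 = 0.66, L = 1)
)
dplyr::filter(ref, wavelength_nm %in% c(550, 670, 865, 1610, 2200))
#>   wavelength_nm  rho_s  rho_d    rho
#> 1           550 0.0999 0.0853 0.0977
#> 2           670 0.0233 0.0187 0.0228
#> 3           865 0.629  0.589  0.626
#> 4          1610 0.351  0.321  0.349
#> 5          2200 0.0431 0.0364 0.0428
```

`rho_s` is the direct-beam (bidirectional) reflectance, `rho_d` the
diffuse-incidence reflectance, and `rho` their sky-condition mix: the
familiar vegetation spectrum with a dark red chlorophyll trough
(0.023 at 670 nm), a bright NIR plateau (0.63 at 865 nm) and water-driven
SWIR absorption. Two bookkeeping one-liners reproduce the headline
field numbers: at a measured tree fraction `f2 = 0.653`, lianas hold

```r
100 * liana_lai_fraction(L = 1, f2 = 0.653)   # 34.7  (% of total plant area)
summarize_trait_contrast(27.9, 37.1)          # -24.8 (% flatter liana leaf angles)
```

And the sensor comparison on default synthetic endmember ensembles
(`canopy_endmembers()`) ranks platforms by how much of the informative
NIR/SWIR region their bands sample:

```r
em <- canopy_endmembers(n_per_class = 30, seed = 1)
sensor_cumulative_kld(em$liana, em$tree, sensor_model("hyperion"))    # 75.9
sensor_cumulative_kld(em$liana, em$tree, sensor_model("worldview2"))  #  1.83
sensor_cumulative_kld(em$liana, em$tree, sensor_model("landsat5_tm")) #  1.64
```

`autoplot()` methods exist for leaf optics, canopy spectra and
trait-swap tables, and `plot_kld_curves()` draws the
divergence-versus-resolution figures.

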