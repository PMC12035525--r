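test_that("trait sampling is reproducible, truncated and contrast-calibrated", {
  a <- sample_traits("liana", n = 50, seed = 9)
  b <- sample_traits("liana", n = 50, seed = 9)
  expect_identical(a, b)

  # zero-SD configuration collapses to the means
  cfg <- trait_defaults()
  cfg$sd <- 0
  c0 <- sample_traits("tree", n = 5, config = cfg, seed = 1)
  expect_equal(unique(c0$angle), 37.1)
  expect_equal(unique(c0$C_m), 0.010)

  # large-sample angle contrast reproduces the field-measured -24.8%
  nl <- sample_traits("liana", n = 10000, seed = 2)
  nt <- sample_traits("tree", n = 10000, seed = 3)
  contrast <- summarize_trait_contrast(mean(nl$angle), mean(nt$angle))
  expect_equal(contrast, -24.8, tolerance = 0.05)

  # draws respect physical bounds
  big <- sample_traits("liana", n = 2000, seed = 4)
  expect_true(all(big$N >= 1 & big$N <= 3.5))
  expect_true(all(big$angle >= 5 & big$angle <= 85))
})

test_that("synthetic leaf spectra carry calibrated noise and liana optics", {
  # noise calibration: repeated spectra of one leaf have sd ~ noise_sd
  cfg <- trait_defaults()
  cfg$sd <- 0
  gen <- generate_leaf_spectra(
    n = 100, growth_form = "tree", noise_sd = 0.005, seed = 5, config = cfg
  )
  per_wl_sd <- apply(gen$spectra, 2, sd)
  mid <- 400:1200 # indices away from clip-prone dark regions
  expect_equal(mean(per_wl_sd[mid]), 0.005, tolerance = 0.1)

  # zero noise reproduces the forward model exactly
  g0 <- generate_leaf_spectra(n = 2, noise_sd = 0, seed = 6)
  expect_equal(g0$spectra[1, ], g0$optics[[1]]$reflectance)

  # liana leaves transmit more and absorb less in the NIR than tree leaves
  gl <- generate_leaf_spectra(n = 40, growth_form = "liana", seed = 7)
  gt <- generate_leaf_spectra(n = 40, growth_form = "tree", seed = 8)
  nir <- spectral_grid() >= 800 & spectral_grid() <= 1300
  tau_l <- mean(sapply(gl$optics, function(o) mean(o$transmittance[nir])))
  tau_t <- mean(sapply(gt$optics, function(o) mean(o$transmittance[nir])))
  alpha_l <- mean(sapply(gl$optics, function(o) mean(o$absorption[nir])))
  alpha_t <- mean(sapply(gt$optics, function(o) mean(o$absorption[nir])))
  expect_gt(tau_l, tau_t)
  expect_lt(alpha_l, alpha_t)
})

test_that("infested canopies reflect more NIR light than liana-free ones", {
  sim <- generate_canopy_spectra(
    n_per_class = 8, L_levels = c(0, 1), seed = 10,
    wavelengths = seq(400, 2500, by = 20)
  )
  nir <- sim$wavelength_nm >= 780 & sim$wavelength_nm <= 1300
  m1 <- mean(sim$rho[sim$L == 1 & nir])
  m0 <- mean(sim$rho[sim$L == 0 & nir])
  expect_gt(m1, m0)

  # identical class settings are statistically indistinguishable
  sim00 <- generate_canopy_spectra(
    n_per_class = 8, L_levels = c(0, 0), seed = 11,
    wavelengths = seq(400, 2500, by = 20)
  )
  cls <- unique(sim00[, c("L", "canopy_id")])
  wide <- tidyr::pivot_wider(sim00,
    id_cols = "canopy_id",
    names_from = "wavelength_nm", values_from = "rho"
  )
  first <- as.matrix(wide[1:8, -1])
  second <- as.matrix(wide[9:16, -1])
  diff <- abs(mean(first) - mean(second))
  pooled_se <- sd(rbind(first, second)) / sqrt(8)
  expect_lt(diff, 4 * pooled_se)
})

test_that("hierarchical trait tables have the configured structure", {
  tb <- generate_trait_table(
    n_studies = 3, n_species = 10, seed = 12,
    gf_contrast = -0.002
  )
  expect_setequal(unique(tb$growth_form), c("liana", "tree"))
  expect_equal(length(unique(tb$study)), 3)
  # species nested in study: each species appears in exactly one study
  nest <- table(tb$species, tb$study) > 0
  expect_true(all(rowSums(nest) == 1))

  # zero-variance table is constant apart from the growth-form offsets
  tb0 <- generate_trait_table(
    n_studies = 2, n_species = 4, sd_species = 0, sd_study = 0,
    sd_resid = 0, beta0 = 0.01, gf_contrast = -0.002, seed = 13
  )
  vals <- tapply(tb0$value, tb0$growth_form, unique)
  expect_equal(unname(vals[["liana"]] - vals[["tree"]]), -0.002)
})
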