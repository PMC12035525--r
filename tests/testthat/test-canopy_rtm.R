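lo <- prospect_forward(liana_leaf_default())
to <- prospect_forward(tree_leaf_default())

test_that("limits: bare soil, zero infestation, identical particles", {
  # LAI = 0 returns the effective soil reflectance in both streams
  cc0 <- canopy_config(lai = 0)
  soil <- soil_model(cc0$omega_soil)
  r0 <- foursail2_forward(lo, to, cc0, view_geometry(), soil)
  expect_equal(r0$rho_s, soil$reflectance)
  expect_equal(r0$rho_d, soil$reflectance)

  # L = 0: output bit-identical under arbitrary liana optics
  ccL0 <- canopy_config(L = 0)
  set.seed(5)
  for (i in 1:10) {
    other <- prospect_forward(random_leaf_params())
    rA <- foursail2_forward(lo, to, ccL0)
    rB <- foursail2_forward(other, to, ccL0)
    expect_identical(rA$rho_s, rB$rho_s)
    expect_identical(rA$rho_d, rB$rho_d)
  }

  # identical particle types and angles: the layer split is invisible
  cc_same <- canopy_config(omega1 = 37.1, omega2 = 37.1, L = 0.5)
  cc_one <- canopy_config(omega1 = 37.1, omega2 = 37.1, L = 0)
  ra <- foursail2_forward(to, to, cc_same)
  rb <- foursail2_forward(to, to, cc_one)
  expect_equal(ra$rho_s, rb$rho_s, tolerance = 1e-9)
  expect_equal(ra$rho_d, rb$rho_d, tolerance = 1e-9)
})

test_that("bidirectional reflectance is reciprocal and shows the hotspot", {
  cc <- canopy_config()
  rx <- foursail2_forward(lo, to, cc, view_geometry(40, 10, 70))
  ry <- foursail2_forward(lo, to, cc, view_geometry(10, 40, 70))
  expect_equal(rx$rho_s, ry$rho_s, tolerance = 1e-8)

  rh <- foursail2_forward(lo, to, cc, view_geometry(30, 30, 0))
  ra <- foursail2_forward(lo, to, cc, view_geometry(30, 30, 180))
  expect_true(all(rh$rho_s >= ra$rho_s))
})

test_that("reflectance stays in [0, 1] across random configurations", {
  set.seed(7)
  for (i in 1:60) {
    cc <- canopy_config(
      lai = runif(1, 0, 9), omega1 = runif(1, 10, 75),
      omega2 = runif(1, 10, 75), f2 = runif(1), L = runif(1),
      D = runif(1), hot = runif(1, 0, 0.3), omega_soil = runif(1)
    )
    gm <- view_geometry(runif(1, 0, 65), runif(1, 0, 55), runif(1, 0, 360))
    r <- foursail2_forward(lo, to, cc, gm, soil_model(cc$omega_soil),
      wavelengths = seq(400, 2500, by = 50)
    )
    expect_true(all(r$rho_s >= 0 & r$rho_s <= 1))
    expect_true(all(r$rho_d >= 0 & r$rho_d <= 1))
  }
})

test_that("dense-canopy reflectance approaches an asymptote over black soil", {
  # Fixed leaf width: the hotspot parameter b/H shrinks as the canopy
  # deepens, so kappa scales inversely with LAI here.
  black <- soil_model(0, dry = rep(0, 2101), wet = rep(0, 2101))
  r15 <- foursail2_forward(lo, to, canopy_config(lai = 15, hot = 0.275 / 15),
    view_geometry(),
    soil = black
  )
  r20 <- foursail2_forward(lo, to, canopy_config(lai = 20, hot = 0.275 / 20),
    view_geometry(),
    soil = black
  )
  expect_lt(max(abs(r20$rho_s - r15$rho_s) / r15$rho_s), 0.005)
  expect_lt(max(abs(r20$rho_d - r15$rho_d) / r15$rho_d), 0.005)
})

test_that("flatter top-layer leaf angles raise nadir NIR reflectance", {
  flat <- foursail2_forward(lo, to, canopy_config(omega1 = 20), view_geometry())
  steep <- foursail2_forward(lo, to, canopy_config(omega1 = 50), view_geometry())
  nir <- flat$wavelength_nm >= 780 & flat$wavelength_nm <= 1300
  expect_true(all(flat$rho_s[nir] > steep$rho_s[nir]))
})

test_that("two-layer solution matches the slab-discretization oracle", {
  # Fixed configuration, black soil, dense canopy, no hotspot
  # correlation; sparse wavelength set for the slow oracle.
  idx <- lianasignal:::grid_index(seq(450, 2450, by = 50))
  cc <- canopy_config(
    lai = 10, omega1 = 25, omega2 = 40, f2 = 0.66, L = 1, hot = 0
  )
  gm <- view_geometry(30, 20, 90)
  black <- rep(0, length(idx))
  r1 <- lo$reflectance[idx]
  t1 <- lo$transmittance[idx]
  r2 <- to$reflectance[idx]
  t2 <- to$transmittance[idx]
  got <- lianasignal:::foursail2_core(r1, t1, r2, t2, black, cc, gm)
  ora <- slab_oracle(r1, t1, r2, t2, black, cc, gm, n_slabs = 600)
  expect_lt(max(abs(got$rso - ora$rso) / pmax(ora$rso, 1e-4)), 0.01)
  expect_lt(max(abs(got$rdo - ora$rdo) / pmax(ora$rdo, 1e-4)), 0.01)
})

test_that("compiled four-stream core agrees with the R reference", {
  idx <- lianasignal:::grid_index(seq(400, 2500, by = 25))
  set.seed(13)
  for (i in 1:5) {
    cc <- canopy_config(
      lai = runif(1, 0.5, 8), omega1 = runif(1, 12, 70),
      omega2 = runif(1, 12, 70), f2 = runif(1), L = runif(1),
      D = runif(1), hot = runif(1, 0, 0.2), omega_soil = runif(1)
    )
    gm <- view_geometry(runif(1, 0, 60), runif(1, 0, 50), runif(1, 0, 360))
    ws <- soil_model(cc$omega_soil)$reflectance[idx]
    a <- lianasignal:::foursail2_core(
      lo$reflectance[idx], lo$transmittance[idx],
      to$reflectance[idx], to$transmittance[idx], ws, cc, gm
    )
    b <- lianasignal:::foursail2_core_r(
      lo$reflectance[idx], lo$transmittance[idx],
      to$reflectance[idx], to$transmittance[idx], ws, cc, gm
    )
    expect_equal(a$rso, b$rso, tolerance = 1e-12)
    expect_equal(a$rdo, b$rdo, tolerance = 1e-12)
  }
})

test_that("diffuse fraction mixes the two streams as configured", {
  cc <- canopy_config()
  gm <- view_geometry()
  ll <- liana_leaf_default()
  tl <- tree_leaf_default()
  soil <- soil_model(cc$omega_soil)

  r0 <- couple_prosail2(ll, tl, cc, gm, soil, diffuse = diffuse_fraction(force = 0))
  rs <- foursail2_forward(lo, to, cc, gm, soil)
  expect_equal(r0$rho, rs$rho_s)

  r1 <- couple_prosail2(ll, tl, cc, gm, soil, diffuse = diffuse_fraction(force = 1))
  expect_equal(r1$rho, rs$rho_d)

  # default table: short wavelengths are more diffuse (Rayleigh regime)
  s <- diffuse_fraction(30)
  i450 <- match(450, spectral_grid())
  i850 <- match(850, spectral_grid())
  expect_gt(s[i450], s[i850])
  vis <- 1:601 # 400-1000 nm
  expect_true(all(diff(s[vis]) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("coupled chain equals the manual composition", {
  cc <- canopy_config()
  gm <- view_geometry()
  soil <- soil_model(cc$omega_soil)
  tab <- prospect_coefficients("D")
  got <- couple_prosail2(
    liana_leaf_default(), tree_leaf_default(), cc, gm, soil, tab
  )
  manual <- foursail2_forward(
    prospect_forward(liana_leaf_default(), tab),
    prospect_forward(tree_leaf_default(), tab), cc, gm, soil
  )
  s <- diffuse_fraction(gm$tts)
  expect_equal(got$rho_s, manual$rho_s)
  expect_equal(got$rho, s * manual$rho_d + (1 - s) * manual$rho_s)
})

test_that("liana LAI share follows the layer-partition rule", {
  expect_equal(liana_lai_fraction(1, 0.653), 0.347)
  expect_equal(liana_lai_fraction(1, 0.66), 0.34)
  expect_equal(liana_lai_fraction(0, 0.3), 0)
  set.seed(17)
  for (i in 1:20) {
    L <- runif(1)
    f2 <- runif(1)
    expect_equal(liana_lai_fraction(L, f2), L * (1 - f2))
  }
  expect_error(liana_lai_fraction(1.2, 0.5), "\\[0, 1\\]")

  # total liana leaf area is conserved under partial dissociation
  comp <- lianasignal:::layer_composition(L = 0.8, f2 = 0.6, D = 0.4)
  lai <- 6
  lai_top <- lai * comp$fl
  lai_bot <- lai - lai_top
  expect_equal(
    lai_top * comp$p_top + lai_bot * comp$p_bot,
    lai * liana_lai_fraction(0.8, 0.6)
  )
})

test_that("configuration objects validate their bounds", {
  expect_error(canopy_config(L = 1.3), "\\[0, 1\\]")
  expect_error(canopy_config(lai = -1), ">= 0")
  expect_error(view_geometry(tts = 95), "\\[0, 90\\)")
  expect_error(soil_model(2), "\\[0, 1\\]")
  sm <- soil_model(0.3)
  expect_equal(sm$reflectance, 0.7 * sm$dry + 0.3 * sm$wet)
})
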