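test_that("total absorption is the normalized constituent sum", {
  tab <- prospect_coefficients("D")

  # zero-absorber leaf
  p0 <- leaf_params(N = 2, C_ab = 0, C_ar = 0, C_an = 0, C_br = 0, C_w = 0, C_m = 0)
  expect_equal(total_absorption(p0, tab), rep(0, 2101))

  # linearity: doubling every content doubles k at fixed N
  set.seed(11)
  p1 <- random_leaf_params()
  p2 <- p1
  for (f in c("C_ab", "C_ar", "C_an", "C_br", "C_w", "C_m")) p2[[f]] <- 2 * p1[[f]]
  p2 <- do.call(leaf_params, unclass(p2))
  expect_equal(total_absorption(p2, tab), 2 * total_absorption(p1, tab),
    tolerance = 1e-12
  )

  # equals a naive elementwise dot product over constituents
  k_naive <- (p1$C_ab * tab$k_cab + p1$C_ar * tab$k_car + p1$C_an * tab$k_can +
    p1$C_br * tab$k_brown + p1$C_w * tab$k_cw + p1$C_m * tab$k_cm) / p1$N
  expect_equal(total_absorption(p1, tab), k_naive, tolerance = 1e-14)

  # invalid inputs
  expect_error(leaf_params(N = 0.5), "N must be")
  expect_error(leaf_params(C_ab = -3), ">= 0")
})

test_that("interface transmissivity matches Fresnel cone integration", {
  for (alpha in c(40, 90)) {
    for (n in c(1.3, 1.45, 1.52)) {
      expect_equal(lianasignal:::tav(alpha, n), fresnel_tav(alpha, n),
        tolerance = 1e-7
      )
    }
  }
})

test_that("plate model conserves energy and behaves physically", {
  tab <- prospect_coefficients("D")

  # no absorbers: alpha = 0 and rho + tau = 1 everywhere
  o0 <- prospect_forward(
    leaf_params(N = 1.8, C_ab = 0, C_ar = 0, C_an = 0, C_br = 0, C_w = 0, C_m = 0),
    tab
  )
  expect_lt(max(abs(o0$absorption)), 1e-12)
  expect_equal(o0$reflectance + o0$transmittance, rep(1, 2101), tolerance = 1e-12)

  # energy conservation over many random draws
  set.seed(21)
  worst <- 0
  for (i in 1:1000) {
    p <- random_leaf_params()
    o <- prospect_forward(p, tab)
    worst <- max(worst, max(abs(o$reflectance + o$transmittance + o$absorption - 1)))
    if (i <= 50) {
      expect_true(all(o$reflectance > 0 & o$reflectance < 1))
      expect_true(all(o$transmittance > 0 & o$transmittance < 1))
    }
  }
  expect_lt(worst, 1e-10)

  # more chlorophyll cannot raise reflectance at the red absorption peak
  lo <- prospect_forward(leaf_params(C_ab = 20), tab)
  hi <- prospect_forward(leaf_params(C_ab = 80), tab)
  i670 <- match(670, lo$wavelength_nm)
  expect_lte(hi$reflectance[i670], lo$reflectance[i670])

  # more interfaces scatter more: NIR reflectance increases with N
  n_lo <- prospect_forward(leaf_params(N = 1.2), tab)
  n_hi <- prospect_forward(leaf_params(N = 2.5), tab)
  nir <- lo$wavelength_nm >= 800 & lo$wavelength_nm <= 1200
  expect_true(all(n_hi$reflectance[nir] > n_lo$reflectance[nir]))
})

test_that("closed-form layer pile matches independent oracles", {
  tab <- prospect_coefficients("D")
  set.seed(31)
  p_int <- leaf_params(N = 3, C_ab = 40, C_ar = 10, C_w = 0.01, C_m = 0.009)
  k <- total_absorption(p_int, tab)
  theta <- lianasignal:::plate_transmissivity(k)
  nr <- tab$refractive_index
  t12 <- lianasignal:::tav(90, nr)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * theta^2
  t <- t12 * theta * t21 / denom
  r <- r12 + r21 * theta * t

  # integer N - 1 = 2: iterative stacking
  cf <- lianasignal:::plate_stack_closed_form(r, t, 2)
  it <- stack_iterative(r, t, 2)
  expect_equal(cf$R, it$R, tolerance = 1e-12)
  expect_equal(cf$T, it$T, tolerance = 1e-12)

  # fractional N - 1 = 0.5 at two witness wavelengths: transfer-matrix
  # eigen-power route
  for (wl in c(550, 1600)) {
    i <- match(wl, tab$wavelength_nm)
    tm <- stack_transfer_matrix(r[i], t[i], 0.5)
    cf5 <- lianasignal:::plate_stack_closed_form(r[i], t[i], 0.5)
    expect_equal(cf5$R, tm$R, tolerance = 1e-10)
    expect_equal(cf5$T, tm$T, tolerance = 1e-10)
  }
})

test_that("full-leaf reflectance matches an independent plate re-derivation", {
  # N = 1.5 leaf: compose the elementary plate and the fractional pile
  # via the transfer-matrix oracle, then couple them by interface adding.
  tab <- prospect_coefficients("D")
  p <- leaf_params(N = 1.5, C_ab = 40, C_ar = 10, C_an = 0, C_br = 0, C_w = 0.01, C_m = 0.009)
  out <- prospect_forward(p, tab)
  for (wl in c(550, 1600)) {
    i <- match(wl, tab$wavelength_nm)
    k <- total_absorption(p, tab)[i]
    theta <- lianasignal:::plate_transmissivity(k)
    nr <- tab$refractive_index[i]
    talf <- lianasignal:::tav(40, nr)
    t12 <- lianasignal:::tav(90, nr)
    t21 <- t12 / nr^2
    r21 <- 1 - t21
    dn <- 1 - r21^2 * theta^2
    Ta <- talf * theta * t21 / dn
    Ra <- (1 - talf) + r21 * theta * Ta
    t <- t12 * theta * t21 / dn
    r <- (1 - t12) + r21 * theta * t
    sub <- stack_transfer_matrix(r, t, 0.5)
    dnm <- 1 - sub$R * r
    expect_equal(out$transmittance[i], Ta * sub$T / dnm, tolerance = 1e-9)
    expect_equal(out$reflectance[i], Ra + Ta * sub$R * t / dnm, tolerance = 1e-9)
  }
})

test_that("anthocyanin-free D variant matches 5b outside the visible", {
  pD <- leaf_params(N = 1.7, C_ab = 35, C_ar = 9, C_an = 0, C_br = 0.2, C_w = 0.01, C_m = 0.008)
  oD <- prospect_forward(pD, prospect_coefficients("D"))
  o5b <- prospect_forward(pD, prospect_coefficients("5b"))
  beyond <- oD$wavelength_nm > 800
  expect_lt(max(abs(oD$reflectance[beyond] - o5b$reflectance[beyond])), 1e-6)
})

test_that("compiled fast path agrees with the R reference", {
  tab <- prospect_coefficients("D")
  idx <- seq(1, 2101, by = 7)
  set.seed(41)
  for (i in 1:5) {
    p <- unclass(random_leaf_params())
    a <- lianasignal:::prospect_rt(p, tab, idx)
    b <- lianasignal:::prospect_rt_r(p, tab, idx)
    expect_equal(a$rho, b$rho, tolerance = 1e-12)
    expect_equal(a$tau, b$tau, tolerance = 1e-12)
  }
})

test_that("coefficient tables validate and round-trip through text files", {
  tab <- prospect_coefficients("D")
  expect_equal(nrow(tab), 2101)
  expect_true(all(tab$refractive_index > 1))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_coefficient_table(tab, path)
  back <- read_coefficient_table(path)
  expect_equal(back$k_cw, tab$k_cw, tolerance = 1e-6)

  bad <- tab
  bad$k_cab[5] <- -1
  expect_error(lianasignal:::validate_coefficient_table(bad), ">= 0")
})
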