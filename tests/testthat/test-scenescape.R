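# Small shared endmembers: well-separated Gaussian classes so scene
# statistics are testable on modest grids.
toy_endmembers <- function(sep = 0.05, sigma = 0.02) {
  wl <- spectral_grid()
  base <- 0.25 + 0.15 * exp(-0.5 * ((wl - 900) / 250)^2)
  list(
    tree = spectral_distribution(base, sigma),
    liana = spectral_distribution(base + sep, sigma)
  )
}

test_that("scene generation meets prevalence, determinism and randomness limits", {
  sc <- generate_scene(cluster_area = 350, seed = 1, grid_size = 200)
  expect_equal(sc$prevalence, 0.5, tolerance = 0.01)
  expect_true(all(sc$grid %in% c(0, 1)))

  sc2 <- generate_scene(cluster_area = 30000, seed = 4, grid_size = 200)
  sc3 <- generate_scene(cluster_area = 30000, seed = 4, grid_size = 200)
  expect_identical(sc2$grid, sc3$grid)

  # cluster_area = 1: spatially independent pixels
  rnd <- generate_scene(cluster_area = 1, seed = 5, grid_size = 200)
  expect_lt(abs(scene_autocorrelation(rnd)), 0.01)
  # clustered scenes are strongly autocorrelated
  expect_gt(scene_autocorrelation(sc), 0.5)

  expect_error(generate_scene(0.5), "cluster_area")
  expect_error(generate_scene(100, prevalence = 1.2), "prevalence")
})

test_that("realized mean cluster area tracks the calibrated target", {
  for (target in c(350, 2000)) {
    areas <- sapply(1:10, function(s) {
      measure_cluster_area(
        generate_scene(target, seed = 100 + s, grid_size = 500)
      )
    })
    expect_equal(mean(areas), target, tolerance = 0.25)
  }
})

test_that("rendering draws pixels from the class endmembers", {
  em <- toy_endmembers()
  sc <- generate_scene(cluster_area = 2000, seed = 6, grid_size = 150)
  cube <- render_scene(sc, em$liana, em$tree, seed = 7)

  # per-class sample moments recover the endmember parameters
  idx <- lianasignal:::grid_index(cube$wavelengths)
  feat <- cube$feature_frac == 1
  mu_f <- colMeans(cube$values[feat, ])
  mu_b <- colMeans(cube$values[!feat, ])
  expect_lt(max(abs(mu_f - em$liana$mu[idx])), 0.005)
  expect_lt(max(abs(mu_b - em$tree$mu[idx])), 0.005)
  sd_f <- apply(cube$values[feat, ], 2, sd)
  expect_equal(mean(sd_f), 0.02, tolerance = 0.05)

  # all-feature scene matches the liana endmember alone
  sc1 <- generate_scene(cluster_area = 1, prevalence = 0.999, seed = 8, grid_size = 80)
  sc1$feature[] <- TRUE
  cube1 <- render_scene(sc1, em$liana, em$tree, seed = 9)
  expect_lt(max(abs(colMeans(cube1$values) - em$liana$mu[idx])), 0.01)

  # zero-noise endmembers give exactly two distinct spectra
  em0 <- list(
    tree = spectral_distribution(rep(0.2, 2101), 1e-12),
    liana = spectral_distribution(rep(0.4, 2101), 1e-12)
  )
  cube0 <- render_scene(sc, em0$liana, em0$tree, seed = 10)
  expect_equal(nrow(unique(round(cube0$values, 6))), 2)
})

test_that("coarsening is a block mean with edge cropping", {
  em <- toy_endmembers()
  sc <- generate_scene(cluster_area = 350, seed = 11, grid_size = 90)
  cube <- render_scene(sc, em$liana, em$tree, seed = 12)

  expect_identical(coarsen(cube, 1), cube)

  # full-grid factor: single pixel equal to the global mean
  all_one <- coarsen(cube, 90)
  expect_equal(dim(all_one$values), c(1L, length(cube$wavelengths)))
  expect_equal(as.numeric(all_one$values), colMeans(cube$values))

  # checkerboard of two constant spectra: factor 2 gives the midpoint
  chk <- cube
  n <- 90
  pattern <- outer(1:n, 1:n, function(i, j) (i + j) %% 2)
  chk$values <- matrix(0.2, n * n, length(cube$wavelengths))
  chk$values[as.vector(pattern) == 1, ] <- 0.4
  chk$feature_frac <- as.numeric(as.vector(pattern))
  c2 <- coarsen(chk, 2)
  expect_true(all(abs(c2$values - 0.3) < 1e-12))

  # non-dividing factor crops the remainder
  c7 <- coarsen(cube, 7)
  expect_equal(c7$nrow, 12L)
  expect_equal(c7$resolution, 7)

  expect_error(coarsen(cube, 200), "exceeds")
})

test_that("divergence decays with coarsening and clustering slows the decay", {
  em <- toy_endmembers()
  res <- c(1, 2, 5, 10, 25, 50)
  curves <- dplyr::bind_rows(
    scene_kld_curve(30000, em, res, reps = 6, seed = 21, grid_size = 150),
    scene_kld_curve(350, em, res, reps = 6, seed = 22, grid_size = 150),
    random_baseline_curve(em, res, reps = 6, seed = 23, grid_size = 150)
  )
  mean_curve <- function(area) {
    d <- curves[curves$cluster_area == area, ]
    tapply(d$kld, d$resolution, mean, na.rm = TRUE)
  }
  big <- mean_curve(30000)
  small <- mean_curve(350)
  rnd <- mean_curve(1)

  # native resolution equals the endmember divergence for all scenarios
  d_em <- gaussian_kld(em$liana, em$tree, per_wavelength = TRUE)
  idx <- lianasignal:::grid_index(seq(400, 2500, 20))
  d_native <- mean(d_em$kld[idx])
  expect_equal(unname(big["1"]), d_native, tolerance = 0.05)
  expect_equal(unname(rnd["1"]), d_native, tolerance = 0.05)

  # decay is monotone (non-increasing within noise) for every scenario
  for (cv in list(big, small, rnd)) {
    expect_true(all(diff(cv) <= 0.05 * cv[1]))
  }

  # large clusters preserve signal better than small clusters and than
  # random placement at intermediate resolution
  expect_gt(big["25"], small["25"])
  expect_gt(big["25"], rnd["25"])
  # crown-scale clusters have lost most signal by 25 m
  expect_lt(small["25"], 0.2 * small["1"])
})

test_that("random-placement coarse pixels match binomial mixture moments", {
  em <- toy_endmembers()
  f <- 5
  prev <- 0.5
  sc <- generate_scene(cluster_area = 1, prevalence = prev, seed = 31, grid_size = 150)
  cube <- render_scene(sc, em$liana, em$tree, seed = 32)
  coarse <- coarsen(cube, f)
  iwl <- 3
  idx <- lianasignal:::grid_index(cube$wavelengths)[iwl]
  mu_l <- em$liana$mu[idx]
  mu_t <- em$tree$mu[idx]
  sig <- em$liana$sigma[idx]

  # mean: prevalence-weighted mixture
  expect_equal(
    mean(coarse$values[, iwl]),
    prev * mu_l + (1 - prev) * mu_t,
    tolerance = 0.01
  )
  # variance: binomial mixing of class means plus averaged pixel noise
  n_pix <- f^2
  var_pred <- (mu_l - mu_t)^2 * prev * (1 - prev) / n_pix + sig^2 / n_pix
  expect_equal(var(coarse$values[, iwl]), var_pred, tolerance = 0.15)
})
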