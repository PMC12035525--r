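test_that("log posterior matches a hand-computed toy problem", {
  # 5-wavelength toy: forward model returns a constant vector
  obs <- c(0.30, 0.32, 0.28, 0.31, 0.29)
  priors <- prior_set(
    level = prior_normal(0.3, 0.1),
    sigma = prior_uniform(0.001, 0.2)
  )
  forward <- function(pars) rep(pars$level, 5)
  theta <- c(level = 0.31, sigma = 0.02)
  got <- log_posterior(theta, obs, priors, forward)
  by_hand <- sum(dnorm(obs, 0.31, 0.02, log = TRUE)) +
    dnorm(0.31, 0.3, 0.1, log = TRUE) - log(0.2 - 0.001)
  expect_equal(got, by_hand, tolerance = 1e-12)

  # outside a uniform prior: -Inf
  expect_identical(
    log_posterior(c(level = 0.31, sigma = 0.5), obs, priors, forward),
    -Inf
  )

  # perfect fit maximizes the sigma profile at the residual scale
  obs2 <- rep(0.3, 50)
  f2 <- function(pars) rep(0.3, 50)
  sig_grid <- seq(0.002, 0.1, by = 0.002)
  ll <- sapply(sig_grid, function(s) {
    log_posterior(c(level = 0.3, sigma = s), obs2, priors, f2)
  })
  expect_equal(sig_grid[which.max(ll)], 0.002)

  expect_error(
    log_posterior(theta, c(obs[-1], NA), priors, forward),
    "NA"
  )
})

test_that("multispectral sensors are refused unless overridden", {
  priors <- prior_set(
    level = prior_normal(0.3, 0.1), sigma = prior_uniform(0.001, 0.2)
  )
  l5 <- sensor_model("landsat5_tm")
  forward <- function(pars) rep(pars$level, 2101)
  obs <- rep(0.3, 6)
  expect_error(
    log_posterior(c(level = 0.3, sigma = 0.01), obs, priors, forward,
      sensor = l5
    ),
    "fewer than 10 bands"
  )
  ok <- log_posterior(c(level = 0.3, sigma = 0.01), obs, priors, forward,
    sensor = l5, allow_multispectral = TRUE
  )
  expect_true(is.finite(ok))
})

test_that("the sampler recovers a known 2-D Gaussian and is reproducible", {
  lp <- function(th) {
    sum(dnorm(th[c("a", "b")], c(1, -2), c(0.5, 2), log = TRUE))
  }
  pr <- prior_set(
    a = prior_uniform(-10, 10), b = prior_uniform(-20, 20),
    sigma = prior_fixed(1)
  )
  s <- run_demc(lp, pr, n_iter = 3000, seed = 2)
  td <- tidy(s)
  flat <- lianasignal:::flatten_draws(s)
  n_eff_floor <- 100 # conservative; MC error bound uses this
  for (i in 1:2) {
    mc_se <- td$std.error[i] / sqrt(n_eff_floor)
    expect_lt(abs(td$mean[i] - c(1, -2)[i]), 3 * mc_se + 0.05)
  }
  expect_equal(unname(td$std.error), c(0.5, 2), tolerance = 0.15)

  s2 <- run_demc(lp, pr, n_iter = 3000, seed = 2)
  expect_identical(s$draws, s2$draws)
  expect_error(run_demc(lp, pr, n_chains = 2), "3 chains")
})

test_that("convergence diagnostic flags identical and disjoint chains", {
  # identical chains: R-hat exactly 1
  one <- matrix(rnorm(200), 100, 2)
  draws <- array(NA, c(100, 3, 2), dimnames = list(NULL, NULL, c("a", "b")))
  for (c_i in 1:3) draws[, c_i, ] <- one
  fake <- structure(
    list(draws = draws, params = c("a", "b"), n_chains = 3),
    class = "posterior_samples"
  )
  expect_equal(unname(gelman_rubin(fake)), c(1, 1), tolerance = 1e-12)

  # chains stuck in disjoint modes: R-hat far above 1.2
  for (c_i in 1:3) draws[, c_i, ] <- one + 10 * c_i
  fake$draws <- draws
  expect_true(all(gelman_rubin(fake) > 1.2))

  fake$draws <- draws[, 1, , drop = FALSE]
  fake$n_chains <- 1
  expect_error(gelman_rubin(fake), "2 chains")
})

test_that("leaf inversion recovers generating parameters from clean spectra", {
  set.seed(71)
  truth <- leaf_params(
    N = 1.7, C_ab = 45, C_ar = 9, C_w = 0.011, C_m = 0.008
  )
  spec <- prospect_forward(truth)$reflectance
  fit <- invert_leaf(spec, seed = 3)
  expect_identical(fit$convergence, "ok")
  for (p in c("N", "C_ab", "C_w", "C_m")) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 0.01)
  }

  # with noise: recovery within a looser tolerance; pigment confounding
  # between C_ab and C_ar is tolerated
  noisy <- pmin(pmax(spec + rnorm(2101, 0, 0.005), 0), 1)
  fitn <- invert_leaf(noisy, seed = 4)
  expect_identical(fitn$convergence, "ok")
  expect_equal(fitn$N, truth$N, tolerance = 0.1)
  expect_equal(fitn$C_w, truth$C_w, tolerance = 0.1)
  expect_equal(fitn$C_m, truth$C_m, tolerance = 0.15)
  expect_equal(fitn$C_ab + fitn$C_ar, truth$C_ab + truth$C_ar,
    tolerance = 0.15
  )

  # degenerate input: flagged, not an exception
  flat0 <- invert_leaf(rep(0, 2101), seed = 5, n_starts = 1)
  expect_true(flat0$convergence %in% c("non_physical", "failed"))
})

test_that("leaf-informed priors pass through and respect fixed parameters", {
  summ <- dplyr::select(
    trait_defaults(), "growth_form", "trait", "mean", "sd"
  )
  pr <- derive_priors(summ, sample_leaf = TRUE)
  spec <- pr[["C_ab_tree"]]
  expect_identical(spec$type, "normal")
  expect_equal(spec$mean, 42)
  expect_equal(spec$sd, 8)

  # liana and tree prior means lie within one sd of each other
  for (tr in c("N", "C_ab", "C_ar", "C_w", "C_m")) {
    a <- pr[[paste0(tr, "_liana")]]
    b <- pr[[paste0(tr, "_tree")]]
    expect_lte(abs(a$mean - b$mean), max(a$sd, b$sd) + 1e-9)
  }

  # fixed parameters are excluded from the sampled dimensions
  expect_false("L" %in% lianasignal:::free_params(pr))
  expect_false("D" %in% lianasignal:::free_params(pr))
  pr2 <- derive_priors(summ, sample_leaf = FALSE)
  expect_false("C_ab_tree" %in% lianasignal:::free_params(pr2))
  expect_equal(lianasignal:::fixed_values(pr2)[["C_ab_tree"]], 42)
})

test_that("more informative wavelengths shrink identifiable posteriors", {
  # direct Gaussian analogy of the likelihood: doubling independent
  # observations of a parameter halves its posterior variance; checked
  # through the sampler on a conjugate toy target.
  make_lp <- function(n_obs) {
    set.seed(81)
    obs <- rnorm(n_obs, 0.4, 0.02)
    function(th) sum(dnorm(obs, th[["m"]], 0.02, log = TRUE))
  }
  pr <- prior_set(m = prior_uniform(0, 1), sigma = prior_fixed(0.02))
  s1 <- run_demc(make_lp(40), pr, n_iter = 2000, seed = 6)
  s2 <- run_demc(make_lp(80), pr, n_iter = 2000, seed = 7)
  sd1 <- tidy(s1)$std.error[1]
  sd2 <- tidy(s2)$std.error[1]
  expect_lt(sd2, sd1)
  expect_equal(unname(sd2 / sd1), 1 / sqrt(2), tolerance = 0.2)
})
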