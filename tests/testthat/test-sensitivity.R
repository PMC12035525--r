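test_that("trait swaps move the model toward the liana signal as expected", {
  swaps <- c(as.list(names(default_swap_traits("tree"))), list(
    character(0),
    names(default_swap_traits("tree")), # full swap
    c("N", "C_m")
  ))
  res <- trait_swap_experiment(swap_sets = swaps)

  # empty swap: zero impact
  expect_equal(res$impact[res$swap == "(none)"], 0, tolerance = 1e-12)

  # full swap reproduces the reference exactly: impact equals baseline
  full_label <- paste(names(default_swap_traits("tree")), collapse = "+")
  expect_equal(res$impact[res$swap == full_label], res$d_base[1],
    tolerance = 1e-10
  )

  # chlorophyll swap matters only where chlorophyll absorbs: the
  # per-wavelength impact peaks in the visible/red-edge region and is
  # negligible on the NIR plateau and in the SWIR
  curves <- attr(res, "curves")
  cab <- curves[curves$swap == "C_ab", ]
  expect_lt(cab$wavelength_nm[which.max(abs(cab$impact))], 750)
  frac_beyond <- sum(abs(cab$impact[cab$wavelength_nm > 800])) /
    sum(abs(cab$impact))
  expect_lt(frac_beyond, 0.1)

  # the leaf-angle swap matters across all three regions
  ang <- res[res$swap == "angle", ]
  full <- res[res$swap == full_label, ]
  for (reg in c("impact_vis", "impact_nir", "impact_swir")) {
    expect_gt(abs(ang[[reg]]), 0.02 * abs(full[[reg]]))
  }

  # unknown parameter is a configuration error
  expect_error(
    trait_swap_experiment(swap_sets = list("not_a_trait")),
    "unknown parameter"
  )
})

test_that("swap impacts are pure functions of the swap set", {
  sets <- list("C_w", "angle", c("C_w", "angle"))
  a <- trait_swap_experiment(swap_sets = sets)
  b <- trait_swap_experiment(swap_sets = rev(sets))
  for (lab in a$swap) {
    expect_equal(a$impact[a$swap == lab], b$impact[b$swap == lab])
  }
})

test_that("interaction separates additive and interactive components", {
  sets <- list("N", "C_m", c("N", "C_m"), "C_w", c("N", "C_w"))
  res <- trait_swap_experiment(swap_sets = sets)
  ie <- interaction_effect(res, c("N", "C_m"))
  expect_equal(
    ie$interactive,
    res$impact[res$swap == "N+C_m"] - res$impact[res$swap == "N"] -
      res$impact[res$swap == "C_m"]
  )
  expect_equal(ie$sign, sign(ie$interactive))
  expect_error(interaction_effect(res, c("N", "angle")), "must contain")
})

test_that("an affine toy model has vanishing interactive component", {
  # Reflectance affine in two parameters with equal sigmas: KLD is
  # quadratic in the mean shift, and the cross terms cancel in the
  # interactive component by construction.
  sigma <- 0.01
  base <- c(a = 0, b = 0)
  target <- c(a = 1, b = 1)
  mu_fun <- function(p) 0.3 + 0.02 * p[["a"]] + 0.01 * p[["b"]]
  kld <- function(p) {
    (mu_fun(p) - mu_fun(target))^2 / (2 * sigma^2)
  }
  d_base <- kld(base)
  imp <- function(set) {
    p <- base
    p[set] <- target[set]
    d_base - kld(p)
  }
  interactive <- imp(c("a", "b")) - imp("a") - imp("b")
  # analytic check: the shared-channel cross term -2*(da)(db)/(2 sigma^2)
  expect_equal(interactive, -2 * 0.02 * 0.01 / (2 * sigma^2))
  # against the generic formula with orthogonal (wavelength-separated)
  # channels the cross term vanishes
  mu2 <- function(p) c(0.3 + 0.02 * p[["a"]], 0.3 + 0.01 * p[["b"]])
  kld2 <- function(p) sum((mu2(p) - mu2(target))^2) / (2 * sigma^2)
  d2 <- kld2(base)
  imp2 <- function(set) {
    p <- base
    p[set] <- target[set]
    d2 - kld2(p)
  }
  expect_equal(imp2(c("a", "b")) - imp2("a") - imp2("b"), 0)
})

test_that("percent trait contrasts compute the printed comparisons", {
  expect_equal(summarize_trait_contrast(27.9, 37.1), -24.8, tolerance = 0.002)
  expect_equal(summarize_trait_contrast(5, 5), 0)
  expect_equal(summarize_trait_contrast(0.347, 0.653), -46.9, tolerance = 0.002)
  expect_error(summarize_trait_contrast(1, 0), "non-zero")
})
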