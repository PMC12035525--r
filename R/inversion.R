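#' Prior specifications for Bayesian spectral inversion
#'
#' A prior set maps parameter names to one of three specifications:
#' `prior_normal(mean, sd)` (optionally bounded), `prior_uniform(lo, hi)`
#' or `prior_fixed(value)`. Fixed parameters are excluded from the
#' sampled dimensions. Leaf parameters typically carry normal priors
#' informed by leaf-scale inversions; canopy structural parameters carry
#' flat priors over their physical ranges.
#'
#' @param ... Named prior specifications.
#' @return A list of class `prior_set`.
#' @export
#' @examples
#' prior_set(
#'   lai = prior_uniform(0.5, 10),
#'   C_ab = prior_normal(40, 8, lower = 0, upper = 100),
#'   L = prior_fixed(1)
#' )
prior_set <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.null(names(specs)) && is.list(specs[[1]])) {
    specs <- specs[[1]]
  }
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("all priors must be named", call. = FALSE)
  }
  ok <- vapply(specs, function(s) inherits(s, "prior_spec"), logical(1))
  if (!all(ok)) stop("priors must be prior_* specifications", call. = FALSE)
  free <- names(specs)[vapply(specs, function(s) s$type != "fixed", logical(1))]
  if (length(free) == 0) {
    stop("at least one parameter must be free", call. = FALSE)
  }
  structure(specs, class = "prior_set")
}

#' @rdname prior_set
#' @param mean,sd Normal prior moments.
#' @param lower,upper Optional truncation bounds.
#' @export
prior_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  structure(
    list(type = "normal", mean = mean, sd = sd, lower = lower, upper = upper),
    class = "prior_spec"
  )
}

#' @rdname prior_set
#' @param lo,hi Uniform prior bounds.
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(lo < hi)
  structure(
    list(type = "uniform", lower = lo, upper = hi),
    class = "prior_spec"
  )
}

#' @rdname prior_set
#' @param value Fixed parameter value.
#' @export
prior_fixed <- function(value) {
  structure(list(type = "fixed", value = value), class = "prior_spec")
}

free_params <- function(priors) {
  names(priors)[vapply(priors, function(s) s$type != "fixed", logical(1))]
}

fixed_values <- function(priors) {
  fx <- priors[vapply(priors, function(s) s$type == "fixed", logical(1))]
  vapply(fx, `[[`, numeric(1), "value")
}

prior_bounds <- function(priors) {
  free <- free_params(priors)
  lo <- vapply(priors[free], function(s) s$lower %||% -Inf, numeric(1))
  hi <- vapply(priors[free], function(s) s$upper %||% Inf, numeric(1))
  list(lower = lo, upper = hi)
}

# Log prior density of a named free-parameter vector; -Inf out of support.
log_prior <- function(theta, priors) {
  total <- 0
  for (nm in names(theta)) {
    s <- priors[[nm]]
    x <- theta[[nm]]
    if (s$type == "uniform") {
      if (x < s$lower || x > s$upper) {
        return(-Inf)
      }
      total <- total - log(s$upper - s$lower)
    } else if (s$type == "normal") {
      if (x < s$lower || x > s$upper) {
        return(-Inf)
      }
      total <- total + stats::dnorm(x, s$mean, s$sd, log = TRUE)
    }
  }
  total
}

# Draw one vector of free parameters from the priors.
prior_draw <- function(priors) {
  free <- free_params(priors)
  out <- vapply(free, function(nm) {
    s <- priors[[nm]]
    if (s$type == "uniform") {
      stats::runif(1, s$lower, s$upper)
    } else {
      repeat {
        x <- stats::rnorm(1, s$mean, s$sd)
        if (x >= s$lower && x <= s$upper) break
      }
      x
    }
  }, numeric(1))
  names(out) <- free
  out
}

#' Log posterior density for spectral inversion
#'
#' Independent Gaussian likelihood over wavelengths (or sensor bands
#' after response convolution) with a single residual standard deviation
#' `sigma`, plus the log priors. `sigma` is itself a model parameter and
#' must appear in the prior set (free or fixed). Returns `-Inf` outside
#' the prior support.
#'
#' @param theta Named vector of free-parameter values.
#' @param observed Observed reflectance: on the model's wavelength grid,
#'   or per-band values if `sensor` is given.
#' @param priors A [prior_set()]; fixed entries are merged into the
#'   forward-model arguments.
#' @param forward Function taking the full named parameter list and
#'   returning predicted reflectance on the same grid as `observed`
#'   (before any sensor convolution).
#' @param sensor Optional [sensor_model()]; predictions and data are
#'   compared per band. Sensors with fewer than 10 bands are refused by
#'   default because parameter uncertainty degrades sharply at low
#'   spectral resolution; override with `allow_multispectral = TRUE`.
#' @param allow_multispectral Allow < 10 bands.
#' @return Scalar log density.
#' @export
log_posterior <- function(theta, observed, priors, forward, sensor = NULL,
                          allow_multispectral = FALSE) {
  if (anyNA(observed)) stop("observed spectrum contains NA", call. = FALSE)
  if (!is.null(sensor) && nrow(sensor$bands) < 10 && !allow_multispectral) {
    stop(
      "sensor has fewer than 10 bands; set allow_multispectral = TRUE ",
      "to invert multispectral data anyway",
      call. = FALSE
    )
  }
  lp <- log_prior(theta, priors)
  if (!is.finite(lp)) {
    return(-Inf)
  }
  pars <- c(as.list(theta), as.list(fixed_values(priors)))
  sigma <- pars$sigma
  if (is.null(sigma)) stop("priors must include sigma", call. = FALSE)
  if (sigma <= 0) {
    return(-Inf)
  }
  pred <- forward(pars)
  if (!is.null(sensor)) {
    pred <- band_convolve(pred, sensor)$value
  }
  if (length(pred) != length(observed)) {
    stop("forward prediction and data lengths differ", call. = FALSE)
  }
  ll <- sum(stats::dnorm(observed, pred, sigma, log = TRUE))
  if (!is.finite(ll)) {
    return(-Inf)
  }
  ll + lp
}

#' Differential-evolution MCMC with snooker updates
#'
#' Samples a target log density with the differential-evolution MCMC
#' variant that proposes jumps from differences of states in a thinned
#' history archive, mixing in snooker updates (10% of proposals). This
#' family needs only a handful of parallel chains (3 by default)
#' regardless of dimension. The first half of each chain is discarded as
#' burn-in.
#'
#' @param log_post Function of a named parameter vector returning the log
#'   posterior density.
#' @param priors A [prior_set()] used for bounds and initialization.
#' @param n_chains Number of parallel chains (>= 3).
#' @param n_iter Iterations per chain (post-thinning history accumulates
#'   every 10th state).
#' @param seed Integer seed; runs are bit-reproducible.
#' @param init Optional matrix (chains x parameters) of starting points.
#' @return A `posterior_samples` object: list with `draws` (array
#'   iterations x chains x parameters, burn-in removed), `log_post`,
#'   `params`, `acceptance`, `seed`.
#' @export
run_demc <- function(log_post, priors, n_chains = 3, n_iter = 2000,
                     seed = 1, init = NULL) {
  if (n_chains < 3) stop("need at least 3 chains", call. = FALSE)
  set.seed(seed)
  free <- free_params(priors)
  d <- length(free)
  bounds <- prior_bounds(priors)

  # Initialize chains from the prior, retrying zero-probability starts.
  if (is.null(init)) {
    init <- matrix(NA_real_, n_chains, d, dimnames = list(NULL, free))
    for (c_i in seq_len(n_chains)) {
      for (try in 1:100) {
        x <- prior_draw(priors)
        if (is.finite(log_post(x))) break
        x <- NULL
      }
      if (is.null(x)) {
        stop("could not initialize chains in the prior support", call. = FALSE)
      }
      init[c_i, ] <- x
    }
  }
  colnames(init) <- free

  # History archive seeded with prior draws.
  n_z0 <- max(10 * d, 3 * n_chains)
  Z <- matrix(NA_real_, n_z0, d, dimnames = list(NULL, free))
  for (i in seq_len(n_z0)) Z[i, ] <- prior_draw(priors)

  gamma_main <- 2.38 / sqrt(2 * d)
  eps_scale <- pmax((bounds$upper - bounds$lower) * 1e-6, 1e-12)
  eps_scale[!is.finite(eps_scale)] <- 1e-6

  x <- init
  lp <- apply(x, 1, function(r) log_post(stats::setNames(r, free)))
  draws <- array(
    NA_real_, c(n_iter, n_chains, d),
    dimnames = list(NULL, NULL, free)
  )
  lpost <- matrix(NA_real_, n_iter, n_chains)
  accept <- 0
  total <- 0
  chol_cov <- NULL

  for (it in seq_len(n_iter)) {
    nz <- if (anyNA(Z[, 1])) which(is.na(Z[, 1]))[1] - 1 else nrow(Z)
    # Refresh the adaptive covariance proposal from the archive tail.
    if (it %% 50 == 1 && nz > 5 * d) {
      tail_rows <- Z[max(1, nz - 500):nz, , drop = FALSE]
      cv <- stats::cov(tail_rows) + diag(1e-12, d)
      chol_cov <- tryCatch(chol(cv), error = function(e) NULL)
    }
    for (c_i in seq_len(n_chains)) {
      u <- stats::runif(1)
      snooker <- u < 0.1
      adaptive <- !snooker && u < 0.3 && !is.null(chol_cov)
      if (adaptive) {
        step <- as.numeric(stats::rnorm(d) %*% chol_cov) * 2.38 / sqrt(d)
        prop <- x[c_i, ] + step
        log_jac <- 0
      } else if (snooker) {
        idx <- sample.int(nz, 3)
        z <- Z[idx[1], ]
        za <- Z[idx[2], ]
        zb <- Z[idx[3], ]
        dxz <- x[c_i, ] - z
        nrm2 <- sum(dxz^2)
        if (nrm2 < 1e-300) next
        e <- dxz / sqrt(nrm2)
        proj <- sum((za - zb) * e)
        gam <- stats::runif(1, 1.2, 2.2)
        prop <- x[c_i, ] + gam * proj * e
        # Snooker Jacobian factor |x* - z|^(d-1) / |x - z|^(d-1).
        log_jac <- (d - 1) * 0.5 * (log(sum((prop - z)^2)) - log(nrm2))
      } else {
        idx <- sample.int(nz, 2)
        # Jittered step length improves acceptance on correlated
        # posteriors; every 10th iteration uses gamma = 1 for mode jumps.
        gam <- if (it %% 10 == 0) 1 else gamma_main * stats::runif(1, 0.4, 1.2)
        prop <- x[c_i, ] + gam * (Z[idx[1], ] - Z[idx[2], ]) +
          stats::rnorm(d, 0, eps_scale)
        log_jac <- 0
      }
      names(prop) <- free
      lp_prop <- log_post(prop)
      total <- total + 1
      if (is.finite(lp_prop) &&
        log(stats::runif(1)) < lp_prop - lp[c_i] + log_jac) {
        x[c_i, ] <- prop
        lp[c_i] <- lp_prop
        accept <- accept + 1
      }
    }
    draws[it, , ] <- x
    lpost[it, ] <- lp
    # Append current states to the archive every 10 iterations.
    if (it %% 10 == 0) {
      Z <- rbind(Z, x)
    }
  }

  keep <- seq(floor(n_iter / 2) + 1L, n_iter)
  structure(
    list(
      draws = draws[keep, , , drop = FALSE],
      log_post = lpost[keep, , drop = FALSE],
      params = free,
      acceptance = accept / total,
      seed = seed,
      n_iter = n_iter,
      n_chains = n_chains
    ),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(
    "posterior_samples:", length(x$params), "parameters,",
    dim(x$draws)[1], "post-burn-in draws x", x$n_chains, "chains",
    sprintf("(acceptance %.2f)\n", x$acceptance)
  )
  print(glance(x))
  invisible(x)
}

# Flatten draws to a matrix (draws*chains) x params.
flatten_draws <- function(samples) {
  d <- samples$draws
  matrix(aperm(d, c(1, 2, 3)),
    nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3],
    dimnames = list(NULL, samples$params)
  )
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter, from the between- and
#' within-chain variances of the post-burn-in draws.
#'
#' @param samples A `posterior_samples` object.
#' @return Named numeric vector of R-hat values (>= 1 up to numerical
#'   noise).
#' @export
gelman_rubin <- function(samples) {
  d <- samples$draws
  n <- dim(d)[1]
  m <- dim(d)[2]
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  if (n < 10) warning("chains are very short; R-hat is unreliable")
  out <- vapply(seq_len(dim(d)[3]), function(p) {
    ch <- d[, , p]
    means <- colMeans(ch)
    W <- mean(apply(ch, 2, stats::var))
    B <- n * stats::var(means)
    if (W <= 0) {
      return(1)
    }
    # Conservative variant: R-hat = sqrt(1 + B / (n W)), exactly 1 for
    # identical chains and >= 1 by construction.
    sqrt(1 + B / (n * W))
  }, numeric(1))
  names(out) <- samples$params
  out
}

#' Posterior summaries in tidy form
#'
#' `tidy()` returns one row per parameter with posterior mean, median,
#' sd and central 95% credible interval; `glance()` returns one row of
#' sampler-level summaries.
#'
#' @param x A `posterior_samples` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.posterior_samples <- function(x, ...) {
  flat <- flatten_draws(x)
  rhat <- gelman_rubin(x)
  tibble::tibble(
    term = x$params,
    estimate = apply(flat, 2, stats::median),
    mean = colMeans(flat),
    std.error = apply(flat, 2, stats::sd),
    conf.low = apply(flat, 2, stats::quantile, 0.025),
    conf.high = apply(flat, 2, stats::quantile, 0.975),
    rhat = rhat
  )
}

#' @rdname tidy.posterior_samples
#' @export
glance.posterior_samples <- function(x, ...) {
  tibble::tibble(
    n_draws = dim(x$draws)[1] * x$n_chains,
    n_chains = x$n_chains,
    acceptance = x$acceptance,
    max_rhat = max(gelman_rubin(x)),
    seed = x$seed
  )
}

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Invert a leaf reflectance spectrum
#'
#' Estimates leaf parameters (and the residual sd) from a single
#' reflectance spectrum. The default is maximum a posteriori estimation
#' with multi-start bounded optimization (5 starts drawn from the
#' priors), which scales to thousands of leaves; full MCMC via
#' [run_demc()] is opt-in with `mode = "mcmc"`.
#'
#' @param spectrum Reflectance on the common grid (vector or
#'   `leaf_optics`-like tibble).
#' @param priors A [prior_set()] over (a subset of) `N`, `C_ab`, `C_ar`,
#'   `C_an`, `C_br`, `C_w`, `C_m` and `sigma`; defaults cover the
#'   physical ranges.
#' @param mode `"map"` or `"mcmc"`.
#' @param table Coefficient table.
#' @param wavelengths Optional grid subset used in the fit (default every
#'   5 nm for speed).
#' @param n_starts Number of optimization starts for `"map"`.
#' @param seed Integer seed.
#' @param n_iter MCMC iterations when `mode = "mcmc"`.
#' @return For `"map"`: a tibble with one row (`convergence` flags a
#'   failed or non-physical fit rather than erroring). For `"mcmc"`: a
#'   `posterior_samples` object.
#' @export
invert_leaf <- function(spectrum, priors = default_leaf_priors(),
                        mode = c("map", "mcmc"),
                        table = prospect_coefficients("D"),
                        wavelengths = seq(400, 2500, by = 5),
                        n_starts = 5, seed = 1, n_iter = 3000) {
  mode <- match.arg(mode)
  vec <- spectrum_vector(spectrum)
  idx <- grid_index(wavelengths)
  obs <- vec[idx]
  flagged <- all(vec <= 1e-6) || anyNA(vec)

  forward <- function(pars) {
    lp <- leaf_params(
      N = pars$N, C_ab = pars$C_ab, C_ar = pars$C_ar,
      C_an = pars$C_an %||% 0, C_br = pars$C_br %||% 0,
      C_w = pars$C_w, C_m = pars$C_m
    )
    prospect_forward(lp, table)$reflectance[idx]
  }
  lpost <- function(theta) {
    tryCatch(
      log_posterior(theta, obs, priors, forward),
      error = function(e) -Inf
    )
  }

  if (mode == "mcmc") {
    return(run_demc(lpost, priors, n_iter = n_iter, seed = seed))
  }

  # MAP with the residual sd profiled out: for the iid Gaussian
  # likelihood the conditional optimum is sigma^2 = SSR / n, so the
  # optimizer works on the concentrated posterior of the leaf
  # parameters only, which is far better conditioned.
  set.seed(seed)
  free <- free_params(priors)
  shape_free <- setdiff(free, "sigma")
  bounds <- prior_bounds(priors)
  sig_lo <- if ("sigma" %in% free) priors$sigma$lower else NULL
  sig_hi <- if ("sigma" %in% free) priors$sigma$upper else NULL
  n_obs <- length(obs)

  conc_obj <- function(v) {
    theta <- stats::setNames(v, shape_free)
    lp <- log_prior(theta, priors)
    if (!is.finite(lp)) {
      return(1e10)
    }
    pred <- tryCatch(
      forward(c(as.list(theta), as.list(fixed_values(priors)))),
      error = function(e) NULL
    )
    if (is.null(pred)) {
      return(1e10)
    }
    ssr <- sum((obs - pred)^2)
    # Profile log-likelihood in sigma: smooth in log(SSR), so the
    # optimizer is well conditioned even near a perfect fit.
    ll <- -n_obs / 2 * (log(2 * pi) + 1 + log(max(ssr, 1e-30) / n_obs))
    if (!is.finite(ll)) {
      return(1e10)
    }
    -(ll + lp)
  }

  ib <- match(shape_free, free)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- prior_draw(priors)[shape_free]
    fit <- tryCatch(
      stats::optim(
        start, conc_obj,
        method = "L-BFGS-B",
        lower = bounds$lower[ib], upper = bounds$upper[ib],
        control = list(
          maxit = 1000,
          parscale = pmin(bounds$upper[ib] - bounds$lower[ib], 1e6)
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9 &&
      (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    est <- stats::setNames(rep(NA_real_, length(free)), free)
    conv <- "failed"
    lpval <- NA_real_
  } else {
    est <- stats::setNames(rep(NA_real_, length(free)), free)
    est[shape_free] <- best$par
    if ("sigma" %in% free) {
      pred <- forward(c(as.list(est[shape_free]), as.list(fixed_values(priors))))
      est[["sigma"]] <- min(max(sqrt(sum((obs - pred)^2) / n_obs), sig_lo), sig_hi)
    }
    conv <- if (flagged) "non_physical" else if (best$convergence == 0) "ok" else "maxit"
    lpval <- -best$value
  }
  out <- tibble::as_tibble(as.list(est))
  out$log_posterior <- lpval
  out$convergence <- conv
  out
}

#' @rdname invert_leaf
#' @export
default_leaf_priors <- function() {
  prior_set(
    N = prior_uniform(1, 3.5),
    C_ab = prior_uniform(0, 100),
    C_ar = prior_uniform(0, 30),
    C_an = prior_fixed(0),
    C_br = prior_fixed(0),
    C_w = prior_uniform(1e-4, 0.05),
    C_m = prior_uniform(5e-4, 0.03),
    sigma = prior_uniform(1e-4, 0.1)
  )
}

#' Derive canopy-inversion priors from leaf-stage posteriors
#'
#' Turns per-growth-form leaf parameter means and standard deviations
#' (from leaf-scale inversions) into normal priors for the canopy
#' inversion, leaves canopy structural parameters on flat priors over
#' their physical ranges, and fixes the parameters the study design
#' fixes (`L`, `D`, `Cv`, `zeta` and the viewing geometry).
#'
#' @param leaf_summary Tibble with columns `growth_form`, `trait`,
#'   `mean`, `sd` (e.g. aggregated leaf inversions, or
#'   [trait_defaults()] renamed).
#' @param fixed Named list of parameters to fix (defaults to the study
#'   design: `L = 1`, `D = 1`, `Cv = 1`, `zeta = 0.5`).
#' @param sample_leaf Include the leaf parameters as sampled dimensions;
#'   if `FALSE` they are fixed at their prior means (the reduced
#'   configuration used for fast canopy-structure inversion).
#' @return A [prior_set()] with parameters named `<trait>_liana`,
#'   `<trait>_tree` for leaf traits plus `lai`, `omega1`, `omega2`,
#'   `f2`, `hot`, `omega_soil`, `sigma`.
#' @export
derive_priors <- function(leaf_summary = NULL,
                          fixed = list(L = 1, D = 1, Cv = 1, zeta = 0.5),
                          sample_leaf = FALSE) {
  if (is.null(leaf_summary)) {
    leaf_summary <- dplyr::select(
      trait_defaults(), "growth_form", "trait", "mean", "sd"
    )
  }
  leaf_summary <- dplyr::filter(leaf_summary, .data$trait != "angle")
  ranges <- list(
    N = c(1, 3.5), C_ab = c(0, 100), C_ar = c(0, 30), C_an = c(0, 10),
    C_br = c(0, 1), C_w = c(1e-4, 0.05), C_m = c(5e-4, 0.03)
  )
  specs <- list()
  for (gf in c("liana", "tree")) {
    sub <- dplyr::filter(leaf_summary, .data$growth_form == gf)
    for (tr in names(ranges)) {
      nm <- paste0(tr, "_", gf)
      row <- sub[sub$trait == tr, ]
      if (nrow(row) == 0) {
        warning("no leaf summary for ", nm, "; using physical-range default")
        specs[[nm]] <- prior_uniform(ranges[[tr]][1], ranges[[tr]][2])
      } else if (sample_leaf) {
        specs[[nm]] <- prior_normal(
          row$mean, row$sd,
          lower = ranges[[tr]][1], upper = ranges[[tr]][2]
        )
      } else {
        specs[[nm]] <- prior_fixed(row$mean)
      }
    }
  }
  specs$lai <- prior_uniform(0.5, 10)
  specs$omega1 <- prior_uniform(5, 85)
  specs$omega2 <- prior_uniform(5, 85)
  specs$f2 <- prior_uniform(0.05, 0.95)
  specs$hot <- prior_fixed(0.05)
  specs$omega_soil <- prior_fixed(0.5)
  specs$sigma <- prior_uniform(1e-3, 0.05)
  for (nm in names(fixed)) specs[[nm]] <- prior_fixed(fixed[[nm]])
  prior_set(specs)
}

#' Forward model closure for canopy inversion
#'
#' Builds the function mapping a full named parameter list (leaf traits
#' per growth form plus canopy structure) to predicted surface
#' reflectance, for use with [log_posterior()] and [run_demc()].
#'
#' @param geom A [view_geometry()].
#' @param wavelengths Wavelength subset (default every 10 nm).
#' @param table Coefficient table.
#' @return A function of a named parameter list.
#' @export
canopy_forward_model <- function(geom = view_geometry(),
                                 wavelengths = seq(400, 2500, by = 10),
                                 table = prospect_coefficients("D")) {
  idx <- grid_index(wavelengths)
  diffuse <- diffuse_fraction(geom$tts)[idx]
  soil_default <- soil_model(0.5)
  force(table)
  function(pars) {
    liana <- list(
      N = pars$N_liana, C_ab = pars$C_ab_liana, C_ar = pars$C_ar_liana,
      C_an = pars$C_an_liana %||% 0, C_br = pars$C_br_liana %||% 0,
      C_w = pars$C_w_liana, C_m = pars$C_m_liana
    )
    tree <- list(
      N = pars$N_tree, C_ab = pars$C_ab_tree, C_ar = pars$C_ar_tree,
      C_an = pars$C_an_tree %||% 0, C_br = pars$C_br_tree %||% 0,
      C_w = pars$C_w_tree, C_m = pars$C_m_tree
    )
    if (liana$N < 1 || tree$N < 1) stop("N must be >= 1", call. = FALSE)
    cc <- list(
      lai = pars$lai, omega1 = pars$omega1, omega2 = pars$omega2,
      f2 = pars$f2, L = pars$L %||% 1, D = pars$D %||% 1,
      hot = pars$hot %||% 0.05, omega_soil = pars$omega_soil %||% 0.5
    )
    ws <- if (cc$omega_soil == 0.5) {
      soil_default$reflectance[idx]
    } else {
      soil_model(cc$omega_soil)$reflectance[idx]
    }
    lo <- prospect_rt(liana, table, idx)
    to <- prospect_rt(tree, table, idx)
    ops <- foursail2_core(lo$rho, lo$tau, to$rho, to$tau, ws, cc, geom)
    diffuse * ops$rdo + (1 - diffuse) * ops$rso
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
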