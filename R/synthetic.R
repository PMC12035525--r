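#' Default trait distributions for lianas and trees
#'
#' Per-growth-form means and standard deviations of the leaf parameters
#' and the mean leaf inclination angle. The defaults encode the
#' well-documented contrasts between liana and tree leaves in tropical
#' canopies: lianas build cheaper leaves (lower dry mass and water mass
#' per area, lower chlorophyll and carotenoid content, fewer cell--air
#' interfaces, i.e. thinner leaves) and hold them flatter. Angle means
#' are 27.9 degrees (liana) and 37.1 degrees (tree), matching field
#' measurements of canopy leaves; the remaining contrasts are set at
#' 15--30% relative differences. All traits are drawn from normal
#' distributions truncated to their physical ranges.
#'
#' @return A tibble with columns `trait`, `growth_form`, `mean`, `sd`,
#'   `lower`, `upper`.
#' @export
trait_defaults <- function() {
  traits <- c("N", "C_ab", "C_ar", "C_an", "C_br", "C_w", "C_m", "angle")
  lower <- c(1, 0, 0, 0, 0, 1e-4, 5e-4, 5)
  upper <- c(3.5, 100, 30, 10, 1, 0.05, 0.03, 85)
  tree <- c(1.9, 42, 11, 1.0, 0.10, 0.012, 0.010, 37.1)
  liana <- c(1.6, 34, 8.5, 0.8, 0.10, 0.009, 0.0075, 27.9)
  tree_sd <- c(0.30, 8, 2.5, 0.5, 0.05, 0.003, 0.0025, 10)
  liana_sd <- c(0.20, 7, 2.0, 0.4, 0.05, 0.0025, 0.002, 8)
  dplyr::bind_rows(
    tibble::tibble(
      trait = traits, growth_form = "tree", mean = tree, sd = tree_sd,
      lower = lower, upper = upper
    ),
    tibble::tibble(
      trait = traits, growth_form = "liana", mean = liana, sd = liana_sd,
      lower = lower, upper = upper
    )
  )
}

# Truncated-normal draws by rejection; bounds sit far enough from the
# default means that acceptance is high and moment distortion negligible.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Sample leaf traits for one growth form
#'
#' Seed-reproducible truncated-normal draws of the seven leaf parameters
#' plus the mean leaf inclination angle.
#'
#' @param growth_form `"liana"` or `"tree"`.
#' @param n Number of individuals.
#' @param config Trait configuration tibble in the format of
#'   [trait_defaults()].
#' @param seed Integer seed.
#' @return A tibble with one row per individual, columns `growth_form`,
#'   the seven leaf parameters and `angle`.
#' @export
#' @examples
#' sample_traits("liana", n = 3, seed = 1)
sample_traits <- function(growth_form = c("liana", "tree"), n = 1,
                          config = trait_defaults(), seed = 1) {
  growth_form <- match.arg(growth_form)
  cfg <- dplyr::filter(config, .data$growth_form == .env$growth_form)
  if (any(cfg$sd < 0)) stop("trait sd must be >= 0", call. = FALSE)
  set.seed(seed)
  draws <- purrr::map(seq_len(nrow(cfg)), function(i) {
    rtruncnorm(n, cfg$mean[i], cfg$sd[i], cfg$lower[i], cfg$upper[i])
  })
  names(draws) <- cfg$trait
  out <- tibble::as_tibble(draws)
  dplyr::bind_cols(tibble::tibble(growth_form = rep(growth_form, n)), out)
}

# One row of a trait draw -> leaf_params.
traits_to_leaf_params <- function(row) {
  leaf_params(
    N = row$N, C_ab = row$C_ab, C_ar = row$C_ar, C_an = row$C_an,
    C_br = row$C_br, C_w = row$C_w, C_m = row$C_m
  )
}

#' Generate synthetic leaf reflectance spectra with known truth
#'
#' Samples leaf traits, runs the forward plate model and adds iid
#' Gaussian noise clipped to \[0, 1\]. The ground-truth trait table is
#' returned alongside the spectra so inversion accuracy can be scored.
#'
#' @inheritParams sample_traits
#' @param noise_sd Standard deviation of the additive reflectance noise.
#' @param table Coefficient table for the forward model.
#' @return A list with `spectra` (matrix, leaves x wavelengths),
#'   `truth` (trait tibble) and `optics` (list of noise-free
#'   `leaf_optics`).
#' @export
generate_leaf_spectra <- function(n = 10, growth_form = c("liana", "tree"),
                                  noise_sd = 0.005, seed = 1,
                                  config = trait_defaults(),
                                  table = prospect_coefficients("D")) {
  growth_form <- match.arg(growth_form)
  truth <- sample_traits(growth_form, n, config, seed)
  optics <- purrr::map(
    seq_len(n),
    function(i) prospect_forward(traits_to_leaf_params(truth[i, ]), table)
  )
  set.seed(seed + 1L)
  spectra <- t(vapply(optics, function(o) {
    r <- o$reflectance + stats::rnorm(n_grid(), 0, noise_sd)
    pmin(pmax(r, 0), 1)
  }, numeric(n_grid())))
  list(spectra = spectra, truth = truth, optics = optics)
}

#' Generate synthetic canopy reflectance ensembles with known truth
#'
#' Draws per-canopy leaf traits for the liana and tree components, runs
#' the coupled leaf--canopy model at the requested infestation levels and
#' adds residual reflectance noise. Emulates ensembles of infested
#' (high `L`) and liana-free (low `L`) canopies.
#'
#' @param n_per_class Canopies per infestation level.
#' @param L_levels Numeric vector of infestation indices.
#' @param canopy Baseline [canopy_config()]; `L` is overridden per level.
#' @param geom A [view_geometry()].
#' @param residual_sd Additive reflectance noise (the model residual).
#' @param seed Integer seed.
#' @param config Trait configuration.
#' @param wavelengths Optional grid subset for speed.
#' @return A tibble with columns `L`, `canopy_id`, `wavelength_nm`,
#'   `rho`, plus a `truth` attribute holding the sampled traits and
#'   canopy parameters per canopy.
#' @export
generate_canopy_spectra <- function(n_per_class = 10, L_levels = c(0, 1),
                                    canopy = canopy_config(),
                                    geom = view_geometry(),
                                    residual_sd = 0.01, seed = 1,
                                    config = trait_defaults(),
                                    wavelengths = NULL) {
  idx <- if (is.null(wavelengths)) spectral_grid() else wavelengths
  soil <- soil_model(canopy$omega_soil)
  diffuse <- diffuse_fraction(geom$tts)
  rows <- list()
  truth <- list()
  counter <- 0L
  level_idx <- 0L
  for (L in L_levels) {
    level_idx <- level_idx + 1L
    liana_tr <- sample_traits("liana", n_per_class, config, seed + counter)
    tree_tr <- sample_traits("tree", n_per_class, config, seed + counter + 1L)
    set.seed(seed + counter + 2L)
    noise_seeds <- sample.int(1e6, n_per_class)
    for (i in seq_len(n_per_class)) {
      counter <- counter + 3L
      cc <- canopy
      cc$L <- L
      cc$omega1 <- liana_tr$angle[i]
      cc$omega2 <- tree_tr$angle[i]
      ref <- couple_prosail2(
        traits_to_leaf_params(liana_tr[i, ]),
        traits_to_leaf_params(tree_tr[i, ]),
        cc, geom, soil,
        diffuse = diffuse, wavelengths = idx
      )
      set.seed(noise_seeds[i])
      rho <- pmin(pmax(ref$rho + stats::rnorm(length(idx), 0, residual_sd), 0), 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        L = L, canopy_id = sprintf("c%d_%02d", level_idx, i),
        wavelength_nm = as.numeric(idx), rho = rho
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        L = L, canopy_id = sprintf("c%d_%02d", level_idx, i),
        liana = list(liana_tr[i, ]), tree = list(tree_tr[i, ]),
        omega1 = cc$omega1, omega2 = cc$omega2, lai = cc$lai, f2 = cc$f2
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Default liana and tree canopy endmember distributions
#'
#' Convenience wrapper producing the two `spectral_distribution`s used by
#' the divergence, sensor-comparison and scene modules: ensembles of
#' fully infested (`L = 1`) and liana-free (`L = 0`) canopies simulated
#' from the default trait distributions, summarized per wavelength.
#'
#' @param n_per_class Ensemble size per class.
#' @param seed Integer seed.
#' @param residual_sd Residual reflectance noise added in simulation.
#' @param ... Passed to [generate_canopy_spectra()].
#' @return A list with elements `liana` and `tree`
#'   (`spectral_distribution` objects).
#' @export
canopy_endmembers <- function(n_per_class = 30, seed = 1, residual_sd = 0.01,
                              ...) {
  sim <- generate_canopy_spectra(
    n_per_class = n_per_class, L_levels = c(0, 1),
    residual_sd = residual_sd, seed = seed, ...
  )
  to_dist <- function(df) {
    wide <- tidyr::pivot_wider(
      df,
      id_cols = "canopy_id", names_from = "wavelength_nm",
      values_from = "rho"
    )
    m <- as.matrix(wide[, -1])
    spectral_distribution(colMeans(m), pmax(apply(m, 2, stats::sd), 1e-6))
  }
  list(
    liana = to_dist(dplyr::filter(sim, .data$L == 1)),
    tree = to_dist(dplyr::filter(sim, .data$L == 0))
  )
}

#' Generate a hierarchical trait table
#'
#' Simulates trait values `T_ijk = beta0 + beta_i + beta_jk + beta_k +
#' eps` for growth form `i`, species `j` nested in study `k`: the data
#' structure consumed by [fit_leaf_hierarchy()].
#'
#' @param n_studies Number of studies.
#' @param n_species Species per growth form per study.
#' @param n_per_species Replicate leaves per species.
#' @param beta0 Grand mean.
#' @param gf_contrast Growth-form effect (liana minus tree).
#' @param sd_species,sd_study,sd_resid Standard deviations of the
#'   species-within-study effects, study effects and residual.
#' @param seed Integer seed.
#' @return A tibble `value`, `growth_form`, `species`, `study` with the
#'   true effects stored in attributes.
#' @export
generate_trait_table <- function(n_studies = 3, n_species = 20,
                                 n_per_species = 4, beta0 = 0.01,
                                 gf_contrast = -0.002,
                                 sd_species = 0.001, sd_study = 0.002,
                                 sd_resid = 0.001, seed = 1) {
  if (n_studies < 1) stop("need at least one study", call. = FALSE)
  set.seed(seed)
  b_study <- stats::rnorm(n_studies, 0, sd_study)
  rows <- list()
  # Symmetric growth-form coding: tree at -contrast/2, liana at +contrast/2.
  gf_eff <- c(tree = -gf_contrast / 2, liana = gf_contrast / 2)
  for (k in seq_len(n_studies)) {
    for (gf in c("tree", "liana")) {
      b_sp <- stats::rnorm(n_species, 0, sd_species)
      for (j in seq_len(n_species)) {
        val <- beta0 + gf_eff[[gf]] + b_study[k] + b_sp[j] +
          stats::rnorm(n_per_species, 0, sd_resid)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          value = val,
          growth_form = gf,
          species = sprintf("s%d_%s_%d", k, gf, j),
          study = sprintf("study%d", k)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "effects") <- list(
    beta0 = beta0, gf_contrast = gf_contrast, b_study = b_study
  )
  out
}
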