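#' Canopy structural configuration for the two-layer model
#'
#' Structural parameters of the two-layer canopy: total leaf area index
#' `lai` (m2/m2), mean leaf inclination of the primary (liana, top) layer
#' `omega1` and secondary (tree, bottom) layer `omega2` (degrees from
#' zenith), the tree fraction `f2` of total LAI, the liana infestation
#' index `L` (0--1), the dissociation factor `D` (1 = all liana leaves in
#' the top layer, 0 = perfectly mixed canopy), the hotspot parameter `hot`
#' (leaf width over canopy height), the soil moisture mixing weight
#' `omega_soil`, the vertical crown cover `Cv` (fixed at 1 for closed
#' tropical canopies, which makes the crown-shape parameter `zeta` inert)
#' and `zeta` itself.
#'
#' The liana (top) layer receives the LAI share `L * (1 - f2)`; the tree
#' layer the remainder, so total LAI is conserved and the canopy collapses
#' to a single tree layer at `L = 0`.
#'
#' @param lai,omega1,omega2,f2,L,D,hot,omega_soil,Cv,zeta Scalar parameters.
#' @return A named list of class `canopy_config`.
#' @export
canopy_config <- function(lai = 5.5, omega1 = 27.9, omega2 = 37.1,
                          f2 = 0.66, L = 1, D = 1, hot = 0.05,
                          omega_soil = 0.5, Cv = 1, zeta = 0.5) {
  if (lai < 0) stop("lai must be >= 0", call. = FALSE)
  for (nm in c("f2", "L", "D", "omega_soil", "Cv")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  if (lai > 0 && (omega1 < 5 || omega1 > 85 || omega2 < 5 || omega2 > 85)) {
    stop("mean leaf angles must lie in [5, 85] degrees", call. = FALSE)
  }
  if (hot < 0) stop("hotspot parameter must be >= 0", call. = FALSE)
  if (Cv < 1) {
    warning("Cv < 1 (fractional crown cover) is not modelled; using Cv = 1")
  }
  structure(
    list(
      lai = lai, omega1 = omega1, omega2 = omega2, f2 = f2, L = L, D = D,
      hot = hot, omega_soil = omega_soil, Cv = 1, zeta = zeta
    ),
    class = "canopy_config"
  )
}

#' Sun-sensor geometry
#'
#' @param tts Solar zenith angle (degrees, 0--90 exclusive of 90).
#' @param tto Observer zenith angle (degrees).
#' @param psi Relative azimuth between sun and observer (degrees, 0--360).
#' @return A named list of class `view_geometry`.
#' @export
view_geometry <- function(tts = 30, tto = 0, psi = 0) {
  if (tts < 0 || tts >= 90 || tto < 0 || tto >= 90) {
    stop("zenith angles must lie in [0, 90)", call. = FALSE)
  }
  psi <- psi %% 360
  structure(list(tts = tts, tto = tto, psi = psi), class = "view_geometry")
}

#' Soil lower boundary
#'
#' The effective soil reflectance is a linear mix of a dry and a wet
#' reference spectrum, `(1 - omega_soil) * dry + omega_soil * wet`. The
#' built-in reference spectra are synthetic smooth curves shaped like
#' typical bright tropical soil (brightness rising from the visible into
#' the SWIR, water absorption dips at 1450/1940 nm in the wet spectrum).
#'
#' @param omega_soil Moisture mixing weight in \[0, 1\].
#' @param dry,wet Optional replacement spectra on the common grid.
#' @return A list of class `soil_model` with elements `dry`, `wet`,
#'   `omega_soil` and the effective `reflectance`.
#' @export
soil_model <- function(omega_soil = 0.5, dry = NULL, wet = NULL) {
  if (omega_soil < 0 || omega_soil > 1) {
    stop("omega_soil must lie in [0, 1]", call. = FALSE)
  }
  wl <- as.numeric(spectral_grid())
  if (is.null(dry)) {
    dry <- 0.10 + 0.25 * (1 - exp(-(wl - 400) / 900))
  }
  if (is.null(wet)) {
    dip <- exp(-0.5 * ((wl - 1450) / 90)^2) + 1.6 * exp(-0.5 * ((wl - 1940) / 110)^2)
    wet <- 0.55 * dry * (1 - 0.35 * pmin(dip, 1))
  }
  if (length(dry) != n_grid() || length(wet) != n_grid()) {
    stop("soil spectra must be on the common 1-nm grid", call. = FALSE)
  }
  if (any(dry < 0 | dry > 1 | wet < 0 | wet > 1)) {
    stop("soil reflectance must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      dry = dry, wet = wet, omega_soil = omega_soil,
      reflectance = (1 - omega_soil) * dry + omega_soil * wet
    ),
    class = "soil_model"
  )
}

#' Diffuse skylight fraction
#'
#' Fraction of incident irradiance that is diffuse, per wavelength and
#' solar zenith angle. The built-in default is a tabulated smooth curve:
#' a Rayleigh-like component falling off as `(400 / lambda)^4` plus a
#' weak aerosol tail, scaled up with solar zenith angle (longer air mass
#' means a larger diffuse share). It is monotonically non-increasing in
#' wavelength and is a documented stand-in for an atmospheric model; a
#' user table (columns `wavelength_nm` and one column per solar zenith,
#' named `s<deg>`) can replace it via `table`.
#'
#' @param tts Solar zenith angle in degrees.
#' @param table Optional data frame with column `wavelength_nm` and
#'   columns `s0`, `s10`, ..., `s80` giving the fraction at those zeniths;
#'   interpolated in both wavelength and zenith.
#' @param force Optional scalar in \[0, 1\]: ignore the table and return a
#'   constant fraction (useful to isolate the direct or diffuse stream).
#' @return Numeric vector on the common grid, values in \[0, 1\].
#' @export
diffuse_fraction <- function(tts = 30, table = NULL, force = NULL) {
  if (!is.null(force)) {
    if (force < 0 || force > 1) stop("force must lie in [0, 1]", call. = FALSE)
    return(rep(force, n_grid()))
  }
  if (tts < 0 || tts >= 90) stop("tts must lie in [0, 90)", call. = FALSE)
  if (is.null(table)) table <- default_diffuse_table()
  zen <- as.numeric(sub("^s", "", setdiff(names(table), "wavelength_nm")))
  cols <- paste0("s", zen[order(zen)])
  zen <- sort(zen)
  mat <- vapply(cols, function(cl) regrid(table$wavelength_nm, table[[cl]]),
    numeric(n_grid())
  )
  if (tts <= zen[1]) {
    out <- mat[, 1]
  } else if (tts >= zen[length(zen)]) {
    out <- mat[, length(zen)]
  } else {
    i <- findInterval(tts, zen)
    wgt <- (tts - zen[i]) / (zen[i + 1] - zen[i])
    out <- (1 - wgt) * mat[, i] + wgt * mat[, i + 1]
  }
  pmin(pmax(out, 0), 1)
}

# Built-in diffuse-fraction table, one column per 10 degrees of solar
# zenith. Cached after first construction.
.diffuse_cache <- new.env(parent = emptyenv())

default_diffuse_table <- function() {
  if (!is.null(.diffuse_cache$tab)) {
    return(.diffuse_cache$tab)
  }
  wl <- as.numeric(spectral_grid())
  zen <- seq(0, 80, by = 10)
  tab <- tibble::tibble(wavelength_nm = wl)
  for (z in zen) {
    airmass <- 1 / max(cos(z * pi / 180), 0.15)
    base <- 1 - exp(-0.30 * airmass)
    ray <- (400 / wl)^4
    aer <- exp(-(wl - 400) / 1500)
    tab[[paste0("s", z)]] <- pmin(base * (0.75 * ray + 0.25 * aer) + 0.02, 1)
  }
  .diffuse_cache$tab <- tab
  tab
}

#' Liana share of total leaf area
#'
#' The fraction of total LAI held by the liana (top) layer under the
#' layer-partition rule: `L * (1 - f2)`, where `L` is the infestation
#' index and `f2` the tree fraction at full infestation.
#'
#' @param L Infestation index in \[0, 1\].
#' @param f2 Tree fraction of total LAI in \[0, 1\].
#' @return Scalar fraction in \[0, 1\].
#' @export
#' @examples
#' liana_lai_fraction(1, 0.653) # 0.347
liana_lai_fraction <- function(L, f2) {
  if (L < 0 || L > 1 || f2 < 0 || f2 > 1) {
    stop("L and f2 must lie in [0, 1]", call. = FALSE)
  }
  L * (1 - f2)
}

# Per-layer particle composition. With dissociation D = 1 the top layer is
# pure liana; with D = 0 both layers carry the global liana fraction. The
# top-layer liana share interpolates linearly in D and the bottom layer
# balances it so total liana leaf area is conserved.
layer_composition <- function(L, f2, D) {
  fl <- liana_lai_fraction(L, f2)
  p_top <- fl + D * (1 - fl)
  p_bot <- if (fl >= 1 - 1e-12) 0 else fl * (1 - p_top) / (1 - fl)
  list(fl = fl, p_top = p_top, p_bot = p_bot)
}

#' Two-layer canopy bidirectional and hemispherical reflectance
#'
#' Four-stream solution of the two-layer canopy: the liana layer (leaf
#' area `lai * L * (1 - f2)`, mean inclination `omega1`) on top of the
#' tree layer (remaining leaf area, inclination `omega2`), over a
#' Lambertian soil. Each layer's extinction and scattering coefficients
#' derive from its own particle mix and ellipsoidal leaf-angle
#' distribution; the direct beam carries a hotspot correction, and layers
#' are combined by adding, with the bidirectional gap probability
#' propagating the direct-direct response of the lower medium.
#'
#' @param liana_optics,tree_optics `leaf_optics` tibbles from
#'   [prospect_forward()] (or any tibble with `wavelength_nm`,
#'   `reflectance`, `transmittance`).
#' @param canopy A [canopy_config()].
#' @param geom A [view_geometry()].
#' @param soil A [soil_model()].
#' @param wavelengths Optional integer subset of the common grid on which
#'   to evaluate (speeds up inversion); default is the full grid.
#' @return A tibble of class `canopy_reflectance` with columns
#'   `wavelength_nm`, `rho_s` (bidirectional, direct beam), `rho_d`
#'   (hemispherical-directional, diffuse incidence).
#' @export
foursail2_forward <- function(liana_optics, tree_optics,
                              canopy = canopy_config(),
                              geom = view_geometry(),
                              soil = soil_model(canopy$omega_soil),
                              wavelengths = NULL) {
  idx <- if (is.null(wavelengths)) seq_len(n_grid()) else grid_index(wavelengths)
  wl <- as.numeric(spectral_grid())[idx]
  if (nrow(liana_optics) != nrow(tree_optics)) {
    stop("leaf optics must share a common grid", call. = FALSE)
  }
  # Leaf optics may arrive on the full grid or already on the requested
  # subset (as produced by prospect_forward(wavelengths = ...)).
  sub_idx <- if (nrow(liana_optics) == length(idx) &&
    all(liana_optics$wavelength_nm == wl)) {
    seq_along(idx)
  } else if (nrow(liana_optics) == n_grid()) {
    idx
  } else {
    stop("leaf optics must be on the common 1-nm grid", call. = FALSE)
  }
  rho1 <- liana_optics$reflectance[sub_idx]
  tau1 <- liana_optics$transmittance[sub_idx]
  rho2 <- tree_optics$reflectance[sub_idx]
  tau2 <- tree_optics$transmittance[sub_idx]
  rsoil <- soil$reflectance[idx]

  ops <- foursail2_core(rho1, tau1, rho2, tau2, rsoil, canopy, geom)

  tibble::new_tibble(
    tibble::tibble(
      wavelength_nm = wl,
      rho_s = ops$rso,
      rho_d = ops$rdo
    ),
    class = "canopy_reflectance"
  )
}

# Internal core of the two-layer solution operating on bare vectors.
# The compiled four-stream kernel is the production path; the pure-R
# reference implementation (foursail2_core_r) is retained and tested
# against it.
foursail2_core <- function(rho1, tau1, rho2, tau2, rsoil, canopy, geom) {
  comp <- layer_composition(canopy$L, canopy$f2, canopy$D)
  lai_top <- canopy$lai * comp$fl
  lai_bot <- canopy$lai - lai_top
  p <- comp$p_top
  q <- comp$p_bot
  gl <- gauss_nodes(32)
  .foursail2_cpp(
    p * rho1 + (1 - p) * rho2, p * tau1 + (1 - p) * tau2,
    q * rho1 + (1 - q) * rho2, q * tau1 + (1 - q) * tau2,
    rsoil,
    lidf_ellipsoidal(canopy$omega1), lidf_ellipsoidal(canopy$omega2),
    lidf_class_centers(),
    lai_top, lai_bot, canopy$hot,
    geom$tts, geom$tto, geom$psi, gl$x, gl$w
  )
}

# Pure-R reference implementation of the same computation.
foursail2_core_r <- function(rho1, tau1, rho2, tau2, rsoil, canopy, geom) {
  comp <- layer_composition(canopy$L, canopy$f2, canopy$D)
  lai_top <- canopy$lai * comp$fl
  lai_bot <- canopy$lai - lai_top

  # Effective particle optics per layer: linear mix of the scattering
  # cross-sections of the two leaf types.
  p <- comp$p_top
  q <- comp$p_bot
  lay_top <- sail_layer(
    p * rho1 + (1 - p) * rho2, p * tau1 + (1 - p) * tau2,
    lai_top, lidf_ellipsoidal(canopy$omega1),
    geom$tts, geom$tto, geom$psi, canopy$hot
  )
  lay_bot <- sail_layer(
    q * rho1 + (1 - q) * rho2, q * tau1 + (1 - q) * tau2,
    lai_bot, lidf_ellipsoidal(canopy$omega2),
    geom$tts, geom$tto, geom$psi, canopy$hot
  )
  combine_canopy(
    lay_top, lay_bot, rsoil, canopy$hot,
    geom$tts, geom$tto, geom$psi
  )
}

#' Coupled leaf-canopy forward simulation
#'
#' Runs the plate leaf model for the liana and tree leaf types, feeds both
#' into the two-layer canopy model, and mixes the direct-beam and
#' diffuse-incidence reflectances with the diffuse skylight fraction
#' `S(lambda, tts)` to give the surface reflectance
#' `rho = S * rho_d + (1 - S) * rho_s`.
#'
#' @param liana_leaf,tree_leaf [leaf_params()] for the two leaf types.
#' @inheritParams foursail2_forward
#' @param table Coefficient table for the leaf model.
#' @param diffuse Per-wavelength diffuse fraction on the common grid;
#'   default [diffuse_fraction()] at the configured solar zenith.
#' @return A `canopy_reflectance` tibble with the additional combined
#'   column `rho`.
#' @export
#' @examples
#' ref <- couple_prosail2(
#'   liana_leaf = leaf_params(N = 1.6, C_ab = 34),
#'   tree_leaf = leaf_params(N = 1.9, C_ab = 42)
#' )
#' head(ref)
couple_prosail2 <- function(liana_leaf, tree_leaf,
                            canopy = canopy_config(),
                            geom = view_geometry(),
                            soil = soil_model(canopy$omega_soil),
                            table = prospect_coefficients("D"),
                            diffuse = diffuse_fraction(geom$tts),
                            wavelengths = NULL) {
  lo <- prospect_forward(liana_leaf, table, wavelengths)
  to <- prospect_forward(tree_leaf, table, wavelengths)
  out <- foursail2_forward(lo, to, canopy, geom, soil, wavelengths)
  idx <- if (is.null(wavelengths)) seq_len(n_grid()) else grid_index(wavelengths)
  s <- diffuse[idx]
  out$rho <- s * out$rho_d + (1 - s) * out$rho_s
  out
}
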