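#' Leaf biochemical and structural parameters
#'
#' Container for the seven parameters of the generalized plate model of leaf
#' radiative transfer: the structure parameter `N` (average number of
#' air--cell-wall interfaces, unitless, >= 1), chlorophyll a+b content
#' `C_ab` (ug/cm2), carotenoid content `C_ar` (ug/cm2), anthocyanin content
#' `C_an` (ug/cm2), brown pigment content `C_br` (arbitrary units),
#' equivalent water thickness `C_w` (g/cm2) and leaf dry mass per area
#' `C_m` (g/cm2).
#'
#' @param N,C_ab,C_ar,C_an,C_br,C_w,C_m Scalar parameter values.
#' @return A named list of class `leaf_params`.
#' @export
#' @examples
#' leaf_params(N = 1.5, C_ab = 40, C_w = 0.01, C_m = 0.009)
leaf_params <- function(N = 1.5, C_ab = 40, C_ar = 10, C_an = 0, C_br = 0,
                        C_w = 0.01, C_m = 0.009) {
  p <- list(
    N = N, C_ab = C_ab, C_ar = C_ar, C_an = C_an, C_br = C_br,
    C_w = C_w, C_m = C_m
  )
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("leaf parameters must be finite", call. = FALSE)
  }
  if (N < 1) stop("leaf structure parameter N must be >= 1", call. = FALSE)
  if (any(vals[-1] < 0)) {
    stop("leaf constituent contents must be >= 0", call. = FALSE)
  }
  structure(p, class = "leaf_params")
}

# Map from leaf_params fields to coefficient-table columns.
constituent_map <- function() {
  c(
    C_ab = "k_cab", C_ar = "k_car", C_an = "k_can", C_br = "k_brown",
    C_w = "k_cw", C_m = "k_cm"
  )
}

#' Per-wavelength absorption argument of the elementary plate
#'
#' Computes `k(lambda) = sum_i c_i * sac_i(lambda) / N`: total specific
#' absorption of all constituents present in the table variant, normalized
#' by the number of elementary layers so that `k` is the absorption of one
#' plate. Constituents switched off by the variant have all-zero columns
#' and contribute nothing.
#'
#' @param params A [leaf_params()] object.
#' @param table A coefficient table from [prospect_coefficients()] or
#'   [read_coefficient_table()].
#' @return Numeric vector `k(lambda)` on the common grid, >= 0.
#' @export
total_absorption <- function(params, table) {
  if (!inherits(params, "leaf_params")) params <- do.call(leaf_params, params)
  validate_coefficient_table(table)
  cmap <- constituent_map()
  k <- numeric(n_grid())
  for (field in names(cmap)) {
    k <- k + params[[field]] * table[[cmap[[field]]]]
  }
  k / params$N
}

# Transmissivity of an isotropic-radiation plate with absorption argument k:
# theta(k) = (1 - k) exp(-k) + k^2 E1(k), with theta(0) = 1.
plate_transmissivity <- function(k) {
  out <- numeric(length(k))
  zero <- k <= 0
  out[zero] <- 1
  kk <- k[!zero]
  if (length(kk) > 0) {
    out[!zero] <- (1 - kk) * exp(-kk) + kk^2 * pracma::expint(kk)
  }
  out
}

# Average transmissivity of a dielectric interface for radiation incident
# within a cone of half-angle alpha (degrees), refractive index ratio nr.
# Closed form after Stern (1964) as used throughout the plate-model family.
tav <- function(alpha, nr) {
  rd <- pi / 180
  n2 <- nr^2
  np <- n2 + 1
  nm <- n2 - 1
  a <- (nr + 1)^2 / 2
  k <- -(n2 - 1)^2 / 4
  sa <- sin(alpha * rd)

  b1 <- if (alpha == 90) 0 else sqrt((sa^2 - np / 2)^2 + k)
  b2 <- sa^2 - np / 2
  b <- b1 - b2
  b3 <- b^3
  a3 <- a^3
  ts <- (k^2 / (6 * b3) + k / b - b / 2) - (k^2 / (6 * a3) + k / a - a / 2)
  tp1 <- -2 * n2 * (b - a) / np^2
  tp2 <- -2 * n2 * np * log(b / a) / nm^2
  tp3 <- n2 * (1 / b - 1 / a) / 2
  tp4 <- 16 * n2^2 * (n2^2 + 1) * log((2 * np * b - nm^2) / (2 * np * a - nm^2)) /
    (np^3 * nm^2)
  tp5 <- 16 * n2^3 * (1 / (2 * np * b - nm^2) - 1 / (2 * np * a - nm^2)) / np^3
  tp <- tp1 + tp2 + tp3 + tp4 + tp5
  (ts + tp) / (2 * sa^2)
}

# Cone half-angle (degrees) for the illuminated top surface of the leaf.
# The conventional value for a leaf in a canopy; a fixed model constant.
LEAF_INCIDENCE_ANGLE <- 40

#' Forward leaf radiative transfer (generalized plate model)
#'
#' Simulates leaf reflectance, transmittance and absorption on the common
#' wavelength grid by radiative transfer through `N` semitransparent plates:
#' one elementary plate whose upper interface receives radiation within a
#' 40 degree cone, stacked on `N - 1` internal layers solved with the
#' classical closed form for a pile of identical plates. `N` may be
#' non-integer.
#'
#' @inheritParams total_absorption
#' @param wavelengths Optional integer subset of the common grid on which
#'   to evaluate (used by the inversion machinery for speed).
#' @return A tibble of class `leaf_optics` with columns `wavelength_nm`,
#'   `reflectance`, `transmittance`, `absorption`; the three optical columns
#'   sum to 1 at every wavelength.
#' @export
#' @examples
#' opt <- prospect_forward(leaf_params(N = 1.5, C_ab = 40))
#' summary(opt$reflectance)
prospect_forward <- function(params, table = prospect_coefficients("D"),
                             wavelengths = NULL) {
  if (!inherits(params, "leaf_params")) params <- do.call(leaf_params, params)
  k <- total_absorption(params, table)
  idx <- if (is.null(wavelengths)) seq_len(n_grid()) else grid_index(wavelengths)
  k <- k[idx]
  theta <- plate_transmissivity(k)
  nr <- table$refractive_index[idx]
  N <- params$N

  # Elementary plate: top interface illuminated within a 40 deg cone,
  # internal interfaces under isotropic (90 deg) radiation.
  talf <- tav(LEAF_INCIDENCE_ANGLE, nr)
  ralf <- 1 - talf
  t12 <- tav(90, nr)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21

  denom <- 1 - r21^2 * theta^2
  Ta <- talf * theta * t21 / denom
  Ra <- ralf + r21 * theta * Ta
  t <- t12 * theta * t21 / denom
  r <- r12 + r21 * theta * t

  # Pile of N - 1 identical internal layers (two-flux closed form).
  sub <- plate_stack_closed_form(r, t, N - 1)

  dnm <- 1 - sub$R * r
  transmittance <- Ta * sub$T / dnm
  reflectance <- Ra + Ta * sub$R * t / dnm

  tibble::new_tibble(
    tibble::tibble(
      wavelength_nm = as.numeric(spectral_grid())[idx],
      reflectance = reflectance,
      transmittance = transmittance,
      absorption = 1 - reflectance - transmittance
    ),
    class = "leaf_optics"
  )
}

# Internal tibble-free fast path: leaf reflectance/transmittance vectors
# at precomputed grid indices, using the compiled plate kernel. No input
# validation; used in tight inversion loops.
prospect_rt <- function(params, table, idx) {
  cmap <- constituent_map()
  k <- 0
  for (field in names(cmap)) {
    k <- k + params[[field]] * table[[cmap[[field]]]][idx]
  }
  k <- k / params$N
  .prospect_plate_cpp(
    params$N, k, table$refractive_index[idx], LEAF_INCIDENCE_ANGLE
  )
}

# Pure-R reference of the same fast path (tested against prospect_rt).
prospect_rt_r <- function(params, table, idx) {
  cmap <- constituent_map()
  k <- 0
  for (field in names(cmap)) {
    k <- k + params[[field]] * table[[cmap[[field]]]][idx]
  }
  k <- k / params$N
  theta <- plate_transmissivity(k)
  nr <- table$refractive_index[idx]
  talf <- tav(LEAF_INCIDENCE_ANGLE, nr)
  ralf <- 1 - talf
  t12 <- tav(90, nr)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * theta^2
  Ta <- talf * theta * t21 / denom
  Ra <- ralf + r21 * theta * Ta
  t <- t12 * theta * t21 / denom
  r <- r12 + r21 * theta * t
  sub <- plate_stack_closed_form(r, t, params$N - 1)
  dnm <- 1 - sub$R * r
  list(
    tau = Ta * sub$T / dnm,
    rho = Ra + Ta * sub$R * t / dnm
  )
}

# Reflectance and transmittance of a pile of m identical layers, each with
# reflectance r and transmittance t, for real (possibly non-integer) m.
# Closed form of the two-flux difference equations; the conservative case
# r + t -> 1 is handled by its analytic limit.
plate_stack_closed_form <- function(r, t, m) {
  if (m <= 0) {
    return(list(R = numeric(length(r)), T = rep(1, length(r))))
  }
  D2 <- (1 + r + t) * (1 + r - t) * (1 - r + t) * (1 - r - t)
  conservative <- D2 < 1e-14 | (r + t) >= 1 - 1e-10
  D <- sqrt(pmax(D2, 0))
  rq <- r^2
  tq <- t^2
  a <- (1 + rq - tq + D) / (2 * r)
  b <- (1 - rq + tq + D) / (2 * t)
  bm <- b^m
  b2m <- bm^2
  a2 <- a^2
  dn <- a2 * b2m - 1
  R <- a * (b2m - 1) / dn
  Tm <- bm * (a2 - 1) / dn
  # Conservative limit: R + T = 1, T = t / (t + (1 - t) m).
  if (any(conservative)) {
    Tc <- t / (t + (1 - t) * m)
    Tm[conservative] <- Tc[conservative]
    R[conservative] <- 1 - Tc[conservative]
  }
  list(R = R, T = Tm)
}
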