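# Independent reference implementations used as oracles. These solve the
# same physical problems by different numerical routes than the package
# code and are deliberately simple and slow.

# --- Leaf plate model oracles -----------------------------------------

# Reflectance/transmittance of a pile of m layers by iterative adding of
# one layer at a time (integer m only).
stack_iterative <- function(r, t, m) {
  R <- r
  Tm <- t
  if (m >= 2) {
    for (j in seq_len(m - 1)) {
      dn <- 1 - R * r
      Tm_new <- t * Tm / dn
      R_new <- r + t^2 * R / dn
      Tm <- Tm_new
      R <- R_new
    }
  }
  list(R = R, T = Tm)
}

# Same quantity via the two-flux transfer matrix raised to a real power
# by eigen-decomposition (works for non-integer m); scalar r, t.
stack_transfer_matrix <- function(r, t, m) {
  # Transfer matrix of one layer acting on (down, up) fluxes:
  # M = 1/t * [[t^2 - r^2, r], [-r, 1]]
  M <- matrix(c(t^2 - r^2, -r, r, 1), 2, 2) / t
  e <- eigen(M)
  Mm <- e$vectors %*% diag(e$values^m) %*% solve(e$vectors)
  # For incident unit down-flux at top and no up-flux at bottom:
  # (T, 0)' = Mm (1, R)' refactored: down_out = Mm11 + Mm12 R, 0 = Mm21 + Mm22 R
  R <- -Mm[2, 1] / Mm[2, 2]
  T <- Mm[1, 1] + Mm[1, 2] * R
  list(R = Re(R), T = Re(T))
}

# Interface transmissivity by direct integration of Fresnel coefficients
# over the incidence cone.
fresnel_tav <- function(alpha, n) {
  Tfun <- function(th) {
    st <- sin(th)
    ct <- cos(th)
    stt <- st / n
    ctt <- sqrt(1 - stt^2)
    rs <- ((ct - n * ctt) / (ct + n * ctt))^2
    rp <- ((n * ct - ctt) / (n * ct + ctt))^2
    1 - (rs + rp) / 2
  }
  a <- alpha * pi / 180
  num <- stats::integrate(function(th) Tfun(th) * sin(th) * cos(th), 0, a,
    rel.tol = 1e-10
  )$value
  num / (sin(a)^2 / 2)
}

# --- Canopy four-stream slab-discretization oracle --------------------

# Numerical solution of the two-layer four-stream problem by adding many
# thin homogeneous slabs bottom-up over the soil, first order per slab,
# with Richardson extrapolation over the slab count. No hotspot
# correlation (use hot = 0 in the configuration under test).
slab_oracle <- function(rho1, tau1, rho2, tau2, rsoil, canopy, geom,
                        n_slabs = 800, richardson = TRUE) {
  run <- function(ns) {
    comp <- lianasignal:::layer_composition(canopy$L, canopy$f2, canopy$D)
    lai_top <- canopy$lai * comp$fl
    lai_bot <- canopy$lai - lai_top
    p <- comp$p_top
    q <- comp$p_bot
    layers <- list(
      list(
        rho = q * rho1 + (1 - q) * rho2, tau = q * tau1 + (1 - q) * tau2,
        lai = lai_bot, lidf = lianasignal::lidf_ellipsoidal(canopy$omega2)
      ),
      list(
        rho = p * rho1 + (1 - p) * rho2, tau = p * tau1 + (1 - p) * tau2,
        lai = lai_top, lidf = lianasignal::lidf_ellipsoidal(canopy$omega1)
      )
    )
    below <- list(rdd = rsoil, rsd = rsoil, rdo = rsoil, rso = rsoil)
    for (lay in layers) {
      if (lay$lai <= 0) next
      g <- lianasignal:::sail_geometry(lay$lidf, geom$tts, geom$tto, geom$psi)
      sigb <- g$ddb * lay$rho + g$ddf * lay$tau
      sigf <- g$ddf * lay$rho + g$ddb * lay$tau
      att <- 1 - sigf
      sb <- g$sdb * lay$rho + g$sdf * lay$tau
      sf <- g$sdf * lay$rho + g$sdb * lay$tau
      vb <- g$dob * lay$rho + g$dof * lay$tau
      vf <- g$dof * lay$rho + g$dob * lay$tau
      w <- g$sob * lay$rho + g$sof * lay$tau
      d <- lay$lai / ns
      tss_d <- exp(-g$ks * d)
      too_d <- exp(-g$ko * d)
      tdd_d <- 1 - att * d
      rdd_d <- sigb * d
      tsd_d <- sf * d
      rsd_d <- sb * d
      tdo_d <- vf * d
      rdo_d <- vb * d
      rso_d <- w * d
      for (s in seq_len(ns)) {
        dn <- 1 - rdd_d * below$rdd
        Em <- (tsd_d + rdd_d * below$rsd * tss_d) / dn
        Ep <- (below$rsd * tss_d + below$rdd * tsd_d) / dn
        Emd <- tdd_d / dn
        Epd <- below$rdd * Emd
        below <- list(
          rsd = rsd_d + tdd_d * Ep,
          rdd = rdd_d + tdd_d * Epd,
          rdo = rdo_d + too_d * below$rdo * Emd + tdo_d * Epd,
          rso = rso_d + tss_d * too_d * below$rso +
            too_d * below$rdo * Em + tdo_d * Ep
        )
      }
    }
    below
  }
  if (!richardson) {
    return(run(n_slabs))
  }
  a <- run(n_slabs)
  b <- run(2 * n_slabs)
  list(
    rso = 2 * b$rso - a$rso, rdo = 2 * b$rdo - a$rdo,
    rdd = 2 * b$rdd - a$rdd, rsd = 2 * b$rsd - a$rsd
  )
}

# --- Misc fixtures ----------------------------------------------------

liana_leaf_default <- function() {
  leaf_params(N = 1.6, C_ab = 34, C_ar = 8.5, C_w = 0.009, C_m = 0.0075)
}

tree_leaf_default <- function() {
  leaf_params(N = 1.9, C_ab = 42, C_ar = 11, C_w = 0.012, C_m = 0.010)
}

random_leaf_params <- function() {
  leaf_params(
    N = runif(1, 1.1, 3), C_ab = runif(1, 5, 80), C_ar = runif(1, 1, 25),
    C_an = runif(1, 0, 3), C_br = runif(1, 0, 0.5),
    C_w = runif(1, 0.002, 0.03), C_m = runif(1, 0.002, 0.02)
  )
}
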