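# Four-stream turbid-medium machinery: geometric projection factors per
# leaf-angle class, the analytic single-layer solution (direct, diffuse and
# observer streams with hotspot correction), and the adding equations that
# stack two layers on a soil lower boundary.

# Projection and scattering geometry for one leaf inclination (all angles
# in degrees). Returns the sun/view extinction contributions and the
# bidirectional scattering fractions of the classical four-stream model.
volscatt <- function(tts, tto, psi, ttl) {
  rd <- pi / 180
  costs <- cos(rd * tts)
  costo <- cos(rd * tto)
  sints <- sin(rd * tts)
  sinto <- sin(rd * tto)
  cospsi <- cos(rd * psi)
  psir <- rd * psi
  costl <- cos(rd * ttl)
  sintl <- sin(rd * ttl)
  cs <- costl * costs
  co <- costl * costo
  ss <- sintl * sints
  so <- sintl * sinto

  cosbts <- 5
  if (abs(ss) > 1e-6) cosbts <- -cs / ss
  cosbto <- 5
  if (abs(so) > 1e-6) cosbto <- -co / so

  if (abs(cosbts) < 1) {
    bts <- acos(cosbts)
    ds <- ss
  } else {
    bts <- pi
    ds <- cs
  }
  chi_s <- 2 / pi * ((bts - pi / 2) * cs + sin(bts) * ss)

  if (abs(cosbto) < 1) {
    bto <- acos(cosbto)
    doo <- so
  } else if (tto < 90) {
    bto <- pi
    doo <- co
  } else {
    bto <- 0
    doo <- -co
  }
  chi_o <- 2 / pi * ((bto - pi / 2) * co + sin(bto) * so)

  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psir <= btran1) {
    bt1 <- psir
    bt2 <- btran1
    bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psir <= btran2) {
      bt2 <- psir
      bt3 <- btran2
    } else {
      bt2 <- btran2
      bt3 <- psir
    }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- 0
  if (bt2 > 0) t2 <- sin(bt2) * (2 * ds * doo + ss * so * cos(bt1) * cos(bt3))
  denom <- 2 * pi^2
  frho <- ((pi - bt2) * t1 + t2) / denom
  ftau <- (-bt2 * t1 + t2) / denom
  c(
    chi_s = chi_s, chi_o = chi_o,
    frho = max(frho, 0), ftau = max(ftau, 0)
  )
}

# LIDF-averaged extinction and scattering coefficients of one layer.
# Scalars except where noted; spectral quantities come in via rho/tau later.
sail_geometry <- function(lidf, tts, tto, psi) {
  rd <- pi / 180
  centers <- lidf_class_centers()
  costs <- cos(rd * tts)
  costo <- cos(rd * tto)
  ks <- ko <- bf <- sob <- sof <- 0
  for (i in seq_along(centers)) {
    v <- volscatt(tts, tto, psi, centers[i])
    f <- lidf[i]
    ks <- ks + f * v[["chi_s"]] / costs
    ko <- ko + f * v[["chi_o"]] / costo
    bf <- bf + f * cos(rd * centers[i])^2
    sob <- sob + f * v[["frho"]] * pi / (costs * costo)
    sof <- sof + f * v[["ftau"]] * pi / (costs * costo)
  }
  list(
    ks = ks, ko = ko, bf = bf, sob = sob, sof = sof,
    sdb = 0.5 * (ks + bf), sdf = 0.5 * (ks - bf),
    dob = 0.5 * (ko + bf), dof = 0.5 * (ko - bf),
    ddb = 0.5 * (1 + bf), ddf = 0.5 * (1 - bf)
  )
}

# Exponential auxiliary functions with series fallbacks near k = m.
Jfunc1 <- function(k, m, t) {
  del <- (k - m) * t
  out <- numeric(length(m))
  big <- abs(del) > 1e-3
  out[big] <- (exp(-m[big] * t) - exp(-k * t)) / (k - m[big])
  sm <- !big
  out[sm] <- 0.5 * t * (exp(-k * t) + exp(-m[sm] * t)) * (1 - del[sm]^2 / 12)
  out
}

Jfunc2 <- function(k, m, t) {
  (1 - exp(-(k + m) * t)) / (k + m)
}

# Horizontal sun-view displacement parameter of the hotspot kernel.
hotspot_dso <- function(tts, tto, psi) {
  rd <- pi / 180
  tants <- tan(rd * tts)
  tanto <- tan(rd * tto)
  sqrt(max(tants^2 + tanto^2 - 2 * tants * tanto * cos(rd * psi), 0))
}

# Joint single-scattering machinery for a stack of homogeneous layers.
#
# Depth x runs 0 (top) to 1 (soil) in relative canopy height, with leaf
# area density assumed uniform in height so layer j occupies a height
# share proportional to its LAI. The joint sun-view gap probability at
# depth x is Pso(x) = exp(-A(x) + C(x)) with
#   A(x) = int_0^x (ks(u) + ko(u)) Ltot du            (two-way extinction)
#   C(x) = int_0^x g(u) Ltot exp(-a(u) (x - u)) du    (path correlation)
# where g = sqrt(ks ko) and the decorrelation rate a = 2 dso / (hot (ks+ko))
# follows the classical single-layer hotspot formulation, to which this
# reduces exactly when the layers are identical. Both integrals are
# piecewise analytic, so Pso is evaluated in closed form at any x and the
# layer integrals int Pso dx are done with Gauss-Legendre quadrature.
#
# layers: list with elements ks, ko (scalars) and lai per layer, top first.
# Returns tsstoo (joint bidirectional gap, Pso(1)) and the per-layer depth
# integrals Ltot * int_{layer j} Pso(x) dx, which multiply each layer's
# bidirectional scattering coefficient w_j(lambda) to give the
# single-scattering reflectance.
joint_hotspot <- function(layers, hot, tts, tto, psi, n_nodes = 32) {
  lais <- vapply(layers, `[[`, numeric(1), "lai")
  ltot <- sum(lais)
  if (ltot <= 0) {
    return(list(tsstoo = 1, sumint = numeric(length(layers))))
  }
  dso <- hotspot_dso(tts, tto, psi)
  bounds <- c(0, cumsum(lais / ltot))
  ks <- vapply(layers, `[[`, numeric(1), "ks")
  ko <- vapply(layers, `[[`, numeric(1), "ko")
  g <- sqrt(ks * ko) * ltot
  ext <- (ks + ko) * ltot
  # Decorrelation rate per layer; Inf disables correlation (hot = 0),
  # 0 freezes it (exact hotspot direction).
  a <- if (hot > 0) 2 * dso / (hot * (ks + ko)) else rep(Inf, length(layers))

  nlay <- length(layers)
  sumint <- numeric(nlay)
  nodes <- gauss_nodes(n_nodes)
  eval_pts <- c(1, unlist(lapply(seq_len(nlay), function(j) {
    if (bounds[j + 1] <= bounds[j]) {
      return(numeric(0))
    }
    bounds[j] + (bounds[j + 1] - bounds[j]) * nodes$x
  })))

  # log Pso at all evaluation points, vectorized over points.
  A <- numeric(length(eval_pts))
  C <- numeric(length(eval_pts))
  for (j in seq_len(nlay)) {
    u0 <- bounds[j]
    u1 <- pmin(bounds[j + 1], eval_pts)
    len <- pmax(u1 - u0, 0)
    A <- A + ext[j] * len
    if (is.finite(a[j])) {
      C <- C + if (a[j] < 1e-12) {
        g[j] * len
      } else {
        ifelse(
          len > 0,
          g[j] / a[j] *
            (exp(-a[j] * (eval_pts - u1)) - exp(-a[j] * (eval_pts - u0))),
          0
        )
      }
    }
  }
  pso <- exp(-A + C)

  pos <- 2L
  for (j in seq_len(nlay)) {
    if (bounds[j + 1] <= bounds[j]) next
    h <- bounds[j + 1] - bounds[j]
    sumint[j] <- ltot * h * sum(nodes$w * pso[pos:(pos + n_nodes - 1L)])
    pos <- pos + n_nodes
  }
  list(tsstoo = pso[1], sumint = sumint)
}

# Cached Gauss-Legendre nodes/weights on [0, 1].
.gauss_cache <- new.env(parent = emptyenv())

gauss_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gauss_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gauss_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gauss_cache[[key]]
}

# Analytic four-stream solution for one homogeneous layer. rho and tau are
# spectral vectors (leaf reflectance/transmittance of the layer's particle
# mix); the output operators are spectral vectors, plus the scalar gap
# probabilities tss, too, tsstoo.
sail_layer <- function(rho, tau, lai, lidf, tts, tto, psi, hot) {
  nw <- length(rho)
  geo <- sail_geometry(lidf, tts, tto, psi)
  ks <- geo$ks
  ko <- geo$ko
  if (lai <= 0) {
    z <- numeric(nw)
    one <- rep(1, nw)
    return(list(
      tss = 1, too = 1,
      rdd = z, tdd = one, rsd = z, tsd = z, rdo = z, tdo = z,
      rsod = z, w = geo$sob * rho + geo$sof * tau,
      ks = ks, ko = ko, lai = 0
    ))
  }

  sigb <- geo$ddb * rho + geo$ddf * tau
  sigf <- geo$ddf * rho + geo$ddb * tau
  att <- 1 - sigf
  m2 <- (att + sigb) * (att - sigb)
  m2[m2 < 0] <- 0
  m <- sqrt(m2)
  sb <- geo$sdb * rho + geo$sdf * tau
  sf <- geo$sdf * rho + geo$sdb * tau
  vb <- geo$dob * rho + geo$dof * tau
  vf <- geo$dof * rho + geo$dob * tau
  w <- geo$sob * rho + geo$sof * tau

  tss <- exp(-ks * lai)
  too <- exp(-ko * lai)

  e1 <- exp(-m * lai)
  e2 <- e1^2
  rinf <- (att - m) / pmax(sigb, 1e-12)
  rinf2 <- rinf^2
  re <- rinf * e1
  denom <- 1 - rinf2 * e2

  J1ks <- Jfunc1(ks, m, lai)
  J2ks <- Jfunc2(ks, m, lai)
  J1ko <- Jfunc1(ko, m, lai)
  J2ko <- Jfunc2(ko, m, lai)

  Ps <- (sf + sb * rinf) * J1ks
  Qs <- (sf * rinf + sb) * J2ks
  Pv <- (vf + vb * rinf) * J1ko
  Qv <- (vf * rinf + vb) * J2ko

  tdd <- (1 - rinf2) * e1 / denom
  rdd <- rinf * (1 - e2) / denom
  tsd <- (Ps - re * Qs) / denom
  rsd <- (Qs - re * Ps) / denom
  tdo <- (Pv - re * Qv) / denom
  rdo <- (Qv - re * Pv) / denom

  # Multiple-scattering part of the bidirectional reflectance.
  z <- Jfunc2(ks, ko, lai)
  g1 <- (z - J1ks * too) / (ko + m)
  g2 <- (z - J1ko * tss) / (ks + m)
  Tv1 <- (vf * rinf + vb) * g1
  Tv2 <- (vf + vb * rinf) * g2
  T1 <- Tv1 * (sf + sb * rinf)
  T2 <- Tv2 * (sf * rinf + sb)
  T3 <- (rdo * Qs + tdo * Ps) * rinf
  rsod <- (T1 + T2 - T3) / (1 - rinf2)

  list(
    tss = tss, too = too,
    rdd = rdd, tdd = tdd, rsd = rsd, tsd = tsd, rdo = rdo, tdo = tdo,
    rsod = rsod, w = w, ks = ks, ko = ko, lai = lai
  )
}

# Stack top layer / bottom layer / Lambertian soil. Multiple-scattering
# streams compose by the exact adding equations of the linear four-stream
# system; the single-scattering bidirectional term (with hotspot) is
# evaluated jointly across both layers by joint_hotspot(), so a
# homogeneous canopy split arbitrarily into two identical layers yields
# the same reflectance as a single layer.
combine_canopy <- function(lay_top, lay_bot, rsoil, hot, tts, tto, psi) {
  # Bottom layer over soil: direct-direct gap terms excluded here (they
  # are handled jointly), everything else is standard adding.
  dn2 <- 1 - lay_bot$rdd * rsoil
  rdd_b <- lay_bot$rdd + lay_bot$tdd^2 * rsoil / dn2
  rsd_b <- lay_bot$rsd + (lay_bot$tss + lay_bot$tsd) * rsoil * lay_bot$tdd / dn2
  rdo_b <- lay_bot$rdo + lay_bot$tdd * rsoil * (lay_bot$tdo + lay_bot$too) / dn2
  rso_b <- lay_bot$rsod +
    ((lay_bot$tss + lay_bot$tsd) * lay_bot$tdo +
      (lay_bot$tsd + lay_bot$tss * rsoil * lay_bot$rdd) * lay_bot$too) *
      rsoil / dn2

  # Top layer over the bottom system.
  dn <- 1 - lay_top$rdd * rdd_b
  Em <- (lay_top$tsd + lay_top$rdd * rsd_b * lay_top$tss) / dn
  Ep <- (rsd_b * lay_top$tss + rdd_b * lay_top$tsd) / dn
  rsd <- lay_top$rsd + lay_top$tdd * Ep
  Emd <- lay_top$tdd / dn
  Epd <- rdd_b * Emd
  rdd <- lay_top$rdd + lay_top$tdd * Epd
  rdo <- lay_top$rdo + lay_top$too * rdo_b * Emd + lay_top$tdo * Epd

  # Joint single-scattering with hotspot, plus the gap-gap soil bounce.
  hs <- joint_hotspot(
    list(
      list(ks = lay_top$ks, ko = lay_top$ko, lai = lay_top$lai),
      list(ks = lay_bot$ks, ko = lay_bot$ko, lai = lay_bot$lai)
    ),
    hot, tts, tto, psi
  )
  rsos <- lay_top$w * hs$sumint[1] + lay_bot$w * hs$sumint[2]
  rso <- rsos + hs$tsstoo * rsoil +
    lay_top$rsod +
    lay_top$too * lay_top$tss * rso_b +
    lay_top$too * rdo_b * Em + lay_top$tdo * Ep

  list(rdd = rdd, rsd = rsd, rdo = rdo, rso = rso)
}
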