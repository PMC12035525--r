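// Four-stream two-layer canopy core. Mirrors the reference R
// implementation (sail.R); kept in C++ because the Bayesian inversion
// evaluates this model tens of thousands of times per fit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Geometry/scattering projection for one leaf inclination angle.
static void volscatt(double tts, double tto, double psi, double ttl,
                     double &chi_s, double &chi_o, double &frho,
                     double &ftau) {
  double costs = std::cos(DEG * tts), costo = std::cos(DEG * tto);
  double sints = std::sin(DEG * tts), sinto = std::sin(DEG * tto);
  double cospsi = std::cos(DEG * psi), psir = DEG * psi;
  double costl = std::cos(DEG * ttl), sintl = std::sin(DEG * ttl);
  double cs = costl * costs, co = costl * costo;
  double ss = sintl * sints, so = sintl * sinto;

  double cosbts = 5.0, cosbto = 5.0;
  if (std::fabs(ss) > 1e-6) cosbts = -cs / ss;
  if (std::fabs(so) > 1e-6) cosbto = -co / so;

  double bts, ds;
  if (std::fabs(cosbts) < 1.0) {
    bts = std::acos(cosbts);
    ds = ss;
  } else {
    bts = M_PI;
    ds = cs;
  }
  chi_s = 2.0 / M_PI * ((bts - M_PI / 2.0) * cs + std::sin(bts) * ss);

  double bto, doo;
  if (std::fabs(cosbto) < 1.0) {
    bto = std::acos(cosbto);
    doo = so;
  } else if (tto < 90.0) {
    bto = M_PI;
    doo = co;
  } else {
    bto = 0.0;
    doo = -co;
  }
  chi_o = 2.0 / M_PI * ((bto - M_PI / 2.0) * co + std::sin(bto) * so);

  double btran1 = std::fabs(bts - bto);
  double btran2 = M_PI - std::fabs(bts + bto - M_PI);
  double bt1, bt2, bt3;
  if (psir <= btran1) {
    bt1 = psir;
    bt2 = btran1;
    bt3 = btran2;
  } else {
    bt1 = btran1;
    if (psir <= btran2) {
      bt2 = psir;
      bt3 = btran2;
    } else {
      bt2 = btran2;
      bt3 = psir;
    }
  }
  double t1 = 2.0 * cs * co + ss * so * cospsi;
  double t2 = 0.0;
  if (bt2 > 0.0)
    t2 = std::sin(bt2) * (2.0 * ds * doo + ss * so * std::cos(bt1) * std::cos(bt3));
  double denom = 2.0 * M_PI * M_PI;
  frho = ((M_PI - bt2) * t1 + t2) / denom;
  ftau = (-bt2 * t1 + t2) / denom;
  if (frho < 0) frho = 0;
  if (ftau < 0) ftau = 0;
}

struct LayerGeom {
  double ks, ko, sob, sof, sdb, sdf, dob, dof, ddb, ddf;
};

static LayerGeom sail_geometry_cpp(const NumericVector &lidf,
                                   const NumericVector &centers, double tts,
                                   double tto, double psi) {
  double costs = std::cos(DEG * tts), costo = std::cos(DEG * tto);
  LayerGeom g = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  double bf = 0;
  for (int i = 0; i < lidf.size(); ++i) {
    double chi_s, chi_o, frho, ftau;
    volscatt(tts, tto, psi, centers[i], chi_s, chi_o, frho, ftau);
    double f = lidf[i];
    g.ks += f * chi_s / costs;
    g.ko += f * chi_o / costo;
    bf += f * std::pow(std::cos(DEG * centers[i]), 2);
    g.sob += f * frho * M_PI / (costs * costo);
    g.sof += f * ftau * M_PI / (costs * costo);
  }
  g.sdb = 0.5 * (g.ks + bf);
  g.sdf = 0.5 * (g.ks - bf);
  g.dob = 0.5 * (g.ko + bf);
  g.dof = 0.5 * (g.ko - bf);
  g.ddb = 0.5 * (1.0 + bf);
  g.ddf = 0.5 * (1.0 - bf);
  return g;
}

struct LayerOps {
  double tss, too, ks, ko, lai;
  std::vector<double> rdd, tdd, rsd, tsd, rdo, tdo, rsod, w;
};

static double jfunc1(double k, double m, double t) {
  double del = (k - m) * t;
  if (std::fabs(del) > 1e-3)
    return (std::exp(-m * t) - std::exp(-k * t)) / (k - m);
  return 0.5 * t * (std::exp(-k * t) + std::exp(-m * t)) *
         (1.0 - del * del / 12.0);
}

static double jfunc2(double k, double m, double t) {
  return (1.0 - std::exp(-(k + m) * t)) / (k + m);
}

static LayerOps sail_layer_cpp(const std::vector<double> &rho,
                               const std::vector<double> &tau, double lai,
                               const LayerGeom &g) {
  int n = rho.size();
  LayerOps L;
  L.lai = lai;
  L.ks = g.ks;
  L.ko = g.ko;
  L.rdd.assign(n, 0.0);
  L.tdd.assign(n, 1.0);
  L.rsd.assign(n, 0.0);
  L.tsd.assign(n, 0.0);
  L.rdo.assign(n, 0.0);
  L.tdo.assign(n, 0.0);
  L.rsod.assign(n, 0.0);
  L.w.assign(n, 0.0);
  for (int i = 0; i < n; ++i) L.w[i] = g.sob * rho[i] + g.sof * tau[i];
  if (lai <= 0) {
    L.tss = 1.0;
    L.too = 1.0;
    return L;
  }
  L.tss = std::exp(-g.ks * lai);
  L.too = std::exp(-g.ko * lai);
  for (int i = 0; i < n; ++i) {
    double sigb = g.ddb * rho[i] + g.ddf * tau[i];
    double sigf = g.ddf * rho[i] + g.ddb * tau[i];
    double att = 1.0 - sigf;
    double m2 = (att + sigb) * (att - sigb);
    if (m2 < 0) m2 = 0;
    double m = std::sqrt(m2);
    double sb = g.sdb * rho[i] + g.sdf * tau[i];
    double sf = g.sdf * rho[i] + g.sdb * tau[i];
    double vb = g.dob * rho[i] + g.dof * tau[i];
    double vf = g.dof * rho[i] + g.dob * tau[i];

    double e1 = std::exp(-m * lai), e2 = e1 * e1;
    double sigb_safe = sigb > 1e-12 ? sigb : 1e-12;
    double rinf = (att - m) / sigb_safe;
    double rinf2 = rinf * rinf;
    double re = rinf * e1;
    double denom = 1.0 - rinf2 * e2;

    double J1ks = jfunc1(g.ks, m, lai), J2ks = jfunc2(g.ks, m, lai);
    double J1ko = jfunc1(g.ko, m, lai), J2ko = jfunc2(g.ko, m, lai);
    double Ps = (sf + sb * rinf) * J1ks;
    double Qs = (sf * rinf + sb) * J2ks;
    double Pv = (vf + vb * rinf) * J1ko;
    double Qv = (vf * rinf + vb) * J2ko;

    L.tdd[i] = (1.0 - rinf2) * e1 / denom;
    L.rdd[i] = rinf * (1.0 - e2) / denom;
    L.tsd[i] = (Ps - re * Qs) / denom;
    L.rsd[i] = (Qs - re * Ps) / denom;
    L.tdo[i] = (Pv - re * Qv) / denom;
    L.rdo[i] = (Qv - re * Pv) / denom;

    double z = jfunc2(g.ks, g.ko, lai);
    double g1 = (z - J1ks * L.too) / (g.ko + m);
    double g2 = (z - J1ko * L.tss) / (g.ks + m);
    double Tv1 = (vf * rinf + vb) * g1;
    double Tv2 = (vf + vb * rinf) * g2;
    double T1 = Tv1 * (sf + sb * rinf);
    double T2 = Tv2 * (sf * rinf + sb);
    double T3 = (L.rdo[i] * Qs + L.tdo[i] * Ps) * rinf;
    L.rsod[i] = (T1 + T2 - T3) / (1.0 - rinf2);
  }
  return L;
}

// Joint single-scattering hotspot machinery across the layer stack;
// mirrors joint_hotspot() in R.
static void joint_hotspot_cpp(const LayerOps &top, const LayerOps &bot,
                              double hot, double tts, double tto, double psi,
                              const NumericVector &gx, const NumericVector &gw,
                              double &tsstoo, double &sum1, double &sum2) {
  double ltot = top.lai + bot.lai;
  if (ltot <= 0) {
    tsstoo = 1.0;
    sum1 = 0.0;
    sum2 = 0.0;
    return;
  }
  double tants = std::tan(DEG * tts), tanto = std::tan(DEG * tto);
  double d2 = tants * tants + tanto * tanto -
              2.0 * tants * tanto * std::cos(DEG * psi);
  double dso = std::sqrt(d2 > 0 ? d2 : 0);

  double bounds[3] = {0.0, top.lai / ltot, 1.0};
  double ks[2] = {top.ks, bot.ks}, ko[2] = {top.ko, bot.ko};
  double g[2], ext[2], a[2];
  for (int j = 0; j < 2; ++j) {
    g[j] = std::sqrt(ks[j] * ko[j]) * ltot;
    ext[j] = (ks[j] + ko[j]) * ltot;
    a[j] = hot > 0 ? 2.0 * dso / (hot * (ks[j] + ko[j])) : INFINITY;
  }

  auto logPso = [&](double x) {
    double A = 0.0, C = 0.0;
    for (int j = 0; j < 2; ++j) {
      double u0 = bounds[j];
      double u1 = std::min(bounds[j + 1], x);
      if (u1 <= u0) continue;
      A += ext[j] * (u1 - u0);
      if (std::isfinite(a[j])) {
        if (a[j] < 1e-12)
          C += g[j] * (u1 - u0);
        else
          C += g[j] / a[j] *
               (std::exp(-a[j] * (x - u1)) - std::exp(-a[j] * (x - u0)));
      }
    }
    return -A + C;
  };

  tsstoo = std::exp(logPso(1.0));
  double sums[2] = {0.0, 0.0};
  for (int j = 0; j < 2; ++j) {
    double h = bounds[j + 1] - bounds[j];
    if (h <= 0) continue;
    double s = 0.0;
    for (int q = 0; q < gx.size(); ++q) {
      double x = bounds[j] + h * gx[q];
      s += gw[q] * std::exp(logPso(x));
    }
    sums[j] = ltot * h * s;
  }
  sum1 = sums[0];
  sum2 = sums[1];
}

// Exponential integral E1(x), x > 0: power series for small x, modified
// Lentz continued fraction for large x; ~1e-14 relative accuracy.
static double expint_e1(double x) {
  const double euler = 0.57721566490153286061;
  if (x <= 0) return INFINITY;
  if (x <= 1.0) {
    double sum = 0.0, term = 1.0;
    for (int n = 1; n <= 40; ++n) {
      term *= -x / n;
      double add = -term / n;
      sum += add;
      if (std::fabs(add) < 1e-17 * std::fabs(sum)) break;
    }
    return -euler - std::log(x) + sum;
  }
  // Continued fraction: E1(x) = e^{-x} * (1/(x+1- 1/(x+3- 4/(x+5- ...))))
  double b = x + 1.0;
  double c = 1e300;
  double d = 1.0 / b;
  double h = d;
  for (int i = 1; i <= 120; ++i) {
    double a = -1.0 * i * i;
    b += 2.0;
    d = 1.0 / (a * d + b);
    c = b + a / c;
    double del = c * d;
    h *= del;
    if (std::fabs(del - 1.0) < 1e-15) break;
  }
  return h * std::exp(-x);
}

// Average interface transmissivity for a cone of half-angle alpha
// (degrees); closed form after Stern, identical to tav() in R.
static double tav_cpp(double alpha, double nr) {
  double n2 = nr * nr, np = n2 + 1.0, nm = n2 - 1.0;
  double a = (nr + 1.0) * (nr + 1.0) / 2.0;
  double k = -(n2 - 1.0) * (n2 - 1.0) / 4.0;
  double sa = std::sin(alpha * DEG);
  double b1 = (alpha == 90.0)
                  ? 0.0
                  : std::sqrt(std::pow(sa * sa - np / 2.0, 2) + k);
  double b2 = sa * sa - np / 2.0;
  double b = b1 - b2;
  double b3 = b * b * b, a3 = a * a * a;
  double ts = (k * k / (6.0 * b3) + k / b - b / 2.0) -
              (k * k / (6.0 * a3) + k / a - a / 2.0);
  double tp1 = -2.0 * n2 * (b - a) / (np * np);
  double tp2 = -2.0 * n2 * np * std::log(b / a) / (nm * nm);
  double tp3 = n2 * (1.0 / b - 1.0 / a) / 2.0;
  double tp4 = 16.0 * n2 * n2 * (n2 * n2 + 1.0) *
               std::log((2.0 * np * b - nm * nm) / (2.0 * np * a - nm * nm)) /
               (np * np * np * nm * nm);
  double tp5 = 16.0 * n2 * n2 * n2 *
               (1.0 / (2.0 * np * b - nm * nm) - 1.0 / (2.0 * np * a - nm * nm)) /
               (np * np * np);
  double tp = tp1 + tp2 + tp3 + tp4 + tp5;
  return (ts + tp) / (2.0 * sa * sa);
}

// [[Rcpp::export(name = ".prospect_plate_cpp")]]
List prospect_plate_cpp(double N, NumericVector k, NumericVector nr,
                        double alpha_top) {
  int n = k.size();
  NumericVector rho(n), tau(n);
  double m = N - 1.0;
  for (int i = 0; i < n; ++i) {
    double theta =
        k[i] <= 0 ? 1.0
                  : (1.0 - k[i]) * std::exp(-k[i]) +
                        k[i] * k[i] * expint_e1(k[i]);
    double talf = tav_cpp(alpha_top, nr[i]);
    double ralf = 1.0 - talf;
    double t12 = tav_cpp(90.0, nr[i]);
    double r12 = 1.0 - t12;
    double t21 = t12 / (nr[i] * nr[i]);
    double r21 = 1.0 - t21;
    double denom = 1.0 - r21 * r21 * theta * theta;
    double Ta = talf * theta * t21 / denom;
    double Ra = ralf + r21 * theta * Ta;
    double t = t12 * theta * t21 / denom;
    double r = r12 + r21 * theta * t;

    // Pile of N-1 identical layers (Stokes closed form).
    double Rsub, Tsub;
    if (m <= 0) {
      Rsub = 0.0;
      Tsub = 1.0;
    } else {
      double D2 = (1.0 + r + t) * (1.0 + r - t) * (1.0 - r + t) * (1.0 - r - t);
      if (D2 < 1e-14 || (r + t) >= 1.0 - 1e-10) {
        Tsub = t / (t + (1.0 - t) * m);
        Rsub = 1.0 - Tsub;
      } else {
        double D = std::sqrt(D2);
        double rq = r * r, tq = t * t;
        double aa = (1.0 + rq - tq + D) / (2.0 * r);
        double bb = (1.0 - rq + tq + D) / (2.0 * t);
        double bm = std::pow(bb, m);
        double b2m = bm * bm;
        double a2 = aa * aa;
        double dn = a2 * b2m - 1.0;
        Rsub = aa * (b2m - 1.0) / dn;
        Tsub = bm * (a2 - 1.0) / dn;
      }
    }
    double dnm = 1.0 - Rsub * r;
    tau[i] = Ta * Tsub / dnm;
    rho[i] = Ra + Ta * Rsub * t / dnm;
  }
  return List::create(Named("rho") = rho, Named("tau") = tau);
}

// [[Rcpp::export(name = ".foursail2_cpp")]]
List foursail2_cpp(NumericVector rho_top, NumericVector tau_top,
                   NumericVector rho_bot, NumericVector tau_bot,
                   NumericVector rsoil, NumericVector lidf1,
                   NumericVector lidf2, NumericVector centers, double lai_top,
                   double lai_bot, double hot, double tts, double tto,
                   double psi, NumericVector gx, NumericVector gw) {
  int n = rho_top.size();
  std::vector<double> r1(rho_top.begin(), rho_top.end());
  std::vector<double> t1(tau_top.begin(), tau_top.end());
  std::vector<double> r2(rho_bot.begin(), rho_bot.end());
  std::vector<double> t2(tau_bot.begin(), tau_bot.end());

  LayerGeom g1 = sail_geometry_cpp(lidf1, centers, tts, tto, psi);
  LayerGeom g2 = sail_geometry_cpp(lidf2, centers, tts, tto, psi);
  LayerOps top = sail_layer_cpp(r1, t1, lai_top, g1);
  LayerOps bot = sail_layer_cpp(r2, t2, lai_bot, g2);

  double tsstoo, sum_top, sum_bot;
  joint_hotspot_cpp(top, bot, hot, tts, tto, psi, gx, gw, tsstoo, sum_top,
                    sum_bot);

  NumericVector rso(n), rdo(n), rdd(n), rsd(n);
  for (int i = 0; i < n; ++i) {
    double rs = rsoil[i];
    // Bottom layer over soil (gap-gap term excluded; handled jointly).
    double dn2 = 1.0 - bot.rdd[i] * rs;
    double rdd_b = bot.rdd[i] + bot.tdd[i] * bot.tdd[i] * rs / dn2;
    double rsd_b = bot.rsd[i] + (bot.tss + bot.tsd[i]) * rs * bot.tdd[i] / dn2;
    double rdo_b =
        bot.rdo[i] + bot.tdd[i] * rs * (bot.tdo[i] + bot.too) / dn2;
    double rso_b = bot.rsod[i] +
                   ((bot.tss + bot.tsd[i]) * bot.tdo[i] +
                    (bot.tsd[i] + bot.tss * rs * bot.rdd[i]) * bot.too) *
                       rs / dn2;

    // Top layer over the bottom system.
    double dn = 1.0 - top.rdd[i] * rdd_b;
    double Em = (top.tsd[i] + top.rdd[i] * rsd_b * top.tss) / dn;
    double Ep = (rsd_b * top.tss + rdd_b * top.tsd[i]) / dn;
    rsd[i] = top.rsd[i] + top.tdd[i] * Ep;
    double Emd = top.tdd[i] / dn;
    double Epd = rdd_b * Emd;
    rdd[i] = top.rdd[i] + top.tdd[i] * Epd;
    rdo[i] = top.rdo[i] + top.too * rdo_b * Emd + top.tdo[i] * Epd;

    double rsos = top.w[i] * sum_top + bot.w[i] * sum_bot;
    rso[i] = rsos + tsstoo * rs + top.rsod[i] +
             top.too * top.tss * rso_b + top.too * rdo_b * Em +
             top.tdo[i] * Ep;
  }
  return List::create(Named("rso") = rso, Named("rdo") = rdo,
                      Named("rdd") = rdd, Named("rsd") = rsd);
}
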