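#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Univariate standard normal CDF.
static inline double phid(double z) {
  return 0.5 * erfc(-z * M_SQRT1_2);
}

// Genz's BVND: P(X > dh, Y > dk) for standard bivariate normal with
// correlation r.  Hybrid Drezner-Wesolowsky / Genz algorithm with
// Gauss-Legendre quadrature; absolute accuracy ~5e-16, far better than
// the 1e-7 this package requires of its CDF routine.
static double bvnd(double dh, double dk, double r) {
  static const double w1[3] = {0.1713244923791704, 0.3607615730481386,
                               0.4679139345726910};
  static const double x1[3] = {0.9324695142031521, 0.6612093864662645,
                               0.2386191860831969};
  static const double w2[6] = {0.04717533638651183, 0.1069393259953184,
                               0.1600783285433462,  0.2031674267230659,
                               0.2334925365383548,  0.2491470458134028};
  static const double x2[6] = {0.9815606342467192, 0.9041172563704749,
                               0.7699026741943047, 0.5873179542866175,
                               0.3678314989981802, 0.1252334085114689};
  static const double w3[10] = {0.01761400713915212, 0.04060142980038694,
                                0.06267204833410907, 0.08327674157670475,
                                0.1019301198172404,  0.1181945319615184,
                                0.1316886384491766,  0.1420961093183820,
                                0.1491729864726037,  0.1527533871307258};
  static const double x3[10] = {0.9931285991850949,  0.9639719272779138,
                                0.9122344282513259,  0.8391169718222188,
                                0.7463319064601508,  0.6360536807265150,
                                0.5108670019508271,  0.3737060887154195,
                                0.2277858511416451,  0.07652652113349734};
  const double twopi = 2.0 * M_PI;
  const double *w, *x;
  int lg;
  if (std::fabs(r) < 0.3) {
    lg = 3; w = w1; x = x1;
  } else if (std::fabs(r) < 0.75) {
    lg = 6; w = w2; x = x2;
  } else {
    lg = 10; w = w3; x = x3;
  }
  double h = dh, k = dk;
  double hk = h * k;
  double bvn = 0.0;
  if (std::fabs(r) < 0.925) {
    if (std::fabs(r) > 0.0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0.0) {
      k = -k;
      hk = -hk;
    }
    if (std::fabs(r) < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr1 = -(bs / xs + hk) / 2.0;
          if (asr1 > -100.0)
            bvn += a * w[i] * std::exp(asr1) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / twopi;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// [[Rcpp::export]]
NumericVector cpp_pbvnorm(NumericVector x, NumericVector y, NumericVector rho) {
  R_xlen_t n = std::max(std::max(x.size(), y.size()), rho.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    // P(X <= x, Y <= y) = P(X > -x, Y > -y)
    out[i] = bvnd(-x[i % x.size()], -y[i % y.size()], rho[i % rho.size()]);
  }
  return out;
}

// Region probabilities for one bivariate Gaussian percept distribution cut
// by two linear bounds.  Discriminants: u = x - mA*y - bA, v = y - mB*x - bB;
// (u, v) is bivariate normal and the four response regions are its four
// quadrants about the origin.  Output order: a1b1, a2b1, a1b2, a2b2.
// Returns false (degenerate) when the induced |correlation| >= 1 - 1e-12.
static bool region_probs(double mx, double my, double sx2, double sy2,
                         double rho, double mA, double bA, double mB,
                         double bB, double *out) {
  double cxy = rho * std::sqrt(sx2 * sy2);
  double mu_u = mx - mA * my - bA;
  double mu_v = my - mB * mx - bB;
  double var_u = sx2 - 2.0 * mA * cxy + mA * mA * sy2;
  double var_v = sy2 - 2.0 * mB * cxy + mB * mB * sx2;
  double cov_uv = cxy * (1.0 + mA * mB) - mB * sx2 - mA * sy2;
  if (var_u <= 0.0 || var_v <= 0.0) return false;
  double su = std::sqrt(var_u), sv = std::sqrt(var_v);
  double r = cov_uv / (su * sv);
  if (std::fabs(r) >= 1.0 - 1e-12) return false;
  double zu = mu_u / su, zv = mu_v / sv;
  double p11 = bvnd(zu, zv, r);       // P(u < 0, v < 0)
  double pu = phid(-zu);              // P(u < 0)
  double pv = phid(-zv);              // P(v < 0)
  out[0] = p11;
  out[1] = pv - p11;
  out[2] = pu - p11;
  out[3] = 1.0 - pu - pv + p11;
  for (int j = 0; j < 4; j++) {
    if (out[j] < 0.0) out[j] = 0.0;
    if (out[j] > 1.0) out[j] = 1.0;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_region_probs(NumericVector mean, NumericVector var,
                               double rho, double slope_a, double int_a,
                               double slope_b, double int_b) {
  double out[4];
  if (!region_probs(mean[0], mean[1], var[0], var[1], rho, slope_a, int_a,
                    slope_b, int_b, out))
    stop("degenerate transformed covariance: bounds (slope %g, slope %g) "
         "induce |correlation| >= 1 - 1e-12", slope_a, slope_b);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// Full GRT-wIND parameter vector, length 16 + 6K:
//   [0..5]   free means: a2b1.(x,y), a1b2.(x,y), a2b2.(x,y)  (a1b1 at (0,0))
//   [6..11]  log variances of the same three stimuli (a1b1 at (1,1))
//   [12..15] correlation transforms z, rho = 0.99*tanh(z), stimuli in order
//   then per participant p: log kappa, logit lambda, slope_a, int_a,
//                           slope_b, int_b
// counts: K x 16 matrix, row p = participant p's confusion matrix by rows
// (stimulus-major).  Effective participant variances are sx2/(kappa*lambda)
// and sy2/(kappa*(1-lambda)).
static double wind_negll(const double *th, const NumericMatrix &counts) {
  int K = counts.nrow();
  double mx[4], my[4], sx2[4], sy2[4], rho[4];
  mx[0] = 0.0; my[0] = 0.0;
  mx[1] = th[0]; my[1] = th[1];
  mx[2] = th[2]; my[2] = th[3];
  mx[3] = th[4]; my[3] = th[5];
  sx2[0] = 1.0; sy2[0] = 1.0;
  for (int s = 1; s < 4; s++) {
    sx2[s] = std::exp(th[6 + 2 * (s - 1)]);
    sy2[s] = std::exp(th[7 + 2 * (s - 1)]);
  }
  for (int s = 0; s < 4; s++) rho[s] = 0.99 * std::tanh(th[12 + s]);
  double nll = 0.0;
  for (int p = 0; p < K; p++) {
    const double *pp = th + 16 + 6 * p;
    double kappa = std::exp(pp[0]);
    double lambda = 1.0 / (1.0 + std::exp(-pp[1]));
    double ax = 1.0 / (kappa * lambda);
    double ay = 1.0 / (kappa * (1.0 - lambda));
    for (int s = 0; s < 4; s++) {
      double probs[4];
      if (!region_probs(mx[s], my[s], sx2[s] * ax, sy2[s] * ay, rho[s],
                        pp[2], pp[3], pp[4], pp[5], probs))
        return 1e10;
      for (int j = 0; j < 4; j++) {
        double r = counts(p, 4 * s + j);
        if (r > 0.0) {
          double pr = probs[j];
          if (pr < 1e-10) pr = 1e-10;
          nll -= r * std::log(pr);
        }
      }
    }
  }
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}

// Build the full vector from free parameters via map/fixed encoding:
// full[i] = free[map[i] - 1] when map[i] > 0, else fixed[i].
static void build_full(const NumericVector &free, const IntegerVector &map,
                       const NumericVector &fixed, std::vector<double> &full) {
  int n = map.size();
  for (int i = 0; i < n; i++)
    full[i] = map[i] > 0 ? free[map[i] - 1] : fixed[i];
}

// [[Rcpp::export]]
double cpp_wind_negll(NumericVector free, IntegerVector map,
                      NumericVector fixed, NumericMatrix counts) {
  std::vector<double> full(map.size());
  build_full(free, map, fixed, full);
  return wind_negll(full.data(), counts);
}

// Central-difference gradient of the mapped objective.
// [[Rcpp::export]]
NumericVector cpp_wind_negll_grad(NumericVector free, IntegerVector map,
                                  NumericVector fixed, NumericMatrix counts) {
  std::vector<double> full(map.size());
  int nf = free.size();
  NumericVector g(nf);
  NumericVector fr = clone(free);
  for (int j = 0; j < nf; j++) {
    double x0 = fr[j];
    double h = 1e-6 * std::max(1.0, std::fabs(x0));
    fr[j] = x0 + h;
    build_full(fr, map, fixed, full);
    double fp = wind_negll(full.data(), counts);
    fr[j] = x0 - h;
    build_full(fr, map, fixed, full);
    double fm = wind_negll(full.data(), counts);
    fr[j] = x0;
    g[j] = (fp - fm) / (2.0 * h);
  }
  return g;
}
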