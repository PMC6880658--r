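// Two-step maximum-likelihood polychoric / polyserial correlation.
//
// Step 1: category thresholds from the inverse-normal of cumulative marginal
// proportions. Step 2: Brent maximization of the bivariate-normal cell
// likelihood over rho in [-0.999, 0.999]. The bivariate normal CDF is Genz's
// adaptive Gauss-Legendre quadrature (absolute accuracy ~5e-16 away from
// |r| = 1), so the likelihood is smooth enough for derivative-free search.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;

static inline double phid(double z) {
  return 0.5 * erfc(-z * M_SQRT1_2);
}

// Upper-quadrant probability P(X > h, Y > k) of a standard bivariate normal
// with correlation r. Genz (2004) BVND algorithm.
static double bvnu(double h, double k, double r) {
  static const double w6[] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
  static const double x6[] = {0.9324695142031522, 0.6612093864662647,
                              0.2386191860831970};
  static const double w12[] = {0.04717533638651177, 0.1069393259953183,
                               0.1600783285433464,  0.2031674267230659,
                               0.2334925365383547,  0.2491470458134029};
  static const double x12[] = {0.9815606342467191, 0.9041172563704750,
                               0.7699026741943050, 0.5873179542866171,
                               0.3678314989981802, 0.1252334085114692};
  static const double w20[] = {0.01761400713915212, 0.04060142980038694,
                               0.06267204833410906, 0.08327674157670475,
                               0.1019301198172404,  0.1181945319615184,
                               0.1316886384491766,  0.1420961093183821,
                               0.1491729864726037,  0.1527533871307259};
  static const double x20[] = {0.9931285991850949, 0.9639719272779138,
                               0.9122344282513259, 0.8391169718222188,
                               0.7463319064601508, 0.6360536807265150,
                               0.5108670019508271, 0.3737060887154196,
                               0.2277858511416451, 0.07652652113349733};
  const double *w, *x;
  int lg;
  double ar = std::fabs(r);
  if (ar < 0.3) {
    lg = 3; w = w6; x = x6;
  } else if (ar < 0.75) {
    lg = 6; w = w12; x = x12;
  } else {
    lg = 10; w = w20; x = x20;
  }
  double hh = h, kk = k, hk = hh * kk, bvn = 0.0;
  if (ar < 0.925) {
    double hs = (hh * hh + kk * kk) / 2.0;
    double asr = std::asin(r);
    for (int i = 0; i < lg; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * TWOPI) + phid(-hh) * phid(-kk);
  } else {
    if (r < 0.0) { kk = -kk; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
      double bs = (hh - kk) * (hh - kk);
      double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(TWOPI) * phid(-b / a) * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = a * (is * x[i] + 1.0);
          xs = xs * xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            bvn += a * w[i] * std::exp(asr2) *
                   (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                    (1.0 + c * xs * (1.0 + d * xs)));
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(hh, kk));
    } else {
      bvn = -bvn;
      if (kk > hh) bvn += phid(kk) - phid(hh);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// P(X < h, Y < k)
// [[Rcpp::export(name = ".pbvnorm_cpp")]]
double pbvnorm_cpp(double h, double k, double r) {
  return bvnu(-h, -k, r);
}

// Rectangle probabilities over threshold grids a (rows), b (cols); a and b
// are the finite interior thresholds (length R-1, C-1). Fills an R x C matrix.
static void cell_probs(const std::vector<double> &a, const std::vector<double> &b,
                       double rho, std::vector<double> &P, int R, int C) {
  // grid of CDF values with -Inf/+Inf borders
  std::vector<double> G((R + 1) * (C + 1));
  for (int i = 0; i <= R; i++) {
    for (int j = 0; j <= C; j++) {
      double g;
      if (i == 0 || j == 0) g = 0.0;
      else if (i == R && j == C) g = 1.0;
      else if (i == R) g = phid(b[j - 1]);
      else if (j == C) g = phid(a[i - 1]);
      else g = bvnu(-a[i - 1], -b[j - 1], rho);
      G[i * (C + 1) + j] = g;
    }
  }
  for (int i = 0; i < R; i++)
    for (int j = 0; j < C; j++)
      P[i * C + j] = G[(i + 1) * (C + 1) + (j + 1)] - G[i * (C + 1) + (j + 1)] -
                     G[(i + 1) * (C + 1) + j] + G[i * (C + 1) + j];
}

static double table_loglik(const std::vector<double> &n,
                           const std::vector<double> &a,
                           const std::vector<double> &b, double rho, int R,
                           int C) {
  std::vector<double> P(R * C);
  cell_probs(a, b, rho, P, R, C);
  double ll = 0.0;
  for (int i = 0; i < R * C; i++) {
    if (n[i] > 0.0) {
      double p = P[i];
      if (p < 1e-300) p = 1e-300;
      ll += n[i] * std::log(p);
    }
  }
  return ll;
}

// Brent's localmin on [lo, hi] for a unimodal negated objective.
template <typename F>
static double brent_max(F f, double lo, double hi, double tol) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = -f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; iter++) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
          p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = -f(u);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}

// Thresholds from a marginal count vector (categories observed, in order).
static std::vector<double> margin_thresholds(const std::vector<double> &m) {
  double tot = 0.0;
  for (double v : m) tot += v;
  std::vector<double> t;
  double cum = 0.0;
  for (size_t i = 0; i + 1 < m.size(); i++) {
    cum += m[i];
    t.push_back(R::qnorm(cum / tot, 0.0, 1.0, 1, 0));
  }
  return t;
}

// Polychoric correlation from a contingency table of counts. Empty cells
// contribute nothing to the likelihood, so no correction is needed in
// general; only a 2x2 table with a zero cell (where the MLE diverges to
// +/-1) receives the 0.5 continuity correction in every cell. Thresholds
// always use the raw margins. Estimates are clipped at +/-0.999.
// [[Rcpp::export(name = ".polychoric_table_cpp")]]
double polychoric_table_cpp(NumericMatrix tab, double tol = 1e-6) {
  int R = tab.nrow(), C = tab.ncol();
  if (R < 2 || C < 2) stop("polychoric is undefined for a single-category variable");
  std::vector<double> n(R * C);
  bool any_zero = false;
  for (int i = 0; i < R; i++)
    for (int j = 0; j < C; j++) {
      n[i * C + j] = tab(i, j);
      if (tab(i, j) == 0.0) any_zero = true;
    }
  std::vector<double> rm(R, 0.0), cm(C, 0.0);
  for (int i = 0; i < R; i++)
    for (int j = 0; j < C; j++) {
      rm[i] += n[i * C + j];
      cm[j] += n[i * C + j];
    }
  std::vector<double> a = margin_thresholds(rm), b = margin_thresholds(cm);
  if (any_zero && R == 2 && C == 2)
    for (int i = 0; i < R * C; i++) n[i] += 0.5;
  auto obj = [&](double rho) { return table_loglik(n, a, b, rho, R, C); };
  return brent_max(obj, -0.999, 0.999, tol);
}

static void tabulate_pair(const IntegerVector &x, const IntegerVector &y,
                          std::vector<double> &tab, std::vector<int> &xl,
                          std::vector<int> &yl) {
  int n = x.size();
  int xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; i++) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  int R = xmax - xmin + 1, C = ymax - ymin + 1;
  std::vector<double> full(R * C, 0.0);
  for (int i = 0; i < n; i++) full[(x[i] - xmin) * C + (y[i] - ymin)] += 1.0;
  // drop empty rows/columns (unobserved categories carry no threshold)
  std::vector<int> rkeep, ckeep;
  for (int i = 0; i < R; i++) {
    double s = 0.0;
    for (int j = 0; j < C; j++) s += full[i * C + j];
    if (s > 0.0) rkeep.push_back(i);
  }
  for (int j = 0; j < C; j++) {
    double s = 0.0;
    for (int i = 0; i < R; i++) s += full[i * C + j];
    if (s > 0.0) ckeep.push_back(j);
  }
  tab.assign(rkeep.size() * ckeep.size(), 0.0);
  for (size_t i = 0; i < rkeep.size(); i++)
    for (size_t j = 0; j < ckeep.size(); j++)
      tab[i * ckeep.size() + j] = full[rkeep[i] * C + ckeep[j]];
  xl.assign(1, (int)rkeep.size());
  yl.assign(1, (int)ckeep.size());
}

static double polychoric_pair(const IntegerVector &x, const IntegerVector &y,
                              double tol) {
  std::vector<double> tab;
  std::vector<int> xl, yl;
  tabulate_pair(x, y, tab, xl, yl);
  int R = xl[0], C = yl[0];
  if (R < 2 || C < 2) stop("polychoric is undefined for a single-category variable");
  NumericMatrix m(R, C);
  for (int i = 0; i < R; i++)
    for (int j = 0; j < C; j++) m(i, j) = tab[i * C + j];
  return polychoric_table_cpp(m, tol);
}

// [[Rcpp::export(name = ".polychoric_vec_cpp")]]
double polychoric_vec_cpp(IntegerVector x, IntegerVector y, double tol = 1e-6) {
  return polychoric_pair(x, y, tol);
}

// All pairwise polychoric correlations of an integer score matrix.
// [[Rcpp::export(name = ".polychoric_matrix_cpp")]]
NumericMatrix polychoric_matrix_cpp(IntegerMatrix data, double tol = 1e-6) {
  int p = data.ncol();
  NumericMatrix out(p, p);
  out.fill_diag(1.0);
  for (int i = 0; i < p; i++) {
    IntegerVector xi = data(_, i);
    for (int j = i + 1; j < p; j++) {
      IntegerVector yj = data(_, j);
      double r = polychoric_pair(xi, yj, tol);
      out(i, j) = r;
      out(j, i) = r;
    }
  }
  return out;
}

// Polyserial correlation: ordinal x against continuous y (two-step; y is
// standardized, thresholds from the x margins, rho by Brent on the
// conditional ordinal likelihood given y).
// [[Rcpp::export(name = ".polyserial_vec_cpp")]]
double polyserial_vec_cpp(IntegerVector x, NumericVector y, double tol = 1e-6) {
  int n = x.size();
  // relabel x to 0..K-1 over observed categories
  int xmin = x[0], xmax = x[0];
  for (int i = 1; i < n; i++) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
  }
  int K = xmax - xmin + 1;
  std::vector<double> cnt(K, 0.0);
  for (int i = 0; i < n; i++) cnt[x[i] - xmin] += 1.0;
  std::vector<int> code(K, -1);
  std::vector<double> obs;
  int k = 0;
  for (int c = 0; c < K; c++)
    if (cnt[c] > 0.0) { code[c] = k++; obs.push_back(cnt[c]); }
  if (k < 2) stop("polyserial is undefined for a single-category variable");
  std::vector<double> tau = margin_thresholds(obs);
  // standardize y
  double my = 0.0, sy = 0.0;
  for (int i = 0; i < n; i++) my += y[i];
  my /= n;
  for (int i = 0; i < n; i++) sy += (y[i] - my) * (y[i] - my);
  sy = std::sqrt(sy / (n - 1));
  if (sy <= 0.0) stop("polyserial is undefined for a constant continuous variable");
  std::vector<double> z(n);
  std::vector<int> xc(n);
  for (int i = 0; i < n; i++) {
    z[i] = (y[i] - my) / sy;
    xc[i] = code[x[i] - xmin];
  }
  auto obj = [&](double rho) {
    double s = std::sqrt(1.0 - rho * rho);
    double ll = 0.0;
    for (int i = 0; i < n; i++) {
      int c = xc[i];
      double hi = (c == k - 1) ? 1.0 : phid((tau[c] - rho * z[i]) / s);
      double lo = (c == 0) ? 0.0 : phid((tau[c - 1] - rho * z[i]) / s);
      double p = hi - lo;
      if (p < 1e-300) p = 1e-300;
      ll += std::log(p);
    }
    return ll;
  };
  return brent_max(obj, -0.999, 0.999, tol);
}
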