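// Polya-Gamma PG(1, z) sampler, Devroye-type alternating-series rejection
// (Polson, Scott & Windle style). Uses R's RNG so draws are reproducible
// under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64; // series switch point, ~2/pi
static const double PISQ = M_PI * M_PI;

// piecewise coefficients a_n(x) of the Jacobi density alternating series
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * PISQ * x / 2.0);
  }
  // left-tail (inverse-Gaussian-like) representation
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
         std::exp(-2.0 * np5 * np5 / x);
}

// P(choose the truncated-exponential right tail) for the proposal mixture
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = 0.125 * PISQ + 0.5 * z * z;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double z) {
  z = std::fabs(z);
  double t = TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) { // mu > t: rejection from truncated inverse-chi^2
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(muy * (4.0 + muy));
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one PG(1, z) draw; PG(1, z) = 0.25 * J*(1, z/2) with J* the tilted Jacobi
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double fz = 0.125 * PISQ + 0.5 * z * z;
  for (;;) {
    double x;
    if (unif_rand() < mass_texpon(z)) {
      x = TRUNC + exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    // squeeze/accept by the alternating series
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break; // reject, start over
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_devroye")]]
NumericVector rpg_devroye(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
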