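#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first-passage simulation for the single-particle model
// family (DDM, full-DDM via per-trial parameter vectors, Ornstein-Uhlenbeck,
// Levy flight, collapsing Weibull / linear bounds).
//
// Geometry: symmetric decision boundaries at +/- B(t) with B(0) = a; the
// particle starts at x0 = (2 w - 1) * a.  Exit through the upper boundary is
// coded +1, through the lower -1.  Trials still inside the decision region
// at t_max are censored and carry rt = -1.  All draws go through R's RNG so
// set.seed() governs reproducibility; `noise_sign` = -1 replays the mirrored
// noise path (common-random-number mirror tests).

// Marsaglia polar Gaussian draws on top of R's uniform stream: noticeably
// faster than the inversion sampler behind norm_rand() in the tight
// Euler-Maruyama loops below. The spare is reset at every entry point so a
// given set.seed() always reproduces the same paths.
static double polar_spare = 0.0;
static bool polar_have = false;

static inline double fast_norm() {
  if (polar_have) { polar_have = false; return polar_spare; }
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double f = sqrt(-2.0 * log(s) / s);
  polar_spare = v * f;
  polar_have = true;
  return u * f;
}

// Chambers-Mallows-Stuck draw from the symmetric alpha-stable law
// L(alpha, 0, 1, 0); exact for all alpha in (0, 2], N(0, 2) at alpha = 2.
static inline double stable_draw(double alpha) {
  double u = M_PI * (unif_rand() - 0.5); // Uniform(-pi/2, pi/2)
  double w = exp_rand();                 // Exp(1)
  double t1 = sin(alpha * u) / pow(cos(u), 1.0 / alpha);
  double t2 = pow(cos(u - alpha * u) / w, (1.0 - alpha) / alpha);
  return t1 * t2; // at alpha = 2 this reduces to 2 sin(u) sqrt(w) ~ N(0, 2)
}

static inline double bound_height(double t, double a, int bound_type,
                                  double p1, double p2, int weibull_alt) {
  switch (bound_type) {
  case 1: // Weibull collapse: a * exp(-t^beta / alpha) (p1 = alpha, p2 = beta)
    if (weibull_alt)
      return a * exp(-pow(t / p2, p1)); // alternative reading a*exp(-(t/beta)^alpha)
    return a * exp(-pow(t, p2) / p1);
  case 2: // linear collapse: a - t * tan(angle) (p1 = angle)
    return a - t * tan(p1);
  default:
    return a;
  }
}

// [[Rcpp::export]]
List sim_single_cpp(int n_trials, NumericVector v, double a, NumericVector w,
                    NumericVector tau, double g, int noise_type,
                    double alpha_stable, int bound_type, double bp1,
                    double bp2, int weibull_alt, double dt, double t_max,
                    double noise_sign) {
  NumericVector rt(n_trials);
  IntegerVector choice(n_trials);
  polar_have = false; // seed-reproducible paths
  const double sdt = sqrt(dt);
  const double levy_scale = pow(dt, 1.0 / alpha_stable);
  const bool use_stable = noise_type == 1; // 0: Gaussian dW, 1: alpha-stable dL

  for (int i = 0; i < n_trials; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double wi = w[w.size() == 1 ? 0 : i];
    double ti = tau[tau.size() == 1 ? 0 : i];
    double x = (2.0 * wi - 1.0) * a;
    double t = 0.0;
    int c = NA_INTEGER;
    double fpt = -1.0;

    // immediate absorption if the start already sits on/outside the bound
    double b0 = bound_height(0.0, a, bound_type, bp1, bp2, weibull_alt);
    if (b0 <= 0.0 || x >= b0 || x <= -b0) {
      fpt = 0.0;
      c = (x >= 0.0) ? 1 : -1;
    } else {
      while (t < t_max) {
        double dx;
        if (use_stable) {
          dx = vi * dt + levy_scale * noise_sign * stable_draw(alpha_stable);
        } else {
          dx = (vi + g * x) * dt + sdt * noise_sign * fast_norm();
        }
        x += dx;
        t += dt;
        double b = bound_height(t, a, bound_type, bp1, bp2, weibull_alt);
        if (b <= 0.0) { // bounds have met: forced absorption by particle sign
          fpt = t;
          c = (x >= 0.0) ? 1 : -1;
          break;
        }
        if (x >= b) { fpt = t; c = 1; break; }
        if (x <= -b) { fpt = t; c = -1; break; }
      }
    }
    if (fpt < 0.0) { // censored at t_max
      rt[i] = -1.0;
      choice[i] = NA_INTEGER;
    } else {
      rt[i] = fpt + ti;
      choice[i] = c;
    }
  }
  return List::create(_["rt"] = rt, _["choice"] = choice);
}

// N-particle race toward a shared constant upper bound a; particle i starts
// at w_i * a and drifts at v_i under unit Gaussian noise.  The first particle
// to reach a determines the (0-based) choice; ties at the same step go to the
// lowest index.
// [[Rcpp::export]]
List sim_race_cpp(int n_trials, NumericVector v, double a, NumericVector w,
                  double ndt, double dt, double t_max) {
  int n_acc = v.size();
  NumericVector rt(n_trials);
  IntegerVector choice(n_trials);
  polar_have = false; // seed-reproducible paths
  const double sdt = sqrt(dt);
  std::vector<double> x(n_acc);

  for (int i = 0; i < n_trials; ++i) {
    for (int j = 0; j < n_acc; ++j) x[j] = w[j] * a;
    double t = 0.0;
    int c = -1;
    double fpt = -1.0;
    for (int j = 0; j < n_acc; ++j)
      if (x[j] >= a) { c = j; fpt = 0.0; break; }
    while (fpt < 0.0 && t < t_max) {
      for (int j = 0; j < n_acc; ++j)
        x[j] += v[j] * dt + sdt * fast_norm();
      t += dt;
      for (int j = 0; j < n_acc; ++j)
        if (x[j] >= a) { c = j; fpt = t; break; }
    }
    if (fpt < 0.0) {
      rt[i] = -1.0;
      choice[i] = NA_INTEGER;
    } else {
      rt[i] = fpt + ndt;
      choice[i] = c;
    }
  }
  return List::create(_["rt"] = rt, _["choice"] = choice);
}

// [[Rcpp::export]]
NumericVector sample_alpha_stable_cpp(int n, double alpha) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = stable_draw(alpha);
  return out;
}
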