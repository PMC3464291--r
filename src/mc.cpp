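// Greedy Monte Carlo engine for the two-morphogen hair-patterning model.
// The inner loop evaluates O(N) exact cone geodesics per proposal, so it
// lives in C++; all randomness is drawn from R's RNG (unif_rand), which
// keeps runs reproducible from set.seed() on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  // domain
  double L, h0, h1, apex, slant, sinA;
  // params
  double c1, a_star, lamB, lamT, srange, lamM, msat, vsign;
  // cached normalization of the direction-morphogen profile
  double raw0, raw05;

  double raw(double z) const {
    return std::exp(-z / lamM) + std::exp(-(1.0 - z) / lamM);
  }
  // normalized, saturating response of the direction morphogen
  double m_resp(double u) const {
    double xm = 1.0 - std::fabs(u);           // distance from medial line
    double norm = (raw(xm) - raw05) / (raw0 - raw05);
    double m = norm / msat;
    return m > 1.0 ? 1.0 : m;
  }
  double angle_cost(double theta, double u) const {
    double m = m_resp(u);
    bool v = (theta > 0.0 && theta < 180.0) &&
             ((u > 0.0 && vsign > 0.0) || (u < 0.0 && vsign < 0.0));
    double th = theta * M_PI / 180.0;
    double bracket = m * std::fabs(std::sin(th)) +
                     (1.0 - m) * std::fabs(std::cos(th));
    return c1 * (1.0 - (v ? a_star : 0.0)) * bracket;
  }
  double geo(double x1, double u1, double x2, double u2) const {
    double r1 = (apex - x1) * slant, r2 = (apex - x2) * slant;
    double du = std::fabs(u1 - u2);
    du -= 2.0 * std::floor(du * 0.5);
    if (du > 1.0) du = 2.0 - du;
    double s = std::sin(0.5 * M_PI * sinA * du);
    double d = r1 - r2;
    return std::sqrt(d * d + 4.0 * r1 * r2 * s * s);
  }
  double lam_mid(double x1, double x2) const {
    return lamB + (lamT - lamB) * (0.5 * (x1 + x2) / L);
  }
  double pair_f(double x1, double u1, double x2, double u2) const {
    double l = lam_mid(x1, x2);
    double r = geo(x1, u1, x2, u2);
    return r < srange * l ? std::exp(-r / l) : 0.0;
  }
  // hairs exactly on a restriction line belong to neither half
  bool ventral(double u) const {
    return vsign > 0.0 ? (u > 0.0 && u < 1.0) : (u < 0.0);
  }
  double vweight(double u) const {
    return ventral(u) ? 1.0 - a_star : 1.0;
  }
  // axial position with density proportional to the local sheet height
  double sample_axial(double q) const {
    double c = (h1 - h0) / L;
    double I = L * 0.5 * (h0 + h1);
    if (std::fabs(c) < 1e-12) return q * L;
    double x = (-h0 + std::sqrt(h0 * h0 + 2.0 * c * q * I)) / c;
    if (x < 0.0) x = 0.0;
    if (x > L) x = L;
    return x;
  }
};

double wrap_theta(double t) {
  double w = t - 360.0 * std::floor(t / 360.0);   // [0, 360)
  if (w > 180.0) w -= 360.0;                      // (-180, 180]
  return w;
}

Model make_model(List domain, List params) {
  Model m;
  m.L = as<double>(domain["axial_length"]);
  m.h0 = as<double>(domain["base_height_flat"]);
  m.h1 = as<double>(domain["tip_height_flat"]);
  m.apex = as<double>(domain["apex_axial"]);
  m.slant = as<double>(domain["slant_factor"]);
  m.sinA = as<double>(domain["sin_half_angle"]);
  m.c1 = as<double>(params["c1"]);
  m.a_star = as<double>(params["a_star"]);
  m.lamB = as<double>(params["lambda_base"]);
  m.lamT = as<double>(params["lambda_tip"]);
  m.srange = as<double>(params["spacing_range"]);
  m.lamM = as<double>(params["lambda_m"]);
  m.msat = as<double>(params["m_saturation"]);
  m.vsign = as<double>(params["ventral_sign"]);
  m.raw0 = m.raw(0.0);
  m.raw05 = m.raw(0.5);
  return m;
}

double full_cost(const Model& m, const std::vector<double>& xs,
                 const std::vector<double>& us,
                 const std::vector<double>& th) {
  int n = (int)xs.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    e += m.angle_cost(th[i], us[i]);
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      s += m.pair_f(xs[i], us[i], xs[j], us[j]);
    }
    e += m.vweight(us[i]) * s;
  }
  return e;
}

} // namespace

// [[Rcpp::export(name = ".mc_run")]]
List mc_run(NumericVector axial, NumericVector circum, NumericVector theta,
            List domain, List params, double p_iterations, int log_stride) {
  Model m = make_model(domain, params);
  int n = axial.size();
  std::vector<double> xs(axial.begin(), axial.end());
  std::vector<double> us(circum.begin(), circum.end());
  std::vector<double> th(theta.begin(), theta.end());

  double e = full_cost(m, xs, us, th);
  double e_init = e;
  long long P = (long long)p_iterations;
  long long accepted = 0;

  std::vector<double> trace_t, trace_e;
  trace_t.reserve((size_t)(P / log_stride) + 2);
  trace_e.reserve((size_t)(P / log_stride) + 2);
  trace_t.push_back(0.0); trace_e.push_back(e);

  RNGScope scope;
  for (long long t = 1; t <= P && n > 0; ++t) {
    int idx = (int)(unif_rand() * n);
    if (idx >= n) idx = n - 1;
    double nx = m.sample_axial(unif_rand());
    double nu = unif_rand() * 2.0 - 1.0;
    double nth = wrap_theta(th[idx] + (unif_rand() * 360.0 - 180.0));

    double d_ang = m.angle_cost(nth, nu) - m.angle_cost(th[idx], us[idx]);
    // one pass over the neighbours: the mover's own (ventrally weighted)
    // spacing sums plus each neighbour's weighted change in its pair term.
    // Pairs whose slant separation already exceeds the largest possible
    // interaction range contribute nothing and are skipped cheaply.
    double rho_old = (m.apex - xs[idx]) * m.slant;
    double rho_new = (m.apex - nx) * m.slant;
    double max_range = m.srange * (m.lamB > m.lamT ? m.lamB : m.lamT);
    double s_old = 0.0, s_new = 0.0, nb = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == idx) continue;
      double rho_j = (m.apex - xs[j]) * m.slant;
      double f0 = (std::fabs(rho_old - rho_j) < max_range)
                      ? m.pair_f(xs[idx], us[idx], xs[j], us[j]) : 0.0;
      double f1 = (std::fabs(rho_new - rho_j) < max_range)
                      ? m.pair_f(nx, nu, xs[j], us[j]) : 0.0;
      if (f0 == 0.0 && f1 == 0.0) continue;
      s_old += f0; s_new += f1;
      nb += m.vweight(us[j]) * (f1 - f0);
    }
    double de = d_ang + m.vweight(nu) * s_new - m.vweight(us[idx]) * s_old + nb;
    if (de < 0.0) {                 // strictly greedy: ties rejected
      xs[idx] = nx; us[idx] = nu; th[idx] = nth;
      e += de;
      ++accepted;
    }
    if (t % log_stride == 0) {
      trace_t.push_back((double)t);
      trace_e.push_back(e);
    }
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  if (P > 0 && (P % log_stride) != 0) {
    trace_t.push_back((double)P);
    trace_e.push_back(e);
  }

  return List::create(
    _["axial"] = NumericVector(xs.begin(), xs.end()),
    _["circum"] = NumericVector(us.begin(), us.end()),
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["e_initial"] = e_init,
    _["e_final"] = e,
    _["e_final_recomputed"] = full_cost(m, xs, us, th),
    _["accepted"] = (double)accepted,
    _["trace_proposal"] = NumericVector(trace_t.begin(), trace_t.end()),
    _["trace_cost"] = NumericVector(trace_e.begin(), trace_e.end()));
}
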