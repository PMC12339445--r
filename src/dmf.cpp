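#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoidal-like transfer function H(x) = (a*x - b) / (1 - exp(-d*(a*x - b)))
// with the removable singularity at a*x = b handled by the series
// u/(1 - e^{-du}) = (1/d) * (1 + v/2 + v^2/12 - v^4/720 + ...), v = d*u.
static inline double transfer(double x, double a, double b, double d) {
  double u = a * x - b;
  double v = d * u;
  if (std::fabs(v) < 1e-4) {
    return (1.0 + v / 2.0 + v * v / 12.0 - v * v * v * v / 720.0) / d;
  }
  return u / (-std::expm1(-v));
}

// Gaussian draws via Box-Muller on R's uniform stream: deterministic given
// set.seed() and considerably faster than the inversion method when tens of
// millions of increments are needed per simulation.
struct GaussStream {
  bool has = false;
  double cached = 0.0;
  double next() {
    if (has) {
      has = false;
      return cached;
    }
    double u1 = unif_rand();
    if (u1 < 1e-300) u1 = 1e-300;
    double u2 = unif_rand();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    cached = r * std::sin(th);
    has = true;
    return r * std::cos(th);
  }
};

// [[Rcpp::export]]
NumericVector transfer_cpp(NumericVector x, double a, double b, double d) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = transfer(x[i], a, b, d);
  return out;
}

// Balloon-Windkessel hemodynamic states per region: vasodilatory signal s,
// inflow f, volume v, deoxyhemoglobin q. Baseline (0,1,1,1). Driven by z.
struct HemoState {
  std::vector<double> s, f, v, q;
  void init(int n) {
    s.assign(n, 0.0);
    f.assign(n, 1.0);
    v.assign(n, 1.0);
    q.assign(n, 1.0);
  }
};

static inline void hemo_step(HemoState &h, const double *z, int n, double dt,
                             double kappa, double gammaf, double tauh,
                             double alpha, double rho) {
  double ia = 1.0 / alpha;
  for (int i = 0; i < n; ++i) {
    double fi = h.f[i] > 1e-9 ? h.f[i] : 1e-9;
    double vi = h.v[i] > 1e-9 ? h.v[i] : 1e-9;
    double E = 1.0 - std::pow(1.0 - rho, 1.0 / fi);
    double vout = std::pow(vi, ia);
    double ds = z[i] - kappa * h.s[i] - gammaf * (fi - 1.0);
    double df = h.s[i];
    double dv = (fi - vout) / tauh;
    double dq = (fi * E / rho - vout * h.q[i] / vi) / tauh;
    h.s[i] += dt * ds;
    h.f[i] += dt * df;
    h.v[i] += dt * dv;
    h.q[i] += dt * dq;
  }
}

static inline double bold_readout(double v, double q, double V0, double k1,
                                  double k2, double k3) {
  return V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
}

// Standalone Balloon-Windkessel transform of a T x N gating time course
// sampled at dt, emitting BOLD every tr seconds.
// [[Rcpp::export]]
NumericMatrix balloon_windkessel_cpp(NumericMatrix SE, double dt, double tr,
                                     double kappa, double gammaf, double tauh,
                                     double alpha, double rho, double V0,
                                     double k1, double k2, double k3) {
  int T = SE.nrow(), n = SE.ncol();
  int stride = (int)std::lround(tr / dt);
  if (stride < 1) stride = 1;
  int Tb = T / stride;
  NumericMatrix bold(Tb, n);
  HemoState h;
  h.init(n);
  std::vector<double> z(n);
  int row = 0;
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n; ++i) z[i] = SE(t, i);
    hemo_step(h, z.data(), n, dt, kappa, gammaf, tauh, alpha, rho);
    if ((t + 1) % stride == 0 && row < Tb) {
      for (int i = 0; i < n; ++i)
        bold(row, i) = bold_readout(h.v[i], h.q[i], V0, k1, k2, k3);
      ++row;
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(h.v[i]) || !std::isfinite(h.q[i]))
        stop("hemodynamic integration diverged at step %d", t + 1);
    }
  }
  return bold;
}

// Euler-Maruyama integration of the reduced Wong-Wang E/I model on a
// connectome, with optional per-pair conduction delays (ring buffer) and an
// optional per-region override of the global coupling G. The hemodynamic
// states are integrated in lockstep so BOLD is produced without storing the
// full gating history when store_states is false.
//
// Noise uses R's RNG (norm_rand), so set.seed() in R gives bit-identical
// trajectories. Draw order per step: N excitatory, then N inhibitory normals.
// [[Rcpp::export]]
List integrate_dmf_cpp(NumericMatrix C, IntegerMatrix delay_steps,
                       NumericVector Gvec, double JN, double Ji, double wp,
                       double aE, double bE, double dE, double aI, double bI,
                       double dI, double tauE, double tauI, double gammaE,
                       double sigma, double I0, double wE, double wI,
                       double dt, int n_steps, int burn_steps, int bold_stride,
                       NumericVector init_SE, NumericVector init_SI,
                       double kappa, double gammaf, double tauh, double alpha,
                       double rho, double V0, double k1, double k2, double k3,
                       bool store_states, int state_stride) {
  int n = C.nrow();
  int max_delay = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (delay_steps(i, j) > max_delay) max_delay = delay_steps(i, j);
  int buf_len = max_delay + 1;

  // ring buffer of S_E history; column t mod buf_len
  std::vector<double> hist((size_t)buf_len * n);
  std::vector<double> SE(init_SE.begin(), init_SE.end());
  std::vector<double> SI(init_SI.begin(), init_SI.end());
  for (int t = 0; t < buf_len; ++t)
    for (int i = 0; i < n; ++i) hist[(size_t)t * n + i] = SE[i];

  bool has_delay = max_delay > 0;
  double sq = sigma * std::sqrt(dt);

  HemoState h;
  h.init(n);

  int keep_steps = n_steps - burn_steps;
  int Tb = keep_steps / bold_stride;
  NumericMatrix bold(Tb > 0 ? Tb : 0, n);
  int Ts = store_states ? (keep_steps + state_stride - 1) / state_stride : 0;
  NumericMatrix SE_out(Ts, n), SI_out(Ts, n), rE_out(Ts, n);

  std::vector<double> IE(n), II(n), rE(n), rI(n), coupling(n);
  RNGScope scope;
  GaussStream gauss;

  int bold_row = 0, state_row = 0, kept = 0;
  for (int t = 0; t < n_steps; ++t) {
    int cur = t % buf_len;
    // long-range input from lagged gating
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      if (has_delay) {
        for (int j = 0; j < n; ++j) {
          double c = C(i, j);
          if (c != 0.0) {
            int lag = delay_steps(i, j);
            int idx = cur - lag;
            if (idx < 0) idx += buf_len;
            acc += c * hist[(size_t)idx * n + j];
          }
        }
      } else {
        for (int j = 0; j < n; ++j) acc += C(i, j) * SE[j];
      }
      coupling[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      IE[i] = wE * I0 + wp * JN * SE[i] + Gvec[i] * JN * coupling[i] -
              Ji * SI[i];
      II[i] = wI * I0 + JN * SE[i] - SI[i];
      rE[i] = transfer(IE[i], aE, bE, dE);
      rI[i] = transfer(II[i], aI, bI, dI);
    }
    // gating update, independent Gaussian increments per population & region
    for (int i = 0; i < n; ++i) {
      double noise = sigma > 0.0 ? sq * gauss.next() : 0.0;
      SE[i] += dt * (-SE[i] / tauE + (1.0 - SE[i]) * gammaE * rE[i]) + noise;
      if (SE[i] < 0.0) SE[i] = 0.0;
      if (SE[i] > 1.0) SE[i] = 1.0;
    }
    for (int i = 0; i < n; ++i) {
      double noise = sigma > 0.0 ? sq * gauss.next() : 0.0;
      SI[i] += dt * (-SI[i] / tauI + rI[i]) + noise;
      if (SI[i] < 0.0) SI[i] = 0.0;
      if (SI[i] > 1.0) SI[i] = 1.0;
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(SE[i]) || !std::isfinite(SI[i]))
        stop("integration diverged at step %d", t + 1);
    }
    int nxt = (t + 1) % buf_len;
    for (int i = 0; i < n; ++i) hist[(size_t)nxt * n + i] = SE[i];

    // hemodynamics run throughout so BOLD is equilibrated when sampling starts
    hemo_step(h, SE.data(), n, dt, kappa, gammaf, tauh, alpha, rho);
    if (t >= burn_steps) {
      if (store_states && kept % state_stride == 0 && state_row < Ts) {
        for (int i = 0; i < n; ++i) {
          SE_out(state_row, i) = SE[i];
          SI_out(state_row, i) = SI[i];
          rE_out(state_row, i) = rE[i];
        }
        ++state_row;
      }
      ++kept;
      if (kept % bold_stride == 0 && bold_row < Tb) {
        for (int i = 0; i < n; ++i)
          bold(bold_row, i) = bold_readout(h.v[i], h.q[i], V0, k1, k2, k3);
        ++bold_row;
      }
    }
  }
  return List::create(_["bold"] = bold, _["S_E"] = SE_out, _["S_I"] = SI_out,
                      _["r_E"] = rE_out,
                      _["terminal_S_E"] = NumericVector(SE.begin(), SE.end()),
                      _["terminal_S_I"] = NumericVector(SI.begin(), SI.end()));
}
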