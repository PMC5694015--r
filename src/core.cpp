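// Integration core for the marginal-zone ring model.
//
// State layout: N x 4 matrix, columns B, V, FB, FV.
// Topology: closed ring, optionally cut into sealed arcs. A cut at boundary b
// (0-based, b in 0..N-1) severs the edge between cell b-1 and cell b, so a cut
// at 0 separates cell N-1 from cell 0. Perceived signals are windowed means
// truncated at cuts; the mean is over the cells actually available.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double xpow(double x, double n, int ni, bool is_int) {
  if (!is_int) return std::pow(x, n);
  double r = 1.0;
  int m = ni;
  while (m) { if (m & 1) r *= x; x *= x; m >>= 1; }
  return r;
}

static inline double hillA(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return xn / (Kn + xn);
}

struct Pars {
  int N, r;
  double n, aB, aV, bB, bV, dF, dB, dV, KBB, KVB, KVV, Klo, Khi, cBV;
  // precomputed K^n and exponent fast path
  double KBBn, KVBn, KVVn, Klon, Khin;
  int ni;
  bool n_int;
};

static Pars unpack(const List& par) {
  Pars p;
  p.N   = as<int>(par["n_cells"]);
  p.r   = as<int>(par["coupling_radius"]);
  p.n   = as<double>(par["hill_exponent"]);
  p.aB  = as<double>(par["alpha_B"]);
  p.aV  = as<double>(par["alpha_V"]);
  p.bB  = as<double>(par["beta_B"]);
  p.bV  = as<double>(par["beta_V"]);
  p.dF  = as<double>(par["delta_F"]);
  p.dB  = as<double>(par["delta_B"]);
  p.dV  = as<double>(par["delta_V"]);
  p.KBB = as<double>(par["K_BB"]);
  p.KVB = as<double>(par["K_VB"]);
  p.KVV = as<double>(par["K_VV"]);
  p.Klo = as<double>(par["K_lo"]);
  p.Khi = as<double>(par["K_hi"]);
  p.cBV = as<double>(par["c_BV"]);
  p.ni = (int)std::lround(p.n);
  p.n_int = std::fabs(p.n - p.ni) < 1e-12 && p.ni >= 1 && p.ni <= 64;
  p.KBBn = std::pow(p.KBB, p.n);
  p.KVBn = std::pow(p.KVB, p.n);
  p.KVVn = std::pow(p.KVV, p.n);
  p.Klon = std::pow(p.Klo, p.n);
  p.Khin = std::pow(p.Khi, p.n);
  return p;
}

// Window reach of every cell: how many steps left/right before hitting a cut
// (at most r). cutbefore[i] is true when the edge between cell i-1 and cell i
// is severed.
static void window_reach(int N, int r, const std::vector<bool>& cutbefore,
                         std::vector<int>& left, std::vector<int>& right) {
  left.assign(N, 0);
  right.assign(N, 0);
  for (int i = 0; i < N; ++i) {
    int pos = i;
    for (int l = 0; l < r; ++l) {
      if (cutbefore[pos]) break;
      pos = (pos - 1 + N) % N;
      left[i]++;
    }
    pos = i;
    for (int l = 0; l < r; ++l) {
      int nxt = (pos + 1) % N;
      if (cutbefore[nxt]) break;
      pos = nxt;
      right[i]++;
    }
  }
}

static void perceived(const std::vector<double>& x, int N,
                      const std::vector<int>& left, const std::vector<int>& right,
                      std::vector<double>& S) {
  for (int i = 0; i < N; ++i) {
    double s = x[i];
    int cnt = 1;
    int pos = i;
    for (int l = 0; l < left[i]; ++l) { pos = (pos - 1 + N) % N; s += x[pos]; cnt++; }
    pos = i;
    for (int l = 0; l < right[i]; ++l) { pos = (pos + 1) % N; s += x[pos]; cnt++; }
    S[i] = s / cnt;
  }
}

// Right-hand side. y is 4N (column-major: B, V, FB, FV blocks).
static void rhs_eval(const std::vector<double>& y, const Pars& p,
                     const std::vector<int>& left, const std::vector<int>& right,
                     const std::vector<double>& srcB, const std::vector<double>& srcV,
                     const std::vector<double>& mFB, const std::vector<double>& mFV,
                     std::vector<double>& dy,
                     std::vector<double>& SB, std::vector<double>& SV,
                     std::vector<double>& tmpB, std::vector<double>& tmpV) {
  const int N = p.N;
  for (int i = 0; i < N; ++i) { tmpB[i] = y[i]; tmpV[i] = y[N + i]; }
  perceived(tmpB, N, left, right, SB);
  perceived(tmpV, N, left, right, SV);
  for (int i = 0; i < N; ++i) {
    double B = y[i], V = y[N + i], FB = y[2 * N + i], FV = y[3 * N + i];
    // one power per perceived signal; Hill fractions reuse precomputed K^n
    double SBn = SB[i] > 0.0 ? xpow(SB[i], p.n, p.ni, p.n_int) : 0.0;
    double SVn = SV[i] > 0.0 ? xpow(SV[i], p.n, p.ni, p.n_int) : 0.0;
    double hBB = SBn / (p.KBBn + SBn);
    double hVBi = p.KVBn / (p.KVBn + SVn);
    double hVV = SVn / (p.KVVn + SVn);
    double hHi = p.Khin / (p.Khin + SBn);
    double hLo = SBn / (p.Klon + SBn);
    double prodFB = p.aB * hBB * hVBi * mFB[i];
    double prodFV = p.aV * hHi * (hVV + p.cBV * hLo) * mFV[i];
    dy[i]         = p.bB * FB - p.dB * B + srcB[i];
    dy[N + i]     = p.bV * FV - p.dV * V + srcV[i];
    dy[2 * N + i] = prodFB - p.dF * FB;
    dy[3 * N + i] = prodFV - p.dF * FV;
  }
}

static void fill_sources(double t, const NumericMatrix& ev, const List& ev_cells,
                         int N, std::vector<double>& srcB, std::vector<double>& srcV,
                         std::vector<double>& mFB, std::vector<double>& mFV) {
  std::fill(srcB.begin(), srcB.end(), 0.0);
  std::fill(srcV.begin(), srcV.end(), 0.0);
  std::fill(mFB.begin(), mFB.end(), 1.0);
  std::fill(mFV.begin(), mFV.end(), 1.0);
  for (int e = 0; e < ev.nrow(); ++e) {
    if (t < ev(e, 1) || t >= ev(e, 2)) continue;
    int type = (int)ev(e, 0);
    double s = ev(e, 3);
    IntegerVector cells = ev_cells[e];
    for (int j = 0; j < cells.size(); ++j) {
      int c = cells[j];
      if (type == 0) srcB[c] += s;
      else if (type == 1) srcV[c] += s;
      else if (type == 2) mFB[c] *= (1.0 - s);
      else if (type == 3) mFV[c] *= (1.0 - s);
    }
  }
}

// [[Rcpp::export(name = ".rhs_core")]]
NumericMatrix rhs_core(NumericMatrix state, List par, IntegerVector cuts,
                       NumericVector srcB_in, NumericVector srcV_in,
                       NumericVector multFB_in, NumericVector multFV_in) {
  Pars p = unpack(par);
  const int N = state.nrow();
  if (N != p.N) stop("state has %d cells but parameters say n_cells = %d", N, p.N);
  std::vector<bool> cutbefore(N, false);
  for (int i = 0; i < cuts.size(); ++i) cutbefore[cuts[i]] = true;
  std::vector<int> left, right;
  window_reach(N, p.r, cutbefore, left, right);
  std::vector<double> y(4 * N), dy(4 * N), SB(N), SV(N), tB(N), tV(N);
  std::vector<double> srcB(srcB_in.begin(), srcB_in.end());
  std::vector<double> srcV(srcV_in.begin(), srcV_in.end());
  std::vector<double> mFB(multFB_in.begin(), multFB_in.end());
  std::vector<double> mFV(multFV_in.begin(), multFV_in.end());
  for (int c = 0; c < 4; ++c)
    for (int i = 0; i < N; ++i) y[c * N + i] = state(i, c);
  rhs_eval(y, p, left, right, srcB, srcV, mFB, mFV, dy, SB, SV, tB, tV);
  NumericMatrix out(N, 4);
  for (int c = 0; c < 4; ++c)
    for (int i = 0; i < N; ++i) out(i, c) = dy[c * N + i];
  colnames(out) = CharacterVector::create("B", "V", "FB", "FV");
  return out;
}

// [[Rcpp::export(name = ".perceived_core")]]
NumericVector perceived_core(NumericVector x, int r, IntegerVector cuts) {
  const int N = x.size();
  std::vector<bool> cutbefore(N, false);
  for (int i = 0; i < cuts.size(); ++i) cutbefore[cuts[i]] = true;
  std::vector<int> left, right;
  window_reach(N, r, cutbefore, left, right);
  std::vector<double> xx(x.begin(), x.end()), S(N);
  perceived(xx, N, left, right, S);
  return NumericVector(S.begin(), S.end());
}

// Fixed-step classical RK4 with zero-order-held perturbation sources, optional
// post-step multiplicative noise (uses R's RNG), negative clamping, divergence
// abort, and early stop on max|rhs| < conv_tol.
// [[Rcpp::export(name = ".integrate_core")]]
List integrate_core(NumericMatrix state, List par, IntegerVector cuts,
                    NumericMatrix ev, List ev_cells,
                    double t0, double t_end, double dt, double record_every,
                    double sigma_dyn, double conv_tol) {
  Pars p = unpack(par);
  const int N = state.nrow();
  if (N != p.N) stop("state has %d cells but parameters say n_cells = %d", N, p.N);
  std::vector<bool> cutbefore(N, false);
  for (int i = 0; i < cuts.size(); ++i) cutbefore[cuts[i]] = true;
  std::vector<int> left, right;
  window_reach(N, p.r, cutbefore, left, right);

  const long nsteps = (long)std::llround((t_end - t0) / dt);
  if (nsteps < 1) stop("t_end must exceed the start time by at least one step");
  const long stride = std::max((long)1, (long)std::llround(record_every / dt));

  std::vector<double> y(4 * N), k1(4 * N), k2(4 * N), k3(4 * N), k4(4 * N), yt(4 * N);
  std::vector<double> SB(N), SV(N), tB(N), tV(N);
  std::vector<double> srcB(N), srcV(N), mFB(N), mFV(N);
  for (int c = 0; c < 4; ++c)
    for (int i = 0; i < N; ++i) y[c * N + i] = state(i, c);

  std::vector<double> times;
  std::vector<double> snaps;  // concatenated 4N blocks
  times.reserve(nsteps / stride + 2);
  auto record = [&](double t) {
    times.push_back(t);
    snaps.insert(snaps.end(), y.begin(), y.end());
  };
  record(t0);

  bool converged = false;
  double final_res = NA_REAL, max_clamp = 0.0;
  long step = 0;
  const double noise_sd = sigma_dyn * std::sqrt(dt);

  for (step = 0; step < nsteps; ++step) {
    double t = t0 + step * dt;
    fill_sources(t, ev, ev_cells, N, srcB, srcV, mFB, mFV);

    rhs_eval(y, p, left, right, srcB, srcV, mFB, mFV, k1, SB, SV, tB, tV);

    double res = 0.0;
    for (size_t j = 0; j < k1.size(); ++j) res = std::max(res, std::fabs(k1[j]));
    if (res < conv_tol) { converged = true; final_res = res; break; }

    for (size_t j = 0; j < y.size(); ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
    rhs_eval(yt, p, left, right, srcB, srcV, mFB, mFV, k2, SB, SV, tB, tV);
    for (size_t j = 0; j < y.size(); ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
    rhs_eval(yt, p, left, right, srcB, srcV, mFB, mFV, k3, SB, SV, tB, tV);
    for (size_t j = 0; j < y.size(); ++j) yt[j] = y[j] + dt * k3[j];
    rhs_eval(yt, p, left, right, srcB, srcV, mFB, mFV, k4, SB, SV, tB, tV);
    for (size_t j = 0; j < y.size(); ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    if (noise_sd > 0.0)
      for (size_t j = 0; j < y.size(); ++j) y[j] *= std::exp(noise_sd * norm_rand());

    for (size_t j = 0; j < y.size(); ++j) {
      if (y[j] < 0.0) { max_clamp = std::max(max_clamp, -y[j]); y[j] = 0.0; }
      if (y[j] > 1e6) {
        int cell = (int)(j % N), comp = (int)(j / N);
        const char* nm[4] = {"B", "V", "FB", "FV"};
        stop("integration unstable: %s at cell %d exceeded 1e6 at t = %.4f (reduce dt)",
             nm[comp], cell + 1, t + dt);
      }
    }
    if ((step + 1) % stride == 0 && step + 1 < nsteps) record(t0 + (step + 1) * dt);
  }

  double t_final = t0 + (converged ? step : nsteps) * dt;
  if (times.back() < t_final) record(t_final);
  if (!converged) {
    fill_sources(t_final, ev, ev_cells, N, srcB, srcV, mFB, mFV);
    rhs_eval(y, p, left, right, srcB, srcV, mFB, mFV, k1, SB, SV, tB, tV);
    final_res = 0.0;
    for (size_t j = 0; j < k1.size(); ++j) final_res = std::max(final_res, std::fabs(k1[j]));
    converged = final_res < conv_tol;
  }

  int S = times.size();
  NumericVector arr(snaps.begin(), snaps.end());
  arr.attr("dim") = IntegerVector::create(N, 4, S);
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["snapshots"] = arr,
                      _["converged"] = converged,
                      _["final_residual"] = final_res,
                      _["max_clamp"] = max_clamp);
}
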