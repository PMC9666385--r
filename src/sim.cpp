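#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Discrete-time simulation of the controller families.  One update loop is
// shared by all 19 registry configurations; `eq` selects the governing
// equation (4 = PID, 5 = basic DIVA/state-space, 6 = velocity-generalized
// DIVA, 7 = two-timescale DIVA).
//
// Units: the plant runs in normalized f_o with target f_T = 1; delays are
// rounded to integer step counts; gains are per-step increments.  Velocity
// terms use the per-step backward difference of the delayed sensory signal
// (the perturbation's own discontinuity at onset is excluded), matching the
// scale of the other per-step gains.
//
// par layout (fixed order, see R/params.R):
//  [0] alpha_P [1] alpha_I [2] alpha_D [3] alpha_A [4] alpha_S
//  [5] alpha_Av [6] alpha_Sv [7] alpha_As [8] alpha_Ss
//  [9] tau_A [10] tau_S [11] tau_Av [12] tau_Sv [13] tau_As [14] tau_Ss

static const double F_CAP = 1e6; // divergence guard for unstable particles

static inline double f_hist(const std::vector<double>& f, int j) {
  return j < 0 ? 1.0 : f[j]; // pre-grid history: plant at target
}

static inline double p_hist(const NumericVector& P, int j) {
  return j < 0 ? 0.0 : P[j]; // pre-grid history: no perturbation
}

// backward per-step difference of the heard (perturbed) signal, with the
// perturbation profile's own time-derivative excluded
static inline double dstep_aud(const std::vector<double>& f,
                               const NumericVector& P, int j) {
  return (1.0 + p_hist(P, j)) * (f_hist(f, j) - f_hist(f, j - 1));
}

static inline double dstep_som(const std::vector<double>& f, int j) {
  return f_hist(f, j) - f_hist(f, j - 1);
}

static void sim_into(int eq, const double* par, const NumericVector& P,
                     double dt, int i0, int n, std::vector<double>& f) {
  const double aP = par[0], aI = par[1], aD = par[2];
  const double aA = par[3], aS = par[4];
  const double aAv = par[5], aSv = par[6], aAs = par[7], aSs = par[8];
  const int dA = (int)std::lround(par[9] / dt);
  const int dS = (int)std::lround(par[10] / dt);
  // total delay of each term cannot be negative (no future plant output)
  const int dAv = std::max(0, dA + (int)std::lround(par[11] / dt));
  const int dSv = std::max(0, dS + (int)std::lround(par[12] / dt));
  const int dAs = std::max(0, dA + (int)std::lround(par[13] / dt));
  const int dSs = std::max(0, dS + (int)std::lround(par[14] / dt));

  double errsum = 0.0; // running sum of the delayed auditory error, from t = 0
  f.assign(n, 1.0);
  for (int i = 0; i < n - 1; ++i) {
    double fc = 0.0; // controller command is 0 throughout the baseline window
    if (i >= i0) {
      const double fA = f_hist(f, i - dA) * (1.0 + p_hist(P, i - dA));
      switch (eq) {
      case 4:
        errsum += 1.0 - fA;
        fc = aP * (1.0 - fA) + aI * errsum - aD * dstep_aud(f, P, i - dA);
        break;
      case 5:
        fc = aA * (1.0 - fA) + aS * (1.0 - f_hist(f, i - dS));
        break;
      case 6:
        fc = aA * (1.0 - fA) - aAv * dstep_aud(f, P, i - dAv)
           + aS * (1.0 - f_hist(f, i - dS)) - aSv * dstep_som(f, i - dSv);
        break;
      case 7:
        fc = aA * (1.0 - fA)
           + aAs * (1.0 - f_hist(f, i - dAs) * (1.0 + p_hist(P, i - dAs)))
           + aS * (1.0 - f_hist(f, i - dS))
           + aSs * (1.0 - f_hist(f, i - dSs));
        break;
      default:
        Rcpp::stop("unknown equation id");
      }
    }
    double nxt = f[i] + fc;
    if (!std::isfinite(nxt)) nxt = F_CAP;
    else if (nxt > F_CAP) nxt = F_CAP;
    else if (nxt < -F_CAP) nxt = -F_CAP;
    f[i + 1] = nxt;
  }
}

// [[Rcpp::export]]
NumericVector cpp_simulate(int eq, NumericVector par, NumericVector P,
                           double dt, int i0) {
  const int n = P.size();
  if (par.size() != 15) stop("parameter vector must have length 15");
  std::vector<double> f;
  sim_into(eq, REAL(par), P, dt, i0, n, f);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = f[i] - 1.0; // deviation from baseline
  return out;
}

// RMSE of simulated deviation against `data` over the post-onset window
// [i0, n), for a batch of parameter rows.  Used by the swarm optimizer.
// [[Rcpp::export]]
NumericVector cpp_batch_rmse(int eq, NumericMatrix pars, NumericVector P,
                             NumericVector data, double dt, int i0) {
  const int n = P.size(), m = pars.nrow();
  if (pars.ncol() != 15) stop("parameter matrix must have 15 columns");
  if (data.size() != n) stop("data and perturbation grids differ");
  NumericVector out(m);
  std::vector<double> f;
  std::vector<double> row(15);
  for (int p = 0; p < m; ++p) {
    for (int c = 0; c < 15; ++c) row[c] = pars(p, c);
    sim_into(eq, row.data(), P, dt, i0, n, f);
    double ss = 0.0;
    int cnt = 0;
    for (int i = i0; i < n; ++i) {
      const double d = (f[i] - 1.0) - data[i];
      ss += d * d;
      ++cnt;
    }
    const double r = std::sqrt(ss / cnt);
    out[p] = std::isfinite(r) ? r : F_CAP;
  }
  return out;
}
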