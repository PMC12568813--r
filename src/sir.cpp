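#include <Rcpp.h>
using namespace Rcpp;

// SIR vector field with frequency-scaled state (S(0) = 1):
//   dS = -b S I, dI = b S I - xi I, dR = xi I.
// beta is piecewise constant by calendar day; integration steps are aligned
// to day boundaries (h = 1 / steps_per_day), so each RK4 step sits inside a
// single day and uses that day's rate.

static inline void rk4_step(double &S, double &I, double b, double xi,
                            double h) {
  double k1S = -b * S * I;
  double k1I = b * S * I - xi * I;
  double S2 = S + 0.5 * h * k1S, I2 = I + 0.5 * h * k1I;
  double k2S = -b * S2 * I2;
  double k2I = b * S2 * I2 - xi * I2;
  double S3 = S + 0.5 * h * k2S, I3 = I + 0.5 * h * k2I;
  double k3S = -b * S3 * I3;
  double k3I = b * S3 * I3 - xi * I3;
  double S4 = S + h * k3S, I4 = I + h * k3I;
  double k4S = -b * S4 * I4;
  double k4I = b * S4 * I4 - xi * I4;
  S += h / 6.0 * (k1S + 2 * k2S + 2 * k3S + k4S);
  I += h / 6.0 * (k1I + 2 * k2I + 2 * k3I + k4I);
  I = std::max(I, 1e-300);
  S = std::max(S, 0.0);
}

// Full trajectory on the grid 0, h, 2h, ..., T (T = length(beta_day)).
// Returns a matrix with columns time, S, I, R; R = 1 + I0 - S - I by mass
// conservation.
// [[Rcpp::export]]
NumericMatrix sir_rk4_cpp(NumericVector beta_day, double xi, double I0,
                          int steps_per_day) {
  int T = beta_day.size();
  int nsteps = T * steps_per_day;
  double h = 1.0 / steps_per_day;
  NumericMatrix out(nsteps + 1, 4);
  double S = 1.0, I = I0;
  out(0, 0) = 0.0; out(0, 1) = S; out(0, 2) = I; out(0, 3) = 0.0;
  for (int s = 0; s < nsteps; ++s) {
    int day = s / steps_per_day;          // step lies inside day `day + 1`
    rk4_step(S, I, beta_day[day], xi, h);
    out(s + 1, 0) = (s + 1) * h;
    out(s + 1, 1) = S;
    out(s + 1, 2) = I;
    out(s + 1, 3) = 1.0 + I0 - S - I;
  }
  return out;
}

// Monte-Carlo log-likelihoods for the discrete-day DSA model: one row of
// `bdraws` per MC draw holds the block-specific infection rates; `sizes`
// expands blocks to days. For each draw the SIR system is integrated, the
// density is read off at integer days as beta(t) S(t) I(t), renormalized to
// a proper pmf over days 1..T, and the multinomial log-likelihood
// sum_t y_t log f(t) is returned. Draws whose epidemic never takes off (all
// day masses at the underflow floor) return -Inf.
// [[Rcpp::export]]
NumericVector epi_loglik_mc_cpp(NumericMatrix bdraws, IntegerVector sizes,
                                NumericVector y, double xi, double I0,
                                int steps_per_day, int mc_use = -1) {
  int MCtot = bdraws.nrow();
  int MC = (mc_use > 0 && mc_use < MCtot) ? mc_use : MCtot;
  int m = sizes.size();
  if (bdraws.ncol() < m) stop("bdraws has fewer columns than blocks");
  int T = y.size();
  double h = 1.0 / steps_per_day;
  // day -> draw-column map. Each block's rate uses the draw column indexed
  // by the block's *starting day* (not its index): common random numbers
  // then stay attached to the unchanged blocks when a boundary moves, so a
  // single split/merge only redraws the blocks it touches.
  std::vector<int> block_of(T);
  {
    int d = 0;
    for (int j = 0; j < m; ++j) {
      int start = d;
      for (int s = 0; s < sizes[j]; ++s) block_of[d++] = start;
    }
    if (d != T) stop("block sizes do not sum to T");
  }
  if (bdraws.ncol() < T) stop("bdraws needs one column per day");
  NumericVector out(MC);
  // integrate all draws day by day (vectorizable across draws); day masses
  // f = b S I stay in linear space -- they are O(1) quantities -- and logs
  // are taken only on observed days
  const double *bp = REAL(bdraws);
  std::vector<double> S(MC, 1.0), I(MC, I0);
  std::vector<double> fmat((size_t)MC * T);
  std::vector<double> fsum(MC, 0.0);
  for (int d = 0; d < T; ++d) {
    const double *bcol = bp + (size_t)block_of[d] * MCtot;
    for (int s = 0; s < steps_per_day; ++s) {
      for (int mc = 0; mc < MC; ++mc) {
        rk4_step(S[mc], I[mc], bcol[mc], xi, h);
      }
    }
    double *frow = fmat.data() + (size_t)d * MC;
    for (int mc = 0; mc < MC; ++mc) {
      double f = bcol[mc] * S[mc] * I[mc];
      frow[mc] = f;
      fsum[mc] += f;
    }
  }
  for (int mc = 0; mc < MC; ++mc) {
    if (!(fsum[mc] > 0.0)) { out[mc] = R_NegInf; continue; }
    double lsum = std::log(fsum[mc]);
    double ll = 0.0;
    for (int d = 0; d < T; ++d) {
      if (y[d] == 0.0) continue;
      double f = fmat[(size_t)d * MC + mc];
      if (!(f > 0.0)) { ll = R_NegInf; break; }
      ll += y[d] * (std::log(f) - lsum);
    }
    out[mc] = ll;
  }
  return out;
}

// Exact Doob-Gillespie simulation of the Markov SIR jump process with
// infection propensity beta(t) X_S X_I / S0 (frequency-dependent mixing on
// the scale of the ODE limit) and recovery propensity xi X_I; beta is
// piecewise constant by calendar day, handled by discarding waiting times
// that cross the next day boundary (valid for piecewise-constant rates).
// Uses R's RNG so results are reproducible under set.seed(). Returns daily
// counts of infection events.
// [[Rcpp::export]]
IntegerVector gillespie_sir_cpp(int S0, int I0_count, NumericVector beta_day,
                                double xi, int horizon) {
  IntegerVector counts(horizon);
  double t = 0.0;
  long XS = S0, XI = I0_count, XR = 0;
  int nb = beta_day.size();
  while (t < horizon && XI > 0) {
    int day = (int)t;
    if (day >= horizon) break;
    double b = beta_day[day < nb ? day : nb - 1];
    double rate_inf = b * (double)XS * (double)XI / (double)S0;
    double rate_rec = xi * (double)XI;
    double rate_tot = rate_inf + rate_rec;
    double boundary = day + 1.0;
    if (rate_tot <= 0.0) { t = boundary; continue; }
    double dt = R::rexp(1.0 / rate_tot);
    if (t + dt >= boundary) { t = boundary; continue; }
    t += dt;
    if (R::unif_rand() * rate_tot < rate_inf) {
      --XS; ++XI;
      ++counts[day];
    } else {
      --XI; ++XR;
    }
  }
  counts.attr("final_S") = (double)XS;
  counts.attr("final_I") = (double)XI;
  counts.attr("final_R") = (double)XR;
  return counts;
}
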