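// Compiled core of the sequential importance resampling filter.
// Mirrors the R reference path in R/particle.R: random-walk state
// propagation, Liu-West (or plain random walk) coefficient evolution,
// indicator-weighted joint log-likelihood, log-domain weighting with max
// subtraction, systematic resampling at ESS < ess_frac * N, weighted
// quantiles of p, and the ancestral-genealogy Monte Carlo standard error.
// All randomness comes from R's RNG, so results are reproducible from
// set.seed() alone.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093453;

// Fast internal RNG for the bulk propagation noise: xoshiro256++ seeded
// from R's RNG, so set.seed() fully determines the run while the hot loop
// avoids per-draw R API overhead. Gaussian draws use the polar
// (Marsaglia) Box-Muller method with one cached value.
struct FastRng {
  uint64_t s[4];
  double cached;
  bool has_cached;
  explicit FastRng() : cached(0.0), has_cached(false) {
    // splitmix64 expansion of a 64-bit seed drawn from R's RNG
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                    (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    cached = v * f;
    has_cached = true;
    return u * f;
  }
};

// walk-scale coefficient layout (matches .wp_param_names in R)
enum {
  P_LOG_MU1 = 0, P_EMG_ICPT, P_LOG_EMG_SD,
  P_LOG_A_GAIN, P_A_OFF, P_LOG_A_SD,
  P_LOG_D_GAIN, P_D_OFF, P_LOG_D_SD, NPAR
};

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// weighted empirical quantile (left-continuous inverse CDF), matching the
// R helper: smallest value whose cumulative weight reaches the probability
static void weighted_quantiles(const std::vector<double>& x,
                               const std::vector<double>& w,
                               std::vector<int>& ord,
                               const double* probs, int np, double* out) {
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += w[i];
  int k = 0;
  double cw = w[ord[0]];
  for (int j = 0; j < np; ++j) {
    const double target = probs[j] * tot;
    while (cw < target && k < n - 1) { ++k; cw += w[ord[k]]; }
    out[j] = x[ord[k]];
  }
}

// [[Rcpp::export(name = ".pf_filter_cpp")]]
List pf_filter_cpp(NumericVector time, NumericVector b, NumericVector m,
                   NumericVector ya, NumericVector yd,
                   int n_particles,
                   NumericVector state_prior_mean,
                   NumericVector state_prior_sd,
                   NumericVector param_prior_mean,
                   NumericVector param_prior_sd,
                   NumericVector state_walk_sd,
                   bool liu_west, double lw_delta, double param_walk_sd,
                   double beta, double ess_frac, int n_keep,
                   bool record_obs_pred) {
  const int T = time.size();
  const int N = n_particles;
  const double probs[3] = {0.025, 0.5, 0.975};

  std::vector<double> xs(3 * N);         // states, column-major (m, a, d)
  std::vector<double> th(NPAR * N);      // walk-scale coefficients
  std::vector<double> w(N, 1.0 / N);
  std::vector<int> eve(N), ord(N), ridx(N);
  std::vector<double> pvec(N), ll(N), scratch(N);

  FastRng rng;  // seeded from R's RNG: set.seed() determines everything

  // prior draws (column order matches the R initializer)
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < N; ++i)
      xs[j * N + i] = state_prior_mean[j] + state_prior_sd[j] * rng.norm();
  for (int j = 0; j < NPAR; ++j)
    for (int i = 0; i < N; ++i)
      th[j * N + i] = param_prior_mean[j] + param_prior_sd[j] * rng.norm();
  for (int i = 0; i < N; ++i) eve[i] = i;

  const double a_lw = (3.0 * lw_delta - 1.0) / (2.0 * lw_delta);

  NumericMatrix curve(T, 3);
  NumericMatrix st_mean(T, 3), st_sd(T, 3), st_mcse(T, 3);
  NumericVector ess_out(T);
  LogicalVector resampled(T);
  int n_bt = 0;
  for (int t = 0; t < T; ++t) if (!NumericVector::is_na(b[t])) ++n_bt;
  NumericMatrix pred(n_keep, n_bt);
  NumericMatrix emgq(record_obs_pred ? T : 0, 3);
  NumericMatrix alphaq(record_obs_pred ? T : 0, 3);
  NumericMatrix dtq(record_obs_pred ? T : 0, 3);
  std::vector<double> derived(N);
  int bt_pos = 0;

  for (int t = 0; t < T; ++t) {
    // --- propagate states ---
    for (int j = 0; j < 3; ++j) {
      const double sd = state_walk_sd[j];
      if (sd > 0)
        for (int i = 0; i < N; ++i) xs[j * N + i] += sd * rng.norm();
    }
    // --- coefficient evolution ---
    if (liu_west) {
      for (int j = 0; j < NPAR; ++j) {
        double mu = 0.0, m2 = 0.0;
        double* col = &th[j * N];
        for (int i = 0; i < N; ++i) { mu += w[i] * col[i]; m2 += w[i] * col[i] * col[i]; }
        double v = m2 - mu * mu;
        if (v < 0) v = 0;
        const double nsd = std::sqrt((1.0 - a_lw * a_lw) * v);
        const double shift = (1.0 - a_lw) * mu;
        if (nsd > 0) {
          for (int i = 0; i < N; ++i)
            col[i] = a_lw * col[i] + shift + nsd * rng.norm();
        } else {
          for (int i = 0; i < N; ++i) col[i] = a_lw * col[i] + shift;
        }
      }
    } else if (param_walk_sd > 0) {
      for (int j = 0; j < NPAR; ++j) {
        double* col = &th[j * N];
        for (int i = 0; i < N; ++i) col[i] += param_walk_sd * rng.norm();
      }
    }

    const bool has_b = !NumericVector::is_na(b[t]);
    const bool has_m = !NumericVector::is_na(m[t]);
    const bool has_a = !NumericVector::is_na(ya[t]);
    const bool has_d = !NumericVector::is_na(yd[t]);

    // response probability per particle (needed for curve and behavior)
    for (int i = 0; i < N; ++i)
      pvec[i] = logistic(beta * (xs[i] + xs[N + i] - xs[2 * N + i]));

    // --- one-step-ahead predictive draws at behavioral times ---
    if (has_b) {
      double acc = 0.0;
      for (int i = 0; i < N; ++i) { acc += w[i]; scratch[i] = acc; }
      const double tot = acc;
      for (int k = 0; k < n_keep; ++k) {
        const double u = rng.unif() * tot;
        int pick = (int)(std::upper_bound(scratch.begin(), scratch.end(), u) -
                         scratch.begin());
        if (pick >= N) pick = N - 1;
        pred(k, bt_pos) = pvec[pick];
      }
      ++bt_pos;
    }

    // --- joint log-likelihood and reweighting ---
    bool any_obs = has_b || has_m || has_a || has_d;
    bool did_resample = false;
    if (any_obs) {
      std::fill(ll.begin(), ll.end(), 0.0);
      if (has_b) {
        const double bt = b[t];
        for (int i = 0; i < N; ++i) {
          double p = pvec[i];
          if (p < 1e-12) p = 1e-12;
          if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
          ll[i] += bt * std::log(p) + (1.0 - bt) * std::log(1.0 - p);
        }
      }
      if (has_m) {
        const double obs = m[t];
        for (int i = 0; i < N; ++i) {
          const double log_sd = th[P_LOG_EMG_SD * N + i];
          const double mu1 = std::exp(th[P_LOG_MU1 * N + i]);
          const double z = (obs - th[P_EMG_ICPT * N + i] - mu1 * xs[i]) *
            std::exp(-log_sd);
          ll[i] += -0.5 * LOG_2PI - log_sd - 0.5 * z * z;
        }
      }
      if (has_a) {
        const double obs = ya[t];
        for (int i = 0; i < N; ++i) {
          const double log_sd = th[P_LOG_A_SD * N + i];
          const double gain = std::exp(th[P_LOG_A_GAIN * N + i]);
          const double mu = th[P_A_OFF * N + i] + gain * logistic(xs[N + i]);
          const double z = (obs - mu) * std::exp(-log_sd);
          ll[i] += -0.5 * LOG_2PI - log_sd - 0.5 * z * z;
        }
      }
      if (has_d) {
        const double obs = yd[t];
        for (int i = 0; i < N; ++i) {
          const double log_sd = th[P_LOG_D_SD * N + i];
          const double gain = std::exp(th[P_LOG_D_GAIN * N + i]);
          const double mu = th[P_D_OFF * N + i] + gain * logistic(xs[2 * N + i]);
          const double z = (obs - mu) * std::exp(-log_sd);
          ll[i] += -0.5 * LOG_2PI - log_sd - 0.5 * z * z;
        }
      }
      double mx = R_NegInf;
      for (int i = 0; i < N; ++i) {
        scratch[i] = std::log(w[i]) + ll[i];
        if (scratch[i] > mx) mx = scratch[i];
      }
      if (!R_FINITE(mx))
        stop("all particle weights vanished at t = %g (time index %d); observation inconsistent with the ensemble",
             time[t], t + 1);
      double sum = 0.0;
      for (int i = 0; i < N; ++i) { w[i] = std::exp(scratch[i] - mx); sum += w[i]; }
      double sumsq = 0.0;
      for (int i = 0; i < N; ++i) { w[i] /= sum; sumsq += w[i] * w[i]; }
      const double ess = 1.0 / sumsq;
      if (ess < ess_frac * N) {
        // systematic resampling
        const double u0 = rng.unif() / N;
        double cw = w[0];
        int i = 0;
        for (int k = 0; k < N; ++k) {
          const double u = u0 + (double)k / N;
          while (cw < u && i < N - 1) { ++i; cw += w[i]; }
          ridx[k] = i;
        }
        for (int j = 0; j < 3; ++j) {
          double* col = &xs[j * N];
          for (int k = 0; k < N; ++k) scratch[k] = col[ridx[k]];
          std::copy(scratch.begin(), scratch.end(), col);
        }
        for (int j = 0; j < NPAR; ++j) {
          double* col = &th[j * N];
          for (int k = 0; k < N; ++k) scratch[k] = col[ridx[k]];
          std::copy(scratch.begin(), scratch.end(), col);
        }
        std::vector<int> eve2(N);
        for (int k = 0; k < N; ++k) eve2[k] = eve[ridx[k]];
        eve.swap(eve2);
        std::fill(w.begin(), w.end(), 1.0 / N);
        for (int i2 = 0; i2 < N; ++i2)
          pvec[i2] = logistic(beta * (xs[i2] + xs[N + i2] - xs[2 * N + i2]));
        did_resample = true;
      }
    }
    resampled[t] = did_resample;

    // --- per-time summaries ---
    double sumsq = 0.0;
    for (int i = 0; i < N; ++i) sumsq += w[i] * w[i];
    ess_out[t] = 1.0 / sumsq;
    {
      double q[3];
      weighted_quantiles(pvec, w, ord, probs, 3, q);
      curve(t, 0) = q[0]; curve(t, 1) = q[1]; curve(t, 2) = q[2];
    }
    for (int j = 0; j < 3; ++j) {
      const double* col = &xs[j * N];
      double mu = 0.0, m2 = 0.0;
      for (int i = 0; i < N; ++i) { mu += w[i] * col[i]; m2 += w[i] * col[i] * col[i]; }
      double v = m2 - mu * mu;
      if (v < 0) v = 0;
      st_mean(t, j) = mu;
      st_sd(t, j) = std::sqrt(v);
      // genealogy MC variance: sum over ancestor families of squared
      // weighted deviations
      std::fill(scratch.begin(), scratch.end(), 0.0);
      for (int i = 0; i < N; ++i) scratch[eve[i]] += w[i] * (col[i] - mu);
      double se2 = 0.0;
      for (int i = 0; i < N; ++i) se2 += scratch[i] * scratch[i];
      st_mcse(t, j) = std::sqrt(se2);
    }
    if (record_obs_pred) {
      double q[3];
      for (int i = 0; i < N; ++i)
        derived[i] = th[P_EMG_ICPT * N + i] +
          std::exp(th[P_LOG_MU1 * N + i]) * xs[i];
      weighted_quantiles(derived, w, ord, probs, 3, q);
      emgq(t, 0) = q[0]; emgq(t, 1) = q[1]; emgq(t, 2) = q[2];
      for (int i = 0; i < N; ++i)
        derived[i] = th[P_A_OFF * N + i] +
          std::exp(th[P_LOG_A_GAIN * N + i]) * logistic(xs[N + i]);
      weighted_quantiles(derived, w, ord, probs, 3, q);
      alphaq(t, 0) = q[0]; alphaq(t, 1) = q[1]; alphaq(t, 2) = q[2];
      for (int i = 0; i < N; ++i)
        derived[i] = th[P_D_OFF * N + i] +
          std::exp(th[P_LOG_D_GAIN * N + i]) * logistic(xs[2 * N + i]);
      weighted_quantiles(derived, w, ord, probs, 3, q);
      dtq(t, 0) = q[0]; dtq(t, 1) = q[1]; dtq(t, 2) = q[2];
    }
  }

  return List::create(_["curve"] = curve, _["st_mean"] = st_mean,
                      _["st_sd"] = st_sd, _["st_mcse"] = st_mcse,
                      _["ess"] = ess_out, _["resampled"] = resampled,
                      _["pred"] = pred, _["emgq"] = emgq,
                      _["alphaq"] = alphaq, _["dtq"] = dtq);
}
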