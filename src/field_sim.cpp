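#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Delayed stochastic neural-field integrator on a ring lattice.
//
// Per-population synaptic dynamics (critically damped second-order filter)
// are propagated exactly between steps via the precomputed exponential map
// `prop`; the horizontal coupling drive is evaluated from a delay-history
// ring buffer of the transmitted quantity (gamma*V in linearised mode,
// F(V)-F(0) otherwise), with conduction delays rounded to integration
// steps.  The driven population receives an exact discrete-time stochastic
// increment with Cholesky factor `noiseL`.  Randomness comes from R's RNG,
// so runs are reproducible under set.seed().
//
// prop: 4 x 6 (m11, m12, m21, m22, r1, r2) per population.
// wmat: (jmax+1) x n_groups kernel decay weights over ring distances.
// lags: integer conduction lags (steps) per ring distance.
// edge_*: per-edge target population, (source, decay) group and signed
//   weight alpha/2 * dx.
// wsite: n_sites x n_x spatial integration weights (montage applied).
// [[Rcpp::export]]
NumericMatrix field_sim_cpp(NumericVector kappa, NumericMatrix prop,
                            IntegerVector edge_to, IntegerVector edge_group,
                            NumericVector edge_wt, IntegerVector group_pop,
                            NumericMatrix wmat, IntegerVector lags,
                            double gamma, double r, double eta,
                            bool linearised, NumericMatrix wsite,
                            NumericVector mix, int n_x, int n_steps,
                            int rec_every, NumericVector noiseL, double dt,
                            double init_sd) {
  const int M = n_x;
  const int jmax = lags.size() - 1;
  const int n_groups = wmat.ncol();
  const int n_sites = wsite.nrow();
  int max_lag = 0;
  for (int j = 0; j <= jmax; ++j) if (lags[j] > max_lag) max_lag = lags[j];
  const int n_slots = max_lag + 1;

  std::vector<std::vector<double>> V(4, std::vector<double>(M, 0.0));
  std::vector<std::vector<double>> W(4, std::vector<double>(M, 0.0));
  // history[pop][slot*2M + x] of the transmitted quantity, stored twice
  // (x and x + M) so circular shifts become contiguous reads
  std::vector<std::vector<double>> hist(
      4, std::vector<double>((size_t)n_slots * 2 * M, 0.0));
  std::vector<std::vector<double>> S(n_groups, std::vector<double>(M));
  std::vector<double> drive(4 * M), qv(M);
  const double F0 = 1.0 / (1.0 + std::exp(r * eta));

  const int n_rec = n_steps / rec_every;
  NumericMatrix out(n_sites, n_rec);
  RNGScope scope;
  if (init_sd > 0.0)
    for (int a = 0; a < 4; ++a)
      for (int x = 0; x < M; ++x) V[a][x] = init_sd * norm_rand();
  int rec = 0;

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % n_slots;
    // push transmitted rates at time t into the (duplicated) history
    for (int a = 0; a < 4; ++a) {
      double* h = &hist[a][(size_t)slot * 2 * M];
      const double* v = V[a].data();
      if (linearised)
        for (int x = 0; x < M; ++x) h[x] = h[x + M] = gamma * v[x];
      else
        for (int x = 0; x < M; ++x)
          h[x] = h[x + M] = 1.0 / (1.0 + std::exp(r * (eta - v[x]))) - F0;
    }
    // delayed spatial sums per (source population, decay) group; with the
    // duplicated rows, row[(x-j) mod M] = row[x - j + M] and
    // row[(x+j) mod M] = row[x + j], both contiguous in x.  Adding both
    // shifts double-counts j = 0 and the antipodal point, so those
    // weights are halved.
    for (int g = 0; g < n_groups; ++g) {
      const int b = group_pop[g];
      double* s = S[g].data();
      std::fill(s, s + M, 0.0);
      for (int j = 0; j <= jmax; ++j) {
        double wj = wmat(j, g);
        if (j == 0 || 2 * j == M) wj *= 0.5;
        if (wj < 1e-14 * wmat(0, g)) continue;
        const int sl = ((t - lags[j]) % n_slots + n_slots) % n_slots;
        const double* row = &hist[b][(size_t)sl * 2 * M];
        const double* rm = row + (M - j);
        const double* rp = row + j;
        for (int x = 0; x < M; ++x) s[x] += wj * (rm[x] + rp[x]);
      }
    }
    // combine edges into the per-population drive kappa_a * (K * phi)_a
    std::fill(drive.begin(), drive.end(), 0.0);
    for (int ed = 0; ed < edge_to.size(); ++ed) {
      const int a = edge_to[ed];
      const double wt = edge_wt[ed] * kappa[a];
      const double* s = S[edge_group[ed]].data();
      double* d = &drive[(size_t)a * M];
      for (int x = 0; x < M; ++x) d[x] += wt * s[x];
    }
    // exact propagation of the damped second-order dynamics
    for (int a = 0; a < 4; ++a) {
      const double m11 = prop(a, 0), m12 = prop(a, 1);
      const double m21 = prop(a, 2), m22 = prop(a, 3);
      const double r1 = prop(a, 4), r2 = prop(a, 5);
      double* v = V[a].data();
      double* w = W[a].data();
      const double* d = &drive[(size_t)a * M];
      for (int x = 0; x < M; ++x) {
        const double vv = v[x], ww = w[x], f = d[x];
        v[x] = m11 * vv + m12 * ww + r1 * f;
        w[x] = m21 * vv + m22 * ww + r2 * f;
      }
    }
    // stochastic input to population 1 (exact increment)
    {
      double* v = V[0].data();
      double* w = W[0].data();
      for (int x = 0; x < M; ++x) {
        const double z1 = norm_rand(), z2 = norm_rand();
        v[x] += noiseL[0] * z1;
        w[x] += noiseL[1] * z1 + noiseL[2] * z2;
      }
    }
    if ((t + 1) % rec_every == 0) {
      for (int x = 0; x < M; ++x)
        qv[x] = mix[0] * V[0][x] + mix[1] * V[1][x] +
                mix[2] * V[2][x] + mix[3] * V[3][x];
      for (int l = 0; l < n_sites; ++l) {
        double acc = 0.0;
        for (int x = 0; x < M; ++x) acc += wsite(l, x) * qv[x];
        out(l, rec) = acc;
      }
      ++rec;
      if (rec % 1000 == 0) {
        double mx = 0.0;
        for (int a = 0; a < 4; ++a)
          for (int x = 0; x < M; ++x)
            if (std::fabs(V[a][x]) > mx) mx = std::fabs(V[a][x]);
        if (!std::isfinite(mx) || mx > 1e12)
          stop("field simulation diverged at t = %.4f s", (t + 1) * dt);
      }
    }
  }
  return out;
}
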