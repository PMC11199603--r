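#include <Rcpp.h>
#include "tasep_core.h"
using namespace Rcpp;

// Run the TASEP kernel alone (no polymer). Probabilities are rate*dt per
// attempt; `steps` MCS are simulated, the first `burn_in` discarded from all
// averages. Occupancy snapshots are kept every `thin` MCS after burn-in.
// Per-site means and batch-mean standard errors are accumulated over every
// post-burn-in MCS.
// [[Rcpp::export]]
List tasep_run_cpp(int n, double pa, double pb, double pg, double pg0,
                   double pon, double poff, bool burst, bool start_on,
                   double steps, double burn_in, double thin,
                   IntegerVector init_occ, double seed) {
  if (n < 2) stop("n must be >= 2");
  if (steps <= burn_in) stop("steps must exceed burn_in");
  Xoshiro rng((uint64_t)seed);
  TasepCore tc;
  tc.init(n, pa, pb, pg, pg0, pon, poff, burst, start_on);
  if (init_occ.size() == n) {
    std::vector<int> s0(init_occ.begin(), init_occ.end());
    tc.set_occupancy(s0, 0.0);
  }
  TasepNoCB cb;

  long long nsteps = (long long)steps, nburn = (long long)burn_in;
  long long nthin = (long long)thin;
  long long nsamp = nsteps - nburn;
  long long nsnap = nsamp / nthin;

  IntegerMatrix occ(nsnap, n);
  IntegerVector prom(nsnap);
  IntegerVector trains(nsnap);
  NumericVector snap_t(nsnap);

  const int NBATCH = 20;
  std::vector<double> mean_s(n, 0.0);
  std::vector<double> batch(NBATCH * n, 0.0);
  long long batch_len = nsamp / NBATCH + 1;

  long long isnap = 0;
  for (long long t = 0; t < nsteps; ++t) {
    if (t == nburn) tc.reset_events();
    tc.sweep(rng, (double)t, cb);
    if (t >= nburn) {
      long long ts = t - nburn;
      int b = (int)(ts / batch_len);
      for (int i = 0; i < n; ++i) {
        mean_s[i] += tc.s[i];
        batch[b * n + i] += tc.s[i];
      }
      if ((ts + 1) % nthin == 0 && isnap < nsnap) {
        for (int i = 0; i < n; ++i) occ(isnap, i) = tc.s[i];
        prom[isnap] = tc.promoter_on;
        trains[isnap] = tc.n_trains();
        snap_t[isnap] = (double)t;
        ++isnap;
      }
    }
  }

  NumericVector dens(n), dens_se(n);
  for (int i = 0; i < n; ++i) {
    dens[i] = mean_s[i] / nsamp;
    // batch-means SE
    double bm = 0.0, bv = 0.0;
    std::vector<double> bmeans(NBATCH);
    for (int b = 0; b < NBATCH; ++b) {
      long long len = std::min(batch_len, nsamp - b * batch_len);
      bmeans[b] = batch[b * n + i] / (double)len;
      bm += bmeans[b];
    }
    bm /= NBATCH;
    for (int b = 0; b < NBATCH; ++b) bv += (bmeans[b] - bm) * (bmeans[b] - bm);
    bv /= (NBATCH - 1);
    dens_se[i] = std::sqrt(bv / NBATCH);
  }

  return List::create(
    _["density"] = dens,
    _["density_se"] = dens_se,
    _["occupancy"] = occ,
    _["snap_mcs"] = snap_t,
    _["promoter"] = prom,
    _["trains"] = trains,
    _["n_loads"] = (double)tc.n_loads,
    _["n_unloads"] = (double)tc.n_unloads,
    _["transit_times"] = wrap(tc.transit_times),
    _["unload_times"] = wrap(tc.unload_times),
    _["sampled_mcs"] = (double)nsamp);
}
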