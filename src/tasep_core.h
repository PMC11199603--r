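#ifndef GENEFOLD_TASEP_CORE_H
#define GENEFOLD_TASEP_CORE_H

#include <vector>
#include "rng.h"

// Discrete kinetic Monte Carlo TASEP for Pol II occupancy along a gene of n
// monomers. One Monte Carlo step (MCS) is: (i) one attempt to bind at the TSS
// (site 0) with probability alpha*dt if the site is free and the promoter is
// on; (ii) one attempt to unbind at the TTS (site n-1) with probability
// beta*dt if occupied; (iii) n-1 elongation attempts, each picking a uniform
// site i in [0, n-2] and moving an occupying Pol II forward with probability
// gamma*dt (gamma0*dt for the first hop 0->1) if site i+1 is free; then (iv)
// one promoter-switch attempt (two-state bursting) when enabled.
//
// Each loaded Pol II carries the burst-episode id current at load time, which
// defines the "train" it belongs to, and its load time (for transit times).
struct TasepCore {
  int n;
  double pa, pb, pg, pg0, pon, poff; // rate * dt per attempt
  bool burst;
  std::vector<int> s;        // occupancy, 0/1
  std::vector<long> tag;     // burst-episode id of the Pol II at site i
  std::vector<double> load_t;
  int promoter_on;
  long episode;

  // event tallies
  long n_loads, n_unloads;
  std::vector<double> transit_times; // in MCS
  std::vector<double> unload_times;  // in MCS

  TasepCore() : n(0) {}

  void init(int n_, double pa_, double pb_, double pg_, double pg0_,
            double pon_, double poff_, bool burst_, bool start_on) {
    n = n_;
    pa = pa_; pb = pb_; pg = pg_; pg0 = pg0_; pon = pon_; poff = poff_;
    burst = burst_;
    s.assign(n, 0);
    tag.assign(n, -1);
    load_t.assign(n, 0.0);
    promoter_on = start_on ? 1 : 0;
    episode = 0;
    n_loads = 0; n_unloads = 0;
    transit_times.clear();
    unload_times.clear();
  }

  // Pre-populate occupancy (e.g. a stationary-measure draw done at R level).
  void set_occupancy(const std::vector<int> &s0, double t0) {
    for (int i = 0; i < n; ++i) {
      s[i] = s0[i] ? 1 : 0;
      tag[i] = s[i] ? episode : -1;
      load_t[i] = t0;
    }
  }

  // drop events accumulated during burn-in so rates refer to sampled time
  void reset_events() {
    n_loads = 0; n_unloads = 0;
    transit_times.clear();
    unload_times.clear();
  }

  int n_trains() const {
    // distinct episode ids currently elongating; ids are non-decreasing along
    // the gene from TTS to TSS, so count id changes over occupied sites
    long last = -1;
    int k = 0;
    for (int i = 0; i < n; ++i)
      if (s[i] && tag[i] != last) { ++k; last = tag[i]; }
    return k;
  }

  double density() const {
    long tot = 0;
    for (int i = 0; i < n; ++i) tot += s[i];
    return (double)tot / n;
  }

  // CB must provide on_bind(i), on_unbind(i), on_hop(i) (Pol II moved i->i+1)
  template <class CB>
  void sweep(Xoshiro &rng, double t, CB &cb) {
    if (promoter_on && s[0] == 0 && rng.runif() < pa) {
      s[0] = 1; tag[0] = episode; load_t[0] = t; ++n_loads;
      cb.on_bind(0);
    }
    if (s[n - 1] == 1 && rng.runif() < pb) {
      s[n - 1] = 0;
      transit_times.push_back(t - load_t[n - 1]);
      unload_times.push_back(t);
      tag[n - 1] = -1;
      ++n_unloads;
      cb.on_unbind(n - 1);
    }
    for (int k = 0; k < n - 1; ++k) {
      int i = rng.runif_int(n - 1);
      if (s[i] == 1 && s[i + 1] == 0) {
        double p = (i == 0) ? pg0 : pg;
        if (rng.runif() < p) {
          s[i] = 0; s[i + 1] = 1;
          tag[i + 1] = tag[i]; tag[i] = -1;
          load_t[i + 1] = load_t[i];
          cb.on_hop(i);
        }
      }
    }
    if (burst) {
      if (promoter_on) {
        if (rng.runif() < poff) promoter_on = 0;
      } else if (rng.runif() < pon) {
        promoter_on = 1;
        ++episode; // a new on-period starts a new train
      }
    }
  }
};

// no-op callback for pure-TASEP runs
struct TasepNoCB {
  void on_bind(int) {}
  void on_unbind(int) {}
  void on_hop(int) {}
};

#endif
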