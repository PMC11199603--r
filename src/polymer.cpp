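#include <Rcpp.h>
#include <cmath>
#include "tasep_core.h"
using namespace Rcpp;

// Self-avoiding semi-flexible chain on an FCC lattice (cubic embedding:
// integer sites with x+y+z even, 12 nearest neighbors at permutations of
// (+-1,+-1,0)) with periodic boundaries, coupled to TASEP Pol II occupancy.
// Hamiltonian: H = kappa * sum(1 - cos theta_i) + E * (#pairs in the
// valency-capped interaction lists). Pairs require both monomers Pol II-bound
// and lattice-adjacent; existing pairs persist while valid, free slots are
// refilled in random order after every polymer or TASEP move.

static const int NB = 12;
static const int OFF[NB][3] = {
  {1,1,0},{1,-1,0},{-1,1,0},{-1,-1,0},
  {1,0,1},{1,0,-1},{-1,0,1},{-1,0,-1},
  {0,1,1},{0,1,-1},{0,-1,1},{0,-1,-1}
};

struct PairOp { int a, b; bool added; };

struct Poly {
  int N, Lx, Ly, Lz, val;
  double kappa, E;
  std::vector<int> x, y, z;    // unwrapped lattice coordinates
  std::vector<int> wx, wy, wz; // wrapped coordinates, kept in step
  std::vector<int> grid;       // wrapped site -> monomer index, -1 if empty
  std::vector<int> s;         // Pol II occupancy per chain monomer
  std::vector<int> cnt;       // interaction-list length per monomer
  std::vector<int> part;      // N*val partner indices
  std::vector<PairOp> oplog;  // rollback log for tentative moves
  long long n_pairs;          // total pairs currently in lists

  inline int wrapc(int a, int L) const { a %= L; if (a < 0) a += L; return a; }
  inline int site(int xx, int yy, int zz) const {
    return (wrapc(xx, Lx) * Ly + wrapc(yy, Ly)) * Lz + wrapc(zz, Lz);
  }
  // wrapped coords +/- small offset, folded without modulo
  static inline int foldw(int a, int L) {
    if (a < 0) return a + L;
    if (a >= L) return a - L;
    return a;
  }
  inline int wsite(int xx, int yy, int zz) const {
    return (xx * Ly + yy) * Lz + zz;
  }
  inline int site_of(int m) const { return (wx[m] * Ly + wy[m]) * Lz + wz[m]; }
  // difference of wrapped coords folded to the minimal image
  static inline int wdiff(int d, int L) {
    if (d > L / 2) return d - L;
    if (d < -L / 2) return d + L;
    return d;
  }
  inline bool adjacent_mon(int a, int b) const {
    int dx = wdiff(wx[a] - wx[b], Lx);
    int dy = wdiff(wy[a] - wy[b], Ly);
    int dz = wdiff(wz[a] - wz[b], Lz);
    int ax = dx < 0 ? -dx : dx, ay = dy < 0 ? -dy : dy, az = dz < 0 ? -dz : dz;
    return (ax + ay + az == 2) && ax <= 1 && ay <= 1 && az <= 1;
  }

  void alloc(int N_, int Lx_, int Ly_, int Lz_, int val_, double kappa_, double E_) {
    N = N_; Lx = Lx_; Ly = Ly_; Lz = Lz_; val = val_; kappa = kappa_; E = E_;
    x.assign(N, 0); y.assign(N, 0); z.assign(N, 0);
    wx.assign(N, 0); wy.assign(N, 0); wz.assign(N, 0);
    grid.assign((size_t)Lx * Ly * Lz, -1);
    s.assign(N, 0);
    cnt.assign(N, 0);
    part.assign((size_t)N * val, -1);
    n_pairs = 0;
  }

  // Layered serpentine initial configuration: within each plane y = 2j the
  // FCC sites map bijectively to a (L x L/2) rectangle via u=(x+z)/2-like
  // rotated coordinates; a boustrophedon over that rectangle is a
  // self-avoiding nearest-neighbor path. Consecutive planes are traversed in
  // opposite order and joined through a single connector site in the odd
  // plane between them, so the whole chain is unknotted by construction and
  // fills the box uniformly at 50% when run to capacity.
  void build_initial() {
    if (Lx != Lz) stop("initial configuration requires Lx == Lz");
    if (Lx % 2 || Ly % 2 || Lz % 2) stop("box dimensions must be even");
    if (Lx < 6 || Ly < 2) stop("box too small");
    int L = Lx, V = L / 2;
    long long cap = (long long)(Ly / 2) * L * V + (Ly / 2 - 1);
    if ((long long)N > cap)
      stop("chain does not fit: N=%d exceeds capacity %lld of box %dx%dx%d",
           N, cap, Lx, Ly, Lz);
    // rectangle path for even-indexed planes
    std::vector<std::pair<int,int> > P;
    P.reserve((size_t)L * V);
    for (int v = 0; v < V; ++v) {
      if (v % 2 == 0) for (int u = 0; u < L; ++u) P.push_back(std::make_pair(u, v));
      else            for (int u = L - 1; u >= 0; --u) P.push_back(std::make_pair(u, v));
    }
    int placed = 0, plane = 0;
    int px = 0, py = 0, pz = 0; // previous placed unwrapped coords
    while (placed < N) {
      int yy = 2 * plane;
      if (yy >= Ly) stop("internal error: ran past box while placing chain");
      for (int k = 0; k < (int)P.size() && placed < N; ++k) {
        int idx = (plane % 2 == 0) ? k : (int)P.size() - 1 - k;
        int u = P[idx].first, v = P[idx].second;
        int xx = u + v, zz = u - v; // unwrapped; wrapped via site()
        if (plane > 0 && k == 0 && placed < N) {
          // connector in the odd plane directly between the two plane paths
          x[placed] = xx + 1; y[placed] = yy - 1; z[placed] = zz;
          ++placed;
          if (placed == N) break;
        }
        x[placed] = xx; y[placed] = yy; z[placed] = zz;
        ++placed;
      }
      ++plane;
      (void)px; (void)py; (void)pz;
    }
    for (int i = 0; i < N; ++i) {
      wx[i] = wrapc(x[i], Lx); wy[i] = wrapc(y[i], Ly); wz[i] = wrapc(z[i], Lz);
      int sgrid = site_of(i);
      if (grid[sgrid] != -1) stop("initial configuration self-collision at monomer %d", i);
      grid[sgrid] = i;
      if (i > 0) {
        int dx = x[i] - x[i - 1], dy = y[i] - y[i - 1], dz = z[i] - z[i - 1];
        int ax = std::abs(dx), ay = std::abs(dy), az = std::abs(dz);
        if (!((ax + ay + az == 2) && ax <= 1 && ay <= 1 && az <= 1))
          stop("initial configuration broken bond at monomer %d", i);
      }
    }
  }

  inline bool paired(int a, int b) const {
    for (int k = 0; k < cnt[a]; ++k) if (part[(size_t)a * val + k] == b) return true;
    return false;
  }
  inline void add_pair(int a, int b) {
    part[(size_t)a * val + cnt[a]++] = b;
    part[(size_t)b * val + cnt[b]++] = a;
    ++n_pairs;
  }
  inline void drop_one(int a, int b) {
    for (int k = 0; k < cnt[a]; ++k)
      if (part[(size_t)a * val + k] == b) {
        part[(size_t)a * val + k] = part[(size_t)a * val + --cnt[a]];
        return;
      }
  }
  inline void remove_pair(int a, int b) {
    drop_one(a, b); drop_one(b, a); --n_pairs;
  }

  // Fill free interaction slots of monomer m by scanning its 12 neighbor
  // sites in random order; logged for possible rollback.
  void refill(int m, Xoshiro &rng, bool log) {
    if (cnt[m] >= val || s[m] == 0) return;
    int ord[NB];
    for (int k = 0; k < NB; ++k) ord[k] = k;
    for (int k = NB - 1; k > 0; --k) {
      int j = rng.runif_int(k + 1);
      int tmp = ord[k]; ord[k] = ord[j]; ord[j] = tmp;
    }
    for (int k = 0; k < NB && cnt[m] < val; ++k) {
      const int *o = OFF[ord[k]];
      int g = grid[wsite(foldw(wx[m] + o[0], Lx), foldw(wy[m] + o[1], Ly),
                         foldw(wz[m] + o[2], Lz))];
      if (g >= 0 && g != m && s[g] == 1 && cnt[g] < val && !paired(m, g)) {
        add_pair(m, g);
        if (log) { PairOp op = { m, g, true }; oplog.push_back(op); }
      }
    }
  }

  // TASEP coupling: occupancy changes re-resolve the lists locally.
  void occ_gain(int m, Xoshiro &rng) { refill(m, rng, false); }
  void occ_loss(int m, Xoshiro &rng) {
    int partners[NB];
    int np = cnt[m];
    for (int k = 0; k < np; ++k) partners[k] = part[(size_t)m * val + k];
    for (int k = 0; k < np; ++k) remove_pair(m, partners[k]);
    for (int k = 0; k < np; ++k) refill(partners[k], rng, false);
  }

  double bend_at(int i) const {
    if (i <= 0 || i >= N - 1) return 0.0;
    int b1x = x[i] - x[i - 1], b1y = y[i] - y[i - 1], b1z = z[i] - z[i - 1];
    int b2x = x[i + 1] - x[i], b2y = y[i + 1] - y[i], b2z = z[i + 1] - z[i];
    double c = (b1x * b2x + b1y * b2y + b1z * b2z) / 2.0; // |b| = sqrt(2)
    return kappa * (1.0 - c);
  }
  double bend_window(int m) const {
    return bend_at(m - 1) + bend_at(m) + bend_at(m + 1);
  }

  double total_energy() const {
    double h = 0.0;
    for (int i = 1; i < N - 1; ++i) h += bend_at(i);
    return h + E * (double)n_pairs;
  }

  // One trial move. Returns 1 if accepted.
  int try_move(int m, Xoshiro &rng, bool audit, double *audit_maxerr) {
    // candidate sites keep chain connectivity by construction
    int cx[NB], cy[NB], cz[NB];
    int nc = 0;
    if (m > 0 && m < N - 1) {
      for (int k = 0; k < NB; ++k) {
        int ax = x[m - 1] + OFF[k][0], ay = y[m - 1] + OFF[k][1], az = z[m - 1] + OFF[k][2];
        int dx = x[m + 1] - ax, dy = y[m + 1] - ay, dz = z[m + 1] - az;
        int adx = std::abs(dx), ady = std::abs(dy), adz = std::abs(dz);
        if (adx + ady + adz == 2 && adx <= 1 && ady <= 1 && adz <= 1) {
          if (!(ax == x[m] && ay == y[m] && az == z[m])) {
            cx[nc] = ax; cy[nc] = ay; cz[nc] = az; ++nc;
          }
        }
      }
    } else {
      int nb = (m == 0) ? 1 : N - 2;
      for (int k = 0; k < NB; ++k) {
        int ax = x[nb] + OFF[k][0], ay = y[nb] + OFF[k][1], az = z[nb] + OFF[k][2];
        if (!(ax == x[m] && ay == y[m] && az == z[m])) {
          cx[nc] = ax; cy[nc] = ay; cz[nc] = az; ++nc;
        }
      }
    }
    if (nc == 0) return 0;
    int c = rng.runif_int(nc);
    // wrapped candidate coords from the wrapped current position: the true
    // step is the unwrapped difference, small by construction
    int sx = cx[c] - x[m], sy = cy[c] - y[m], sz = cz[c] - z[m];
    int nwx = wrapc(wx[m] + sx, Lx), nwy = wrapc(wy[m] + sy, Ly),
        nwz = wrapc(wz[m] + sz, Lz);
    int nsite = wsite(nwx, nwy, nwz);
    if (grid[nsite] != -1) return 0; // excluded volume

    double h0 = 0.0;
    if (audit) h0 = total_energy();

    int ox = x[m], oy = y[m], oz = z[m];
    int owx = wx[m], owy = wy[m], owz = wz[m];
    int osite = site_of(m);
    double bend_old = bend_window(m);

    // tentative geometric move
    grid[osite] = -1;
    grid[nsite] = m;
    x[m] = cx[c]; y[m] = cy[c]; z[m] = cz[c];
    wx[m] = nwx; wy[m] = nwy; wz[m] = nwz;
    double dbend = bend_window(m) - bend_old;

    // tentative interaction-list re-resolution (logged)
    double dE = 0.0;
    oplog.clear();
    if (s[m] == 1) {
      int broken[NB], nbk = 0;
      for (int k = cnt[m] - 1; k >= 0; --k) {
        int p = part[(size_t)m * val + k];
        if (!adjacent_mon(m, p)) {
          remove_pair(m, p);
          PairOp op = { m, p, false };
          oplog.push_back(op);
          broken[nbk++] = p;
        }
      }
      for (int k = 0; k < nbk; ++k) refill(broken[k], rng, true);
      refill(m, rng, true);
      long added = 0, removed = 0;
      for (size_t k = 0; k < oplog.size(); ++k)
        if (oplog[k].added) ++added; else ++removed;
      dE = E * (double)(added - removed);
    }

    double dH = dbend + dE;
    bool accept = (dH <= 0.0) || (rng.runif() < std::exp(-dH));
    if (accept) {
      if (audit) {
        double err = std::fabs((total_energy() - h0) - dH);
        if (err > *audit_maxerr) *audit_maxerr = err;
      }
      return 1;
    }
    // rollback in reverse order
    for (int k = (int)oplog.size() - 1; k >= 0; --k) {
      if (oplog[k].added) remove_pair(oplog[k].a, oplog[k].b);
      else add_pair(oplog[k].a, oplog[k].b);
    }
    grid[nsite] = -1;
    x[m] = ox; y[m] = oy; z[m] = oz;
    wx[m] = owx; wy[m] = owy; wz[m] = owz;
    grid[osite] = m;
    return 0;
  }

  void check_invariants() const {
    for (int i = 1; i < N; ++i) {
      int dx = x[i] - x[i - 1], dy = y[i] - y[i - 1], dz = z[i] - z[i - 1];
      int ax = std::abs(dx), ay = std::abs(dy), az = std::abs(dz);
      if (!(ax + ay + az == 2 && ax <= 1 && ay <= 1 && az <= 1))
        stop("invariant violation: bond %d-%d is not a lattice neighbor", i - 1, i);
    }
    for (int i = 0; i < N; ++i)
      if (grid[site(x[i], y[i], z[i])] != i || site(x[i], y[i], z[i]) != site_of(i))
        stop("invariant violation: grid/position mismatch at monomer %d", i);
    long long pairs = 0;
    for (int i = 0; i < N; ++i) {
      if (cnt[i] > val) stop("invariant violation: valency exceeded at %d", i);
      if (cnt[i] > 0 && s[i] == 0)
        stop("invariant violation: unbound monomer %d has partners", i);
      for (int k = 0; k < cnt[i]; ++k) {
        int j = part[(size_t)i * val + k];
        if (j == i) stop("invariant violation: self-pair at %d", i);
        if (s[j] == 0) stop("invariant violation: pair %d-%d with unbound partner", i, j);
        if (!adjacent_mon(i, j))
          stop("invariant violation: pair %d-%d not adjacent", i, j);
        if (!paired(j, i))
          stop("invariant violation: pair %d-%d not symmetric", i, j);
        for (int k2 = k + 1; k2 < cnt[i]; ++k2)
          if (part[(size_t)i * val + k2] == j)
            stop("invariant violation: duplicate pair %d-%d", i, j);
        ++pairs;
      }
    }
    if (pairs != 2 * n_pairs)
      stop("invariant violation: pair count bookkeeping");
  }
};

// occupancy-change callback wiring a gene's TASEP into the polymer lists
struct PolyCB {
  Poly *P;
  Xoshiro *rng;
  int offset; // chain index of the gene's first monomer
  void on_bind(int i) {
    P->s[offset + i] = 1;
    P->occ_gain(offset + i, *rng);
  }
  void on_unbind(int i) {
    P->s[offset + i] = 0;
    P->occ_loss(offset + i, *rng);
  }
  void on_hop(int i) {
    P->s[offset + i] = 0;
    P->occ_loss(offset + i, *rng);
    P->s[offset + i + 1] = 1;
    P->occ_gain(offset + i + 1, *rng);
  }
};

// [[Rcpp::export]]
List polymer_run_cpp(int N, int Lx, int Ly, int Lz,
                     double kappa, double E, int val,
                     IntegerVector gene_start, IntegerVector gene_len,
                     List tasep_probs, List init_occ,
                     double mcs, double burn_in, double snap_every,
                     int rec_start, int rec_len,
                     bool check_inv, bool audit, double seed) {
  if (val < 1 || val > 12) stop("valency must be in [1, 12]");
  Poly P;
  P.alloc(N, Lx, Ly, Lz, val, kappa, E);
  P.build_initial();

  Xoshiro rng((uint64_t)seed);

  int ngene = gene_start.size();
  std::vector<TasepCore> genes(ngene);
  std::vector<PolyCB> cbs(ngene);
  for (int g = 0; g < ngene; ++g) {
    List tp = tasep_probs[g];
    genes[g].init(gene_len[g],
                  as<double>(tp["pa"]), as<double>(tp["pb"]),
                  as<double>(tp["pg"]), as<double>(tp["pg0"]),
                  as<double>(tp["pon"]), as<double>(tp["poff"]),
                  as<bool>(tp["burst"]), as<bool>(tp["start_on"]));
    IntegerVector s0 = init_occ[g];
    if (s0.size() == gene_len[g]) {
      std::vector<int> sv(s0.begin(), s0.end());
      genes[g].set_occupancy(sv, 0.0);
      for (int i = 0; i < gene_len[g]; ++i)
        P.s[gene_start[g] + i] = genes[g].s[i];
    }
    cbs[g].P = &P; cbs[g].rng = &rng; cbs[g].offset = gene_start[g];
  }
  // resolve initial interaction lists in random order
  {
    std::vector<int> ord(N);
    for (int i = 0; i < N; ++i) ord[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = rng.runif_int(i + 1);
      int t = ord[i]; ord[i] = ord[j]; ord[j] = t;
    }
    for (int i = 0; i < N; ++i)
      if (P.s[ord[i]]) P.refill(ord[i], rng, false);
  }

  long long nsteps = (long long)mcs, nburn = (long long)burn_in;
  long long nse = (long long)snap_every;
  long long nsnap = (nsteps - nburn) / nse;
  if (nsnap < 1) stop("schedule yields no snapshots");

  IntegerMatrix pos(nsnap, 3 * rec_len);
  IntegerMatrix occ(nsnap, rec_len);
  NumericVector snap_t(nsnap);
  IntegerMatrix prom(nsnap, ngene);
  IntegerMatrix trains(nsnap, ngene);
  NumericMatrix gdens(nsnap, ngene);
  NumericVector energy(nsnap);

  double audit_maxerr = 0.0;
  long long accepted = 0, attempted = 0;
  long long isnap = 0;

  for (long long t = 0; t < nsteps; ++t) {
    if (t == nburn)
      for (int g = 0; g < ngene; ++g) genes[g].reset_events();
    for (int g = 0; g < ngene; ++g)
      genes[g].sweep(rng, (double)t, cbs[g]);
    for (int k = 0; k < N; ++k) {
      int m = rng.runif_int(N);
      accepted += P.try_move(m, rng, audit, &audit_maxerr);
      ++attempted;
    }
    if (t >= nburn && (t - nburn + 1) % nse == 0 && isnap < nsnap) {
      if (check_inv) P.check_invariants();
      for (int r = 0; r < rec_len; ++r) {
        int m = rec_start + r;
        pos(isnap, 3 * r) = P.x[m];
        pos(isnap, 3 * r + 1) = P.y[m];
        pos(isnap, 3 * r + 2) = P.z[m];
        occ(isnap, r) = P.s[m];
      }
      for (int g = 0; g < ngene; ++g) {
        prom(isnap, g) = genes[g].promoter_on;
        trains(isnap, g) = genes[g].n_trains();
        gdens(isnap, g) = genes[g].density();
      }
      energy[isnap] = P.total_energy();
      snap_t[isnap] = (double)t;
      ++isnap;
    }
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix fpos(N, 3);
  for (int i = 0; i < N; ++i) {
    fpos(i, 0) = P.x[i]; fpos(i, 1) = P.y[i]; fpos(i, 2) = P.z[i];
  }
  List flists(N);
  for (int i = 0; i < N; ++i) {
    IntegerVector li(P.cnt[i]);
    for (int k = 0; k < P.cnt[i]; ++k) li[k] = P.part[(size_t)i * P.val + k] + 1;
    flists[i] = li;
  }
  List tstat(ngene);
  for (int g = 0; g < ngene; ++g)
    tstat[g] = List::create(
      _["n_loads"] = (double)genes[g].n_loads,
      _["n_unloads"] = (double)genes[g].n_unloads,
      _["transit_times"] = wrap(genes[g].transit_times),
      _["unload_times"] = wrap(genes[g].unload_times));

  return List::create(
    _["pos"] = pos,
    _["occ"] = occ,
    _["snap_mcs"] = snap_t,
    _["promoter"] = prom,
    _["trains"] = trains,
    _["gene_density"] = gdens,
    _["energy"] = energy,
    _["final_pos"] = fpos,
    _["final_s"] = wrap(P.s),
    _["final_lists"] = flists,
    _["acceptance"] = (double)accepted / (double)attempted,
    _["audit_maxerr"] = audit_maxerr,
    _["tasep"] = tstat);
}

// Contact counts between recorded monomers, averaged over snapshots: two
// monomers are in contact when they occupy nearest-neighbor FCC sites
// (minimal-image convention). Chain-consecutive monomers are therefore always
// in contact.
// [[Rcpp::export]]
NumericMatrix contacts_from_snapshots_cpp(IntegerMatrix pos, int R,
                                          int Lx, int Ly, int Lz) {
  int nsnap = pos.nrow();
  if (pos.ncol() != 3 * R) stop("pos has wrong shape");
  NumericMatrix M(R, R);
  for (int t = 0; t < nsnap; ++t) {
    for (int i = 0; i < R; ++i) {
      int xi = pos(t, 3 * i), yi = pos(t, 3 * i + 1), zi = pos(t, 3 * i + 2);
      for (int j = i + 1; j < R; ++j) {
        int dx = (xi - pos(t, 3 * j)) % Lx;
        if (dx > Lx / 2) dx -= Lx; else if (dx < -Lx / 2) dx += Lx;
        int dy = (yi - pos(t, 3 * j + 1)) % Ly;
        if (dy > Ly / 2) dy -= Ly; else if (dy < -Ly / 2) dy += Ly;
        int dz = (zi - pos(t, 3 * j + 2)) % Lz;
        if (dz > Lz / 2) dz -= Lz; else if (dz < -Lz / 2) dz += Lz;
        int ax = dx < 0 ? -dx : dx, ay = dy < 0 ? -dy : dy, az = dz < 0 ? -dz : dz;
        if (ax + ay + az == 2 && ax <= 1 && ay <= 1 && az <= 1) {
          M(i, j) += 1.0;
          M(j, i) += 1.0;
        }
      }
    }
  }
  if (nsnap > 0)
    for (int i = 0; i < R; ++i)
      for (int j = 0; j < R; ++j) M(i, j) /= nsnap;
  return M;
}
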