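// Deme-based spatial Moran simulator (2D stepping-stone model).
//
// Dynamics: an individual is chosen at random, weighted by its proliferation
// rate, and replaced by two offspring; each offspring independently migrates
// with probability m to a neighbouring deme; any deme above carrying capacity
// K immediately loses uniformly chosen individuals until it is back at K.
// Mutation is coupled to reproduction of mutation-capable genotypes: a
// division yields a mutated offspring with probability mu.
//
// Exact thinning: a deme that is homogeneous and exactly at capacity only
// changes state through a division that mutates, sends an offspring into a
// non-equivalent deme, or exports both offspring. Such demes are therefore
// scheduled with the marginal rate of those outcomes only, and the outcome is
// sampled conditioned on being one of them. This is an exact reformulation of
// the process (irrelevant events are identity maps on the state), not an
// approximation; it is what makes wave-front simulations with millions of
// individuals tractable.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Fenwick {
  int n;
  std::vector<double> tree;  // 1-indexed
  std::vector<double> w;     // current weights, 0-indexed
  double tot;
  void init(int n_) {
    n = n_;
    tree.assign(n + 1, 0.0);
    w.assign(n, 0.0);
    tot = 0.0;
  }
  void set(int i, double v) {
    double d = v - w[i];
    if (d == 0.0) return;
    w[i] = v;
    tot += d;
    for (int j = i + 1; j <= n; j += j & (-j)) tree[j] += d;
  }
  // largest prefix with cumulative weight <= u
  int sample(double u) const {
    int pos = 0;
    int mask = 1;
    while ((mask << 1) <= n) mask <<= 1;
    for (int k = mask; k > 0; k >>= 1) {
      int nxt = pos + k;
      if (nxt <= n && tree[nxt] <= u) {
        u -= tree[nxt];
        pos = nxt;
      }
    }
    return pos < n ? pos : n - 1;
  }
};

struct Sim {
  // configuration
  int K, W, extent, ndir, n_mig_off;  // n_mig_off: offspring eligible to migrate (1 or 2)
  bool thinning;  // false = simulate every deme explicitly (validation mode)
  double m, mu, stringency, rec_dt;
  double stop_N, stop_T;
  bool fixed_mode, bg_migrates;
  double r_bg, r_wt, r_m_fixed, s_eff, M_cap;
  int max_mut;  // -1 = unlimited

  // genotype records (0 = background/resident, 1 = wildtype invader)
  std::vector<int> parent, nmut, origin_deme;
  std::vector<double> rate, birth_t, origin_dist, birth_Nwt, birth_Ninv;
  std::vector<double> abund, max_abund, fix_time, fix_radius;

  // lattice
  std::vector<std::vector<std::pair<int, int> > > comp;  // (genotype, count)
  std::vector<int> total;
  std::vector<char> active;
  Fenwick FA, FB;

  double t, N_inv;
  bool err_boundary;
  int stop_reason;  // 1 size, 2 time, 3 extinct, 4 boundary

  std::vector<double> rec_t, rec_Ninv, rec_Nwt;

  static const int DX8[8], DY8[8];

  bool on_ring(int i) const {
    int x = i % W, y = i / W;
    return x == 0 || y == 0 || x == W - 1 || y == W - 1;
  }
  int nbr(int i, int dir) const {
    int x = i % W + DX8[dir], y = i / W + DY8[dir];
    if (x < 0 || y < 0 || x >= W || y >= W) return -1;
    return y * W + x;
  }
  bool can_migrate(int g) const { return g == 0 ? bg_migrates : true; }
  bool can_mutate(int g) const {
    return g >= 1 && mu > 0.0 && (max_mut < 0 || nmut[g] < max_mut);
  }

  void init(int seed_invader_geno) {
    W = 2 * extent + 1;
    int n = W * W;
    comp.assign(n, std::vector<std::pair<int, int> >());
    total.assign(n, K);
    active.assign(n, 0);
    FA.init(n);
    FB.init(n);
    t = 0.0;
    N_inv = 0.0;
    err_boundary = false;
    stop_reason = 0;
    for (int i = 0; i < n; ++i) comp[i].push_back(std::make_pair(0, K));
    abund.assign(2, 0.0);
    abund[0] = (double)n * K;
    max_abund = abund;
    for (int i = 0; i < n; ++i) FB.set(i, bulk_weight(i));
    // single invader at the central deme, then immediate capacity death
    int c = (W / 2) * W + W / 2;
    add_indiv(c, seed_invader_geno);
    enforce_capacity(c);
    refresh(c);
    refresh_neighbours(c);
  }

  double deme_rate(int i) const {
    double r = 0.0;
    for (size_t k = 0; k < comp[i].size(); ++k)
      r += comp[i][k].second * rate[comp[i][k].first];
    return r;
  }

  bool equivalent(int j, int g) const {
    return j >= 0 && !active[j] && comp[j].size() == 1 &&
           comp[j][0].first == g;
  }

  double bulk_weight(int i) const {
    if (active[i] || comp[i].size() != 1) return 0.0;
    int g = comp[i][0].first;
    bool mig = can_migrate(g), mut = can_mutate(g);
    if (!mig && !mut) return 0.0;
    double mg = mig ? m : 0.0;
    double mue = mut ? mu : 0.0;
    int nE = 0, nB = 0;
    for (int d = 0; d < ndir; ++d) {
      int j = nbr(i, d);
      if (j < 0) {
        if (g == 0) ++nB;  // background migration off-grid is blocked (stays)
      } else if (equivalent(j, g)) {
        ++nE;
      }
    }
    double p0 = 1.0 - mg + mg * nB / ndir;
    double pE = mg * nE / ndir;
    // a division changes some deme's state only if it mutates, exports an
    // offspring to a non-equivalent deme, or exports both offspring
    double p_irr = n_mig_off == 2
                       ? (1.0 - mue) * (p0 * p0 + 2.0 * p0 * pE)
                       : (1.0 - mue) * (p0 + pE);
    return total[i] * rate[g] * (1.0 - p_irr);
  }

  void refresh(int i) {
    bool act = !thinning || comp[i].size() > 1 || total[i] != K;
    active[i] = act;
    FA.set(i, act ? deme_rate(i) : 0.0);
    FB.set(i, act ? 0.0 : bulk_weight(i));
  }

  void refresh_neighbours(int i) {
    for (int d = 0; d < ndir; ++d) {
      int j = nbr(i, d);
      if (j >= 0 && !active[j]) FB.set(j, bulk_weight(j));
    }
  }

  void add_indiv(int i, int g) {
    std::vector<std::pair<int, int> > &c = comp[i];
    size_t k = 0;
    for (; k < c.size(); ++k)
      if (c[k].first == g) {
        ++c[k].second;
        break;
      }
    if (k == c.size()) c.push_back(std::make_pair(g, 1));
    ++total[i];
    abund[g] += 1.0;
    if (abund[g] > max_abund[g]) max_abund[g] = abund[g];
    if (g >= 1) {
      N_inv += 1.0;
      if (on_ring(i)) err_boundary = true;
    }
  }

  void remove_indiv(int i, int g) {
    std::vector<std::pair<int, int> > &c = comp[i];
    for (size_t k = 0; k < c.size(); ++k)
      if (c[k].first == g) {
        if (--c[k].second == 0) c.erase(c.begin() + k);
        break;
      }
    --total[i];
    abund[g] -= 1.0;
    if (g >= 1) N_inv -= 1.0;
  }

  void enforce_capacity(int i) {
    while (total[i] > K) {
      int pick = (int)(unif_rand() * total[i]);
      if (pick >= total[i]) pick = total[i] - 1;
      int g = -1;
      for (size_t k = 0; k < comp[i].size(); ++k) {
        if (pick < comp[i][k].second) {
          g = comp[i][k].first;
          break;
        }
        pick -= comp[i][k].second;
      }
      remove_indiv(i, g);
    }
  }

  int new_genotype(int g, int deme, double nwt0, double ninv0) {
    double r;
    if (fixed_mode) {
      r = r_m_fixed;
    } else {
      double x = exp_rand();
      r = rate[g] * (1.0 + s_eff * x * (1.0 - rate[g] / M_cap));
      if (r > M_cap) r = M_cap;
    }
    parent.push_back(g);
    nmut.push_back(nmut[g] + 1);
    origin_deme.push_back(deme);
    rate.push_back(r);
    birth_t.push_back(t);
    double dx = deme % W - W / 2, dy = deme / W - W / 2;
    origin_dist.push_back(std::sqrt(dx * dx + dy * dy));
    birth_Nwt.push_back(nwt0);
    birth_Ninv.push_back(ninv0);
    abund.push_back(0.0);
    max_abund.push_back(0.0);
    fix_time.push_back(-1.0);
    fix_radius.push_back(-1.0);
    return (int)parent.size() - 1;
  }

  // destination deme for one offspring of genotype g born in deme i;
  // returns i when the offspring stays (or is blocked at the grid edge)
  int offspring_dest(int i, int g) {
    if (!can_migrate(g) || unif_rand() >= m) return i;
    int dir = (int)(unif_rand() * ndir);
    if (dir >= ndir) dir = ndir - 1;
    int j = nbr(i, dir);
    if (j < 0) {
      if (g == 0) return i;  // blocked
      err_boundary = true;
      return i;
    }
    return j;
  }

  void division(int i, int g, bool mut, int d1, int d2) {
    double nwt0 = abund.size() > 1 ? abund[1] : 0.0;
    double ninv0 = N_inv;
    remove_indiv(i, g);
    int g1 = mut ? new_genotype(g, i, nwt0, ninv0) : g;
    add_indiv(d1, g1);
    add_indiv(d2, g);
    int demes[3] = {i, d1, d2};
    for (int k = 0; k < 3; ++k) {
      bool seen = false;
      for (int q = 0; q < k; ++q) seen = seen || demes[q] == demes[k];
      if (!seen) enforce_capacity(demes[k]);
    }
    for (int k = 0; k < 3; ++k) {
      bool seen = false;
      for (int q = 0; q < k; ++q) seen = seen || demes[q] == demes[k];
      if (!seen) refresh(demes[k]);
    }
    for (int k = 0; k < 3; ++k) {
      bool seen = false;
      for (int q = 0; q < k; ++q) seen = seen || demes[q] == demes[k];
      if (!seen) refresh_neighbours(demes[k]);
    }
  }

  void active_event(int i) {
    double w = FA.w[i];
    if (w <= 0.0) return;
    double u = unif_rand() * w;
    int g = comp[i].back().first;
    for (size_t k = 0; k < comp[i].size(); ++k) {
      double wk = comp[i][k].second * rate[comp[i][k].first];
      if (u < wk) {
        g = comp[i][k].first;
        break;
      }
      u -= wk;
    }
    bool mut = can_mutate(g) && unif_rand() < mu;
    int d1 = offspring_dest(i, g);
    int d2 = n_mig_off == 2 ? offspring_dest(i, g) : i;
    division(i, g, mut, d1, d2);
  }

  // conditional outcome sampling for an inert (thinned) deme
  void bulk_event(int i) {
    if (FB.w[i] <= 0.0 || comp[i].size() != 1) return;
    int g = comp[i][0].first;
    double mg = can_migrate(g) ? m : 0.0;
    double mue = can_mutate(g) ? mu : 0.0;
    // classify directions
    std::vector<int> Edirs, Xdirs;
    int nB = 0;
    for (int d = 0; d < ndir; ++d) {
      int j = nbr(i, d);
      if (j < 0) {
        if (g == 0) ++nB;
        else Xdirs.push_back(d);
      } else if (equivalent(j, g)) {
        Edirs.push_back(d);
      } else {
        Xdirs.push_back(d);
      }
    }
    double p0 = 1.0 - mg + mg * nB / ndir;
    double pE = mg * (double)Edirs.size() / ndir;
    double pX = mg * (double)Xdirs.size() / ndir;
    double w_mut = mue;
    double w_nomut = (1.0 - mue) *
                     (n_mig_off == 2 ? 1.0 - p0 * p0 - 2.0 * p0 * pE : pX);
    bool mut;
    int d1, d2;
    if (unif_rand() * (w_mut + w_nomut) < w_mut) {
      mut = true;  // destinations unconditional
      d1 = offspring_dest(i, g);
      d2 = n_mig_off == 2 ? offspring_dest(i, g) : i;
    } else if (n_mig_off == 1) {
      mut = false;  // conditioned on exporting to a non-equivalent deme
      int pick = (int)(unif_rand() * Xdirs.size());
      if (pick >= (int)Xdirs.size()) pick = (int)Xdirs.size() - 1;
      int j = nbr(i, Xdirs[pick]);
      if (j < 0) {
        err_boundary = true;
        j = i;
      }
      d1 = j;
      d2 = i;
    } else {
      mut = false;
      // ordered destination-class pairs, excluding the no-op set
      // classes: 0 = stay, 1 = equivalent neighbour, 2 = other
      double pc[3] = {p0, pE, pX};
      double wsum = 0.0, wpair[9];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double wv = pc[a] * pc[b];
          if ((a == 0 && b == 0) || (a == 0 && b == 1) || (a == 1 && b == 0))
            wv = 0.0;
          wpair[a * 3 + b] = wv;
          wsum += wv;
        }
      double u = unif_rand() * wsum;
      int sel = 8;
      for (int k = 0; k < 9; ++k) {
        if (u < wpair[k]) {
          sel = k;
          break;
        }
        u -= wpair[k];
      }
      int cls[2] = {sel / 3, sel % 3};
      int dd[2];
      for (int o = 0; o < 2; ++o) {
        if (cls[o] == 0) {
          dd[o] = i;
        } else {
          const std::vector<int> &dirs = cls[o] == 1 ? Edirs : Xdirs;
          int pick = (int)(unif_rand() * dirs.size());
          if (pick >= (int)dirs.size()) pick = (int)dirs.size() - 1;
          int j = nbr(i, dirs[pick]);
          if (j < 0) {  // off-grid target: invader hitting the boundary
            err_boundary = true;
            j = i;
          }
          dd[o] = j;
        }
      }
      d1 = dd[0];
      d2 = dd[1];
    }
    division(i, g, mut, d1, d2);
  }

  void checkpoint(double tc) {
    rec_t.push_back(tc);
    rec_Ninv.push_back(N_inv);
    rec_Nwt.push_back(abund.size() > 1 ? abund[1] : 0.0);
    sweep_scan(tc);
  }

  // clade abundance of each mutation (= all carriers of the mutation that
  // defines genotype g); children always have larger ids than parents
  void clade_abundance(std::vector<double> &cov) const {
    cov = abund;
    for (int g = (int)cov.size() - 1; g >= 2; --g) cov[parent[g]] += cov[g];
  }

  void sweep_scan(double tc) {
    if ((int)abund.size() <= 2 || N_inv <= 0.0) return;
    std::vector<double> cov;
    clade_abundance(cov);
    double need = stringency * N_inv - 1e-9;
    for (size_t g = 2; g < cov.size(); ++g) {
      if (fix_time[g] < 0.0 && cov[g] > 0.0 && cov[g] >= need) {
        fix_time[g] = tc;
        fix_radius[g] = std::sqrt(N_inv / M_PI);
      }
    }
  }

  void run() {
    double next_rec = 0.0;
    checkpoint(0.0);
    next_rec += rec_dt;
    while (true) {
      if (err_boundary) { stop_reason = 4; break; }
      if (N_inv >= stop_N) { stop_reason = 1; break; }
      if (N_inv <= 0.0) { stop_reason = 3; break; }
      double tot = FA.tot + FB.tot;
      if (tot <= 0.0) { stop_reason = 3; break; }
      double dt = exp_rand() / tot;
      if (t + dt >= stop_T) {
        t = stop_T;
        stop_reason = 2;
        break;
      }
      t += dt;
      while (next_rec <= t) {
        checkpoint(next_rec);
        next_rec += rec_dt;
      }
      double u = unif_rand() * tot;
      if (u < FA.tot) {
        active_event(FA.sample(u));
      } else {
        bulk_event(FB.sample(u - FA.tot));
      }
    }
    checkpoint(t);
  }
};

const int Sim::DX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
const int Sim::DY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};

}  // namespace

// [[Rcpp::export(name = ".run_abm_cpp")]]
List run_abm_cpp(int K, double m, double mu, double r_bg, double r_wt,
                 bool fixed_mode, double r_m, double s, double M_cap,
                 int max_mut, double stop_N, double stop_T, int extent,
                 int ndir, double stringency, double record_interval,
                 bool bg_migrates, bool snapshot, int n_mig_off,
                 bool thinning) {
  Sim sim;
  sim.K = K;
  sim.m = m;
  sim.mu = mu;
  sim.extent = extent;
  sim.ndir = ndir;
  sim.n_mig_off = n_mig_off;
  sim.thinning = thinning;
  sim.stringency = stringency;
  sim.rec_dt = record_interval;
  sim.stop_N = stop_N;
  sim.stop_T = stop_T;
  sim.fixed_mode = fixed_mode;
  sim.bg_migrates = bg_migrates;
  sim.r_bg = r_bg;
  sim.r_wt = r_wt;
  sim.r_m_fixed = r_m;
  sim.s_eff = s;
  sim.M_cap = M_cap;
  sim.max_mut = max_mut;

  // genotype 0 = background/resident, genotype 1 = wildtype invader
  sim.parent.assign(2, -1);
  sim.nmut.assign(2, 0);
  sim.origin_deme.assign(2, -1);
  sim.rate.clear();
  sim.rate.push_back(r_bg);
  sim.rate.push_back(r_wt);
  sim.birth_t.assign(2, 0.0);
  sim.origin_dist.assign(2, 0.0);
  sim.birth_Nwt.assign(2, 0.0);
  sim.birth_Ninv.assign(2, 0.0);
  sim.fix_time.assign(2, -1.0);
  sim.fix_radius.assign(2, -1.0);

  sim.init(1);
  sim.run();

  int n_geno = (int)sim.parent.size();
  // final sweep state
  bool sweep = false;
  double sweep_radius = NA_REAL, sweep_time = NA_REAL;
  int n_sweeps = 0;
  if (n_geno > 2 && sim.N_inv > 0) {
    std::vector<double> cov;
    sim.clade_abundance(cov);
    double need = sim.stringency * sim.N_inv - 1e-9;
    for (int g = 2; g < n_geno; ++g) {
      if (sim.fix_time[g] >= 0.0) ++n_sweeps;
      if (cov[g] > 0.0 && cov[g] >= need && sim.fix_time[g] >= 0.0) {
        sweep = true;
        if (!R_finite(sweep_time) || sim.fix_time[g] < sweep_time) {
          sweep_time = sim.fix_time[g];
          sweep_radius = sim.fix_radius[g];
        }
      }
    }
  }

  DataFrame geno = DataFrame::create(
      Named("id") = seq_len(n_geno) - 1,
      Named("parent") = sim.parent,
      Named("n_mutations") = sim.nmut,
      Named("r") = sim.rate,
      Named("birth_time") = sim.birth_t,
      Named("origin_dist_demes") = sim.origin_dist,
      Named("birth_N_wt") = sim.birth_Nwt,
      Named("birth_N_inv") = sim.birth_Ninv,
      Named("abundance") = sim.abund,
      Named("max_abundance") = sim.max_abund,
      Named("fix_time") = sim.fix_time,
      Named("fix_radius") = sim.fix_radius);

  int nr = (int)sim.rec_t.size();
  NumericMatrix series(nr, 3);
  for (int k = 0; k < nr; ++k) {
    series(k, 0) = sim.rec_t[k];
    series(k, 1) = sim.rec_Ninv[k];
    series(k, 2) = sim.rec_Nwt[k];
  }
  colnames(series) = CharacterVector::create("t", "N_inv", "N_wt");

  const char *reasons[] = {"", "size", "time", "extinct", "boundary"};
  List out = List::create(
      Named("stop_reason") = std::string(reasons[sim.stop_reason]),
      Named("t_end") = sim.t,
      Named("N_inv") = sim.N_inv,
      Named("N_wt") = n_geno > 1 ? sim.abund[1] : 0.0,
      Named("sweep") = sweep,
      Named("sweep_radius") = sweep_radius,
      Named("sweep_time") = sweep_time,
      Named("n_sweeps") = n_sweeps,
      Named("genotypes") = geno,
      Named("series") = series);

  if (snapshot) {
    IntegerMatrix snap(sim.W, sim.W);
    for (int i = 0; i < sim.W * sim.W; ++i) {
      int best_g = -1, best_c = 0;
      for (size_t k = 0; k < sim.comp[i].size(); ++k)
        if (sim.comp[i][k].second > best_c) {
          best_c = sim.comp[i][k].second;
          best_g = sim.comp[i][k].first;
        }
      snap(i / sim.W, i % sim.W) = best_g;
    }
    out.push_back(snap, "snapshot");
  }
  return out;
}

// Single-deme Moran fixation experiment: K individuals, one mutant with rate
// r_m against K-1 wildtype at rate r_wt; division (fitness-weighted parent,
// two offspring) followed by a uniform death among the K+1 present.
// [[Rcpp::export(name = ".moran_fix_cpp")]]
int moran_fix_cpp(double r_wt, double r_m, int K, int reps) {
  int fixed = 0;
  for (int rep = 0; rep < reps; ++rep) {
    int i = 1;
    while (i > 0 && i < K) {
      double wm = i * r_m, ww = (K - i) * r_wt;
      int im = i + (unif_rand() * (wm + ww) < wm ? 1 : 0);
      i = im - (unif_rand() * (K + 1) < im ? 1 : 0);
    }
    if (i == K) ++fixed;
  }
  return fixed;
}
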