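// Gibbs sampler over the latent interaction state (Z, X) of every organism.
//
// Each sweep resamples every unordered pair and every protein from its full
// conditional, which multiplies the Bernoulli prior (or homology-transfer
// prior for starred states) with the Y2H, literature and pull-down complex
// factors that contain the variable.  Toggling edge (i, j) can only change
// the 1-/2-step classification of i and j themselves, and only relative to
// baits at distance <= 1 from the opposite endpoint, so the pull-down
// factor update is confined to that small candidate set.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R
// side makes runs exactly reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Org {
  int n = 0;
  long P = 0;
  std::vector<int> z, x;
  // per-pair Y2H evidence, aggregated per parameter group (CSR over pairs)
  std::vector<int> y2h_ptr, y2h_grp, y2h_npos, y2h_nneg;
  // per-protein view of the same records, for X updates
  std::vector<int> xy_ptr, xy_partner, xy_grp, xy_npos, xy_nneg;
  // literature indicators (CSR over pairs)
  std::vector<int> lit_ptr, lit_grp, lit_obs;
  // pull-down complexes
  std::vector<int> cx_bait, cx_grp, cx_ptr, cx_mem;
  std::vector<int> pb_ptr, pb_cx;            // protein -> complex ids
  // homology links into this organism (-1 where absent)
  std::vector<int> sp_link, sx_link;
  // adjacency of the current latent graph (small unsorted neighbour lists)
  std::vector<std::vector<int>> adj;

  inline bool connected(int a, int b) const {
    const std::vector<int>& v = adj[a];
    return std::find(v.begin(), v.end(), b) != v.end();
  }
  inline void add_edge(int a, int b) {
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  inline void drop_edge(int a, int b) {
    auto& va = adj[a];
    va.erase(std::find(va.begin(), va.end(), b));
    auto& vb = adj[b];
    vb.erase(std::find(vb.begin(), vb.end(), a));
  }
  inline bool has_common_neighbour(int a, int b) const {
    const std::vector<int>& sm = (adj[a].size() <= adj[b].size()) ? adj[a]
                                                                  : adj[b];
    int other = (&sm == &adj[a]) ? b : a;
    for (int w : sm)
      if (w != other && connected(other, w)) return true;
    return false;
  }
  inline bool in_complex(int c, int v) const {
    for (int t = cx_ptr[c]; t < cx_ptr[c + 1]; ++t)
      if (cx_mem[t] == v) return true;
    return false;
  }
};

inline long pidx(int n, int i, int j) {  // 0-based, i < j
  return (long)i * n - (long)i * (i + 1) / 2 + (j - i - 1);
}

std::vector<int> iv(const List& L, const char* nm) {
  IntegerVector v = L[nm];
  return std::vector<int>(v.begin(), v.end());
}

struct Model {
  std::vector<Org> orgs;
  // pair transfer links
  std::vector<int> pl_hpair, pl_org, pl_spair;
  std::vector<double> pl_lrz, pl_lrc, pl_lo1, pl_lo0;
  std::vector<int> hp_ptr, hp_link;
  // protein (self-activation) transfer links
  std::vector<int> xl_h, xl_org, xl_star;
  std::vector<double> xl_lrx, xl_lrc, xl_lo1, xl_lo0;
  std::vector<int> xh_ptr, xh_link;
  // group parameter tables
  std::vector<double> y2h_logp;  // [g][z][s][y] flattened, y fastest
  int n_y2h_groups = 0;
  std::vector<double> lit_llr1, lit_llr0;
  NumericMatrix mpc_logs;        // rows: group; cols: lp1,l1m,lp2,l2m,lbg
  double logit_rho = 0, logit_r = 0;

  inline double ylp(int g, int z, int s, int y) const {
    return y2h_logp[((g * 2 + z) * 3 + s) * 2 + y];
  }
  inline double mpc_w(int g, int cls, bool mem) const {
    if (cls == 1) return mem ? mpc_logs(g, 0) : mpc_logs(g, 1);
    if (cls == 2) return mem ? mpc_logs(g, 2) : mpc_logs(g, 3);
    return mem ? mpc_logs(g, 4) : 0.0;
  }
};

// log-likelihood change of bait k's complexes when the class of v improves
// from its current value to c1 (1 when k is an endpoint of the toggled
// edge, otherwise 2); the toggled edge is absent from the adjacency
double bait_terms(const Org& O, const Model& M, int k, int v, int c1) {
  int c0;
  if (O.connected(k, v)) c0 = 1;
  else if (O.has_common_neighbour(k, v)) c0 = 2;
  else c0 = 3;
  if (c1 >= c0) return 0.0;
  double d = 0.0;
  for (int t = O.pb_ptr[k]; t < O.pb_ptr[k + 1]; ++t) {
    int c = O.pb_cx[t], g = O.cx_grp[c];
    bool mem = O.in_complex(c, v);
    d += M.mpc_w(g, c1, mem) - M.mpc_w(g, c0, mem);
  }
  return d;
}

// Total pull-down log-likelihood change when edge (i, j) goes from absent
// to present (the edge must currently be absent from O.adj).  A path of
// length <= 2 through the new edge either starts at it (bait endpoint a:
// the other endpoint becomes 1-step, the other endpoint's neighbours
// become 2-step) or ends at it (bait adjacent to a: the other endpoint
// becomes 2-step) - no other bait/protein classification can change.
double mpc_delta(const Org& O, const Model& M, int i, int j) {
  if (O.cx_bait.empty()) return 0.0;
  double d = 0.0;
  int ends[2] = {i, j};
  for (int t = 0; t < 2; ++t) {
    int a = ends[t], v = ends[1 - t];
    if (O.pb_ptr[a + 1] > O.pb_ptr[a]) {         // bait at an endpoint
      d += bait_terms(O, M, a, v, 1);
      for (int w : O.adj[v])                     // v's neighbours: 2-step
        if (w != a) d += bait_terms(O, M, a, w, 2);
    }
    for (int u : O.adj[a]) {                     // baits one step away
      if (u == v) continue;
      if (O.pb_ptr[u + 1] > O.pb_ptr[u])
        d += bait_terms(O, M, u, v, 2);
    }
  }
  return d;
}

inline double sigmoid(double lo) {
  if (lo > 0) return 1.0 / (1.0 + std::exp(-lo));
  double e = std::exp(lo);
  return e / (1.0 + e);
}

void sweep(Model& M) {
  int G = (int)M.orgs.size();
  for (int o = 0; o < G; ++o) {
    Org& O = M.orgs[o];
    bool has_cx = !O.cx_bait.empty();
    // --- pairs ---
    long p = 0;
    for (int i = 0; i < O.n - 1; ++i) {
      for (int j = i + 1; j < O.n; ++j, ++p) {
        // detach the edge so mpc_delta sees the baseline graph
        if (O.z[p] == 1) O.drop_edge(i, j);
        double lo;
        if (o == 0) {
          lo = M.logit_rho;
        } else {
          int l = O.sp_link[p];
          if (l >= 0) {
            int zh = M.orgs[0].z[M.pl_hpair[l]];
            lo = zh ? M.pl_lo1[l] : M.pl_lo0[l];
          } else lo = M.logit_rho;
        }
        if (O.y2h_ptr[p + 1] > O.y2h_ptr[p]) {
          int s = O.x[i] + O.x[j];
          for (int t = O.y2h_ptr[p]; t < O.y2h_ptr[p + 1]; ++t) {
            int g = O.y2h_grp[t];
            lo += O.y2h_npos[t] * (M.ylp(g, 1, s, 1) - M.ylp(g, 0, s, 1)) +
                  O.y2h_nneg[t] * (M.ylp(g, 1, s, 0) - M.ylp(g, 0, s, 0));
          }
        }
        for (int t = O.lit_ptr[p]; t < O.lit_ptr[p + 1]; ++t) {
          int g = O.lit_grp[t];
          lo += O.lit_obs[t] ? M.lit_llr1[g] : M.lit_llr0[g];
        }
        if (o == 0 && !M.pl_hpair.empty()) {
          for (int t = M.hp_ptr[p]; t < M.hp_ptr[p + 1]; ++t) {
            int l = M.hp_link[t];
            int zs = M.orgs[M.pl_org[l]].z[M.pl_spair[l]];
            lo += zs ? M.pl_lrz[l] : M.pl_lrc[l];
          }
        }
        if (has_cx) lo += mpc_delta(O, M, i, j);
        int znew = (unif_rand() < sigmoid(lo)) ? 1 : 0;
        O.z[p] = znew;
        if (znew == 1) O.add_edge(i, j);
      }
    }
    // --- proteins ---
    for (int i = 0; i < O.n; ++i) {
      double lo;
      if (o == 0) {
        lo = M.logit_r;
        if (!M.xl_h.empty()) {
          for (int t = M.xh_ptr[i]; t < M.xh_ptr[i + 1]; ++t) {
            int l = M.xh_link[t];
            int xs = M.orgs[M.xl_org[l]].x[M.xl_star[l]];
            lo += xs ? M.xl_lrx[l] : M.xl_lrc[l];
          }
        }
      } else {
        int l = O.sx_link[i];
        if (l >= 0) {
          int xh = M.orgs[0].x[M.xl_h[l]];
          lo = xh ? M.xl_lo1[l] : M.xl_lo0[l];
        } else lo = M.logit_r;
      }
      for (int t = O.xy_ptr[i]; t < O.xy_ptr[i + 1]; ++t) {
        int q = O.xy_partner[t], g = O.xy_grp[t];
        long pq = (i < q) ? pidx(O.n, i, q) : pidx(O.n, q, i);
        int z = O.z[pq], sq = O.x[q];
        lo += O.xy_npos[t] * (M.ylp(g, z, 1 + sq, 1) - M.ylp(g, z, sq, 1)) +
              O.xy_nneg[t] * (M.ylp(g, z, 1 + sq, 0) - M.ylp(g, z, sq, 0));
      }
      O.x[i] = (unif_rand() < sigmoid(lo)) ? 1 : 0;
    }
  }
}

struct Stats {
  std::vector<double> zsum, xsum;       // human
  std::vector<double> y2h_tab;          // [g][z][s][y], y fastest
  std::vector<double> lit;              // [g] x (z, z&obs, 1-z, (1-z)&obs)
  std::vector<double> mpc;              // [g] x (cap1, miss1, cap2, miss2)
  double tr_pair[4] = {0, 0, 0, 0};     // z, z&zs, 1-z, (1-z)&zs
  double tr_x[4] = {0, 0, 0, 0};
};

void accumulate(const Model& M, Stats& S) {
  const Org& H = M.orgs[0];
  for (long p = 0; p < H.P; ++p) S.zsum[p] += H.z[p];
  for (int i = 0; i < H.n; ++i) S.xsum[i] += H.x[i];
  std::vector<char> mark;
  for (size_t o = 0; o < M.orgs.size(); ++o) {
    const Org& O = M.orgs[o];
    long p = 0;
    for (int i = 0; i < O.n - 1; ++i) {
      for (int j = i + 1; j < O.n; ++j, ++p) {
        int z = O.z[p];
        if (O.y2h_ptr[p + 1] > O.y2h_ptr[p]) {
          int s = O.x[i] + O.x[j];
          for (int t = O.y2h_ptr[p]; t < O.y2h_ptr[p + 1]; ++t) {
            int g = O.y2h_grp[t];
            S.y2h_tab[((g * 2 + z) * 3 + s) * 2 + 1] += O.y2h_npos[t];
            S.y2h_tab[((g * 2 + z) * 3 + s) * 2 + 0] += O.y2h_nneg[t];
          }
        }
        for (int t = O.lit_ptr[p]; t < O.lit_ptr[p + 1]; ++t) {
          int g = O.lit_grp[t];
          S.lit[g * 4 + (z ? 0 : 2)] += 1;
          if (O.lit_obs[t]) S.lit[g * 4 + (z ? 1 : 3)] += 1;
        }
      }
    }
    // pull-down capture counts at the current graph
    mark.assign(O.n, 0);
    for (size_t c = 0; c < O.cx_bait.size(); ++c) {
      int k = O.cx_bait[c], g = O.cx_grp[c];
      for (int u : O.adj[k]) mark[u] = 1;
      mark[k] = 1;
      for (int u : O.adj[k])
        S.mpc[g * 4 + (O.in_complex(c, u) ? 0 : 1)] += 1;
      std::vector<int> n2;
      for (int u : O.adj[k])
        for (int w : O.adj[u])
          if (!mark[w]) { mark[w] = 2; n2.push_back(w); }
      for (int w : n2)
        S.mpc[g * 4 + (O.in_complex(c, w) ? 2 : 3)] += 1;
      for (int u : O.adj[k]) mark[u] = 0;
      mark[k] = 0;
      for (int w : n2) mark[w] = 0;
    }
  }
  for (size_t l = 0; l < M.pl_hpair.size(); ++l) {
    int zh = M.orgs[0].z[M.pl_hpair[l]];
    int zs = M.orgs[M.pl_org[l]].z[M.pl_spair[l]];
    S.tr_pair[zh ? 0 : 2] += 1;
    if (zs) S.tr_pair[zh ? 1 : 3] += 1;
  }
  for (size_t l = 0; l < M.xl_h.size(); ++l) {
    int xh = M.orgs[0].x[M.xl_h[l]];
    int xs = M.orgs[M.xl_org[l]].x[M.xl_star[l]];
    S.tr_x[xh ? 0 : 2] += 1;
    if (xs) S.tr_x[xh ? 1 : 3] += 1;
  }
}

Org unpack_org(const List& L) {
  Org O;
  O.n = as<int>(L["n"]);
  O.z = iv(L, "z"); O.x = iv(L, "x");
  O.P = (long)O.z.size();
  O.y2h_ptr = iv(L, "y2h_ptr"); O.y2h_grp = iv(L, "y2h_grp");
  O.y2h_npos = iv(L, "y2h_npos"); O.y2h_nneg = iv(L, "y2h_nneg");
  O.xy_ptr = iv(L, "xy_ptr"); O.xy_partner = iv(L, "xy_partner");
  O.xy_grp = iv(L, "xy_grp"); O.xy_npos = iv(L, "xy_npos");
  O.xy_nneg = iv(L, "xy_nneg");
  O.lit_ptr = iv(L, "lit_ptr"); O.lit_grp = iv(L, "lit_grp");
  O.lit_obs = iv(L, "lit_obs");
  O.cx_bait = iv(L, "cx_bait"); O.cx_grp = iv(L, "cx_grp");
  O.cx_ptr = iv(L, "cx_ptr"); O.cx_mem = iv(L, "cx_mem");
  O.pb_ptr = iv(L, "pb_ptr"); O.pb_cx = iv(L, "pb_cx");
  O.sp_link = iv(L, "sp_link"); O.sx_link = iv(L, "sx_link");
  O.adj.assign(O.n, {});
  long p = 0;
  for (int i = 0; i < O.n - 1; ++i)
    for (int j = i + 1; j < O.n; ++j, ++p)
      if (O.z[p]) O.add_edge(i, j);
  return O;
}

}  // namespace

// [[Rcpp::export]]
List gibbs_run_cpp(List pd, int n_burnin, int n_samples) {
  Model M;
  List orgs = pd["orgs"];
  for (int o = 0; o < orgs.size(); ++o)
    M.orgs.push_back(unpack_org(orgs[o]));

  List lp = pd["links_pair"];
  M.pl_hpair = iv(lp, "hpair"); M.pl_org = iv(lp, "org");
  M.pl_spair = iv(lp, "spair");
  {
    NumericVector a = lp["lr_z"], b = lp["lr_c"], c = lp["lo1"], d = lp["lo0"];
    M.pl_lrz.assign(a.begin(), a.end()); M.pl_lrc.assign(b.begin(), b.end());
    M.pl_lo1.assign(c.begin(), c.end()); M.pl_lo0.assign(d.begin(), d.end());
  }
  M.hp_ptr = iv(lp, "hp_ptr"); M.hp_link = iv(lp, "hp_link");

  List lx = pd["links_x"];
  M.xl_h = iv(lx, "h"); M.xl_org = iv(lx, "org"); M.xl_star = iv(lx, "star");
  {
    NumericVector a = lx["lr_x"], b = lx["lr_c"], c = lx["lo1"], d = lx["lo0"];
    M.xl_lrx.assign(a.begin(), a.end()); M.xl_lrc.assign(b.begin(), b.end());
    M.xl_lo1.assign(c.begin(), c.end()); M.xl_lo0.assign(d.begin(), d.end());
  }
  M.xh_ptr = iv(lx, "xh_ptr"); M.xh_link = iv(lx, "xh_link");

  NumericVector ylp = pd["y2h_logp"];
  M.y2h_logp.assign(ylp.begin(), ylp.end());
  M.n_y2h_groups = as<int>(pd["n_y2h_groups"]);
  NumericVector l1 = pd["lit_llr1"], l0 = pd["lit_llr0"];
  M.lit_llr1.assign(l1.begin(), l1.end());
  M.lit_llr0.assign(l0.begin(), l0.end());
  M.mpc_logs = as<NumericMatrix>(pd["mpc_logs"]);
  M.logit_rho = as<double>(pd["logit_rho"]);
  M.logit_r = as<double>(pd["logit_r"]);

  int n_lit_groups = (int)M.lit_llr1.size();
  int n_mpc_groups = M.mpc_logs.nrow();

  Stats S;
  S.zsum.assign(M.orgs[0].P, 0.0);
  S.xsum.assign(M.orgs[0].n, 0.0);
  S.y2h_tab.assign((size_t)M.n_y2h_groups * 12, 0.0);
  S.lit.assign((size_t)std::max(n_lit_groups, 1) * 4, 0.0);
  S.mpc.assign((size_t)std::max(n_mpc_groups, 1) * 4, 0.0);

  for (int it = 0; it < n_burnin; ++it) sweep(M);
  for (int it = 0; it < n_samples; ++it) {
    sweep(M);
    accumulate(M, S);
  }

  List final_state(M.orgs.size());
  for (size_t o = 0; o < M.orgs.size(); ++o) {
    final_state[o] = List::create(_["z"] = wrap(M.orgs[o].z),
                                  _["x"] = wrap(M.orgs[o].x));
  }
  return List::create(
    _["zsum"] = wrap(S.zsum), _["xsum"] = wrap(S.xsum),
    _["y2h_tab"] = wrap(S.y2h_tab), _["lit"] = wrap(S.lit),
    _["mpc"] = wrap(S.mpc),
    _["tr_pair"] = NumericVector::create(S.tr_pair[0], S.tr_pair[1],
                                         S.tr_pair[2], S.tr_pair[3]),
    _["tr_x"] = NumericVector::create(S.tr_x[0], S.tr_x[1],
                                      S.tr_x[2], S.tr_x[3]),
    _["final_state"] = final_state, _["n_samples"] = n_samples);
}
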