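// Exact SSA core for the mitochondrial quality-control model.
//
// One cell = a fixed compartment graph plus a dynamic population of
// mitochondria.  Each mitochondrion is an ordered chain of subcompartments
// (nucleoid pools inherited from past fusions) holding wild-type (W) and
// mutant (M) nucleoid counts.  Reaction channels:
//   replication : one nucleoid copied in place (per-nucleoid propensity,
//                 retrograde-amplified, mutant channels scaled by k_R)
//   mitophagy   : whole-mitochondrion removal (selectivity on R_M^mito)
//   fusion      : pairwise, same/adjacent compartments only, selectivity
//                 factor r() per partner; donor chain appended to acceptor
//   fission     : cut at a random fission site with Binomial(1/2) exchange
//                 across the cut, or a uniform split for single-
//                 subcompartment mitochondria; one daughter may be
//                 displaced to a neighboring compartment
//
// All randomness comes from R's RNG so set.seed() gives bit reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double K_D, K_fusion, K_R, m;
  double k_D, r_D_max;
  double a_R0, r_R_max, k_R, N_ss;
  double a_fusion0, r_fusion_max;
  double V_F_max, K_F, n_hill;
  double ff_scale;
};

Params params_from_list(const List& p) {
  Params q;
  q.K_D          = as<double>(p["K_D"]);
  q.K_fusion     = as<double>(p["K_fusion"]);
  q.K_R          = as<double>(p["K_R"]);
  q.m            = as<double>(p["m"]);
  q.k_D          = as<double>(p["k_D"]);
  q.r_D_max      = as<double>(p["r_D_max"]);
  q.a_R0         = as<double>(p["a_R0"]);
  q.r_R_max      = as<double>(p["r_R_max"]);
  q.k_R          = as<double>(p["k_R"]);
  q.N_ss         = as<double>(p["N_ss"]);
  q.a_fusion0    = as<double>(p["a_fusion0"]);
  q.r_fusion_max = as<double>(p["r_fusion_max"]);
  q.V_F_max      = as<double>(p["V_F_max"]);
  q.K_F          = as<double>(p["K_F"]);
  q.n_hill       = as<double>(p["n"]);
  q.ff_scale     = as<double>(p["ff_scale"]);
  return q;
}

// OXPHOS defect s(R) = R^m / (K^m + R^m); s(0) = 0, s(K) = 1/2.
inline double defect(double R, double K, double m) {
  if (R <= 0.0) return 0.0;
  double num = std::pow(R, m);
  return num / (std::pow(K, m) + num);
}

struct Mito {
  std::vector<int> W, M;  // per-subcompartment counts, chain order
  int comp;               // compartment index, 0-based
  int pos;                // position in the engine's compartment member list
  long id;
  // cached derived quantities
  int nW, nM;
  double R;        // mutant fraction M/(W+M)
  double r_sel;    // fusion selectivity factor r(R)
  double a_fis;    // fission propensity (ff_scale applied)
  double a_mph;    // mitophagy propensity
  // episode bookkeeping
  bool rich;
  double rich_start;
};

struct Cell {
  int n_comp;
  std::vector< std::vector<int> > adj;  // 0-based neighbor lists
  std::vector<Mito> mitos;
  double t;
  long next_id;
};

void refresh(Mito& m, const Params& p) {
  m.nW = 0; m.nM = 0;
  for (size_t k = 0; k < m.W.size(); ++k) { m.nW += m.W[k]; m.nM += m.M[k]; }
  int tot = m.nW + m.nM;
  m.R = (tot > 0) ? (double)m.nM / tot : 0.0;
  m.r_sel = 1.0 - p.r_fusion_max * defect(m.R, p.K_fusion, p.m);
  m.a_mph = p.k_D * (p.r_D_max * defect(m.R, p.K_D, p.m) + 1.0);
  if (tot >= 2) {
    double tn = std::pow((double)tot, p.n_hill);
    m.a_fis = p.ff_scale * p.V_F_max * tn / (std::pow(p.K_F, p.n_hill) + tn);
  } else {
    m.a_fis = 0.0;  // both fission daughters must hold >= 1 nucleoid
  }
}

Cell cell_from_r(const List& state, const Params& p) {
  Cell c;
  List graph = state["graph"];
  c.n_comp = as<int>(graph["n_compartments"]);
  List adj = graph["adjacency"];
  if ((int)adj.size() != c.n_comp)
    stop("adjacency list length does not match n_compartments");
  c.adj.resize(c.n_comp);
  for (int i = 0; i < c.n_comp; ++i) {
    IntegerVector nb = adj[i];
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;
      if (j < 0 || j >= c.n_comp) stop("adjacency index out of range");
      if (j == i) stop("adjacency must be irreflexive");
      c.adj[i].push_back(j);
    }
  }
  c.t = as<double>(state["t"]);
  List mitos = state["mitochondria"];
  c.next_id = 1;
  for (int i = 0; i < mitos.size(); ++i) {
    List ml = mitos[i];
    Mito m;
    IntegerVector W = ml["W"], M = ml["M"];
    if (W.size() != M.size() || W.size() < 1)
      stop("mitochondrion chain must hold matched W/M vectors of length >= 1");
    m.W.assign(W.begin(), W.end());
    m.M.assign(M.begin(), M.end());
    for (size_t k = 0; k < m.W.size(); ++k)
      if (m.W[k] < 0 || m.M[k] < 0) stop("negative nucleoid count");
    m.comp = as<int>(ml["compartment"]) - 1;
    m.pos = 0;
    if (m.comp < 0 || m.comp >= c.n_comp)
      stop("mitochondrion compartment index out of range");
    m.id = ml.containsElementNamed("id") ? as<long>(ml["id"]) : (long)(i + 1);
    if (m.id >= c.next_id) c.next_id = m.id + 1;
    m.rich = false; m.rich_start = 0.0;
    refresh(m, p);
    if (m.nW + m.nM < 1) stop("empty mitochondrion in population");
    c.mitos.push_back(m);
  }
  return c;
}

List cell_to_r(const Cell& c) {
  List mitos(c.mitos.size());
  for (size_t i = 0; i < c.mitos.size(); ++i) {
    const Mito& m = c.mitos[i];
    mitos[i] = List::create(
      _["W"] = IntegerVector(m.W.begin(), m.W.end()),
      _["M"] = IntegerVector(m.M.begin(), m.M.end()),
      _["compartment"] = m.comp + 1,
      _["id"] = (double)m.id);
  }
  List adj(c.n_comp);
  for (int i = 0; i < c.n_comp; ++i) {
    IntegerVector nb(c.adj[i].size());
    for (size_t k = 0; k < c.adj[i].size(); ++k) nb[k] = c.adj[i][k] + 1;
    adj[i] = nb;
  }
  List graph = List::create(_["n_compartments"] = c.n_comp,
                            _["adjacency"] = adj);
  List out = List::create(_["graph"] = graph,
                          _["mitochondria"] = mitos,
                          _["t"] = c.t);
  out.attr("class") = "cell_state";
  return out;
}

// ---- event mechanics (shared by the engine and the exported wrappers) ----

struct EpisodeLog {
  bool on;
  double threshold;
  std::vector<double> start, end;
  std::vector<int> censored;
  int n_starts;
  EpisodeLog() : on(false), threshold(1.0), n_starts(0) {}
  void open(Mito& m, double t) {
    if (!on) return;
    if (!m.rich && m.R > threshold) { m.rich = true; m.rich_start = t; ++n_starts; }
  }
  void close_if_rich(Mito& m, double t) {
    if (!on || !m.rich) return;
    start.push_back(m.rich_start); end.push_back(t); censored.push_back(0);
    m.rich = false;
  }
  void update(Mito& m, double t) {
    if (!on) return;
    if (m.rich && m.R <= threshold) close_if_rich(m, t);
    else if (!m.rich && m.R > threshold) open(m, t);
  }
  void finalize(Cell& c, double t) {
    if (!on) return;
    for (size_t i = 0; i < c.mitos.size(); ++i) {
      Mito& m = c.mitos[i];
      if (m.rich) {
        start.push_back(m.rich_start); end.push_back(t); censored.push_back(1);
        m.rich = false;
      }
    }
  }
};

void do_replication(Cell& c, const Params& p, int mi, int sub, bool mutant,
                    EpisodeLog& ep) {
  Mito& m = c.mitos[mi];
  if (mutant) m.M[sub] += 1; else m.W[sub] += 1;
  refresh(m, p);
  ep.update(m, c.t);
}

void do_mitophagy(Cell& c, int mi, EpisodeLog& ep) {
  ep.close_if_rich(c.mitos[mi], c.t);
  c.mitos[mi] = c.mitos.back();
  c.mitos.pop_back();
}

// donor's chain is appended to the acceptor; merged entity keeps the
// acceptor's compartment and id; the junction becomes a new fission site.
// Merge only: the caller removes the donor slot.
void do_fusion_merge(Cell& c, const Params& p, int ai, int di, EpisodeLog& ep) {
  if (ai == di) stop("a mitochondrion cannot fuse with itself");
  Mito& a = c.mitos[ai];
  Mito& d = c.mitos[di];
  ep.close_if_rich(a, c.t);
  ep.close_if_rich(d, c.t);
  a.W.insert(a.W.end(), d.W.begin(), d.W.end());
  a.M.insert(a.M.end(), d.M.begin(), d.M.end());
  refresh(a, p);
  ep.open(a, c.t);
}

void do_fusion(Cell& c, const Params& p, int ai, int di, EpisodeLog& ep) {
  do_fusion_merge(c, p, ai, di, ep);
  // swap-pop removal of the donor; keep indices coherent
  int last = (int)c.mitos.size() - 1;
  if (di != last) c.mitos[di] = c.mitos[last];
  c.mitos.pop_back();
}

// Fission of mitochondrion mi.  Chains with >1 subcompartment are cut at a
// uniformly chosen fission site after a Binomial(1/2) exchange of the two
// adjacent pools (redrawn until both daughters hold >= 1 nucleoid).  Chains
// of length 1 are split by a uniform cut with hypergeometric identity
// assignment.  One daughter keeps the parent's compartment and id; the
// other is displaced uniformly over {original} + neighbors.
void do_fission(Cell& c, const Params& p, int mi, EpisodeLog& ep) {
  Mito parent = c.mitos[mi];  // copy; we will overwrite + append
  int L = (int)parent.W.size();
  if (parent.nW + parent.nM < 2)
    stop("cannot fission a mitochondrion with fewer than 2 nucleoids");
  Mito left, right;
  if (L > 1) {
    // a site is feasible when a non-empty split has positive probability:
    // each flank must be able to end up with >= 1 nucleoid (its untouched
    // rest plus the exchanged pool).  Chains may hold zero-count
    // subcompartments, so some sites can be strictly infeasible; at least
    // one feasible site always exists when the total is >= 2.
    std::vector<long> pre(L + 1, 0);
    for (int k = 0; k < L; ++k)
      pre[k + 1] = pre[k] + parent.W[k] + parent.M[k];
    std::vector<int> feasible;
    for (int s = 0; s < L - 1; ++s) {
      long pool = (long)parent.W[s] + parent.M[s] +
                  parent.W[s + 1] + parent.M[s + 1];
      long lrest = pre[s];              // subcompartments 0..s-1
      long rrest = pre[L] - pre[s + 2]; // subcompartments s+2..L-1
      if (lrest + pool >= 1 && rrest + pool >= 1) feasible.push_back(s);
    }
    if (feasible.empty())
      stop("internal error: no feasible fission site");  // unreachable
    int pick = (int)(unif_rand() * feasible.size());
    if (pick >= (int)feasible.size()) pick = (int)feasible.size() - 1;
    int site = feasible[pick];
    int Wp = parent.W[site] + parent.W[site + 1];
    int Mp = parent.M[site] + parent.M[site + 1];
    long left_rest = pre[site];
    long right_rest = pre[L] - pre[site + 2];
    int wL, mL;
    for (;;) {  // redraw the exchange only, until both daughters non-empty
      wL = (int) R::rbinom((double)Wp, 0.5);
      mL = (int) R::rbinom((double)Mp, 0.5);
      long lt = left_rest + wL + mL;
      long rt = right_rest + (Wp - wL) + (Mp - mL);
      if (lt >= 1 && rt >= 1) break;
    }
    left.W.assign(parent.W.begin(), parent.W.begin() + site + 1);
    left.M.assign(parent.M.begin(), parent.M.begin() + site + 1);
    left.W[site] = wL; left.M[site] = mL;
    right.W.assign(parent.W.begin() + site + 1, parent.W.end());
    right.M.assign(parent.M.begin() + site + 1, parent.M.end());
    right.W[0] = Wp - wL; right.M[0] = Mp - mL;
  } else {
    int T = parent.nW + parent.nM;
    int kL = 1 + (int)(unif_rand() * (T - 1));  // uniform on 1..T-1
    if (kL > T - 1) kL = T - 1;
    int mL = (int) R::rhyper((double)parent.nM, (double)parent.nW, (double)kL);
    left.W.assign(1, kL - mL); left.M.assign(1, mL);
    right.W.assign(1, parent.nW - (kL - mL));
    right.M.assign(1, parent.nM - mL);
  }
  // placement: one daughter stays put (keeps parent id); the displaced one
  // goes to a destination uniform over {original compartment} + neighbors.
  bool displace_left = unif_rand() < 0.5;
  const std::vector<int>& nb = c.adj[parent.comp];
  int pick = (int)(unif_rand() * (1 + nb.size()));
  if (pick > (int)nb.size()) pick = (int)nb.size();
  int dest = (pick == 0) ? parent.comp : nb[pick - 1];
  Mito& stay = displace_left ? right : left;
  Mito& move = displace_left ? left : right;
  stay.comp = parent.comp; stay.id = parent.id; stay.pos = parent.pos;
  stay.rich = parent.rich; stay.rich_start = parent.rich_start;
  move.comp = dest; move.id = c.next_id++; move.pos = 0;
  move.rich = false;
  refresh(stay, p); refresh(move, p);
  c.mitos[mi] = stay;
  ep.update(c.mitos[mi], c.t);
  c.mitos.push_back(move);
  ep.open(c.mitos.back(), c.t);
}

// member weights used by the engine's two-level channel selection
inline double w_mph(const Mito& m) { return m.a_mph; }
inline double w_fis(const Mito& m) { return m.a_fis; }
inline double w_nW(const Mito& m) { return (double)m.nW; }
inline double w_nM(const Mito& m) { return (double)m.nM; }

}  // namespace

//' @useDynLib mitoqc, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".mqc_run_cell")]]
List mqc_run_cell(List state, List params, LogicalVector channels,
                  double t_end, NumericVector record,
                  double episode_threshold = -1.0,
                  double max_events = 1e9,
                  bool stop_at_homoplasmy = false) {
  Params p = params_from_list(params);
  Cell c = cell_from_r(state, p);
  bool ch_rep = channels[0], ch_mph = channels[1],
       ch_fus = channels[2], ch_fis = channels[3];

  EpisodeLog ep;
  if (episode_threshold > 0) {
    ep.on = true;
    ep.threshold = episode_threshold;
    for (size_t i = 0; i < c.mitos.size(); ++i) ep.open(c.mitos[i], c.t);
  }

  int n_rec = record.size();
  NumericMatrix snap(n_rec, 6);
  std::fill(snap.begin(), snap.end(), NA_REAL);
  int ri = 0;

  std::vector<double> S(c.n_comp), Q(c.n_comp);
  double mito_days = 0.0;
  double counts[4] = {0, 0, 0, 0};
  double n_events = 0.0;
  bool terminated = false, absorbed = false, hit_max = false;

  // snapshot of the current state into row r (time column set by caller loop)
  auto take_snapshot = [&](int r, double at) {
    int n = (int)c.mitos.size();
    snap(r, 0) = at;
    if (n == 0) return;  // leave NA: terminated-empty
    long sw = 0, sm = 0; double sR = 0.0;
    for (int i = 0; i < n; ++i) {
      sw += c.mitos[i].nW; sm += c.mitos[i].nM; sR += c.mitos[i].R;
    }
    double rbar = sR / n;
    double var = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = c.mitos[i].R - rbar; var += d * d;
    }
    var /= n;  // population variance
    snap(r, 1) = (sw + sm > 0) ? (double)sm / (sw + sm) : NA_REAL;
    snap(r, 2) = n;
    snap(r, 3) = (double)(sw + sm);
    snap(r, 4) = rbar;
    snap(r, 5) = (n >= 2 && rbar > 0) ? std::sqrt(var) / rbar : NA_REAL;
  };

  // Running sums over the population and per compartment, updated
  // incrementally around each event and rebuilt exactly every 2^16 events
  // to wash floating-point drift.  Per-compartment member lists make every
  // channel selection O(n_compartments + compartment occupancy) instead of
  // O(population), which matters when retrograde upregulation grows the
  // population by an order of magnitude.
  long sumW = 0, sumM = 0;
  double sumR = 0.0, A_mph = 0.0, A_fis = 0.0;
  std::vector<double> SD(c.n_comp), SF(c.n_comp), CW(c.n_comp), CM(c.n_comp);
  std::vector< std::vector<int> > mem(c.n_comp);
  auto acc = [&](int i, double sg) {
    const Mito& m = c.mitos[i];
    sumW += (long)(sg * m.nW); sumM += (long)(sg * m.nM);
    sumR += sg * m.R; A_mph += sg * m.a_mph; A_fis += sg * m.a_fis;
    S[m.comp] += sg * m.r_sel; Q[m.comp] += sg * m.r_sel * m.r_sel;
    SD[m.comp] += sg * m.a_mph; SF[m.comp] += sg * m.a_fis;
    CW[m.comp] += sg * m.nW; CM[m.comp] += sg * m.nM;
  };
  auto mem_add = [&](int i) {
    Mito& m = c.mitos[i];
    m.pos = (int)mem[m.comp].size();
    mem[m.comp].push_back(i);
  };
  auto mem_remove = [&](int i) {
    Mito& m = c.mitos[i];
    std::vector<int>& v = mem[m.comp];
    int moved = v.back();
    v[m.pos] = moved;
    c.mitos[moved].pos = m.pos;
    v.pop_back();
  };
  // swap-pop the slot i out of the population, keeping member indices valid
  auto remove_slot = [&](int i) {
    int last = (int)c.mitos.size() - 1;
    if (i != last) {
      c.mitos[i] = c.mitos[last];
      Mito& m = c.mitos[i];
      mem[m.comp][m.pos] = i;
    }
    c.mitos.pop_back();
  };
  auto rebuild = [&]() {
    sumW = sumM = 0; sumR = A_mph = A_fis = 0.0;
    std::fill(S.begin(), S.end(), 0.0);
    std::fill(Q.begin(), Q.end(), 0.0);
    std::fill(SD.begin(), SD.end(), 0.0);
    std::fill(SF.begin(), SF.end(), 0.0);
    std::fill(CW.begin(), CW.end(), 0.0);
    std::fill(CM.begin(), CM.end(), 0.0);
    for (int a = 0; a < c.n_comp; ++a) mem[a].clear();
    for (size_t i = 0; i < c.mitos.size(); ++i) {
      mem_add((int)i);
      acc((int)i, 1.0);
    }
  };
  // two-level categorical draw: compartment by its weight sum, then a
  // member by its own weight; falls back to the last positive entry so
  // floating-point residue at the end of a walk cannot fall off the list
  auto pick_by = [&](double u, const std::vector<double>& compw,
                     double (*w)(const Mito&)) -> int {
    int ca = -1, la = -1;
    for (int a = 0; a < c.n_comp; ++a) {
      if (mem[a].empty() || compw[a] <= 0) continue;
      la = a;
      if (u < compw[a]) { ca = a; break; }
      u -= compw[a];
    }
    if (ca < 0) ca = la;
    if (ca < 0) return -1;
    int pick = -1, lastpos = -1;
    for (size_t k = 0; k < mem[ca].size(); ++k) {
      int i = mem[ca][k];
      double wi = w(c.mitos[i]);
      if (wi <= 0) continue;
      lastpos = i;
      if (u < wi) { pick = i; break; }
      u -= wi;
    }
    return pick >= 0 ? pick : lastpos;
  };
  rebuild();

  for (;;) {
    int n = (int)c.mitos.size();
    if (n == 0) { terminated = true; break; }
    if (((long)n_events & 0xFFFF) == 0xFFFF) rebuild();
    if (stop_at_homoplasmy && (sumM == 0 || sumW == 0)) { absorbed = true; break; }

    double rate_wt = 0.0, rate_mut = 0.0, A_rep = 0.0;
    if (ch_rep && sumW + sumM > 0) {
      // cell-level replication propensity (copy number is regulated: the
      // total does not scale with N), allocated over nucleoids with the
      // replicative-advantage weight k_R on mutant copies
      double rbar = sumR / n;
      A_rep = p.a_R0 * (p.r_R_max * defect(rbar, p.K_R, p.m) + 1.0);
      rate_wt = A_rep / (sumW + p.k_R * sumM);
      rate_mut = p.k_R * rate_wt;
    }
    double A_fus = 0.0;
    if (ch_fus) {
      double pairsum = 0.0;
      for (int a = 0; a < c.n_comp; ++a) {
        double w = 0.5 * (S[a] * S[a] - Q[a]);
        if (w > 0) pairsum += w;
        for (size_t k = 0; k < c.adj[a].size(); ++k) {
          int b = c.adj[a][k];
          if (b > a) pairsum += S[a] * S[b];
        }
      }
      A_fus = p.ff_scale * p.a_fusion0 * pairsum;
    }
    double A_mph_eff = ch_mph ? A_mph : 0.0;
    double A_fis_eff = ch_fis ? A_fis : 0.0;
    double A = A_rep + A_mph_eff + A_fus + A_fis_eff;

    double dt = (A > 0) ? exp_rand() / A : R_PosInf;
    double t_next = c.t + dt;

    while (ri < n_rec && record[ri] < t_next && record[ri] <= t_end) {
      take_snapshot(ri, record[ri]);
      ++ri;
    }
    if (t_next >= t_end || !R_FINITE(t_next)) {
      mito_days += n * (t_end - c.t);
      c.t = t_end;
      break;
    }
    mito_days += n * dt;
    c.t = t_next;

    // ---- channel selection (Gillespie direct method) ----
    double u = unif_rand() * A;
    if (u < A_rep) {
      bool mutant;
      if (u < rate_wt * sumW) { mutant = false; u /= rate_wt; }
      else { mutant = true; u = (u - rate_wt * sumW) / rate_mut; }
      // u is now a cumulative nucleoid count in [0, sumW or sumM)
      int mi = mutant ? pick_by(u, CM, w_nM) : pick_by(u, CW, w_nW);
      if (mi < 0) { rebuild(); continue; }
      Mito& m = c.mitos[mi];
      int sub = (int)m.W.size() - 1;
      double u2 = unif_rand() * (mutant ? m.nM : m.nW);
      for (size_t k = 0; k < m.W.size(); ++k) {
        double cnt = mutant ? m.M[k] : m.W[k];
        if (u2 < cnt) { sub = (int)k; break; }
        u2 -= cnt;
      }
      acc(mi, -1.0);
      do_replication(c, p, mi, sub, mutant, ep);
      acc(mi, 1.0);
      counts[0] += 1;
    } else if (u < A_rep + A_mph_eff) {
      int mi = pick_by(u - A_rep, SD, w_mph);
      if (mi < 0) { rebuild(); continue; }
      acc(mi, -1.0);
      ep.close_if_rich(c.mitos[mi], c.t);
      mem_remove(mi);
      remove_slot(mi);
      counts[1] += 1;
    } else if (u < A_rep + A_mph_eff + A_fus) {
      u = (u - A_rep - A_mph_eff) / (p.ff_scale * p.a_fusion0);
      // walk compartment pair terms; remember the last positive-weight term
      // as a guard against floating-point underflow at the end of the walk
      int ca = -1, cb = -1, la = -1, lb = -1;
      for (int a = 0; a < c.n_comp && ca < 0; ++a) {
        double w_within = 0.5 * (S[a] * S[a] - Q[a]);
        if (w_within > 0) { la = a; lb = a; }
        if (u < w_within) { ca = a; cb = a; break; }
        u -= w_within;
        for (size_t k = 0; k < c.adj[a].size(); ++k) {
          int b = c.adj[a][k];
          if (b <= a) continue;
          double w_cross = S[a] * S[b];
          if (w_cross > 0) { la = a; lb = b; }
          if (u < w_cross) { ca = a; cb = b; break; }
          u -= w_cross;
        }
      }
      if (ca < 0) { ca = la; cb = lb; }
      if (ca < 0) { rebuild(); continue; }  // drift residue: no feasible pair
      // sample a member of a compartment with prob prop. its r_sel
      auto samp_comp = [&](int comp, double Sc, int exclude) -> int {
        double u2 = unif_rand() * Sc;
        int lastpos = -1;
        for (size_t k = 0; k < mem[comp].size(); ++k) {
          int i = mem[comp][k];
          if (i == exclude) continue;
          double wi = c.mitos[i].r_sel;
          if (wi <= 0) continue;
          lastpos = i;
          if (u2 < wi) return i;
          u2 -= wi;
        }
        return lastpos;
      };
      int i, j;
      if (ca == cb) {
        // within-compartment unordered pair, prob prop. to r_i r_j: draw the
        // ordered pair from the product measure, rejecting i == j
        int tries = 0;
        for (;;) {
          i = samp_comp(ca, S[ca], -1);
          j = samp_comp(ca, S[ca], -1);
          if (i != j && i >= 0 && j >= 0) break;
          if (++tries > 100000) {
            j = samp_comp(ca, S[ca] - c.mitos[i].r_sel, i);
            break;
          }
        }
      } else {
        i = samp_comp(ca, S[ca], -1);
        j = samp_comp(cb, S[cb], -1);
      }
      if (i < 0 || j < 0 || i == j) { rebuild(); continue; }
      // donor assigned by a fair coin; the other is the acceptor
      int donor = (unif_rand() < 0.5) ? i : j;
      int acceptor = (donor == i) ? j : i;
      acc(acceptor, -1.0);
      acc(donor, -1.0);
      do_fusion_merge(c, p, acceptor, donor, ep);
      mem_remove(donor);
      remove_slot(donor);
      // the merged organelle sits at the acceptor slot unless the acceptor
      // occupied the popped last slot, in which case it moved to the donor's
      int merged = (acceptor == n - 1) ? donor : acceptor;
      acc(merged, 1.0);
      counts[2] += 1;
    } else {
      int mi = pick_by(u - A_rep - A_mph_eff - A_fus, SF, w_fis);
      if (mi < 0) { rebuild(); continue; }
      acc(mi, -1.0);
      do_fission(c, p, mi, ep);
      acc(mi, 1.0);
      mem_add((int)c.mitos.size() - 1);
      acc((int)c.mitos.size() - 1, 1.0);
      counts[3] += 1;
    }

    n_events += 1;
    if (n_events >= max_events) { hit_max = true; break; }
  }

  if (terminated) {
    // remaining snapshot rows stay NA except the time stamps
    while (ri < n_rec && record[ri] <= t_end) { snap(ri, 0) = record[ri]; ++ri; }
  } else if (!hit_max) {
    // absorbed-early runs: mutant-fraction columns are exact for all later
    // times (homoplasmy is absorbing); structural columns are frozen
    while (ri < n_rec && record[ri] <= t_end) { take_snapshot(ri, record[ri]); ++ri; }
    if (absorbed) {
      mito_days += c.mitos.size() * (t_end - c.t);
      c.t = t_end;
    }
  }
  ep.finalize(c, c.t);

  colnames(snap) = CharacterVector::create(
    "time", "r_cell", "n_mito", "n_nucleoid", "rbar_mito", "cov_rmito");
  NumericMatrix epi(ep.start.size(), 3);
  for (size_t k = 0; k < ep.start.size(); ++k) {
    epi(k, 0) = ep.start[k]; epi(k, 1) = ep.end[k]; epi(k, 2) = ep.censored[k];
  }
  colnames(epi) = CharacterVector::create("start", "end", "censored");

  return List::create(
    _["snapshots"] = snap,
    _["final_state"] = cell_to_r(c),
    _["episodes"] = epi,
    _["episode_starts"] = ep.n_starts,
    _["mito_days"] = mito_days,
    _["counts"] = NumericVector::create(
        _["replication"] = counts[0], _["mitophagy"] = counts[1],
        _["fusion"] = counts[2], _["fission"] = counts[3]),
    _["n_events"] = n_events,
    _["terminated_empty"] = terminated,
    _["absorbed_homoplasmic"] = absorbed,
    _["hit_max_events"] = hit_max,
    _["t_final"] = c.t);
}

// [[Rcpp::export(name = ".mqc_enumerate_channels")]]
List mqc_enumerate_channels(List state, List params, LogicalVector channels) {
  Params p = params_from_list(params);
  Cell c = cell_from_r(state, p);
  bool ch_rep = channels[0], ch_mph = channels[1],
       ch_fus = channels[2], ch_fis = channels[3];
  int n = (int)c.mitos.size();

  long sumW = 0, sumM = 0; double sumR = 0.0;
  NumericVector a_mph(n), a_fis(n), r_sel(n), R(n);
  IntegerVector nW(n), nM(n), comp(n);
  for (int i = 0; i < n; ++i) {
    const Mito& m = c.mitos[i];
    sumW += m.nW; sumM += m.nM; sumR += m.R;
    a_mph[i] = ch_mph ? m.a_mph : 0.0;
    a_fis[i] = ch_fis ? m.a_fis : 0.0;
    r_sel[i] = m.r_sel; R[i] = m.R;
    nW[i] = m.nW; nM[i] = m.nM; comp[i] = m.comp + 1;
  }
  double rate_wt = 0.0, rate_mut = 0.0;
  if (ch_rep && n > 0 && sumW + sumM > 0) {
    double rbar = sumR / n;
    rate_wt = p.a_R0 * (p.r_R_max * defect(rbar, p.K_R, p.m) + 1.0) /
              (sumW + p.k_R * sumM);
    rate_mut = p.k_R * rate_wt;
  }
  // feasible fusion pairs
  std::vector<int> pi, pj; std::vector<double> pa;
  if (ch_fus) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        int ci = c.mitos[i].comp, cj = c.mitos[j].comp;
        bool feasible = (ci == cj);
        if (!feasible)
          for (size_t k = 0; k < c.adj[ci].size(); ++k)
            if (c.adj[ci][k] == cj) { feasible = true; break; }
        if (!feasible) continue;
        pi.push_back(i + 1); pj.push_back(j + 1);
        pa.push_back(p.ff_scale * p.a_fusion0 *
                     c.mitos[i].r_sel * c.mitos[j].r_sel);
      }
    }
  }
  double A_fus = 0.0;
  for (size_t k = 0; k < pa.size(); ++k) A_fus += pa[k];
  double A_rep = rate_wt * sumW + rate_mut * sumM;
  double A_mph = Rcpp::sum(a_mph), A_fis = Rcpp::sum(a_fis);

  return List::create(
    _["replication_rate_wt"] = rate_wt,
    _["replication_rate_mut"] = rate_mut,
    _["n_wt"] = (double)sumW, _["n_mut"] = (double)sumM,
    _["mitophagy"] = a_mph, _["fission"] = a_fis,
    _["fusion_selectivity"] = r_sel, _["r_mito"] = R,
    _["n_w"] = nW, _["n_m"] = nM, _["compartment"] = comp,
    _["fusion_pairs"] = DataFrame::create(
        _["i"] = IntegerVector(pi.begin(), pi.end()),
        _["j"] = IntegerVector(pj.begin(), pj.end()),
        _["propensity"] = NumericVector(pa.begin(), pa.end())),
    _["total"] = NumericVector::create(
        _["replication"] = A_rep, _["mitophagy"] = A_mph,
        _["fusion"] = A_fus, _["fission"] = A_fis));
}

// ---- single-event wrappers: same mechanics as the engine ----

// [[Rcpp::export(name = ".mqc_execute_mitophagy")]]
List mqc_execute_mitophagy(List state, List params, int target) {
  Params p = params_from_list(params);
  Cell c = cell_from_r(state, p);
  if (target < 1 || target > (int)c.mitos.size())
    stop("target index out of range");
  EpisodeLog ep;
  do_mitophagy(c, target - 1, ep);
  return cell_to_r(c);
}

// [[Rcpp::export(name = ".mqc_execute_replication")]]
List mqc_execute_replication(List state, List params, int target,
                             int subcompartment, bool mutant) {
  Params p = params_from_list(params);
  Cell c = cell_from_r(state, p);
  if (target < 1 || target > (int)c.mitos.size())
    stop("target index out of range");
  Mito& m = c.mitos[target - 1];
  if (subcompartment < 1 || subcompartment > (int)m.W.size())
    stop("subcompartment index out of range");
  EpisodeLog ep;
  do_replication(c, p, target - 1, subcompartment - 1, mutant, ep);
  return cell_to_r(c);
}

// [[Rcpp::export(name = ".mqc_execute_fusion")]]
List mqc_execute_fusion(List state, List params, int i, int j) {
  Params p = params_from_list(params);
  Cell c = cell_from_r(state, p);
  int n = (int)c.mitos.size();
  if (i < 1 || i > n || j < 1 || j > n) stop("mitochondrion index out of range");
  if (i == j) stop("a mitochondrion cannot fuse with itself");
  EpisodeLog ep;
  int donor = (unif_rand() < 0.5) ? i - 1 : j - 1;
  int acceptor = (donor == i - 1) ? j - 1 : i - 1;
  do_fusion(c, p, acceptor, donor, ep);
  return cell_to_r(c);
}

// [[Rcpp::export(name = ".mqc_execute_fission")]]
List mqc_execute_fission(List state, List params, int target) {
  Params p = params_from_list(params);
  Cell c = cell_from_r(state, p);
  if (target < 1 || target > (int)c.mitos.size())
    stop("target index out of range");
  const Mito& m = c.mitos[target - 1];
  if (m.nW + m.nM < 2)
    stop("cannot fission a mitochondrion with fewer than 2 nucleoids");
  EpisodeLog ep;
  do_fission(c, p, target - 1, ep);
  return cell_to_r(c);
}
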