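// Minimum-free-energy folding and sorted suboptimal enumeration for a single
// RNA sequence under a nearest-neighbor loop-decomposition model.
//
// One best-first (priority queue) engine serves both jobs: the DP matrices
// give exact lower bounds for every partial structure, so completed
// structures pop off the queue in non-decreasing energy order; the first
// completion is the MFE structure. The production grammar (C/M/M1/F below)
// is unambiguous, so every pseudoknot-free structure is generated exactly
// once -- a requirement for the band-enumeration oracle tests.
//
// All energies are integer tenths of kcal/mol.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <queue>
#include <vector>

using namespace Rcpp;

static const int INF = 1000000000;

// base codes: 0 = other (never pairs), 1=A, 2=C, 3=G, 4=U
// pair types: 0 none, 1 AU, 2 UA, 3 GC, 4 CG, 5 GU, 6 UG
static inline int pair_type(int a, int b) {
  if (a == 1 && b == 4) return 1;
  if (a == 4 && b == 1) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 4) return 5;
  if (a == 4 && b == 3) return 6;
  return 0;
}

struct Model {
  int stack[7][7];            // [outer][inner] pair types
  std::vector<int> hp, bu, il; // by loop size (index 0 unused)
  int a, b, c;                // multiloop affine terms
  int tau[7];                 // terminal AU/GU penalty per pair type
  int ninio, ninio_max, max_loop, min_hp;
};

static Model read_model(const List& par, int n) {
  Model md;
  IntegerMatrix st = par["stack"];
  for (int i = 0; i < 7; ++i)
    for (int j = 0; j < 7; ++j) md.stack[i][j] = INF;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) md.stack[i + 1][j + 1] = st(i, j);
  IntegerVector hp = par["hairpin"], bu = par["bulge"], il = par["internal"];
  if (hp.size() < n || bu.size() < n || il.size() < n)
    stop("loop tables shorter than sequence length");
  md.hp.assign(hp.begin(), hp.end());
  md.bu.assign(bu.begin(), bu.end());
  md.il.assign(il.begin(), il.end());
  // shift to 1-based size indexing
  md.hp.insert(md.hp.begin(), INF);
  md.bu.insert(md.bu.begin(), INF);
  md.il.insert(md.il.begin(), INF);
  md.a = as<int>(par["ml_close"]);
  md.b = as<int>(par["ml_branch"]);
  md.c = as<int>(par["ml_unpaired"]);
  int tau = as<int>(par["terminal_au"]);
  md.tau[0] = 0;
  for (int p = 1; p <= 6; ++p) md.tau[p] = (p == 3 || p == 4) ? 0 : tau;
  md.ninio = as<int>(par["ninio"]);
  md.ninio_max = as<int>(par["ninio_max"]);
  md.max_loop = as<int>(par["max_loop"]);
  md.min_hp = as<int>(par["min_hairpin"]);
  return md;
}

struct Iv {
  int16_t i, j;
  int8_t m;  // 0 = F (exterior prefix 0..j), 1 = C, 2 = M, 3 = M1
};

struct State {
  int f;        // exact total lower bound (tenths)
  int64_t id;   // insertion order, tie-break for determinism
  int acc;      // energy of the decided part
  std::vector<std::pair<int16_t, int16_t> > pairs;
  std::vector<Iv> todo;
};

struct StateCmp {
  bool operator()(const State* a, const State* b) const {
    if (a->f != b->f) return a->f > b->f;
    return a->id > b->id;
  }
};

class Folder {
public:
  Folder(const IntegerVector& codes, const List& par)
      : n(codes.size()), s(codes.begin(), codes.end()),
        md(read_model(par, std::max(1, (int)codes.size()))) {
    fill();
  }

  int n;
  std::vector<int> s;
  Model md;
  std::vector<int> C_, M_, M1_;
  std::vector<int> Fv;  // Fv[j+1] = min energy of exterior prefix 0..j

  inline int idx(int i, int j) const { return i * n + j; }
  inline int pt(int i, int j) const { return pair_type(s[i], s[j]); }

  inline int ehairpin(int i, int j) const {
    return md.hp[j - i - 1] + md.tau[pt(i, j)];
  }

  inline int einterior(int i, int j, int p, int q) const {
    int n1 = p - i - 1, n2 = j - q - 1;
    int po = pt(i, j), pi = pt(p, q);
    if (n1 == 0 && n2 == 0) return md.stack[po][pi];
    int len = n1 + n2;
    if (n1 == 0 || n2 == 0) {
      if (len == 1) return md.bu[1] + md.stack[po][pi];
      return md.bu[len] + md.tau[po] + md.tau[pi];
    }
    int asym = md.ninio * std::abs(n1 - n2);
    if (asym > md.ninio_max) asym = md.ninio_max;
    return md.il[len] + asym + md.tau[po] + md.tau[pi];
  }

  void fill() {
    C_.assign((size_t)n * n, INF);
    M_.assign((size_t)n * n, INF);
    M1_.assign((size_t)n * n, INF);
    for (int span = md.min_hp + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // C[i][j]: i pairs j
        if (pt(i, j) > 0) {
          int best = ehairpin(i, j);
          // interior loops (includes stacks and bulges), size-capped
          for (int p = i + 1; p <= std::min(i + 1 + md.max_loop, j - md.min_hp - 2); ++p) {
            int n1 = p - i - 1;
            for (int q = j - 1; q > p + md.min_hp; --q) {
              int n2 = j - q - 1;
              if (n1 + n2 > md.max_loop) break;  // q decreasing -> n2 increasing
              if (pt(p, q) == 0) continue;
              int cpq = C_[idx(p, q)];
              if (cpq >= INF) continue;
              int e = einterior(i, j, p, q) + cpq;
              if (e < best) best = e;
            }
          }
          // multibranch closure: a + tau + M(i+1,u) + M1(u+1,j-1)
          int base = md.a + md.tau[pt(i, j)];
          for (int u = i + 2; u <= j - 2; ++u) {
            int m = M_[idx(i + 1, u)];
            if (m >= INF) continue;
            int m1 = M1_[idx(u + 1, j - 1)];
            if (m1 >= INF) continue;
            int e = base + m + m1;
            if (e < best) best = e;
          }
          C_[idx(i, j)] = best;
        }
        // M1[i][j]: one branch starting exactly at i, tail unpaired
        {
          int best = INF;
          if (M1_[idx(i, j - 1)] < INF) best = M1_[idx(i, j - 1)] + md.c;
          if (C_[idx(i, j)] < INF) {
            int e = C_[idx(i, j)] + md.b + md.tau[pt(i, j)];
            if (e < best) best = e;
          }
          M1_[idx(i, j)] = best;
        }
        // M[i][j]: >= 1 branch anywhere in i..j
        {
          int best = INF;
          if (M_[idx(i, j - 1)] < INF) best = M_[idx(i, j - 1)] + md.c;
          for (int u = i; u <= j - md.min_hp - 1; ++u) {
            int cuj = C_[idx(u, j)];
            if (cuj >= INF) continue;
            int cb = cuj + md.b + md.tau[pt(u, j)];
            int e = cb + (u - i) * md.c;  // no branch before u
            if (e < best) best = e;
            if (u - 1 >= i && M_[idx(i, u - 1)] < INF) {
              int e2 = cb + M_[idx(i, u - 1)];
              if (e2 < best) best = e2;
            }
          }
          M_[idx(i, j)] = best;
        }
      }
    }
    Fv.assign(n + 1, 0);
    for (int j = 0; j < n; ++j) {
      int best = Fv[j];  // j unpaired
      for (int u = 0; u <= j - md.min_hp - 1; ++u) {
        int cuj = C_[idx(u, j)];
        if (cuj >= INF) continue;
        int e = cuj + md.tau[pt(u, j)] + Fv[u];
        if (e < best) best = e;
      }
      Fv[j + 1] = best;
    }
  }

  inline int bound(const Iv& iv) const {
    switch (iv.m) {
      case 0: return Fv[iv.j + 1];
      case 1: return C_[idx(iv.i, iv.j)];
      case 2: return M_[idx(iv.i, iv.j)];
      default: return M1_[idx(iv.i, iv.j)];
    }
  }
};

// ---- best-first enumeration ------------------------------------------------

class Engine {
public:
  Engine(Folder& fo, int ceiling, int max_count, int window,
         long max_gen, long max_queue)
      : fo(fo), ceiling(ceiling), max_count(max_count), window(window),
        max_gen(max_gen), max_queue(max_queue) {}

  Folder& fo;
  int ceiling, max_count, window;
  long max_gen, max_queue;
  bool truncated = false;
  long popped = 0;
  int64_t next_id = 0;

  std::priority_queue<State*, std::vector<State*>, StateCmp> pq;
  std::vector<std::vector<std::pair<int16_t, int16_t> > > accepted;
  std::vector<int> accepted_energy;

  ~Engine() {
    while (!pq.empty()) { delete pq.top(); pq.pop(); }
  }

  void push_state(State* st) {
    if ((long)pq.size() >= max_queue) {
      truncated = true;
      delete st;
      return;
    }
    st->id = next_id++;
    pq.push(st);
  }

  // child = parent with interval iv replaced by new intervals + cost + opt pair
  void spawn(const State* par, int parent_bound, int cost,
             const std::vector<Iv>& add, int pi = -1, int pj = -1) {
    int f = par->f - parent_bound + cost;
    for (size_t k = 0; k < add.size(); ++k) {
      int b = fo.bound(add[k]);
      if (b >= INF) return;
      f += b;
    }
    if (f > ceiling) return;
    State* ch = new State();
    ch->f = f;
    ch->acc = par->acc + cost;
    ch->pairs = par->pairs;
    if (pi >= 0) ch->pairs.push_back(std::make_pair((int16_t)pi, (int16_t)pj));
    ch->todo = par->todo;  // parent's todo already has iv removed by caller
    for (size_t k = 0; k < add.size(); ++k) ch->todo.push_back(add[k]);
    push_state(ch);
  }

  bool window_accept(const std::vector<std::pair<int16_t, int16_t> >& pr) const {
    if (accepted.empty()) return true;
    if (window <= 0) {
      // pure distinctness (grammar is unambiguous, so this is a safety net)
      std::vector<std::pair<int16_t, int16_t> > a(pr);
      std::sort(a.begin(), a.end());
      for (size_t k = 0; k < accepted.size(); ++k) {
        std::vector<std::pair<int16_t, int16_t> > b(accepted[k]);
        std::sort(b.begin(), b.end());
        if (a == b) return false;
      }
      return true;
    }
    if (pr.empty()) return false;
    for (size_t p = 0; p < pr.size(); ++p) {
      bool novel = true;
      for (size_t k = 0; k < accepted.size() && novel; ++k) {
        const std::vector<std::pair<int16_t, int16_t> >& b = accepted[k];
        for (size_t q = 0; q < b.size(); ++q) {
          int d = std::max(std::abs((int)pr[p].first - (int)b[q].first),
                           std::abs((int)pr[p].second - (int)b[q].second));
          if (d < window) { novel = false; break; }
        }
      }
      if (novel) return true;
    }
    return false;
  }

  void expand(State* st) {
    Iv iv = st->todo.back();
    st->todo.pop_back();
    int pb = fo.bound(iv);
    const Model& md = fo.md;
    std::vector<Iv> add;
    if (iv.m == 0) {  // exterior prefix 0..j
      int j = iv.j;
      add.clear();
      if (j - 1 >= 0) { Iv nv = {0, (int16_t)(j - 1), 0}; add.push_back(nv); }
      spawn(st, pb, 0, add);  // j unpaired
      for (int u = 0; u <= j - md.min_hp - 1; ++u) {
        if (fo.pt(u, j) == 0) continue;
        add.clear();
        Iv cv = {(int16_t)u, (int16_t)j, 1};
        add.push_back(cv);
        if (u - 1 >= 0) { Iv fv = {0, (int16_t)(u - 1), 0}; add.push_back(fv); }
        spawn(st, pb, md.tau[fo.pt(u, j)], add);
      }
    } else if (iv.m == 1) {  // C(i,j): i pairs j
      int i = iv.i, j = iv.j;
      add.clear();
      spawn(st, pb, fo.ehairpin(i, j), add, i, j);
      for (int p = i + 1; p <= std::min(i + 1 + md.max_loop, j - md.min_hp - 2); ++p) {
        int n1 = p - i - 1;
        for (int q = j - 1; q > p + md.min_hp; --q) {
          if (n1 + (j - q - 1) > md.max_loop) break;
          if (fo.pt(p, q) == 0) continue;
          add.clear();
          Iv cv = {(int16_t)p, (int16_t)q, 1};
          add.push_back(cv);
          spawn(st, pb, fo.einterior(i, j, p, q), add, i, j);
        }
      }
      int base = md.a + md.tau[fo.pt(i, j)];
      for (int u = i + 2; u <= j - 2; ++u) {
        add.clear();
        Iv mv = {(int16_t)(i + 1), (int16_t)u, 2};
        Iv m1v = {(int16_t)(u + 1), (int16_t)(j - 1), 3};
        add.push_back(mv);
        add.push_back(m1v);
        spawn(st, pb, base, add, i, j);
      }
    } else if (iv.m == 2) {  // M(i,j)
      int i = iv.i, j = iv.j;
      if (j - 1 >= i) {
        add.clear();
        Iv mv = {(int16_t)i, (int16_t)(j - 1), 2};
        add.push_back(mv);
        spawn(st, pb, md.c, add);
      }
      for (int u = i; u <= j - md.min_hp - 1; ++u) {
        if (fo.pt(u, j) == 0) continue;
        int cb = md.b + md.tau[fo.pt(u, j)];
        add.clear();
        Iv cv = {(int16_t)u, (int16_t)j, 1};
        add.push_back(cv);
        spawn(st, pb, cb + (u - i) * md.c, add);  // all unpaired before u
        if (u - 1 >= i) {
          add.clear();
          Iv mv = {(int16_t)i, (int16_t)(u - 1), 2};
          add.push_back(mv);
          add.push_back(cv);
          spawn(st, pb, cb, add);  // >= 1 branch before u
        }
      }
    } else {  // M1(i,j)
      int i = iv.i, j = iv.j;
      if (j - 1 >= i) {
        add.clear();
        Iv mv = {(int16_t)i, (int16_t)(j - 1), 3};
        add.push_back(mv);
        spawn(st, pb, md.c, add);
      }
      if (fo.pt(i, j) > 0) {
        add.clear();
        Iv cv = {(int16_t)i, (int16_t)j, 1};
        add.push_back(cv);
        spawn(st, pb, md.b + md.tau[fo.pt(i, j)], add);
      }
    }
  }

  void run() {
    State* init = new State();
    init->acc = 0;
    init->f = fo.Fv[fo.n];
    if (fo.n >= 1) {
      Iv iv = {0, (int16_t)(fo.n - 1), 0};
      init->todo.push_back(iv);
    }
    if (init->f > ceiling) { delete init; return; }
    push_state(init);
    while (!pq.empty()) {
      if (popped >= max_gen) { truncated = true; break; }
      State* st = pq.top();
      pq.pop();
      ++popped;
      if (st->todo.empty()) {
        if (window_accept(st->pairs)) {
          accepted.push_back(st->pairs);
          accepted_energy.push_back(st->acc);
        }
        delete st;
        if ((int)accepted.size() >= max_count) break;
        continue;
      }
      expand(st);
      delete st;
      if (popped % 4096 == 0) Rcpp::checkUserInterrupt();
    }
  }
};

static List engine_result(const Engine& en, int mfe) {
  int m = en.accepted.size();
  List structs(m);
  for (int k = 0; k < m; ++k) {
    const std::vector<std::pair<int16_t, int16_t> >& pr = en.accepted[k];
    IntegerMatrix pm(pr.size(), 2);
    std::vector<std::pair<int16_t, int16_t> > sp(pr);
    std::sort(sp.begin(), sp.end());
    for (size_t q = 0; q < sp.size(); ++q) {
      pm(q, 0) = sp[q].first + 1;  // 1-based
      pm(q, 1) = sp[q].second + 1;
    }
    structs[k] = List::create(_["pairs"] = pm,
                              _["energy_tenths"] = en.accepted_energy[k]);
  }
  return List::create(_["structures"] = structs, _["mfe_tenths"] = mfe,
                      _["truncated"] = en.truncated, _["popped"] = en.popped);
}

// [[Rcpp::export]]
List c_fold(IntegerVector codes, List par) {
  Folder fo(codes, par);
  int mfe = fo.Fv[fo.n];
  Engine en(fo, mfe, 1, 0, 10000000L, 5000000L);
  en.run();
  return engine_result(en, mfe);
}

// [[Rcpp::export]]
List c_subopt(IntegerVector codes, List par, double max_pct_diff,
              int max_count, int window, double max_gen, double max_queue) {
  Folder fo(codes, par);
  int mfe = fo.Fv[fo.n];
  // band ceiling MFE + |MFE| * pct / 100; energies are integer tenths, so
  // flooring the band reproduces the real-valued filter exactly
  int band = (int)std::floor(std::abs((double)mfe) * max_pct_diff / 100.0 + 1e-9);
  Engine en(fo, mfe + band, max_count, window,
            (long)max_gen, (long)max_queue);
  en.run();
  return engine_result(en, mfe);
}

// [[Rcpp::export]]
int c_mfe_energy(IntegerVector codes, List par) {
  Folder fo(codes, par);
  return fo.Fv[fo.n];
}
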