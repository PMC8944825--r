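// Exact backward induction over belief states of the metalevel MDP.
//
// Two independent code paths:
//   * fork_*  — canonical-state solver for "fork" trees (root fan-out b,
//     a chain of single-successor spine nodes, and k leaves per branch).
//     Branches are exchangeable, and within a branch only the per-depth
//     observation pattern plus the count/maximum of observed leaf values
//     matter, so the belief space collapses to a tractable canonical set.
//   * brute_* — dense enumeration of concrete beliefs for small arbitrary
//     trees; no symmetry reduction. Used as an independent oracle.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- fork model

struct ForkModel {
  int b;                // branches (root fan-out)
  int D;                // number of reward depths
  int nspine;           // D - 1 spine depths per branch
  int k;                // leaves per branch (final depth)
  double cost;          // click cost
  std::vector<std::vector<double>> sup;  // support per depth (0-based depth)
  std::vector<std::vector<double>> pr;   // probabilities per depth
  std::vector<double> mu;                // prior mean per depth
  std::vector<int> place;                // mixed-radix places for spine digits
  int n_spine, n_leaf, n_branch;
  std::unordered_map<uint64_t, double> memo;
};

static inline uint64_t fork_key(const ForkModel& m, const int* st) {
  int s[8];
  for (int i = 0; i < m.b; ++i) s[i] = st[i];
  // insertion sort, descending
  for (int i = 1; i < m.b; ++i) {
    int v = s[i], j = i - 1;
    while (j >= 0 && s[j] < v) { s[j + 1] = s[j]; --j; }
    s[j + 1] = v;
  }
  uint64_t key = 0;
  for (int i = 0; i < m.b; ++i) key = (key << 16) | (uint64_t)s[i];
  return key;
}

// decode branch index -> spine digits (len nspine), o, maxIdx
static inline void fork_decode(const ForkModel& m, int br, int* dig, int& o,
                               int& maxIdx) {
  int leaf = br % m.n_leaf;
  int sp = br / m.n_leaf;
  int sD = (int)m.sup[m.D - 1].size();
  if (leaf == 0) { o = 0; maxIdx = 0; }
  else { leaf -= 1; o = leaf / sD + 1; maxIdx = leaf % sD + 1; }
  for (int d = 0; d < m.nspine; ++d) {
    dig[d] = sp % ((int)m.sup[d].size() + 1);
    sp /= ((int)m.sup[d].size() + 1);
  }
}

static inline int fork_encode(const ForkModel& m, const int* dig, int o,
                              int maxIdx) {
  int sp = 0;
  for (int d = m.nspine - 1; d >= 0; --d)
    sp = sp * ((int)m.sup[d].size() + 1) + dig[d];
  int sD = (int)m.sup[m.D - 1].size();
  int leaf = (o == 0) ? 0 : 1 + (o - 1) * sD + (maxIdx - 1);
  return sp * m.n_leaf + leaf;
}

// expected value of the best path through one branch, under the belief
static inline double fork_branch_ev(const ForkModel& m, int br) {
  int dig[16], o, maxIdx;
  fork_decode(m, br, dig, o, maxIdx);
  double ev = 0.0;
  for (int d = 0; d < m.nspine; ++d)
    ev += dig[d] ? m.sup[d][dig[d] - 1] : m.mu[d];
  double leafBest;
  if (o == 0) leafBest = m.mu[m.D - 1];
  else {
    leafBest = m.sup[m.D - 1][maxIdx - 1];
    if (o < m.k && m.mu[m.D - 1] > leafBest) leafBest = m.mu[m.D - 1];
  }
  return ev + leafBest;
}

static double fork_term(const ForkModel& m, const int* st) {
  double best = -INFINITY;
  for (int j = 0; j < m.b; ++j) {
    double ev = fork_branch_ev(m, st[j]);
    if (ev > best) best = ev;
  }
  return best;
}

static double fork_V(ForkModel& m, int* st);

// Q of clicking the unobserved spine node at depth d (0-based) in branch j
static double fork_q_spine(ForkModel& m, const int* st, int j, int d) {
  int dig[16], o, maxIdx;
  fork_decode(m, st[j], dig, o, maxIdx);
  double q = -m.cost;
  int st2[8];
  for (int i = 0; i < m.b; ++i) st2[i] = st[i];
  for (size_t i = 0; i < m.sup[d].size(); ++i) {
    dig[d] = (int)i + 1;
    st2[j] = fork_encode(m, dig, o, maxIdx);
    q += m.pr[d][i] * fork_V(m, st2);
  }
  return q;
}

// Q of clicking one unobserved leaf in branch j
static double fork_q_leaf(ForkModel& m, const int* st, int j) {
  int dig[16], o, maxIdx;
  fork_decode(m, st[j], dig, o, maxIdx);
  double q = -m.cost;
  int st2[8];
  for (int i = 0; i < m.b; ++i) st2[i] = st[i];
  int dD = m.D - 1;
  for (size_t i = 0; i < m.sup[dD].size(); ++i) {
    int newMax = (o == 0) ? (int)i + 1 : std::max(maxIdx, (int)i + 1);
    st2[j] = fork_encode(m, dig, o + 1, newMax);
    q += m.pr[dD][i] * fork_V(m, st2);
  }
  return q;
}

static double fork_V(ForkModel& m, int* st) {
  uint64_t key = fork_key(m, st);
  auto it = m.memo.find(key);
  if (it != m.memo.end()) return it->second;
  double best = fork_term(m, st);
  for (int j = 0; j < m.b; ++j) {
    bool dup = false;
    for (int jj = 0; jj < j; ++jj) if (st[jj] == st[j]) { dup = true; break; }
    if (dup) continue;
    int dig[16], o, maxIdx;
    fork_decode(m, st[j], dig, o, maxIdx);
    for (int d = 0; d < m.nspine; ++d)
      if (dig[d] == 0) {
        double q = fork_q_spine(m, st, j, d);
        if (q > best) best = q;
      }
    if (o < m.k) {
      double q = fork_q_leaf(m, st, j);
      if (q > best) best = q;
    }
  }
  m.memo.emplace(key, best);
  return best;
}

// [[Rcpp::export]]
List fork_solve_cpp(int b, int k, List supports, List probs, double cost) {
  ForkModel* m = new ForkModel();
  m->b = b; m->k = k; m->cost = cost;
  m->D = supports.size();
  m->nspine = m->D - 1;
  if (b < 1 || b > 4) stop("fork solver supports 1-4 branches");
  if (m->nspine > 15) stop("tree too deep for fork solver");
  for (int d = 0; d < m->D; ++d) {
    m->sup.push_back(as<std::vector<double>>(supports[d]));
    m->pr.push_back(as<std::vector<double>>(probs[d]));
    double mu = 0;
    for (size_t i = 0; i < m->sup[d].size(); ++i)
      mu += m->sup[d][i] * m->pr[d][i];
    m->mu.push_back(mu);
  }
  m->n_spine = 1;
  for (int d = 0; d < m->nspine; ++d) m->n_spine *= (int)m->sup[d].size() + 1;
  m->n_leaf = 1 + k * (int)m->sup[m->D - 1].size();
  m->n_branch = m->n_spine * m->n_leaf;
  if (m->n_branch > 65535) stop("environment too large for fork solver");
  m->memo.reserve(1 << 20);
  int st[8];
  for (int i = 0; i < b; ++i) st[i] = 0;
  double v0 = fork_V(*m, st);
  XPtr<ForkModel> ptr(m, true);
  return List::create(_["ptr"] = ptr, _["root_value"] = v0,
                      _["n_states"] = (double)m->memo.size());
}

// state: integer matrix b x (nspine + 2): spine digits, o, maxIdx
static void fork_state_from_matrix(const ForkModel& m, IntegerMatrix state,
                                   int* st) {
  if (state.nrow() != m.b || state.ncol() != m.nspine + 2)
    stop("bad state matrix");
  for (int j = 0; j < m.b; ++j) {
    int dig[16];
    for (int d = 0; d < m.nspine; ++d) dig[d] = state(j, d);
    int o = state(j, m.nspine), maxIdx = state(j, m.nspine + 1);
    st[j] = fork_encode(m, dig, o, maxIdx);
  }
}

// [[Rcpp::export]]
List fork_q_cpp(SEXP ptr_, IntegerMatrix state) {
  XPtr<ForkModel> ptr(ptr_);
  ForkModel& m = *ptr;
  int st[8];
  fork_state_from_matrix(m, state, st);
  double tv = fork_term(m, st);
  NumericMatrix qspine(m.b, std::max(m.nspine, 1));
  std::fill(qspine.begin(), qspine.end(), NA_REAL);
  NumericVector qleaf(m.b, NA_REAL);
  double best = tv;
  for (int j = 0; j < m.b; ++j) {
    int dig[16], o, maxIdx;
    fork_decode(m, st[j], dig, o, maxIdx);
    for (int d = 0; d < m.nspine; ++d)
      if (dig[d] == 0) {
        double q = fork_q_spine(m, st, j, d);
        qspine(j, d) = q;
        if (q > best) best = q;
      }
    if (o < m.k) {
      double q = fork_q_leaf(m, st, j);
      qleaf[j] = q;
      if (q > best) best = q;
    }
  }
  return List::create(_["term"] = tv, _["V"] = best, _["qspine"] = qspine,
                      _["qleaf"] = qleaf);
}

// --------------------------------------------------------------- brute model

struct BruteModel {
  int n;
  double cost;
  std::vector<std::vector<double>> sup, pr;  // per node
  std::vector<double> mu;
  std::vector<std::vector<int>> paths;       // 0-based node indices
  std::vector<long long> place;              // mixed-radix place per node
  long long S;
  std::vector<double> V;
  std::vector<char> done;
};

static double brute_term(const BruteModel& m, const int* dig) {
  double best = -INFINITY;
  for (size_t p = 0; p < m.paths.size(); ++p) {
    double ev = 0;
    for (size_t i = 0; i < m.paths[p].size(); ++i) {
      int node = m.paths[p][i];
      ev += dig[node] ? m.sup[node][dig[node] - 1] : m.mu[node];
    }
    if (ev > best) best = ev;
  }
  return best;
}

static double brute_V(BruteModel& m, int* dig, long long code) {
  if (m.done[code]) return m.V[code];
  double best = brute_term(m, dig);
  for (int i = 0; i < m.n; ++i) {
    if (dig[i]) continue;
    double q = -m.cost;
    for (size_t v = 0; v < m.sup[i].size(); ++v) {
      dig[i] = (int)v + 1;
      q += m.pr[i][v] * brute_V(m, dig, code + ((long long)v + 1) * m.place[i]);
    }
    dig[i] = 0;
    if (q > best) best = q;
  }
  m.done[code] = 1;
  m.V[code] = best;
  return best;
}

// [[Rcpp::export]]
List brute_solve_cpp(List supports, List probs, List paths, double cost) {
  BruteModel* m = new BruteModel();
  m->cost = cost;
  m->n = supports.size();
  long long S = 1;
  for (int i = 0; i < m->n; ++i) {
    m->sup.push_back(as<std::vector<double>>(supports[i]));
    m->pr.push_back(as<std::vector<double>>(probs[i]));
    double mu = 0;
    for (size_t v = 0; v < m->sup[i].size(); ++v)
      mu += m->sup[i][v] * m->pr[i][v];
    m->mu.push_back(mu);
    m->place.push_back(S);
    S *= (long long)m->sup[i].size() + 1;
    if (S > 8000000LL) { delete m; stop("environment too large for brute-force oracle"); }
  }
  m->S = S;
  for (int p = 0; p < paths.size(); ++p) {
    IntegerVector pv = paths[p];
    std::vector<int> path;
    for (int i = 0; i < pv.size(); ++i) path.push_back(pv[i] - 1);
    m->paths.push_back(path);
  }
  m->V.assign((size_t)S, 0.0);
  m->done.assign((size_t)S, 0);
  std::vector<int> dig(m->n, 0);
  double v0 = brute_V(*m, dig.data(), 0);
  XPtr<BruteModel> ptr(m, true);
  return List::create(_["ptr"] = ptr, _["root_value"] = v0,
                      _["n_states"] = (double)S);
}

// digits: per-node observation index (0 = unobserved, j = j-th support value)
// [[Rcpp::export]]
List brute_q_cpp(SEXP ptr_, IntegerVector digits) {
  XPtr<BruteModel> ptr(ptr_);
  BruteModel& m = *ptr;
  if (digits.size() != m.n) stop("bad digit vector");
  std::vector<int> dig(m.n);
  long long code = 0;
  for (int i = 0; i < m.n; ++i) {
    dig[i] = digits[i];
    code += (long long)digits[i] * m.place[i];
  }
  double tv = brute_term(m, dig.data());
  NumericVector q(m.n, NA_REAL);
  double best = tv;
  for (int i = 0; i < m.n; ++i) {
    if (dig[i]) continue;
    double qi = -m.cost;
    for (size_t v = 0; v < m.sup[i].size(); ++v) {
      dig[i] = (int)v + 1;
      qi += m.pr[i][v] *
            brute_V(m, dig.data(), code + ((long long)v + 1) * m.place[i]);
    }
    dig[i] = 0;
    q[i] = qi;
    if (qi > best) best = qi;
  }
  return List::create(_["term"] = tv, _["V"] = best, _["qclick"] = q);
}
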