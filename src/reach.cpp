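#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Exact two-terminal signal reachability by multiplying per-edge binomials
// p_i x_i + (1-p_i) y_i into an xy-polynomial and collapsing terms whose
// present edges already form a source->target path (into the reached
// coefficient b) or whose absent edges already form a source->target cut
// (into the cut coefficient c).
//
// The engine works per (s,t) pair and restricts itself to the edges that can
// lie on an s->t walk (tail reachable from s, head reaching t): no other edge
// can change two-terminal reachability, it would only double the term count.
// Terms are bitmasks over those relevant edges (at most 64), multiplied in
// breadth-first discovery order from s so collapsing fires early.
//
// Optionally one edge binomial is deferred until the end; by the affine
// decomposition the pair reachability then equals alpha + beta * p_e with
// alpha the reached coefficient and beta the sum of surviving non-free
// coefficients.

namespace {

struct PairResult {
  double alpha;
  double beta;
};

// Does the edge set `mask` (local ids over `order`) connect s to t?
bool mask_reaches(uint64_t mask, int s, int t,
                  const std::vector<std::vector<std::pair<int, int> > > &ladj,
                  int n_nodes,
                  std::unordered_map<uint64_t, char> &memo) {
  std::unordered_map<uint64_t, char>::iterator it = memo.find(mask);
  if (it != memo.end()) return it->second != 0;
  std::vector<char> vis(n_nodes, 0);
  std::vector<int> st;
  st.push_back(s);
  vis[s] = 1;
  bool ok = false;
  while (!st.empty() && !ok) {
    int v = st.back();
    st.pop_back();
    const std::vector<std::pair<int, int> > &out = ladj[v];
    for (size_t i = 0; i < out.size(); ++i) {
      if (!((mask >> out[i].first) & 1ULL)) continue;
      int w = out[i].second;
      if (w == t) { ok = true; break; }
      if (!vis[w]) { vis[w] = 1; st.push_back(w); }
    }
  }
  memo[mask] = ok ? 1 : 0;
  return ok;
}

PairResult pair_reach(int n_nodes,
                      const std::vector<int> &efrom,
                      const std::vector<int> &eto,
                      const std::vector<double> &p,
                      int s, int t, int deferred, double term_cap) {
  PairResult res;
  if (s == t) { res.alpha = 1.0; res.beta = 0.0; return res; }
  int n_edges = (int)efrom.size();

  std::vector<std::vector<int> > out(n_nodes), in(n_nodes);
  for (int e = 0; e < n_edges; ++e) {
    out[efrom[e]].push_back(e);
    in[eto[e]].push_back(e);
  }

  // nodes reachable from s / reaching t in the unweighted graph
  std::vector<char> from_s(n_nodes, 0), to_t(n_nodes, 0);
  {
    std::vector<int> st;
    st.push_back(s);
    from_s[s] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      for (size_t i = 0; i < out[v].size(); ++i) {
        int w = eto[out[v][i]];
        if (!from_s[w]) { from_s[w] = 1; st.push_back(w); }
      }
    }
  }
  if (!from_s[t]) { res.alpha = 0.0; res.beta = 0.0; return res; }
  {
    std::vector<int> st;
    st.push_back(t);
    to_t[t] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      for (size_t i = 0; i < in[v].size(); ++i) {
        int w = efrom[in[v][i]];
        if (!to_t[w]) { to_t[w] = 1; st.push_back(w); }
      }
    }
  }

  // relevant edges: can lie on an s -> t walk
  std::vector<char> rel(n_edges, 0);
  int n_rel = 0;
  for (int e = 0; e < n_edges; ++e) {
    if (from_s[efrom[e]] && to_t[eto[e]]) { rel[e] = 1; ++n_rel; }
  }
  bool defer = deferred >= 0;
  bool defer_rel = defer && rel[deferred] != 0;
  if (n_rel > 64)
    stop("exact reachability engine supports at most 64 edges on source->target paths (pair has %d)", n_rel);

  // breadth-first multiplication order over the relevant subgraph
  std::vector<std::vector<int> > relout(n_nodes);
  for (int e = 0; e < n_edges; ++e)
    if (rel[e]) relout[efrom[e]].push_back(e);
  std::vector<int> order;
  order.reserve(n_rel);
  {
    std::vector<char> vis(n_nodes, 0);
    std::deque<int> q;
    q.push_back(s);
    vis[s] = 1;
    while (!q.empty()) {
      int v = q.front(); q.pop_front();
      for (size_t i = 0; i < relout[v].size(); ++i) {
        int e = relout[v][i];
        order.push_back(e);
        int w = eto[e];
        if (!vis[w]) { vis[w] = 1; q.push_back(w); }
      }
    }
  }
  int m = (int)order.size();

  // local adjacency keyed by local edge id (its bit position)
  std::vector<std::vector<std::pair<int, int> > > ladj(n_nodes);
  int deferred_local = -1;
  for (int i = 0; i < m; ++i) {
    ladj[efrom[order[i]]].push_back(std::make_pair(i, eto[order[i]]));
    if (defer_rel && order[i] == deferred) deferred_local = i;
  }

  std::unordered_map<uint64_t, char> memo;
  uint64_t full = (m == 64) ? ~0ULL : ((1ULL << m) - 1ULL);
  uint64_t remaining = full;  // unmultiplied edges (deferred stays in forever)

  std::vector<uint64_t> masks;
  std::vector<double> coefs;
  masks.push_back(0ULL);
  coefs.push_back(1.0);
  double b = 0.0, c = 0.0;

  for (int i = 0; i < m; ++i) {
    if (i == deferred_local) continue;
    double pe = p[order[i]];
    uint64_t bit = 1ULL << i;
    remaining &= ~bit;

    std::vector<uint64_t> nmasks;
    std::vector<double> ncoefs;
    nmasks.reserve(2 * masks.size());
    ncoefs.reserve(2 * masks.size());
    for (size_t j = 0; j < masks.size(); ++j) {
      // absent branch
      double ca = coefs[j] * (1.0 - pe);
      if (ca > 0.0) {
        uint64_t mk = masks[j];
        if (mask_reaches(mk, s, t, ladj, n_nodes, memo)) {
          b += ca;
        } else if (!mask_reaches(mk | remaining, s, t, ladj, n_nodes, memo)) {
          c += ca;
        } else {
          nmasks.push_back(mk);
          ncoefs.push_back(ca);
        }
      }
      // present branch
      double cp = coefs[j] * pe;
      if (cp > 0.0) {
        uint64_t mk = masks[j] | bit;
        if (mask_reaches(mk, s, t, ladj, n_nodes, memo)) {
          b += cp;
        } else if (!mask_reaches(mk | remaining, s, t, ladj, n_nodes, memo)) {
          c += cp;
        } else {
          nmasks.push_back(mk);
          ncoefs.push_back(cp);
        }
      }
    }
    masks.swap(nmasks);
    coefs.swap(ncoefs);
    if ((double)masks.size() > term_cap)
      stop("xy-polynomial exceeded the term cap (%.0f terms); raise term_cap or simplify the network", term_cap);

    double total = b + c;
    for (size_t j = 0; j < coefs.size(); ++j) total += coefs[j];
    if (total < 1.0 - 1e-9 || total > 1.0 + 1e-9)
      stop("xy-polynomial conservation drifted beyond 1e-9 (sum = %.12f)", total);
  }

  double beta = 0.0;
  for (size_t j = 0; j < coefs.size(); ++j) beta += coefs[j];
  if (!defer_rel && !coefs.empty())
    stop("internal error: uncollapsed terms remain after multiplying all edge binomials");
  res.alpha = b;
  res.beta = defer_rel ? beta : 0.0;
  return res;
}

std::vector<int> as_std_int(const IntegerVector &v) {
  return std::vector<int>(v.begin(), v.end());
}

}  // namespace

// [[Rcpp::export]]
double cpp_reachability(IntegerVector efrom, IntegerVector eto, int n_nodes,
                        NumericVector p, int s, int t, double term_cap) {
  std::vector<int> f = as_std_int(efrom), g = as_std_int(eto);
  std::vector<double> pv(p.begin(), p.end());
  PairResult r = pair_reach(n_nodes, f, g, pv, s, t, -1, term_cap);
  return r.alpha;
}

// [[Rcpp::export]]
NumericVector cpp_linear(IntegerVector efrom, IntegerVector eto, int n_nodes,
                         NumericVector p, int s, int t, int deferred,
                         double term_cap) {
  std::vector<int> f = as_std_int(efrom), g = as_std_int(eto);
  std::vector<double> pv(p.begin(), p.end());
  PairResult r = pair_reach(n_nodes, f, g, pv, s, t, deferred, term_cap);
  NumericVector out(2);
  out[0] = r.alpha;
  out[1] = r.beta;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_reach_matrix(IntegerVector efrom, IntegerVector eto,
                               int n_nodes, NumericVector p,
                               IntegerVector sources, IntegerVector targets,
                               double term_cap) {
  std::vector<int> f = as_std_int(efrom), g = as_std_int(eto);
  std::vector<double> pv(p.begin(), p.end());
  NumericMatrix out(sources.size(), targets.size());
  for (int i = 0; i < sources.size(); ++i)
    for (int j = 0; j < targets.size(); ++j) {
      PairResult r =
          pair_reach(n_nodes, f, g, pv, sources[i], targets[j], -1, term_cap);
      out(i, j) = r.alpha;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_linear_pairs(IntegerVector efrom, IntegerVector eto, int n_nodes,
                      NumericVector p, IntegerVector sources,
                      IntegerVector targets, int deferred, double term_cap) {
  std::vector<int> f = as_std_int(efrom), g = as_std_int(eto);
  std::vector<double> pv(p.begin(), p.end());
  NumericMatrix alpha(sources.size(), targets.size());
  NumericMatrix beta(sources.size(), targets.size());
  for (int i = 0; i < sources.size(); ++i)
    for (int j = 0; j < targets.size(); ++j) {
      PairResult r = pair_reach(n_nodes, f, g, pv, sources[i], targets[j],
                                deferred, term_cap);
      alpha(i, j) = r.alpha;
      beta(i, j) = r.beta;
    }
  return List::create(Named("alpha") = alpha, Named("beta") = beta);
}
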