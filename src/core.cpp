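#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Compiled synchronous Boolean network.
// Nodes are indexed 0..n-1.  Each node carries a list of regulator indices
// and a truth table of length 2^k; regulator j contributes bit j (LSB first)
// of the truth-table index.  fixed[i] in {-1, 0, 1}: -1 means the node
// follows its function, otherwise the fixed value dominates.
struct CompiledNet {
  int n;
  std::vector<std::vector<int> > reg;
  std::vector<std::vector<uint8_t> > tt;
  std::vector<int> fixed;
};

static CompiledNet unpack_net(const List &net) {
  CompiledNet cn;
  List reg = net["reg"];
  List tt = net["tt"];
  IntegerVector fixed = net["fixed"];
  cn.n = fixed.size();
  cn.reg.resize(cn.n);
  cn.tt.resize(cn.n);
  cn.fixed.resize(cn.n);
  for (int i = 0; i < cn.n; ++i) {
    IntegerVector r = reg[i];
    IntegerVector t = tt[i];
    cn.reg[i].assign(r.begin(), r.end());
    for (size_t j = 0; j < cn.reg[i].size(); ++j) cn.reg[i][j] -= 1; // 1- to 0-based
    cn.tt[i].assign(t.begin(), t.end());
    cn.fixed[i] = fixed[i];
  }
  return cn;
}

static inline void step_state(const CompiledNet &cn, const std::vector<uint8_t> &s,
                              std::vector<uint8_t> &out) {
  for (int i = 0; i < cn.n; ++i) {
    if (cn.fixed[i] >= 0) {
      out[i] = (uint8_t)cn.fixed[i];
    } else {
      size_t idx = 0;
      const std::vector<int> &r = cn.reg[i];
      for (size_t j = 0; j < r.size(); ++j) idx |= ((size_t)s[r[j]]) << j;
      out[i] = cn.tt[i][idx];
    }
  }
}

static inline uint64_t encode_state(const std::vector<uint8_t> &s) {
  uint64_t code = 0;
  for (size_t i = 0; i < s.size(); ++i) code |= ((uint64_t)s[i]) << i;
  return code;
}

static inline void decode_state(uint64_t code, int n, std::vector<uint8_t> &s) {
  for (int i = 0; i < n; ++i) s[i] = (uint8_t)((code >> i) & 1ULL);
}

// Rotate a cycle of state codes so the minimal code comes first.
static std::vector<uint64_t> canonical_cycle(const std::vector<uint64_t> &cyc) {
  size_t m = cyc.size(), at = 0;
  for (size_t i = 1; i < m; ++i) if (cyc[i] < cyc[at]) at = i;
  std::vector<uint64_t> out(m);
  for (size_t i = 0; i < m; ++i) out[i] = cyc[(at + i) % m];
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_step_matrix(List net, IntegerMatrix states) {
  CompiledNet cn = unpack_net(net);
  int m = states.nrow();
  if (states.ncol() != cn.n) stop("state length does not match network size");
  IntegerMatrix out(m, cn.n);
  std::vector<uint8_t> s(cn.n), nx(cn.n);
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < cn.n; ++i) s[i] = (uint8_t)states(r, i);
    step_state(cn, s, nx);
    for (int i = 0; i < cn.n; ++i) out(r, i) = nx[i];
  }
  return out;
}

// Deterministic path from `start` until the synchronous dynamics close a
// cycle.  Returns the full path (including one complete cycle traversal),
// the transient length, and the cycle length.
// [[Rcpp::export]]
List cpp_trajectory(List net, IntegerVector start, int max_iter) {
  CompiledNet cn = unpack_net(net);
  if (start.size() != cn.n) stop("state length does not match network size");
  if (cn.n > 64) stop("compiled dynamics support at most 64 nodes");
  std::vector<uint8_t> s(cn.n), nx(cn.n);
  for (int i = 0; i < cn.n; ++i) s[i] = (uint8_t)start[i];
  std::unordered_map<uint64_t, int> seen;
  std::vector<uint64_t> path;
  path.reserve(64);
  uint64_t code = encode_state(s);
  int first = -1;
  for (int t = 0; t <= max_iter; ++t) {
    std::unordered_map<uint64_t, int>::iterator it = seen.find(code);
    if (it != seen.end()) { first = it->second; break; }
    seen[code] = (int)path.size();
    path.push_back(code);
    step_state(cn, s, nx);
    s.swap(nx);
    code = encode_state(s);
  }
  if (first < 0)
    stop("iteration cap exceeded without closing a cycle; raise max_iter");
  int cycle_len = (int)path.size() - first;
  IntegerMatrix states((int)path.size(), cn.n);
  std::vector<uint8_t> tmp(cn.n);
  for (size_t r = 0; r < path.size(); ++r) {
    decode_state(path[r], cn.n, tmp);
    for (int i = 0; i < cn.n; ++i) states((int)r, i) = tmp[i];
  }
  return List::create(_["states"] = states,
                      _["transient"] = first,
                      _["cycle_length"] = cycle_len);
}

// Exhaustive attractor search over all 2^n states (n <= 25 guard upstream).
// Returns one entry per attractor: canonical cycle codes and basin count.
// [[Rcpp::export]]
List cpp_exhaustive(List net) {
  CompiledNet cn = unpack_net(net);
  if (cn.n > 25) stop("exhaustive enumeration limited to 25 nodes");
  uint64_t nstates = 1ULL << cn.n;
  std::vector<uint32_t> succ(nstates);
  std::vector<uint8_t> s(cn.n), nx(cn.n);
  for (uint64_t c = 0; c < nstates; ++c) {
    decode_state(c, cn.n, s);
    step_state(cn, s, nx);
    succ[c] = (uint32_t)encode_state(nx);
  }
  const int32_t UNSEEN = -1, ONSTACK = -2;
  std::vector<int32_t> label(nstates, UNSEEN);
  std::vector<std::vector<uint64_t> > cycles;
  std::vector<double> basin;
  std::vector<uint64_t> stack;
  for (uint64_t c0 = 0; c0 < nstates; ++c0) {
    if (label[c0] != UNSEEN) continue;
    stack.clear();
    uint64_t cur = c0;
    while (label[cur] == UNSEEN) {
      label[cur] = ONSTACK;
      stack.push_back(cur);
      cur = succ[cur];
    }
    int attr;
    if (label[cur] == ONSTACK) {
      // new cycle: locate cur within the stack
      size_t pos = 0;
      for (size_t i = 0; i < stack.size(); ++i) if (stack[i] == cur) { pos = i; break; }
      std::vector<uint64_t> cyc(stack.begin() + pos, stack.end());
      attr = (int)cycles.size();
      cycles.push_back(canonical_cycle(cyc));
      basin.push_back(0.0);
    } else {
      attr = label[cur];
    }
    for (size_t i = 0; i < stack.size(); ++i) label[stack[i]] = attr;
    basin[attr] += (double)stack.size();
  }
  List out_cycles((int)cycles.size());
  for (size_t a = 0; a < cycles.size(); ++a) {
    NumericVector v((int)cycles[a].size());
    for (size_t i = 0; i < cycles[a].size(); ++i) v[(int)i] = (double)cycles[a][i];
    out_cycles[(int)a] = v;
  }
  return List::create(_["cycles"] = out_cycles,
                      _["basin"] = wrap(basin));
}

// Attractor discovery and basin estimation from uniformly random start
// states.  Uses R's RNG so results are reproducible under set.seed().
// Visited transient states are memoised so repeated walks short-circuit.
// [[Rcpp::export]]
List cpp_sample_attractors(List net, double n_samples, int max_iter) {
  CompiledNet cn = unpack_net(net);
  if (cn.n > 64) stop("compiled dynamics support at most 64 nodes");
  RNGScope scope;
  std::unordered_map<uint64_t, int> state2attr;
  std::unordered_map<uint64_t, int> key2attr; // min cycle code -> attractor id
  std::vector<std::vector<uint64_t> > cycles;
  std::vector<double> counts;
  std::vector<uint8_t> s(cn.n), nx(cn.n);
  std::vector<uint64_t> path;
  std::unordered_map<uint64_t, int> onpath;
  long long N = (long long)n_samples;
  for (long long k = 0; k < N; ++k) {
    for (int i = 0; i < cn.n; ++i) s[i] = (uint8_t)(unif_rand() < 0.5);
    uint64_t code = encode_state(s);
    path.clear();
    onpath.clear();
    int attr = -1;
    for (int t = 0; t <= max_iter; ++t) {
      std::unordered_map<uint64_t, int>::iterator hit = state2attr.find(code);
      if (hit != state2attr.end()) { attr = hit->second; break; }
      std::unordered_map<uint64_t, int>::iterator cyc = onpath.find(code);
      if (cyc != onpath.end()) {
        // closed a new cycle within this walk
        std::vector<uint64_t> c(path.begin() + cyc->second, path.end());
        std::vector<uint64_t> canon = canonical_cycle(c);
        std::unordered_map<uint64_t, int>::iterator reg = key2attr.find(canon[0]);
        if (reg != key2attr.end()) {
          attr = reg->second;
        } else {
          attr = (int)cycles.size();
          cycles.push_back(canon);
          counts.push_back(0.0);
          key2attr[canon[0]] = attr;
        }
        break;
      }
      onpath[code] = (int)path.size();
      path.push_back(code);
      step_state(cn, s, nx);
      s.swap(nx);
      code = encode_state(s);
    }
    if (attr < 0)
      stop("iteration cap exceeded without closing a cycle; raise max_iter");
    counts[attr] += 1.0;
    for (size_t i = 0; i < path.size(); ++i) state2attr[path[i]] = attr;
  }
  List out_cycles((int)cycles.size());
  for (size_t a = 0; a < cycles.size(); ++a) {
    NumericVector v((int)cycles[a].size());
    for (size_t i = 0; i < cycles[a].size(); ++i) v[(int)i] = (double)cycles[a][i];
    out_cycles[(int)a] = v;
  }
  return List::create(_["cycles"] = out_cycles,
                      _["basin"] = wrap(counts));
}

// One-bit-flip perturbation response: for n_states random states, flip one
// random bit, advance both states one synchronous step, and record the
// normalized Hamming distance between the successors.
// [[Rcpp::export]]
NumericVector cpp_bitflip(List net, int n_states) {
  CompiledNet cn = unpack_net(net);
  RNGScope scope;
  NumericVector out(n_states);
  std::vector<uint8_t> s(cn.n), sp(cn.n), a(cn.n), b(cn.n);
  for (int k = 0; k < n_states; ++k) {
    for (int i = 0; i < cn.n; ++i) s[i] = (uint8_t)(unif_rand() < 0.5);
    int bit = (int)(unif_rand() * cn.n);
    if (bit >= cn.n) bit = cn.n - 1;
    sp = s;
    sp[bit] ^= 1;
    step_state(cn, s, a);
    step_state(cn, sp, b);
    int h = 0;
    for (int i = 0; i < cn.n; ++i) h += (a[i] != b[i]);
    out[k] = (double)h / (double)cn.n;
  }
  return out;
}

// Graded-input simulation for one starting state: scheduled nodes are
// overridden with their realized ON/OFF sequence after every synchronous
// update.  Returns the mean activity of every node over the last `window`
// of the T simulated steps.
// [[Rcpp::export]]
NumericVector cpp_graded_one(List net, IntegerVector start,
                             IntegerMatrix schedule, IntegerVector sched_nodes,
                             int window) {
  CompiledNet cn = unpack_net(net);
  int T = schedule.nrow();
  int ns = sched_nodes.size();
  if (schedule.ncol() != ns) stop("schedule/node mismatch");
  if (window > T) stop("window larger than number of steps");
  std::vector<uint8_t> s(cn.n), nx(cn.n);
  for (int i = 0; i < cn.n; ++i) s[i] = (uint8_t)start[i];
  for (int j = 0; j < ns; ++j) {
    int node = sched_nodes[j] - 1;
    if (node < 0 || node >= cn.n) stop("scheduled node out of range");
  }
  std::vector<double> acc(cn.n, 0.0);
  for (int t = 0; t < T; ++t) {
    step_state(cn, s, nx);
    s.swap(nx);
    for (int j = 0; j < ns; ++j) s[sched_nodes[j] - 1] = (uint8_t)schedule(t, j);
    if (t >= T - window)
      for (int i = 0; i < cn.n; ++i) acc[i] += s[i];
  }
  NumericVector out(cn.n);
  for (int i = 0; i < cn.n; ++i) out[i] = acc[i] / (double)window;
  return out;
}

// Least-squares optimal step functions on sorted data for every number of
// discontinuities d = 1..dmax (dynamic programming).  For each d the
// strongest discontinuity of the optimal d-step function is returned as the
// index of the last element of the lower step (ties: lower index).  The
// strength of a discontinuity combines its jump height (difference of the
// adjacent step means) with the approximation error of thresholding the
// whole series at that position (the SSE of the best one-break fit there):
// score = jump / (sse + eps), so a large jump that also separates the data
// well dominates.
// [[Rcpp::export]]
List cpp_basca_breaks(NumericVector sorted_values, int dmax) {
  int N = sorted_values.size();
  if (N < 3) stop("need at least 3 values");
  if (dmax < 1) stop("dmax must be >= 1");
  if (dmax > N - 2) dmax = N - 2;
  std::vector<double> pre(N + 1, 0.0), pre2(N + 1, 0.0);
  for (int i = 0; i < N; ++i) {
    pre[i + 1] = pre[i] + sorted_values[i];
    pre2[i + 1] = pre2[i] + sorted_values[i] * sorted_values[i];
  }
  // cost of approximating u[i..j] (0-based, inclusive) by its mean
  #define SEGCOST(i, j) (pre2[(j) + 1] - pre2[(i)] - \
    (pre[(j) + 1] - pre[(i)]) * (pre[(j) + 1] - pre[(i)]) / (double)((j) - (i) + 1))
  #define SEGMEAN(i, j) ((pre[(j) + 1] - pre[(i)]) / (double)((j) - (i) + 1))
  // D[j] = optimal cost of fitting u[0..j] with the current number of
  // breaks; B[d][j] = position of the last break (last index of the
  // preceding segment).
  std::vector<double> Dprev(N), Dcur(N);
  std::vector<std::vector<int> > B(dmax + 1, std::vector<int>(N, -1));
  for (int j = 0; j < N; ++j) Dprev[j] = SEGCOST(0, j);
  // one-break SSE of the full series for every break position
  std::vector<double> sse1(N - 1);
  double sse_min = R_PosInf;
  for (int b = 0; b < N - 1; ++b) {
    sse1[b] = SEGCOST(0, b) + SEGCOST(b + 1, N - 1);
    if (sse1[b] < sse_min) sse_min = sse1[b];
  }
  double eps = 1e-12;
  {
    double total = SEGCOST(0, N - 1);
    if (total > 0) eps = 1e-9 * total;
  }
  IntegerVector strongest(dmax);
  NumericVector jump(dmax);
  for (int d = 1; d <= dmax; ++d) {
    for (int j = d; j < N; ++j) {
      double best = R_PosInf;
      int barg = -1;
      for (int i = d - 1; i < j; ++i) {
        double c = Dprev[i] + SEGCOST(i + 1, j);
        if (c < best - 1e-12) { best = c; barg = i; }
      }
      Dcur[j] = best;
      B[d][j] = barg;
    }
    // backtrack the optimal d-break step function over u[0..N-1]
    std::vector<int> breaks(d);
    int j = N - 1;
    for (int dd = d; dd >= 1; --dd) {
      breaks[dd - 1] = B[dd][j];
      j = B[dd][j];
    }
    // segment means -> strongest discontinuity (jump weighted by the
    // quality of a global one-break fit at that position)
    double bestscore = -1.0, bestjump = 0.0;
    int bestat = -1;
    int lo = 0;
    int prevlo_ = 0, prevhi_ = -1;
    for (int k = 0; k <= d; ++k) {
      int hi = (k == d) ? (N - 1) : breaks[k];
      if (k > 0) {
        double jmp = SEGMEAN(lo, hi) - SEGMEAN(prevlo_, prevhi_);
        double score = jmp / (sse1[prevhi_] + eps);
        if (score > bestscore * (1 + 1e-12)) {
          bestscore = score; bestjump = jmp; bestat = prevhi_;
        }
      }
      prevlo_ = lo; prevhi_ = hi;
      lo = hi + 1;
    }
    strongest[d - 1] = bestat + 1; // 1-based index of last element below break
    jump[d - 1] = bestjump;
    Dprev.swap(Dcur);
  }
  #undef SEGCOST
  #undef SEGMEAN
  return List::create(_["break_index"] = strongest, _["jump"] = jump);
}
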