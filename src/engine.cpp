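// Bit-parallel synchronous Boolean network engine.
//
// The dynamics of a network whose source (identity-rule) nodes are fixed by
// an environment decomposes exactly into one functional graph per
// environment over the remaining "free" nodes. Each environment's successor
// map is built here by evaluating the update rules bit-sliced over 64
// states per machine word, and its cycles are found by an O(N) colored
// walk of the functional graph.
//
// Postfix opcodes (shared with the R compiler): a non-negative value pushes
// the slice of that 0-based node; -1 NOT, -2 AND, -3 OR, -4 push constant
// 0, -5 push constant 1.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// In-place 64x64 bit-matrix transpose, little-endian in both indices:
// afterwards bit j of a[i] equals bit i of the original a[j]. Each stage
// swaps the high j-bit blocks of rows k with the low j-bit blocks of rows
// k+j.
static inline void transpose64(uint64_t a[64]) {
  for (int j = 32; j != 0; j >>= 1) {
    const uint64_t m = (j == 32) ? 0xFFFFFFFF00000000ULL
                     : (j == 16) ? 0xFFFF0000FFFF0000ULL
                     : (j == 8)  ? 0xFF00FF00FF00FF00ULL
                     : (j == 4)  ? 0xF0F0F0F0F0F0F0F0ULL
                     : (j == 2)  ? 0xCCCCCCCCCCCCCCCCULL
                                 : 0xAAAAAAAAAAAAAAAAULL;
    for (int k = 0; k < 64; k = (k + j + 1) & ~j) {
      const uint64_t t = (a[k] & m) >> j;
      const uint64_t u = a[k + j] & (m >> j);
      a[k] = (a[k] & ~m) | (u << j);
      a[k + j] = (a[k + j] & ~(m >> j)) | t;
    }
  }
}

// Successor map of one environment. free_idx: 0-based node indices whose
// joint configuration enumerates the map (node free_idx[j] is bit j of the
// configuration index); fixed_idx/fixed_val: the remaining nodes and their
// pinned values. Every node must appear in exactly one of the two sets.
// [[Rcpp::export]]
IntegerVector cpp_build_succ(List programs, int n_nodes,
                             IntegerVector free_idx,
                             IntegerVector fixed_idx,
                             IntegerVector fixed_val) {
  const int nf = free_idx.size();
  if (nf < 0 || nf > 26)
    stop("successor map over %d free nodes exceeds the memory budget", nf);
  if ((int)(free_idx.size() + fixed_idx.size()) != n_nodes)
    stop("free and fixed nodes must partition the network");
  const size_t nstates = (size_t)1 << nf;
  const size_t nwords = (nstates + 63) / 64;

  std::vector<int> role(n_nodes, -3);          // >=0 free position, -2 fixed
  std::vector<int> fixv(n_nodes, 0);
  for (int j = 0; j < nf; ++j) role[free_idx[j]] = j;
  for (int i = 0; i < fixed_idx.size(); ++i) {
    if (role[fixed_idx[i]] != -3) stop("node %d listed twice", fixed_idx[i] + 1);
    role[fixed_idx[i]] = -2;
    fixv[fixed_idx[i]] = fixed_val[i];
  }
  for (int v = 0; v < n_nodes; ++v)
    if (role[v] == -3) stop("node %d neither free nor fixed", v + 1);

  // Input slices: bit s of slice v = value of node v in configuration s.
  static const uint64_t pat[6] = {
      0xAAAAAAAAAAAAAAAAULL, 0xCCCCCCCCCCCCCCCCULL, 0xF0F0F0F0F0F0F0F0ULL,
      0xFF00FF00FF00FF00ULL, 0xFFFF0000FFFF0000ULL, 0xFFFFFFFF00000000ULL};
  std::vector<std::vector<uint64_t>> slice(n_nodes);
  for (int v = 0; v < n_nodes; ++v) {
    slice[v].assign(nwords, 0ULL);
    if (role[v] == -2) {
      if (fixv[v]) std::fill(slice[v].begin(), slice[v].end(), ~0ULL);
    } else {
      const int j = role[v];
      if (j < 6) {
        std::fill(slice[v].begin(), slice[v].end(), pat[j]);
      } else {
        for (size_t w = 0; w < nwords; ++w)
          if ((w >> (j - 6)) & 1) slice[v][w] = ~0ULL;
      }
    }
  }

  // Evaluate each free node's rule on the slices.
  std::vector<std::vector<uint64_t>> out(nf);
  for (int j = 0; j < nf; ++j) {
    IntegerVector prog = programs[free_idx[j]];
    std::vector<std::vector<uint64_t>> st;
    for (int pc = 0; pc < prog.size(); ++pc) {
      const int op = prog[pc];
      if (op >= 0) {
        st.push_back(slice[op]);
      } else if (op == -1) {
        for (auto &w : st.back()) w = ~w;
      } else if (op == -2 || op == -3) {
        std::vector<uint64_t> b = std::move(st.back());
        st.pop_back();
        std::vector<uint64_t> &a = st.back();
        if (op == -2)
          for (size_t w = 0; w < nwords; ++w) a[w] &= b[w];
        else
          for (size_t w = 0; w < nwords; ++w) a[w] |= b[w];
      } else if (op == -4) {
        st.push_back(std::vector<uint64_t>(nwords, 0ULL));
      } else if (op == -5) {
        st.push_back(std::vector<uint64_t>(nwords, ~0ULL));
      } else {
        stop("bad opcode %d", op);
      }
    }
    if (st.size() != 1) stop("malformed rule program for node %d", free_idx[j] + 1);
    out[j] = std::move(st.back());
  }

  // Transpose the output slices into successor configuration indices:
  // per 64-state block, succ[base+b] needs bit j = bit b of out[j], a
  // 64x64 bit-matrix transpose.
  IntegerVector succ((R_xlen_t)nstates);
  int *sp = INTEGER(succ);
  uint64_t blk[64];
  for (size_t w = 0; w < nwords; ++w) {
    const size_t base = w * 64;
    const size_t lim = std::min<size_t>(64, nstates - base);
    for (int j = 0; j < nf; ++j) blk[j] = out[j][w];
    for (int j = nf; j < 64; ++j) blk[j] = 0;
    transpose64(blk);
    for (size_t b = 0; b < lim; ++b) sp[base + b] = (int)blk[b];
  }
  return succ;
}

// All cycles of the functional graph i -> succ[i]. Each cycle is returned
// in step order; rotation canonicalization happens in R.
// [[Rcpp::export]]
List cpp_find_cycles(IntegerVector succ) {
  const R_xlen_t n = succ.size();
  const int *sp = INTEGER(succ);
  std::vector<uint8_t> color(n, 0);  // 0 new, 1 on current path, 2 finished
  std::vector<int> path;
  std::vector<std::vector<int>> cycles;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (color[i]) continue;
    path.clear();
    int x = (int)i;
    while (color[x] == 0) {
      color[x] = 1;
      path.push_back(x);
      x = sp[x];
    }
    if (color[x] == 1) {  // closed a new cycle within the current path
      size_t pos = path.size() - 1;
      while (path[pos] != x) --pos;
      cycles.emplace_back(path.begin() + pos, path.end());
    }
    for (int v : path) color[v] = 2;
  }
  List res((R_xlen_t)cycles.size());
  for (size_t c = 0; c < cycles.size(); ++c)
    res[c] = IntegerVector(cycles[c].begin(), cycles[c].end());
  return res;
}

// For each query configuration, the 1-based index of the cycle its
// trajectory reaches, plus the transient length (steps to first cycle
// state), by walking the successor map.
// [[Rcpp::export]]
List cpp_reach_cycle(IntegerVector succ, List cycles, IntegerVector queries) {
  const R_xlen_t n = succ.size();
  const int *sp = INTEGER(succ);
  std::vector<int> attr(n, -1);
  for (R_xlen_t c = 0; c < cycles.size(); ++c) {
    IntegerVector cyc = cycles[c];
    for (int s : cyc) attr[s] = (int)c;
  }
  const R_xlen_t m = queries.size();
  IntegerVector which((R_xlen_t)m), steps((R_xlen_t)m);
  for (R_xlen_t q = 0; q < m; ++q) {
    int x = queries[q], k = 0;
    while (attr[x] < 0) {
      x = sp[x];
      if (++k > (int)n) stop("no cycle reached; inconsistent successor map");
    }
    which[q] = attr[x] + 1;
    steps[q] = k;
  }
  return List::create(_["attractor"] = which, _["transient"] = steps);
}

// ---- per-state stepping on full integer-encoded states -------------------

struct CompiledRules {
  int n;
  std::vector<std::vector<int>> regs;   // 0-based regulator indices
  std::vector<std::vector<uint8_t>> tab;
  CompiledRules(List regulators, List tables, int n_nodes) : n(n_nodes) {
    regs.resize(n);
    tab.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector r = regulators[i];
      regs[i].assign(r.begin(), r.end());
      IntegerVector t = tables[i];
      tab[i].assign(t.begin(), t.end());
    }
  }
  inline uint32_t step(uint32_t s) const {
    uint32_t nxt = 0;
    for (int i = 0; i < n; ++i) {
      uint32_t idx = 0;
      for (int r : regs[i]) idx = (idx << 1) | ((s >> r) & 1u);
      nxt |= (uint32_t)tab[i][idx] << i;
    }
    return nxt;
  }
};

// One synchronous step for each integer-encoded state (node 0 = bit 0).
// [[Rcpp::export]]
IntegerVector cpp_step_batch(List regulators, List tables, int n_nodes,
                             IntegerVector states) {
  CompiledRules cr(regulators, tables, n_nodes);
  const R_xlen_t m = states.size();
  IntegerVector res(m);
  for (R_xlen_t q = 0; q < m; ++q)
    res[q] = (int)cr.step((uint32_t)states[q]);
  return res;
}

// Walk each start state until it hits one of the known (sorted) attractor
// states; report the attractor id of the state hit and the number of steps
// taken. known_state must be sorted ascending; known_attr gives the
// attractor id for each known state.
// [[Rcpp::export]]
List cpp_walk_to_known(List regulators, List tables, int n_nodes,
                       IntegerVector starts, IntegerVector known_state,
                       IntegerVector known_attr, int max_steps) {
  CompiledRules cr(regulators, tables, n_nodes);
  const int *ks = INTEGER(known_state);
  const int *ka = INTEGER(known_attr);
  const int nk = known_state.size();
  const R_xlen_t m = starts.size();
  IntegerVector attr(m), steps(m);
  for (R_xlen_t q = 0; q < m; ++q) {
    uint32_t x = (uint32_t)starts[q];
    int k = 0;
    for (;;) {
      const int *hit = std::lower_bound(ks, ks + nk, (int)x);
      if (hit != ks + nk && *hit == (int)x) {
        attr[q] = ka[hit - ks];
        steps[q] = k;
        break;
      }
      if (k >= max_steps)
        stop("state did not reach a known attractor within %d steps", max_steps);
      x = cr.step(x);
      ++k;
    }
  }
  return List::create(_["attractor"] = attr, _["transient"] = steps);
}
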