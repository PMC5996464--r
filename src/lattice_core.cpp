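// Compiled core for the IUPAC motif lattice.
//
// IUPAC characters are encoded as 4-bit masks over {A,C,G,T}
// (A=1, C=2, G=4, T=8); a motif of length L is a 4L-bit code with
// position 0 (leftmost character) in the lowest nibble.  The lattice over
// a positive key set can be complete (all 15^L motifs when every L-mer is
// present), so node storage is flat arrays indexed by a dense code table
// when 16^L is small, and a hash map otherwise.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <memory>

using namespace Rcpp;

namespace {

// degeneracy level (popcount) per nibble
const int NIB_LEVEL[16] = {0, 1, 1, 2, 1, 2, 2, 3, 1, 2, 2, 3, 2, 3, 3, 4};
// display character per nibble
const char NIB_CHAR[16] = {'?', 'A', 'C', 'M', 'G', 'R', 'S', 'V',
                           'T', 'W', 'Y', 'H', 'K', 'D', 'B', 'N'};
// canonical ordering A,C,G,T,M,R,W,S,Y,K,V,H,D,B,N used for deterministic
// lexicographic tie-breaks
const int NIB_RANK[16] = {99, 0, 1, 4, 2, 5, 7, 10, 3, 6, 8, 11, 9, 12, 13, 14};

inline int nib(uint64_t code, int i) { return (int)((code >> (4 * i)) & 15ULL); }
inline uint64_t set_nib(uint64_t code, int i, int v) {
  return (code & ~(15ULL << (4 * i))) | ((uint64_t)v << (4 * i));
}

int nib_from_char(char ch) {
  switch (ch) {
    case 'A': return 1;  case 'C': return 2;  case 'M': return 3;
    case 'G': return 4;  case 'R': return 5;  case 'S': return 6;
    case 'V': return 7;  case 'T': return 8;  case 'W': return 9;
    case 'Y': return 10; case 'H': return 11; case 'K': return 12;
    case 'D': return 13; case 'B': return 14; case 'N': return 15;
    default:  return 0;
  }
}

struct LatticeCore {
  int L = 0, d = 0;
  int n_pos = 0, n_neg = 0;
  bool dense = false;
  uint64_t code_space = 0;
  std::vector<int32_t> dense_idx;                 // code -> node id, -1 absent
  std::unordered_map<uint64_t, int32_t> map_idx;
  std::vector<uint64_t> id2code;
  std::vector<int32_t> level_start;               // node-id bounds per weight level
  // level-0 (exact word) data, in node-id order
  std::vector<double> w_occ_pos, w_occ_neg;
  std::vector<std::vector<int32_t>> w_seq_pos, w_seq_neg;  // 0-based seq indices
  // per-node statistics (filled by attach)
  double win_pos = 0, win_neg = 0;  // total valid windows per dataset
  bool occurrence_stat = false;
  std::vector<int32_t> a, b;
  std::vector<double> occ_pos, occ_neg, mi;
  std::vector<uint8_t> removed;                   // persistent masking flag
  std::vector<int32_t> order;                     // ids sorted for simplification
  bool attached = false;

  int32_t lookup(uint64_t code) const {
    if (dense) return dense_idx[code];
    auto it = map_idx.find(code);
    return it == map_idx.end() ? -1 : it->second;
  }
  void insert(uint64_t code, int32_t id) {
    if (dense) dense_idx[code] = id; else map_idx[code] = id;
  }
  int n_nodes() const { return (int)id2code.size(); }
  int deg_of(uint64_t code) const {
    int k = 0;
    for (int i = 0; i < L; ++i) k += NIB_LEVEL[nib(code, i)] >= 2;
    return k;
  }
  std::string text(uint64_t code) const {
    std::string s((size_t)L, '?');
    for (int i = 0; i < L; ++i) s[(size_t)i] = NIB_CHAR[nib(code, i)];
    return s;
  }
  uint64_t code_from_text(const std::string &s) const {
    if ((int)s.size() != L) stop("motif length does not match lattice L");
    uint64_t code = 0;
    for (int i = 0; i < L; ++i) {
      int v = nib_from_char(s[(size_t)i]);
      if (v == 0) stop("invalid IUPAC character in motif: %s", s.c_str());
      code = set_nib(code, i, v);
    }
    return code;
  }
};

void lattice_finalizer(SEXP x) {
  LatticeCore *p = (LatticeCore *)R_ExternalPtrAddr(x);
  if (p) { delete p; R_ClearExternalPtr(x); }
}

LatticeCore &get_core(SEXP x) {
  if (TYPEOF(x) != EXTPTRSXP) stop("not a lattice pointer");
  LatticeCore *p = (LatticeCore *)R_ExternalPtrAddr(x);
  if (!p) stop("lattice has been released");
  return *p;
}

double mi_bits_cells(double a, double b, double c, double d) {
  double n = a + b + c + d;
  double rows[2] = {a + b, c + d};
  double cols[2] = {a + c, b + d};
  double cell[2][2] = {{a, b}, {c, d}};
  double s = 0.0;
  for (int r = 0; r < 2; ++r)
    for (int cc = 0; cc < 2; ++cc)
      if (cell[r][cc] > 0)
        s += (cell[r][cc] / n) * std::log2(cell[r][cc] * n / (rows[r] * cols[cc]));
  return s > 0 ? s : 0.0;
}

// Union DP over sequence-presence bitsets.  A node's instance set is the
// union of the instance sets of its remove-one-letter children at its
// first degenerate position, all of which sit exactly one weight level
// below, so only two adjacent level buffers (ping-pong, allocated once)
// are live at any time.  Positive and negative presence are packed into
// one bitset per node and counted from the two word ranges.
void sweep_seq_block(LatticeCore &core,
                     const std::vector<std::vector<int32_t>> &wseqs,
                     int s0, int s1, uint64_t *prev, uint64_t *cur,
                     std::vector<int32_t> &out);

void sweep_seq_counts(LatticeCore &core,
                      const std::vector<std::vector<int32_t>> &wseqs,
                      int nseq, std::vector<int32_t> &out) {
  int nlev = (int)core.level_start.size() - 1;
  size_t maxlev = (size_t)core.level_start[1];
  for (int g = 1; g < nlev; ++g) {
    size_t sz = (size_t)(core.level_start[(size_t)g + 1] -
                         core.level_start[(size_t)g]);
    if (sz > maxlev) maxlev = sz;
  }
  // cap the two transient level buffers at ~1.2 GB by sweeping the
  // sequence space in blocks; per-block union counts add up because the
  // blocks partition the sequences
  int W_full = (nseq + 63) / 64;
  if (W_full < 1) W_full = 1;
  double bytes = 2.0 * (double)maxlev * W_full * 8.0;
  int nblocks = (int)(bytes / 1.2e9) + 1;
  int block_seqs = (nseq + nblocks - 1) / nblocks;
  block_seqs = ((block_seqs + 63) / 64) * 64;  // word-aligned blocks
  if (block_seqs < 64) block_seqs = 64;
  int W = block_seqs / 64;
  std::unique_ptr<uint64_t[]> prev(new uint64_t[maxlev * W]),
      cur(new uint64_t[maxlev * W]);
  for (int s0 = 0; s0 < nseq || s0 == 0; s0 += block_seqs) {
    int s1 = s0 + block_seqs;
    if (s1 > nseq) s1 = nseq;
    sweep_seq_block(core, wseqs, s0, s1, prev.get(), cur.get(), out);
    if (nseq == 0) break;
  }
}

void sweep_seq_block(LatticeCore &core,
                     const std::vector<std::vector<int32_t>> &wseqs,
                     int s0, int s1, uint64_t *prev_buf, uint64_t *cur_buf,
                     std::vector<int32_t> &out) {
  int W = ((s1 - s0) + 63) / 64;
  if (W < 1) W = 1;
  int nlev = (int)core.level_start.size() - 1;
  int n0 = core.level_start[1];
  uint64_t *prev = prev_buf, *cur = cur_buf;
  std::memset(prev, 0, (size_t)n0 * W * 8);
  for (int id = 0; id < n0; ++id) {
    uint64_t *bs = &prev[(size_t)id * W];
    const std::vector<int32_t> &sl = wseqs[(size_t)id];
    auto lo = std::lower_bound(sl.begin(), sl.end(), (int32_t)s0);
    auto hi = std::lower_bound(lo, sl.end(), (int32_t)s1);
    for (auto it = lo; it != hi; ++it) {
      int s = *it - s0;
      bs[s >> 6] |= 1ULL << (s & 63);
    }
    out[(size_t)id] += (int32_t)(hi - lo);
  }
  for (int g = 1; g < nlev; ++g) {
    int lo = core.level_start[(size_t)g], hi = core.level_start[(size_t)g + 1];
    int plo = core.level_start[(size_t)g - 1];
    for (int id = lo; id < hi; ++id) {
      uint64_t code = core.id2code[(size_t)id];
      int i = 0;
      while (NIB_LEVEL[nib(code, i)] < 2) ++i;
      int c = nib(code, i);
      const uint64_t *child[4];
      int nch = 0;
      for (int m = c; m; m &= m - 1) {
        int32_t cid = core.lookup(set_nib(code, i, c & ~(m & -m)));
        child[nch++] = &prev[(size_t)(cid - plo) * W];
      }
      uint64_t *__restrict dst = &cur[(size_t)(id - lo) * W];
      int32_t cnt = 0;
      if (nch == 2) {
        const uint64_t *__restrict c0 = child[0], *__restrict c1 = child[1];
        for (int w = 0; w < W; ++w) {
          uint64_t v = c0[w] | c1[w];
          dst[w] = v;
          cnt += __builtin_popcountll(v);
        }
      } else {
        std::memcpy(dst, child[0], (size_t)W * 8);
        for (int k = 1; k + 1 < nch; ++k) {
          const uint64_t *__restrict src = child[k];
          for (int w = 0; w < W; ++w) dst[w] |= src[w];
        }
        const uint64_t *__restrict last = child[nch - 1];
        for (int w = 0; w < W; ++w) {
          uint64_t v = dst[w] | last[w];
          dst[w] = v;
          cnt += __builtin_popcountll(v);
        }
      }
      out[(size_t)id] += cnt;
    }
    std::swap(prev, cur);
  }
}

// flag-bit flood to all present ancestors (add one base to one position).
// The flagged set stays upward-closed, so stopping at flagged nodes is safe.
void flood_up(LatticeCore &core, uint64_t code0,
              std::vector<uint8_t> &flag, uint8_t bit) {
  std::vector<uint64_t> stack;
  stack.push_back(code0);
  while (!stack.empty()) {
    uint64_t code = stack.back();
    stack.pop_back();
    for (int i = 0; i < core.L; ++i) {
      int c = nib(code, i);
      for (int m = 15 & ~c; m; m &= m - 1) {
        uint64_t p = set_nib(code, i, c | (m & -m));
        int32_t pid = core.lookup(p);
        if (pid >= 0 && !(flag[(size_t)pid] & bit)) {
          flag[(size_t)pid] |= bit;
          stack.push_back(p);
        }
      }
    }
  }
}

void flood_down(LatticeCore &core, uint64_t code0,
                std::vector<uint8_t> &flag, uint8_t bit) {
  std::vector<uint64_t> stack;
  stack.push_back(code0);
  while (!stack.empty()) {
    uint64_t code = stack.back();
    stack.pop_back();
    for (int i = 0; i < core.L; ++i) {
      int c = nib(code, i);
      if (NIB_LEVEL[c] < 2) continue;
      for (int m = c; m; m &= m - 1) {
        uint64_t ch = set_nib(code, i, c & ~(m & -m));
        int32_t cid = core.lookup(ch);
        if (cid >= 0 && !(flag[(size_t)cid] & bit)) {
          flag[(size_t)cid] |= bit;
          stack.push_back(ch);
        }
      }
    }
  }
}

void flood_up_removed(LatticeCore &core, uint64_t code0) {
  std::vector<uint64_t> stack;
  stack.push_back(code0);
  while (!stack.empty()) {
    uint64_t code = stack.back();
    stack.pop_back();
    for (int i = 0; i < core.L; ++i) {
      int c = nib(code, i);
      for (int m = 15 & ~c; m; m &= m - 1) {
        uint64_t p = set_nib(code, i, c | (m & -m));
        int32_t pid = core.lookup(p);
        if (pid >= 0 && !core.removed[(size_t)pid]) {
          core.removed[(size_t)pid] = 1;
          stack.push_back(p);
        }
      }
    }
  }
}

void enum_instances(const LatticeCore &core, uint64_t code, int i,
                    uint64_t acc, std::vector<uint64_t> &out) {
  if (i == core.L) { out.push_back(acc); return; }
  int c = nib(code, i);
  for (int m = c; m; m &= m - 1)
    enum_instances(core, code, i + 1, set_nib(acc, i, m & -m), out);
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_lattice(CharacterVector lmers, NumericVector occ_pos,
                       NumericVector occ_neg, List seqs_pos, List seqs_neg,
                       int n_pos, int n_neg, int d) {
  int nw = lmers.size();
  if (nw == 0) stop("empty L-mer table");
  std::string first = as<std::string>(lmers[0]);
  int L = (int)first.size();
  if (L < 1 || L > 15) stop("motif length must be between 1 and 15");
  if (d < 0 || d > L) stop("d must satisfy 0 <= d <= L");

  LatticeCore *core = new LatticeCore();
  core->L = L;
  core->d = d;
  core->n_pos = n_pos;
  core->n_neg = n_neg;
  core->dense = (4 * L) <= 24;
  if (core->dense) {
    core->code_space = 1ULL << (4 * L);
    core->dense_idx.assign((size_t)core->code_space, -1);
  }

  core->w_occ_pos.resize((size_t)nw);
  core->w_occ_neg.resize((size_t)nw);
  core->w_seq_pos.resize((size_t)nw);
  core->w_seq_neg.resize((size_t)nw);
  for (int k = 0; k < nw; ++k) {
    std::string s = as<std::string>(lmers[k]);
    if ((int)s.size() != L) { delete core; stop("L-mers have unequal lengths"); }
    uint64_t code = 0;
    for (int i = 0; i < L; ++i) {
      int v = nib_from_char(s[(size_t)i]);
      if (NIB_LEVEL[v] != 1) { delete core; stop("L-mer keys must be exact words over A,C,G,T"); }
      code = set_nib(code, i, v);
    }
    if (core->lookup(code) >= 0) { delete core; stop("duplicate L-mer key: %s", s.c_str()); }
    core->insert(code, k);
    core->id2code.push_back(code);
    core->w_occ_pos[(size_t)k] = occ_pos[k];
    core->w_occ_neg[(size_t)k] = occ_neg[k];
    IntegerVector sp = seqs_pos[k], sn = seqs_neg[k];
    core->w_seq_pos[(size_t)k].assign(sp.begin(), sp.end());
    core->w_seq_neg[(size_t)k].assign(sn.begin(), sn.end());
    for (int32_t &v : core->w_seq_pos[(size_t)k]) --v;  // R 1-based -> 0-based
    for (int32_t &v : core->w_seq_neg[(size_t)k]) --v;
  }

  core->level_start.push_back(0);
  core->level_start.push_back(nw);

  // Apriori-style level-wise generalization: raise one position by one
  // character-lattice level; keep a candidate iff every remove-one-letter
  // child at that position is already a node (all instances present).
  std::vector<int32_t> prev(nw);
  for (int k = 0; k < nw; ++k) prev[(size_t)k] = k;
  while (!prev.empty()) {
    std::vector<int32_t> next;
    for (int32_t id : prev) {
      uint64_t code = core->id2code[(size_t)id];
      int degc = core->deg_of(code);
      for (int i = 0; i < L; ++i) {
        int c = nib(code, i);
        if (NIB_LEVEL[c] == 4) continue;
        bool base = NIB_LEVEL[c] == 1;
        if (base && degc + 1 > d) continue;
        for (int m = 15 & ~c; m; m &= m - 1) {
          int pc = c | (m & -m);
          uint64_t cand = set_nib(code, i, pc);
          if (core->lookup(cand) >= 0) continue;
          bool ok = true;
          for (int mm = pc; mm; mm &= mm - 1) {
            if (core->lookup(set_nib(cand, i, pc & ~(mm & -mm))) < 0) {
              ok = false;
              break;
            }
          }
          if (!ok) continue;
          int32_t nid = core->n_nodes();
          core->insert(cand, nid);
          core->id2code.push_back(cand);
          next.push_back(nid);
        }
      }
    }
    if (next.empty()) break;
    core->level_start.push_back(core->n_nodes());
    prev.swap(next);
  }

  core->removed.assign((size_t)core->n_nodes(), 0);

  SEXP x = PROTECT(R_MakeExternalPtr(core, R_NilValue, R_NilValue));
  R_RegisterCFinalizerEx(x, lattice_finalizer, TRUE);
  UNPROTECT(1);
  return x;
}

// stat: "sequence" scores the Table-style sequence-presence cells
// (a, b, n_pos - a, n_neg - b); "occurrence" scores occurrence-count
// cells (occ_pos, occ_neg, win_pos - occ_pos, win_neg - occ_neg).
// [[Rcpp::export]]
void cpp_attach_tables(SEXP ptr, bool occurrence_stat, double win_pos,
                       double win_neg) {
  LatticeCore &core = get_core(ptr);
  core.occurrence_stat = occurrence_stat;
  core.win_pos = win_pos;
  core.win_neg = win_neg;
  int n = core.n_nodes();
  core.a.assign((size_t)n, 0);
  core.b.assign((size_t)n, 0);
  sweep_seq_counts(core, core.w_seq_pos, core.n_pos, core.a);
  sweep_seq_counts(core, core.w_seq_neg, core.n_neg, core.b);

  // occurrence totals: additive over the disjoint split of the first
  // degenerate position into its lowest base and the remainder
  core.occ_pos.assign((size_t)n, 0.0);
  core.occ_neg.assign((size_t)n, 0.0);
  int n0 = core.level_start[1];
  for (int id = 0; id < n0; ++id) {
    core.occ_pos[(size_t)id] = core.w_occ_pos[(size_t)id];
    core.occ_neg[(size_t)id] = core.w_occ_neg[(size_t)id];
  }
  for (int id = n0; id < n; ++id) {
    uint64_t code = core.id2code[(size_t)id];
    int i = 0;
    while (NIB_LEVEL[nib(code, i)] < 2) ++i;
    int c = nib(code, i);
    int low = c & -c;
    int32_t id1 = core.lookup(set_nib(code, i, low));
    int32_t id2 = core.lookup(set_nib(code, i, c ^ low));
    core.occ_pos[(size_t)id] = core.occ_pos[(size_t)id1] + core.occ_pos[(size_t)id2];
    core.occ_neg[(size_t)id] = core.occ_neg[(size_t)id1] + core.occ_neg[(size_t)id2];
  }

  // MI via the entropy identity with a precomputed x*log2(x) table:
  // n*MI = sum_cells xlx - sum_rows xlx - sum_cols xlx + xlx(n)
  core.mi.assign((size_t)n, 0.0);
  {
    long long np, nn;
    if (occurrence_stat) {
      np = (long long)win_pos;
      nn = (long long)win_neg;
    } else {
      np = core.n_pos;
      nn = core.n_neg;
    }
    long long ntot = np + nn;
    std::vector<double> xlx((size_t)ntot + 1, 0.0);
    for (long long x = 2; x <= ntot; ++x)
      xlx[(size_t)x] = (double)x * std::log2((double)x);
    for (int id = 0; id < n; ++id) {
      long long av, bv;
      if (occurrence_stat) {
        av = (long long)core.occ_pos[(size_t)id];
        bv = (long long)core.occ_neg[(size_t)id];
      } else {
        av = core.a[(size_t)id];
        bv = core.b[(size_t)id];
      }
      long long cv = np - av, dv = nn - bv;
      double v = xlx[(size_t)av] + xlx[(size_t)bv] + xlx[(size_t)cv] +
                 xlx[(size_t)dv] - xlx[(size_t)(av + bv)] -
                 xlx[(size_t)(cv + dv)] - xlx[(size_t)(av + cv)] -
                 xlx[(size_t)(bv + dv)] + xlx[(size_t)ntot];
      core.mi[(size_t)id] = v > 0 ? v / ntot : 0.0;
    }
  }

  // contiguous sort keys: MI desc, a desc, canonical motif text asc
  struct Key { double mi; uint64_t lex; int32_t a, id; };
  std::vector<Key> keys((size_t)n);
  const int LL = core.L;
  for (int id = 0; id < n; ++id) {
    uint64_t code = core.id2code[(size_t)id], lex = 0;
    for (int i = 0; i < LL; ++i)
      lex = (lex << 4) | (uint64_t)NIB_RANK[nib(code, i)];
    int32_t support = occurrence_stat ? (int32_t)core.occ_pos[(size_t)id]
                                      : core.a[(size_t)id];
    keys[(size_t)id] = {core.mi[(size_t)id], lex, support, id};
  }
  std::sort(keys.begin(), keys.end(), [](const Key &x, const Key &y) {
    if (x.mi != y.mi) return x.mi > y.mi;
    if (x.a != y.a) return x.a > y.a;
    return x.lex < y.lex;
  });
  core.order.resize((size_t)n);
  for (int id = 0; id < n; ++id) core.order[(size_t)id] = keys[(size_t)id].id;
  core.attached = true;
}

// [[Rcpp::export]]
List cpp_lattice_info(SEXP ptr) {
  LatticeCore &core = get_core(ptr);
  int nlev = (int)core.level_start.size() - 1;
  IntegerVector per(nlev);
  for (int g = 0; g < nlev; ++g)
    per[g] = core.level_start[(size_t)g + 1] - core.level_start[(size_t)g];
  return List::create(_["L"] = core.L, _["d"] = core.d,
                      _["n_nodes"] = core.n_nodes(),
                      _["n_pos"] = core.n_pos, _["n_neg"] = core.n_neg,
                      _["nodes_per_weight"] = per,
                      _["attached"] = core.attached);
}

// [[Rcpp::export]]
IntegerVector cpp_simplify(SEXP ptr) {
  LatticeCore &core = get_core(ptr);
  if (!core.attached) stop("attach tables before simplifying");
  int n = core.n_nodes();
  std::vector<uint8_t> flag((size_t)n, 0);
  std::vector<int32_t> sel;
  for (int32_t id : core.order) {
    if (core.removed[(size_t)id] || flag[(size_t)id]) continue;
    sel.push_back(id);
    flag[(size_t)id] = 3;
    uint64_t code = core.id2code[(size_t)id];
    flood_up(core, code, flag, 1);
    flood_down(core, code, flag, 2);
  }
  return IntegerVector(sel.begin(), sel.end());
}

// [[Rcpp::export]]
void cpp_mask(SEXP ptr, std::string motif) {
  LatticeCore &core = get_core(ptr);
  uint64_t code = core.code_from_text(motif);
  if (core.lookup(code) < 0) stop("motif %s is not a lattice node", motif.c_str());
  std::vector<uint64_t> words;
  enum_instances(core, code, 0, 0ULL, words);
  for (uint64_t w : words) {
    int32_t wid = core.lookup(w);
    if (wid >= 0 && !core.removed[(size_t)wid]) {
      core.removed[(size_t)wid] = 1;
      flood_up_removed(core, w);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_node_info(SEXP ptr, IntegerVector ids) {
  LatticeCore &core = get_core(ptr);
  int n = ids.size();
  CharacterVector motif(n);
  IntegerVector lev(n), av(n), bv(n);
  NumericVector op(n), on(n), miv(n);
  for (int k = 0; k < n; ++k) {
    int id = ids[k];
    if (id < 0 || id >= core.n_nodes()) stop("node id out of range");
    uint64_t code = core.id2code[(size_t)id];
    motif[k] = core.text(code);
    lev[k] = core.deg_of(code);
    if (core.attached) {
      av[k] = core.a[(size_t)id];
      bv[k] = core.b[(size_t)id];
      op[k] = core.occ_pos[(size_t)id];
      on[k] = core.occ_neg[(size_t)id];
      miv[k] = core.mi[(size_t)id];
    } else {
      av[k] = NA_INTEGER; bv[k] = NA_INTEGER;
      op[k] = NA_REAL; on[k] = NA_REAL; miv[k] = NA_REAL;
    }
  }
  return DataFrame::create(_["motif"] = motif, _["level"] = lev,
                           _["a"] = av, _["b"] = bv,
                           _["occ_pos"] = op, _["occ_neg"] = on,
                           _["mi"] = miv, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_all_nodes(SEXP ptr) {
  LatticeCore &core = get_core(ptr);
  int n = core.n_nodes();
  IntegerVector ids(n);
  for (int id = 0; id < n; ++id) ids[id] = id;
  DataFrame df = cpp_node_info(ptr, ids);
  CharacterVector status(n);
  for (int id = 0; id < n; ++id)
    status[id] = core.removed[(size_t)id] ? "removed" : "active";
  df.push_back(status, "status");
  return df;
}

// [[Rcpp::export]]
IntegerVector cpp_status(SEXP ptr, CharacterVector motifs) {
  LatticeCore &core = get_core(ptr);
  int n = motifs.size();
  IntegerVector out(n);  // -1 absent, 0 active, 1 removed
  for (int k = 0; k < n; ++k) {
    uint64_t code = core.code_from_text(as<std::string>(motifs[k]));
    int32_t id = core.lookup(code);
    out[k] = id < 0 ? -1 : (core.removed[(size_t)id] ? 1 : 0);
  }
  return out;
}

// [[Rcpp::export]]
void cpp_free_lattice(SEXP ptr) {
  if (TYPEOF(ptr) != EXTPTRSXP) stop("not a lattice pointer");
  LatticeCore *p = (LatticeCore *)R_ExternalPtrAddr(ptr);
  if (p) { delete p; R_ClearExternalPtr(ptr); }
}

// ---- counting ------------------------------------------------------------

namespace {

// encode one sequence as 0..3 per base, -1 for non-ACGT
void encode_bases(const char *s, int len, std::vector<int8_t> &out) {
  out.resize((size_t)len);
  for (int i = 0; i < len; ++i) {
    switch (s[i]) {
      case 'A': out[(size_t)i] = 0; break;
      case 'C': out[(size_t)i] = 1; break;
      case 'G': out[(size_t)i] = 2; break;
      case 'T': out[(size_t)i] = 3; break;
      default:  out[(size_t)i] = -1;
    }
  }
}

struct WordStats {
  double occ_pos = 0, occ_neg = 0;
  std::vector<int32_t> seq_pos, seq_neg;
};

// emit valid windows of one sequence; scanning if offset < 0, else the
// single window at `offset` (already resolved; caller skips short seqs)
template <typename F>
void emit_windows(const std::vector<int8_t> &enc, int L, int offset, F f) {
  int len = (int)enc.size();
  if (len < L) return;
  if (offset >= 0 && offset + L > len) return;
  int lo = offset < 0 ? 0 : offset;
  int hi = offset < 0 ? len - L : offset;
  for (int i = lo; i <= hi; ++i) {
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < L; ++j) {
      int8_t bb = enc[(size_t)(i + j)];
      if (bb < 0) { ok = false; break; }
      code |= (uint64_t)bb << (2 * j);
    }
    if (ok) f(code);
  }
}

std::string decode_word(uint64_t code, int L) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s((size_t)L, 'A');
  for (int j = 0; j < L; ++j) s[(size_t)j] = B[(code >> (2 * j)) & 3ULL];
  return s;
}

}  // namespace

// offsets: one per sequence, 0-based window start, or -1 for scanning mode,
// or -2 to skip the sequence (shorter than L in fixed mode)
// [[Rcpp::export]]
List cpp_count_lmers(CharacterVector pos, CharacterVector neg, int L,
                     IntegerVector pos_offsets, IntegerVector neg_offsets) {
  if (L < 1 || L > 15) stop("L must be between 1 and 15");
  std::unordered_map<uint64_t, int32_t> widx;
  std::vector<WordStats> stats;
  std::vector<uint64_t> codes;
  std::vector<int8_t> enc;

  double win_pos = 0, win_neg = 0;
  for (int s = 0; s < pos.size(); ++s) {
    const char *str = CHAR(STRING_ELT(pos, s));
    int off = pos_offsets.size() ? pos_offsets[s] : -1;
    if (off == -2) continue;
    encode_bases(str, (int)std::strlen(str), enc);
    emit_windows(enc, L, off, [&](uint64_t code) {
      win_pos += 1;
      auto it = widx.find(code);
      int32_t k;
      if (it == widx.end()) {
        k = (int32_t)stats.size();
        widx.emplace(code, k);
        stats.emplace_back();
        codes.push_back(code);
      } else {
        k = it->second;
      }
      WordStats &w = stats[(size_t)k];
      w.occ_pos += 1;
      if (w.seq_pos.empty() || w.seq_pos.back() != s) w.seq_pos.push_back(s);
    });
  }

  for (int s = 0; s < neg.size(); ++s) {
    const char *str = CHAR(STRING_ELT(neg, s));
    int off = neg_offsets.size() ? neg_offsets[s] : -1;
    if (off == -2) continue;
    encode_bases(str, (int)std::strlen(str), enc);
    emit_windows(enc, L, off, [&](uint64_t code) {
      win_neg += 1;
      auto it = widx.find(code);
      if (it == widx.end()) return;  // only words present in the positive set
      WordStats &w = stats[(size_t)it->second];
      w.occ_neg += 1;
      if (w.seq_neg.empty() || w.seq_neg.back() != s) w.seq_neg.push_back(s);
    });
  }

  // deterministic alphabetical key order (A<C<G<T == numeric code order)
  std::vector<int32_t> ord(codes.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int32_t)k;
  std::sort(ord.begin(), ord.end(), [&codes](int32_t x, int32_t y) {
    uint64_t cx = codes[(size_t)x], cy = codes[(size_t)y];
    // compare leftmost position first (low bits)
    for (int j = 0; 4 * j < 64; ++j) {
      int bx = (int)((cx >> (2 * j)) & 3ULL), by = (int)((cy >> (2 * j)) & 3ULL);
      if (bx != by) return bx < by;
    }
    return false;
  });

  int nk = (int)ord.size();
  CharacterVector lmers(nk);
  NumericVector occ_pos(nk), occ_neg(nk);
  List seq_pos(nk), seq_neg(nk);
  for (int k = 0; k < nk; ++k) {
    const WordStats &w = stats[(size_t)ord[(size_t)k]];
    lmers[k] = decode_word(codes[(size_t)ord[(size_t)k]], L);
    occ_pos[k] = w.occ_pos;
    occ_neg[k] = w.occ_neg;
    IntegerVector sp(w.seq_pos.begin(), w.seq_pos.end());
    IntegerVector sn(w.seq_neg.begin(), w.seq_neg.end());
    for (int &v : sp) ++v;  // 1-based for R
    for (int &v : sn) ++v;
    seq_pos[k] = sp;
    seq_neg[k] = sn;
  }
  return List::create(_["lmer"] = lmers, _["occ_pos"] = occ_pos,
                      _["occ_neg"] = occ_neg, _["seqs_pos"] = seq_pos,
                      _["seqs_neg"] = seq_neg,
                      _["n_windows_pos"] = win_pos,
                      _["n_windows_neg"] = win_neg);
}

// scanning-mode occurrence starts (1-based) of an IUPAC motif per sequence
// [[Rcpp::export]]
List cpp_scan_motif(CharacterVector seqs, std::string motif) {
  int L = (int)motif.size();
  std::vector<int> mnib((size_t)L);
  for (int i = 0; i < L; ++i) {
    mnib[(size_t)i] = nib_from_char(motif[(size_t)i]);
    if (mnib[(size_t)i] == 0) stop("invalid IUPAC character in motif");
  }
  List out(seqs.size());
  std::vector<int8_t> enc;
  for (int s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    encode_bases(str, (int)std::strlen(str), enc);
    std::vector<int> hits;
    int len = (int)enc.size();
    for (int i = 0; i + L <= len; ++i) {
      bool ok = true;
      for (int j = 0; j < L; ++j) {
        int8_t bb = enc[(size_t)(i + j)];
        if (bb < 0 || !(mnib[(size_t)j] & (1 << bb))) { ok = false; break; }
      }
      if (ok) hits.push_back(i + 1);
    }
    out[s] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}
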