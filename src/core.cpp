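// Alignment engine: k-mer seeded, diagonal-banded local alignment of noisy
// long reads, plus low-complexity scoring, tandem self-matching, exact
// edit distance (blocked bit-parallel) and pileup majority polishing.
#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <map>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- encoding

static inline uint8_t base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

// mask intervals (half-open, 0-based) -> per-position flag
static std::vector<uint8_t> mask_flags(int len, const IntegerMatrix& iv) {
  std::vector<uint8_t> f(len, 0);
  for (int r = 0; r < iv.nrow(); ++r) {
    int b = std::max(0, iv(r, 0)), e = std::min(len, iv(r, 1));
    for (int p = b; p < e; ++p) f[p] = 1;
  }
  return f;
}

// ------------------------------------------------- exact edit distance
// Blocked bit-parallel Levenshtein (Myers/Hyyro). Global distance between
// code vectors; vertical deltas of the final column are summed at the end,
// so no per-column score bookkeeping is needed.
static int myers_global(const uint8_t* p, int m, const uint8_t* t, int n) {
  if (m == 0) return n;
  if (n == 0) return m;
  const int w = (m + 63) / 64;
  static thread_local std::vector<uint64_t> Peq;
  Peq.assign(5 * w, 0);
  for (int i = 0; i < m; ++i) {
    uint8_t c = p[i];
    if (c < 4) Peq[(size_t)c * w + i / 64] |= (uint64_t)1 << (i % 64);
    // 'N' (code 4) matches nothing
  }
  static thread_local std::vector<uint64_t> Pv, Mv, Zero;
  Pv.assign(w, ~(uint64_t)0); Mv.assign(w, 0);
  if ((int)Zero.size() < w) Zero.assign(w, 0);
  uint64_t* __restrict pv = Pv.data();
  uint64_t* __restrict mv = Mv.data();
  const uint64_t* peq = Peq.data();
  const uint64_t* zero = Zero.data();
  for (int j = 0; j < n; ++j) {
    uint8_t c = t[j];
    const uint64_t* __restrict eq = (c < 4) ? peq + (size_t)c * w : zero;
    int hin = 1; // D(0, j) = j
    for (int b = 0; b < w; ++b) {
      uint64_t Eq = eq[b];
      if (hin < 0) Eq |= 1;
      uint64_t Pv0 = pv[b], Mv0 = mv[b];
      uint64_t Xv = Eq | Mv0;
      uint64_t Xh = (((Eq & Pv0) + Pv0) ^ Pv0) | Eq;
      uint64_t Ph = Mv0 | ~(Xh | Pv0);
      uint64_t Mh = Pv0 & Xh;
      int hout = (int)(Ph >> 63) - (int)(Mh >> 63);
      Ph = (Ph << 1) | (uint64_t)(hin > 0);
      Mh = (Mh << 1) | (uint64_t)(hin < 0);
      pv[b] = Mh | ~(Xv | Ph);
      mv[b] = Ph & Xv;
      hin = hout;
    }
  }
  long d = n;
  for (int i = 0; i < m; ++i) {
    if ((Pv[i / 64] >> (i % 64)) & 1) d += 1;
    else if ((Mv[i / 64] >> (i % 64)) & 1) d -= 1;
  }
  return (int)d;
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  std::vector<uint8_t> ea = encode_seq(a), eb = encode_seq(b);
  if (ea.size() <= eb.size())
    return myers_global(ea.data(), ea.size(), eb.data(), eb.size());
  return myers_global(eb.data(), eb.size(), ea.data(), ea.size());
}

// ---------------------------------------------------------------- seeding

struct Seed { int a, b; };

struct AlnSeg {
  int a_b, a_e, b_b, b_e;   // oriented coordinates within the pair
  int path_diffs;           // diffs along the banded path (upper bound)
  std::vector<int> segd_a;  // per segment-bucket diffs along A
  std::vector<int> segd_b;  // ... along B (forward-strand buckets)
  int seg0_a, seg0_b;
  std::vector<uint8_t> ops; // kept only when want_ops (polishing)
};

struct PairParams {
  int k, band_w, diag_band, min_seeds, max_seed_gap, min_len, max_kmer_occ;
  double max_div;
  int seg_width;
  int mask_ext;     // masked bases an extension may cross before stopping
  bool want_seg;
  bool want_ops = false;
};

static PairParams read_params(const List& p) {
  PairParams q;
  q.k = as<int>(p["k"]);
  q.band_w = as<int>(p["band_width"]);
  q.diag_band = as<int>(p["diag_band"]);
  q.min_seeds = as<int>(p["min_seeds"]);
  q.max_seed_gap = as<int>(p["max_seed_gap"]);
  q.min_len = as<int>(p["min_alignment_length"]);
  q.max_kmer_occ = as<int>(p["max_kmer_occ"]);
  q.max_div = as<double>(p["max_divergence"]);
  q.seg_width = as<int>(p["segment_width"]);
  q.mask_ext = as<int>(p["mask_extension_limit"]);
  q.want_seg = as<bool>(p["segment_diffs"]);
  return q;
}

// k-mers as 2-bit packed values; returns -1 for windows containing N
static void kmer_scan(const std::vector<uint8_t>& s, int k,
                      std::vector<int64_t>& out) {
  int n = (int)s.size();
  out.assign(std::max(0, n - k + 1), -1);
  int64_t val = 0, mask = ((int64_t)1 << (2 * k)) - 1;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    if (s[i] < 4) { val = ((val << 2) | s[i]) & mask; ++run; }
    else { val = 0; run = 0; }
    if (run >= k) out[i - k + 1] = val;
  }
}

// ------------------------------------------------- banded guided alignment

// Global alignment of A[As,Ae) vs B[Bs,Be) banded around a guide diagonal
// derived from the seed chain; emits the op string (0=match,1=sub,2=insB,3=delA).
// Returns false if the band bookkeeping fails (degenerate region).
static bool guided_band_align(const std::vector<uint8_t>& A,
                              const std::vector<uint8_t>& B,
                              int As, int Ae, int Bs, int Be,
                              const std::vector<Seed>& chain, int k, int W,
                              std::vector<uint8_t>& ops) {
  const int n = Ae - As, m = Be - Bs;
  if (n <= 0 || m <= 0) return false;
  const int width = 2 * W + 1;
  const int BIG = 1 << 28;

  // guide diagonal per row (global A coordinate -> expected diag a-b)
  static thread_local std::vector<int> diag;
  diag.assign(n + 1, 0);
  {
    size_t t = 0;
    for (int i = 0; i <= n; ++i) {
      int ga = As + i;
      while (t + 1 < chain.size() && chain[t + 1].a <= ga) ++t;
      if (chain.empty()) { diag[i] = As - Bs; continue; }
      if (ga <= chain.front().a) diag[i] = chain.front().a - chain.front().b;
      else if (ga >= chain.back().a) diag[i] = chain.back().a - chain.back().b;
      else {
        const Seed &p = chain[t], &q = chain[t + 1];
        double f = (double)(ga - p.a) / (double)(q.a - p.a);
        diag[i] = p.a - p.b + (int)std::lround(f * ((q.a - q.b) - (p.a - p.b)));
      }
    }
  }
  static thread_local std::vector<int> lo, hi;
  lo.assign(n + 1, 0); hi.assign(n + 1, 0);
  for (int i = 0; i <= n; ++i) {
    int jg = (As + i) - diag[i] - Bs;
    lo[i] = std::max(0, jg - W);
    hi[i] = std::min(m, jg + W);
    if (i > 0) { // monotone, connected windows
      lo[i] = std::max(lo[i], lo[i - 1]);
      if (lo[i] > hi[i - 1] + 1) lo[i] = hi[i - 1] + 1;
      hi[i] = std::max(hi[i], lo[i]);
    }
  }
  lo[0] = 0; hi[n] = std::max(hi[n], m); // corners must be reachable
  if (hi[n] - lo[n] > 2 * width || hi[0] > 2 * width) {
    // widened corner rows beyond band capacity: fall back to clamping
    hi[0] = std::min(hi[0], lo[0] + width - 1);
    hi[n] = std::min(hi[n], lo[n] + width - 1);
    if (hi[n] < m) return false;
  }
  int cap = width + 2;
  for (int i = 0; i <= n; ++i) if (hi[i] - lo[i] + 1 > cap) cap = hi[i] - lo[i] + 1;

  static thread_local std::vector<int> prev, cur;
  static thread_local std::vector<uint8_t> bp;
  prev.assign(cap + 1, BIG); cur.assign(cap + 1, BIG);
  // only in-band cells are written and read back during traceback
  if (bp.size() < (size_t)(n + 1) * cap) bp.resize((size_t)(n + 1) * cap);

  for (int j = lo[0]; j <= hi[0]; ++j) { prev[j - lo[0]] = j; bp[j - lo[0]] = 2; }
  for (int i = 1; i <= n; ++i) {
    uint8_t ac = A[As + i - 1];
    int l = lo[i], h = hi[i], pl = lo[i - 1], ph = hi[i - 1];
    for (int j = l; j <= h; ++j) {
      // tie preference: insert, delete, then diagonal — co-optimal paths
      // then push indels to the alignment ends, where trimming wants them
      int best = BIG; uint8_t dir = 0;
      if (j - 1 >= l) { // left: insert from B
        int c = cur[j - 1 - l] + 1;
        if (c < best) { best = c; dir = 2; }
      }
      if (j >= pl && j <= ph) { // up: delete from A
        int c = prev[j - pl] + 1;
        if (c < best) { best = c; dir = 1; }
      }
      if (j >= 1 && j - 1 >= pl && j - 1 <= ph) { // diag
        int c = prev[j - 1 - pl] + ((ac == B[Bs + j - 1] && ac < 4) ? 0 : 1);
        if (c < best) { best = c; dir = 0; }
      }
      if (j == 0) { int c = i; if (c < best) { best = c; dir = 1; } } // D(i,0)=i
      cur[j - l] = best;
      bp[(size_t)i * cap + (j - l)] = dir;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), BIG);
  }
  if (m < lo[n] || m > hi[n]) return false;

  // traceback from (n, m)
  ops.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(3); --i; continue; }
    if (j < lo[i] || j > hi[i]) return false;
    uint8_t d = bp[(size_t)i * cap + (j - lo[i])];
    if (d == 0) {
      uint8_t ac = A[As + i - 1];
      ops.push_back((ac == B[Bs + j - 1] && ac < 4) ? 0 : 1);
      --i; --j;
    } else if (d == 1) { ops.push_back(3); --i; }
    else { ops.push_back(2); --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return true;
}

// full (unbanded) DP for short inter-anchor gaps; same op codes and the
// same gap-first tie preference as the banded version
#define SMALL_GAP_MAX 96
static void small_gap_dp(const std::vector<uint8_t>& A,
                         const std::vector<uint8_t>& B,
                         int ca, int ta, int cb, int tb,
                         std::vector<uint8_t>& out_ops) {
  const int n = ta - ca, m = tb - cb;
  static thread_local int16_t row0[SMALL_GAP_MAX + 1], row1[SMALL_GAP_MAX + 1];
  static thread_local uint8_t bpm[(SMALL_GAP_MAX + 1) * (SMALL_GAP_MAX + 1)];
  static thread_local uint8_t path[2 * SMALL_GAP_MAX + 2];
  int16_t* prev = row0; int16_t* cur = row1;
  const uint8_t* __restrict bseq = B.data() + cb;
  for (int j = 0; j <= m; ++j) { prev[j] = (int16_t)j; bpm[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    uint8_t ac = A[ca + i - 1];
    uint8_t* __restrict bprow = bpm + (size_t)i * (m + 1);
    cur[0] = (int16_t)i; bprow[0] = 1;
    for (int j = 1; j <= m; ++j) {
      int best = cur[j - 1] + 1; uint8_t d = 2;
      int up = prev[j] + 1;
      if (up < best) { best = up; d = 1; }
      int dg = prev[j - 1] + (int)!(ac == bseq[j - 1] && ac < 4);
      if (dg < best) { best = dg; d = 0; }
      cur[j] = (int16_t)best; bprow[j] = d;
    }
    std::swap(prev, cur);
  }
  int np = 0, i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t d = bpm[(size_t)i * (m + 1) + j];
    if (d == 0) {
      uint8_t ac = A[ca + i - 1];
      path[np++] = (ac == bseq[j - 1] && ac < 4) ? 0 : 1;
      --i; --j;
    } else if (d == 1) { path[np++] = 3; --i; }
    else { path[np++] = 2; --j; }
  }
  out_ops.insert(out_ops.end(),
                 std::reverse_iterator<uint8_t*>(path + np),
                 std::reverse_iterator<uint8_t*>(path));
}

// Anchored middle alignment along a seed chain: stretches where
// consecutive anchors share a diagonal and the intervening bases match
// are emitted directly; everything else goes through a small banded DP
// between the anchors. Far cheaper than one DP across the whole chain.
static bool align_middle(const std::vector<uint8_t>& A,
                         const std::vector<uint8_t>& B,
                         const std::vector<Seed>& chain, int k, int W,
                         std::vector<uint8_t>& ops) {
  ops.clear();
  if (chain.empty()) return false;
  int ca = chain[0].a, cb = chain[0].b;
  ops.insert(ops.end(), k, 0); // the first seed is an exact k-mer match
  ca += k; cb += k;
  for (size_t t = 1; t < chain.size(); ++t) {
    int ta = chain[t].a + k, tb = chain[t].b + k;
    if (ta <= ca || tb <= cb) continue; // engulfed by the previous anchor
    int ga = ta - ca, gb = tb - cb;
    if (chain[t].a < ca || chain[t].b < cb) {
      // overlapping seeds: consistent only if the diagonal is unchanged
      if (ga != gb) continue;
      ops.insert(ops.end(), ga, 0); // inside the t-th exact k-mer
      ca = ta; cb = tb;
      continue;
    }
    if (ga == gb) {
      bool same = true;
      for (int x = 0; x < ga; ++x)
        if (A[ca + x] != B[cb + x] || A[ca + x] >= 4) { same = false; break; }
      if (same) {
        ops.insert(ops.end(), ga, 0);
        ca = ta; cb = tb;
        continue;
      }
    }
    if (ga <= 96 && gb <= 96) {
      small_gap_dp(A, B, ca, ta, cb, tb, ops);
      ca = ta; cb = tb;
      continue;
    }
    int Wsub = std::min(W, std::abs(ga - gb) + 16);
    std::vector<Seed> anchors = {{ca - k, cb - k}, {chain[t].a, chain[t].b}};
    std::vector<uint8_t> sub;
    if (!guided_band_align(A, B, ca, ta, cb, tb, anchors, k, Wsub, sub))
      return false;
    ops.insert(ops.end(), sub.begin(), sub.end());
    ca = ta; cb = tb;
  }
  return true;
}

// Score-maximizing banded extension from an anchor toward the sequence
// boundaries (match +max_div, error -(1-max_div), X-drop). dir=+1
// extends forward from (ax, bx); dir=-1 backward with (ax, bx)
// exclusive. Returned ops are in forward sequence order.
struct ExtRes { std::vector<uint8_t> ops; int alen, blen; };

// steps outward from `from` before more than `limit` masked bases are
// crossed (mask == nullptr means unbounded)
static int mask_capped_extent(const std::vector<uint8_t>* m, int from,
                              int dir, int limit, int full) {
  if (!m || m->empty()) return full;
  int cnt = 0;
  for (int s = 1; s <= full; ++s) {
    int pos = dir > 0 ? from + s - 1 : from - s;
    if ((*m)[pos] && ++cnt > limit) return s - 1;
  }
  return full;
}

static ExtRes extend_score(const std::vector<uint8_t>& A,
                           const std::vector<uint8_t>& B,
                           int ax, int bx, int dir, int W, double md,
                           int maxA, int maxB) {
  const double gain = md, loss = 1.0 - md, XDROP = 30.0;
  ExtRes res; res.alen = 0; res.blen = 0;
  if (maxA == 0 && maxB == 0) return res;
  const int width = 2 * W + 1;
  const double NEG = -1e18;
  static thread_local std::vector<double> prev, cur;
  static thread_local std::vector<uint8_t> bp;
  prev.assign(width + 2, NEG); cur.assign(width + 2, NEG);
  // bp grows row by row; only in-window cells are ever written and read
  if ((int)bp.size() < width) bp.resize((size_t)width * 64);
  double best = 0.0; int bi = 0, bj = 0;
  // row 0: pure insertions
  {
    int l0 = 0, h0 = std::min(maxB, W);
    for (int j = l0; j <= h0; ++j) {
      prev[j - l0] = -loss * j;
      if (j > 0) bp[j - l0] = 2;
      else bp[0] = 254; // origin
    }
  }
  int lo_prev = 0, hi_prev = std::min(maxB, W);
  for (int i = 1; i <= maxA; ++i) {
    int l = std::max(0, i - W), h = std::min(maxB, i + W);
    if (l > h) break;
    if (bp.size() < (size_t)(i + 1) * width)
      bp.resize(std::max((size_t)(i + 1) * width, bp.size() * 2));
    uint8_t ac = dir > 0 ? A[ax + i - 1] : A[ax - i];
    double rowbest = NEG;
    for (int j = l; j <= h; ++j) {
      double s = NEG; uint8_t d = 255;
      if (j - 1 >= l) { double c = cur[j - 1 - l] - loss;
        if (c > s) { s = c; d = 2; } }
      if (j >= lo_prev && j <= hi_prev) { double c = prev[j - lo_prev] - loss;
        if (c > s) { s = c; d = 1; } }
      if (j >= 1 && j - 1 >= lo_prev && j - 1 <= hi_prev) {
        uint8_t bc = dir > 0 ? B[bx + j - 1] : B[bx - j];
        bool m = (ac == bc && ac < 4);
        double c = prev[j - 1 - lo_prev] + (m ? gain : -loss);
        if (c > s) { s = c; d = m ? 0 : 4; } // 4 = substitution
      }
      if (j == 0) { double c = -loss * i; if (c > s) { s = c; d = 1; } }
      cur[j - l] = s;
      bp[(size_t)i * width + (j - l)] = d;
      if (s > rowbest) rowbest = s;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    if (rowbest < best - XDROP) break; // X-drop termination
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), NEG);
    lo_prev = l; hi_prev = h;
  }
  if (best <= 0.0) return res;
  // traceback from (bi, bj) to the origin
  std::vector<uint8_t> path;
  int i = bi, j = bj;
  while (!(i == 0 && j == 0)) {
    int l = std::max(0, i - W);
    uint8_t d = bp[(size_t)i * width + (j - l)];
    if (d == 0) { path.push_back(0); --i; --j; }
    else if (d == 4) { path.push_back(1); --i; --j; }
    else if (d == 1) { path.push_back(3); --i; }
    else if (d == 2) { path.push_back(2); --j; }
    else break;
  }
  // traceback order is endpoint->anchor; forward order needs a reverse
  // for dir=+1 (anchor->endpoint) and is already forward for dir=-1
  if (dir > 0) std::reverse(path.begin(), path.end());
  res.ops = std::move(path);
  res.alen = bi; res.blen = bj;
  return res;
}

// Extract all maximal high-identity segments from the op string
// (iterated Kadane with positive-score segments masked out between passes).
struct OpSeg { int o_b, o_e; };

static std::vector<OpSeg> identity_segments(const std::vector<uint8_t>& ops,
                                            double max_div, int min_len) {
  std::vector<OpSeg> out;
  const int n = (int)ops.size();
  std::vector<double> sc(n);
  for (int i = 0; i < n; ++i)
    sc[i] = (ops[i] == 0) ? max_div : -(1.0 - max_div);
  std::vector<uint8_t> used(n, 0);
  for (int pass = 0; pass < 12; ++pass) {
    double best = 0, run = 0;
    int bs = -1, be = -1, rs = 0;
    for (int i = 0; i < n; ++i) {
      double v = used[i] ? -1e18 : sc[i];
      if (run <= 0) { run = v; rs = i; } else run += v;
      if (run > best) { best = run; bs = rs; be = i + 1; }
    }
    if (bs < 0 || best <= 0) break;
    // trim to match ops at the borders
    while (bs < be && ops[bs] != 0) ++bs;
    while (be > bs && ops[be - 1] != 0) --be;
    for (int i = bs; i < be; ++i) used[i] = 1;
    if (be - bs >= min_len) out.push_back({bs, be});
    if (be - bs < min_len / 2) break;
  }
  std::sort(out.begin(), out.end(),
            [](const OpSeg& x, const OpSeg& y) { return x.o_b < y.o_b; });
  return out;
}

// Run the guided alignment for one seed cluster and collect segments.
// `comp` and Lb are needed only to bucket B-side segment diffs on the
// forward strand.
static void align_cluster(const std::vector<uint8_t>& A,
                          const std::vector<uint8_t>& B,
                          std::vector<Seed>& seeds, const PairParams& P,
                          std::vector<AlnSeg>& out,
                          bool comp = false, int Lb = 0,
                          const std::vector<uint8_t>* mA = nullptr,
                          const std::vector<uint8_t>* mBo = nullptr) {
  if (Lb == 0) Lb = (int)B.size();
  if ((int)seeds.size() < P.min_seeds) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    return x.a != y.a ? x.a < y.a : x.b < y.b;
  });
  // longest strictly-increasing chain in b (a already sorted)
  const int ns = (int)seeds.size();
  std::vector<int> tail, tidx(ns), par(ns, -1);
  for (int i = 0; i < ns; ++i) {
    int lod = 0, hid = (int)tail.size();
    while (lod < hid) {
      int mid = (lod + hid) / 2;
      if (seeds[tail[mid]].b < seeds[i].b &&
          seeds[tail[mid]].a < seeds[i].a) lod = mid + 1;
      else hid = mid;
    }
    if (lod == (int)tail.size()) tail.push_back(i); else tail[lod] = i;
    tidx[i] = lod;
    par[i] = lod > 0 ? tail[lod - 1] : -1;
  }
  std::vector<Seed> chain;
  for (int i = tail.empty() ? -1 : tail.back(); i >= 0; i = par[i])
    chain.push_back(seeds[i]);
  std::reverse(chain.begin(), chain.end());
  if ((int)chain.size() < P.min_seeds) return;

  // split the chain where the diagonal jumps beyond the band or the seed
  // gap is large; each piece is aligned separately and re-joined by chaining
  std::vector<std::vector<Seed>> pieces;
  pieces.push_back({chain[0]});
  for (size_t i = 1; i < chain.size(); ++i) {
    const Seed &p = pieces.back().back(), &q = chain[i];
    int dd = std::abs((q.a - q.b) - (p.a - p.b));
    if (dd > P.band_w / 2 || q.a - p.a > P.max_seed_gap ||
        q.b - p.b > P.max_seed_gap)
      pieces.push_back({});
    pieces.back().push_back(q);
  }
  for (auto& pc : pieces) {
    if ((int)pc.size() < 1) continue;
    if ((int)pc.size() < P.min_seeds && pieces.size() > 1 &&
        (pc.back().a + P.k - pc.front().a) < P.min_len / 2) continue;
    int a1 = pc.front().a, b1 = pc.front().b;
    int a2 = pc.back().a + P.k, b2 = pc.back().b + P.k;
    int W = P.band_w / 4; // half-band of the DP window
    // anchored alignment along the seed chain, plus score-maximizing
    // extensions outward to the sequence boundaries
    std::vector<uint8_t> mid;
    if (!align_middle(A, B, pc, P.k, W, mid)) continue;
    // extensions may cross only a bounded stretch of masked sequence, so
    // alignments end at long masked repeats (rescued later by chaining
    // or mask-free re-alignment)
    ExtRes le = extend_score(A, B, a1, b1, -1, W, P.max_div,
      mask_capped_extent(mA, a1, -1, P.mask_ext, a1),
      mask_capped_extent(mBo, b1, -1, P.mask_ext, b1));
    ExtRes re = extend_score(A, B, a2, b2, +1, W, P.max_div,
      mask_capped_extent(mA, a2, +1, P.mask_ext, (int)A.size() - a2),
      mask_capped_extent(mBo, b2, +1, P.mask_ext, (int)B.size() - b2));
    int As = a1 - le.alen, Bs = b1 - le.blen;
    std::vector<uint8_t> ops;
    ops.reserve(le.ops.size() + mid.size() + re.ops.size());
    ops.insert(ops.end(), le.ops.begin(), le.ops.end());
    ops.insert(ops.end(), mid.begin(), mid.end());
    ops.insert(ops.end(), re.ops.begin(), re.ops.end());
    std::vector<OpSeg> segs = identity_segments(ops, P.max_div, P.min_len);
    // map op offsets to coordinates
    std::vector<int> ai(ops.size() + 1), bj(ops.size() + 1);
    int ia = As, jb = Bs;
    for (size_t t = 0; t < ops.size(); ++t) {
      ai[t] = ia; bj[t] = jb;
      if (ops[t] == 0 || ops[t] == 1) { ++ia; ++jb; }
      else if (ops[t] == 2) ++jb;
      else ++ia;
    }
    ai[ops.size()] = ia; bj[ops.size()] = jb;
    for (const OpSeg& sg : segs) {
      AlnSeg s;
      s.a_b = ai[sg.o_b]; s.a_e = ai[sg.o_e];
      s.b_b = bj[sg.o_b]; s.b_e = bj[sg.o_e];
      if (s.a_e - s.a_b < P.min_len && s.b_e - s.b_b < P.min_len) continue;
      s.path_diffs = 0;
      int fbb = comp ? (Lb - s.b_e) : s.b_b;
      int fbe = comp ? (Lb - s.b_b) : s.b_e;
      if (P.want_seg) {
        s.seg0_a = s.a_b / P.seg_width;
        s.segd_a.assign(s.a_e / P.seg_width - s.seg0_a + 1, 0);
        s.seg0_b = fbb / P.seg_width;
        s.segd_b.assign(fbe / P.seg_width - s.seg0_b + 1, 0);
      } else { s.seg0_a = 0; s.seg0_b = 0; }
      for (int t = sg.o_b; t < sg.o_e; ++t) {
        if (ops[t] != 0) {
          ++s.path_diffs;
          if (P.want_seg) {
            int ka = std::min(ai[t], s.a_e - 1) / P.seg_width - s.seg0_a;
            if (ka >= 0 && ka < (int)s.segd_a.size()) s.segd_a[ka]++;
            int jb = std::min(std::max(bj[t], s.b_b), s.b_e - 1);
            int fb = comp ? (Lb - 1 - jb) : jb;
            int kb2 = fb / P.seg_width - s.seg0_b;
            if (kb2 >= 0 && kb2 < (int)s.segd_b.size()) s.segd_b[kb2]++;
          }
        }
      }
      if (P.want_ops)
        s.ops.assign(ops.begin() + sg.o_b, ops.begin() + sg.o_e);
      out.push_back(std::move(s));
    }
  }
}

// Align one oriented pair: seeds from A's k-mer table vs oriented B.
static void align_oriented(const std::vector<uint8_t>& A,
                           const std::vector<uint8_t>& B,
                           const std::vector<uint8_t>& maskA,
                           const std::vector<uint8_t>& maskB_oriented,
                           const PairParams& P, std::vector<AlnSeg>& out,
                           bool comp = false) {
  if ((int)A.size() < P.k || (int)B.size() < P.k) return;
  std::vector<int64_t> ka, kb;
  kmer_scan(A, P.k, ka);
  kmer_scan(B, P.k, kb);
  std::unordered_map<int64_t, std::vector<int>> tab;
  tab.reserve(ka.size() * 2);
  for (int i = 0; i < (int)ka.size(); ++i) {
    if (ka[i] < 0) continue;
    if (!maskA.empty() && maskA[i]) continue;
    tab[ka[i]].push_back(i);
  }
  std::vector<Seed> seeds;
  for (int j = 0; j < (int)kb.size(); ++j) {
    if (kb[j] < 0) continue;
    if (!maskB_oriented.empty() && maskB_oriented[j]) continue;
    auto it = tab.find(kb[j]);
    if (it == tab.end()) continue;
    if ((int)it->second.size() > P.max_kmer_occ) continue;
    for (int i : it->second) seeds.push_back({i, j});
  }
  if ((int)seeds.size() < P.min_seeds) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
    int dx = x.a - x.b, dy = y.a - y.b;
    return dx != dy ? dx < dy : x.a < y.a;
  });
  std::vector<Seed> clus;
  for (size_t t = 0; t <= seeds.size(); ++t) {
    bool flush = (t == seeds.size());
    if (!flush && !clus.empty()) {
      int dprev = clus.back().a - clus.back().b;
      int dcur = seeds[t].a - seeds[t].b;
      if (dcur - dprev > P.diag_band) flush = true;
    }
    if (flush) {
      if ((int)clus.size() >= P.min_seeds)
        align_cluster(A, B, clus, P, out, comp, (int)B.size(),
                      maskA.empty() ? nullptr : &maskA,
                      maskB_oriented.empty() ? nullptr : &maskB_oriented);
      clus.clear();
      if (t == seeds.size()) break;
    }
    clus.push_back(seeds[t]);
  }
}

// convert oriented-B segments to forward-strand B coordinates and finalize
// exact diffs; dedup and identity-filter
static void finalize_pair(const std::vector<uint8_t>& A,
                          const std::vector<uint8_t>& Bor, int Lb, bool comp,
                          const PairParams& P, std::vector<AlnSeg>& segs,
                          int a_id, int b_id,
                          std::vector<int>& ra, std::vector<int>& rb,
                          std::vector<int>& rc, std::vector<int>& rab,
                          std::vector<int>& rae, std::vector<int>& rbb,
                          std::vector<int>& rbe, std::vector<int>& rd,
                          std::vector<std::vector<int>>* sega_out,
                          std::vector<int>* seg0a_out,
                          std::vector<std::vector<int>>* segb_out,
                          std::vector<int>* seg0b_out) {
  std::sort(segs.begin(), segs.end(), [](const AlnSeg& x, const AlnSeg& y) {
    if (x.a_b != y.a_b) return x.a_b < y.a_b;
    if (x.a_e != y.a_e) return x.a_e < y.a_e;
    return x.b_b < y.b_b;
  });
  for (size_t i = 0; i < segs.size(); ++i) {
    const AlnSeg& s = segs[i];
    if (i > 0) {
      const AlnSeg& p = segs[i - 1];
      if (p.a_b == s.a_b && p.a_e == s.a_e && p.b_b == s.b_b && p.b_e == s.b_e)
        continue; // duplicate from overlapping clusters
    }
    int spanA = s.a_e - s.a_b, spanB = s.b_e - s.b_b;
    // the banded path cost bounds the true distance from above; a clean
    // path needs no exact recompute
    int d = (s.path_diffs == 0 && spanA == spanB)
      ? 0 : myers_global(&A[s.a_b], spanA, &Bor[s.b_b], spanB);
    double ident = 1.0 - (double)d / (double)std::max(spanA, spanB);
    if (ident < 1.0 - P.max_div) continue;
    if (std::max(spanA, spanB) < P.min_len) continue;
    int fb = comp ? (Lb - s.b_e) : s.b_b;
    int fe = comp ? (Lb - s.b_b) : s.b_e;
    ra.push_back(a_id); rb.push_back(b_id); rc.push_back(comp ? 1 : 0);
    rab.push_back(s.a_b); rae.push_back(s.a_e);
    rbb.push_back(fb); rbe.push_back(fe);
    rd.push_back(d);
    if (sega_out) {
      sega_out->push_back(s.segd_a);
      seg0a_out->push_back(s.seg0_a);
      segb_out->push_back(s.segd_b);
      seg0b_out->push_back(s.seg0_b);
    }
  }
}

static std::vector<uint8_t> orient_mask(const std::vector<uint8_t>& m, bool comp) {
  if (!comp || m.empty()) return m;
  // k-mer start positions map to forward positions L - j - k; masking is
  // applied per-position, so reversing the flag vector is the transform
  std::vector<uint8_t> r(m.rbegin(), m.rend());
  return r;
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b,
                    IntegerMatrix mask_a, IntegerMatrix mask_b, List params) {
  PairParams P = read_params(params);
  std::vector<uint8_t> A = encode_seq(a), Bf = encode_seq(b);
  std::vector<uint8_t> Br = revcomp_codes(Bf);
  std::vector<uint8_t> ma = mask_flags((int)A.size(), mask_a);
  std::vector<uint8_t> mb = mask_flags((int)Bf.size(), mask_b);
  std::vector<int> ra, rb, rc, rab, rae, rbb, rbe, rd, seg0a, seg0b;
  std::vector<std::vector<int>> sega, segb;
  for (int o = 0; o < 2; ++o) {
    bool comp = (o == 1);
    const std::vector<uint8_t>& B = comp ? Br : Bf;
    std::vector<uint8_t> mbo = orient_mask(mb, comp);
    std::vector<AlnSeg> segs;
    align_oriented(A, B, ma, mbo, P, segs, comp);
    finalize_pair(A, B, (int)Bf.size(), comp, P, segs, 1, 2,
                  ra, rb, rc, rab, rae, rbb, rbe, rd,
                  P.want_seg ? &sega : nullptr, P.want_seg ? &seg0a : nullptr,
                  P.want_seg ? &segb : nullptr, P.want_seg ? &seg0b : nullptr);
  }
  DataFrame tab = DataFrame::create(
    _["comp"] = rc, _["a_begin"] = rab, _["a_end"] = rae,
    _["b_begin"] = rbb, _["b_end"] = rbe, _["diffs"] = rd);
  List segla(sega.size()), seglb(segb.size());
  for (size_t i = 0; i < sega.size(); ++i) segla[i] = wrap(sega[i]);
  for (size_t i = 0; i < segb.size(); ++i) seglb[i] = wrap(segb[i]);
  return List::create(_["tab"] = tab, _["seg_a"] = segla, _["seg0_a"] = seg0a,
                      _["seg_b"] = seglb, _["seg0_b"] = seg0b);
}

// All-vs-all over a read set: one global k-mer index over forward strands,
// every unordered pair attempted once via shared seeds.
// [[Rcpp::export]]
List cpp_all_vs_all(CharacterVector seqs, List masks, List params) {
  PairParams P = read_params(params);
  const int R = seqs.size();
  std::vector<std::vector<uint8_t>> enc(R), rcv(R), mfl(R);
  for (int i = 0; i < R; ++i) {
    enc[i] = encode_seq(as<std::string>(seqs[i]));
    rcv[i] = revcomp_codes(enc[i]);
    if (masks.size() > i && !Rf_isNull(masks[i]))
      mfl[i] = mask_flags((int)enc[i].size(), as<IntegerMatrix>(masks[i]));
  }
  // global index: kmer -> (read, pos) on forward strands, unmasked starts
  std::unordered_map<int64_t, std::vector<std::pair<int, int>>> index;
  {
    std::vector<int64_t> km;
    for (int i = 0; i < R; ++i) {
      kmer_scan(enc[i], P.k, km);
      for (int p = 0; p < (int)km.size(); ++p) {
        if (km[p] < 0) continue;
        if (!mfl[i].empty() && mfl[i][p]) continue;
        index[km[p]].push_back({i, p});
      }
    }
  }
  std::vector<int> ra, rb, rc, rab, rae, rbb, rbe, rd, seg0a, seg0b;
  std::vector<std::vector<int>> sega, segb;
  std::vector<int64_t> km;
  // per B-read: gather seeds against all A-reads with smaller index as a
  // flat vector sorted afterwards (a per-hit map is far too slow for
  // low-error data where seeds are dense)
  struct Hit { int32_t i, a, b; };
  std::vector<Hit> hits;
  for (int j = 1; j < R; ++j) {
    for (int o = 0; o < 2; ++o) {
      bool comp = (o == 1);
      const std::vector<uint8_t>& B = comp ? rcv[j] : enc[j];
      std::vector<uint8_t> mbo = orient_mask(mfl[j], comp);
      kmer_scan(B, P.k, km);
      hits.clear();
      for (int p = 0; p < (int)km.size(); ++p) {
        if (km[p] < 0) continue;
        if (!mbo.empty() && mbo[p]) continue;
        auto it = index.find(km[p]);
        if (it == index.end()) continue;
        if ((int)it->second.size() > P.max_kmer_occ) continue;
        for (const auto& hit : it->second)
          if (hit.first < j) hits.push_back({hit.first, hit.second, p});
      }
      std::sort(hits.begin(), hits.end(), [](const Hit& x, const Hit& y) {
        if (x.i != y.i) return x.i < y.i;
        int dx = x.a - x.b, dy = y.a - y.b;
        return dx != dy ? dx < dy : x.a < y.a;
      });
      size_t lo = 0;
      std::vector<Seed> seeds, clus;
      while (lo < hits.size()) {
        size_t hi = lo;
        while (hi < hits.size() && hits[hi].i == hits[lo].i) ++hi;
        int i = hits[lo].i;
        if ((int)(hi - lo) >= P.min_seeds) {
          seeds.clear();
          int stride = std::max((size_t)1, (hi - lo) / 6000);
          for (size_t t = lo; t < hi; t += stride)
            seeds.push_back({hits[t].a, hits[t].b});
          std::vector<AlnSeg> segs;
          clus.clear();
          for (size_t t = 0; t <= seeds.size(); ++t) {
            bool flush = (t == seeds.size());
            if (!flush && !clus.empty()) {
              int dprev = clus.back().a - clus.back().b;
              if ((seeds[t].a - seeds[t].b) - dprev > P.diag_band) flush = true;
            }
            if (flush) {
              if ((int)clus.size() >= P.min_seeds)
                align_cluster(enc[i], B, clus, P, segs, comp, (int)B.size(),
                              mfl[i].empty() ? nullptr : &mfl[i],
                              mbo.empty() ? nullptr : &mbo);
              clus.clear();
              if (t == seeds.size()) break;
            }
            clus.push_back(seeds[t]);
          }
          finalize_pair(enc[i], B, (int)enc[j].size(), comp, P, segs,
                        i + 1, j + 1, ra, rb, rc, rab, rae, rbb, rbe, rd,
                        P.want_seg ? &sega : nullptr,
                        P.want_seg ? &seg0a : nullptr,
                        P.want_seg ? &segb : nullptr,
                        P.want_seg ? &seg0b : nullptr);
        }
        lo = hi;
      }
    }
  }
  DataFrame tab = DataFrame::create(
    _["a_id"] = ra, _["b_id"] = rb, _["comp"] = rc,
    _["a_begin"] = rab, _["a_end"] = rae,
    _["b_begin"] = rbb, _["b_end"] = rbe, _["diffs"] = rd);
  List segla(sega.size()), seglb(segb.size());
  for (size_t i = 0; i < sega.size(); ++i) segla[i] = wrap(sega[i]);
  for (size_t i = 0; i < segb.size(); ++i) seglb[i] = wrap(segb[i]);
  return List::create(_["tab"] = tab, _["seg_a"] = segla, _["seg0_a"] = seg0a,
                      _["seg_b"] = seglb, _["seg0_b"] = seg0b);
}

// ------------------------------------------------------------ DUST scoring

// Windowed triplet-composition score; intervals where the per-triplet score
// exceeds the threshold are reported (merged).
// [[Rcpp::export]]
IntegerMatrix cpp_dust_intervals(std::string seq, int window, double threshold) {
  std::vector<uint8_t> s = encode_seq(seq);
  const int n = (int)s.size();
  std::vector<std::pair<int, int>> hits;
  if (n >= window && window >= 3) {
    std::vector<int> trip(n - 2, -1);
    for (int i = 0; i + 2 < n; ++i)
      if (s[i] < 4 && s[i + 1] < 4 && s[i + 2] < 4)
        trip[i] = s[i] * 16 + s[i + 1] * 4 + s[i + 2];
    const int tw = window - 2; // triplets per window
    std::vector<int> cnt(64, 0);
    long S = 0; int valid = 0;
    auto add = [&](int t, int dir) {
      if (t < 0) return;
      if (dir > 0) { S += cnt[t]; cnt[t]++; valid++; }
      else { cnt[t]--; S -= cnt[t]; valid--; }
    };
    for (int i = 0; i < tw; ++i) add(trip[i], +1);
    for (int w0 = 0;; ++w0) {
      if (valid > 1) {
        // per-triplet score: sum over triplet counts c of c(c-1)/2, / count
        double score = (double)S / (double)valid;
        if (score > threshold) {
          if (!hits.empty() && hits.back().second >= w0)
            hits.back().second = w0 + window;
          else hits.push_back({w0, w0 + window});
        }
      }
      if (w0 + tw >= (int)trip.size()) break;
      add(trip[w0], -1);
      add(trip[w0 + tw], +1);
    }
  }
  IntegerMatrix out((int)hits.size(), 2);
  for (int i = 0; i < (int)hits.size(); ++i) {
    out(i, 0) = hits[i].first;
    out(i, 1) = std::min(n, hits[i].second);
  }
  return out;
}

// --------------------------------------------------------- tandem matching

// Self-matches at positive offsets <= max_period mark tandem territory;
// matched k-mer footprints are merged with a gap allowance and span-filtered.
// [[Rcpp::export]]
IntegerMatrix cpp_tandem_intervals(std::string seq, int k, int max_period,
                                   int max_gap, int min_span) {
  std::vector<uint8_t> s = encode_seq(seq);
  const int n = (int)s.size();
  std::vector<int64_t> km;
  kmer_scan(s, k, km);
  std::unordered_map<int64_t, std::vector<int>> pos;
  for (int i = 0; i < (int)km.size(); ++i)
    if (km[i] >= 0) pos[km[i]].push_back(i);
  std::vector<uint8_t> covered(n, 0);
  bool any = false;
  for (auto& kv : pos) {
    const std::vector<int>& v = kv.second;
    for (size_t x = 0; x + 1 < v.size(); ++x) {
      for (size_t y = x + 1; y < v.size(); ++y) {
        int off = v[y] - v[x];
        if (off > max_period) break;
        any = true;
        for (int t = 0; t < k; ++t) {
          if (v[x] + t < n) covered[v[x] + t] = 1;
          if (v[y] + t < n) covered[v[y] + t] = 1;
        }
      }
    }
  }
  if (!any) return IntegerMatrix(0, 2);
  // runs of covered positions merged across small gaps; isolated chance
  // self-matches are rejected by requiring most of the span be covered
  std::vector<std::pair<int, int>> keep;
  int run_b = -1, run_e = -1; long run_cov = 0;
  auto flush = [&]() {
    if (run_b >= 0 && run_e - run_b >= min_span &&
        run_cov * 10 >= 6L * (run_e - run_b))
      keep.push_back({run_b, run_e});
    run_b = -1; run_cov = 0;
  };
  for (int i = 0; i < n; ++i) {
    if (covered[i]) {
      if (run_b < 0) { run_b = i; run_e = i + 1; }
      else if (i - run_e > max_gap) { flush(); run_b = i; }
      run_e = i + 1; ++run_cov;
    }
  }
  flush();
  IntegerMatrix out((int)keep.size(), 2);
  for (int i = 0; i < (int)keep.size(); ++i) {
    out(i, 0) = keep[i].first; out(i, 1) = keep[i].second;
  }
  return out;
}

// ------------------------------------------------------------- polishing

// Majority consensus of reads over a backbone: every read is seeded and
// banded-aligned to the backbone; per-column votes (base / deletion) and
// between-column insertion strings are tallied; majority wins.
// [[Rcpp::export]]
List cpp_polish(std::string backbone, CharacterVector reads, List params) {
  PairParams P = read_params(params);
  P.want_seg = false;
  P.want_ops = true;
  std::vector<uint8_t> A = encode_seq(backbone);
  const int n = (int)A.size();
  // votes: A,C,G,T,del per column; coverage; insertions per boundary
  std::vector<std::array<int, 5>> votes(n, {0, 0, 0, 0, 0});
  std::vector<int> inscov(n + 1, 0);
  std::vector<std::map<std::string, int>> ins(n + 1);

  std::vector<int64_t> ka;
  kmer_scan(A, P.k, ka);
  std::unordered_map<int64_t, std::vector<int>> tab;
  for (int i = 0; i < (int)ka.size(); ++i)
    if (ka[i] >= 0) tab[ka[i]].push_back(i);

  const char* letters = "ACGT";
  std::vector<int64_t> kb;
  for (int r = 0; r < reads.size(); ++r) {
    std::vector<uint8_t> Bf = encode_seq(as<std::string>(reads[r]));
    for (int o = 0; o < 2; ++o) {
      std::vector<uint8_t> B = o ? revcomp_codes(Bf) : Bf;
      if ((int)B.size() < P.k) continue;
      kmer_scan(B, P.k, kb);
      std::vector<Seed> seeds;
      for (int p = 0; p < (int)kb.size(); ++p) {
        if (kb[p] < 0) continue;
        auto it = tab.find(kb[p]);
        if (it == tab.end()) continue;
        if ((int)it->second.size() > P.max_kmer_occ) continue;
        for (int i : it->second) seeds.push_back({i, p});
      }
      if ((int)seeds.size() < P.min_seeds) continue;
      std::sort(seeds.begin(), seeds.end(), [](const Seed& x, const Seed& y) {
        int dx = x.a - x.b, dy = y.a - y.b;
        return dx != dy ? dx < dy : x.a < y.a;
      });
      // cluster by diagonal, align each, vote along the op path
      std::vector<Seed> clus;
      for (size_t t = 0; t <= seeds.size(); ++t) {
        bool flush = (t == seeds.size());
        if (!flush && !clus.empty()) {
          int dprev = clus.back().a - clus.back().b;
          if ((seeds[t].a - seeds[t].b) - dprev > P.diag_band) flush = true;
        }
        if (flush) {
          if ((int)clus.size() >= P.min_seeds) {
            std::vector<AlnSeg> segs;
            std::vector<Seed> cl2 = clus;
            align_cluster(A, B, cl2, P, segs);
            // vote along each segment's op path
            for (AlnSeg& s : segs) {
              int spanA = s.a_e - s.a_b, spanB = s.b_e - s.b_b;
              if (spanA <= 0 || spanB <= 0 || s.ops.empty()) continue;
              double ident = 1.0 - (double)s.path_diffs /
                                   (double)std::max(spanA, spanB);
              if (ident < 1.0 - P.max_div) continue;
              int ia = s.a_b, jb = s.b_b;
              std::string pend;
              for (uint8_t op : s.ops) {
                if (op == 2) { // insertion relative to backbone
                  if (jb < (int)B.size() && B[jb] < 4) pend += letters[B[jb]];
                  ++jb;
                  continue;
                }
                if (ia >= 0 && ia <= n) {
                  ins[ia][pend] += 1;
                  inscov[ia] += 1;
                }
                pend.clear();
                if (op == 0 || op == 1) {
                  if (ia < n && B[jb] < 4) votes[ia][B[jb]] += 1;
                  ++ia; ++jb;
                } else { // deletion: backbone base absent from read
                  if (ia < n) votes[ia][4] += 1;
                  ++ia;
                }
              }
            }
          }
          clus.clear();
          if (t == seeds.size()) break;
        }
        clus.push_back(seeds[t]);
      }
    }
  }
  std::string out;
  out.reserve(n + n / 10);
  std::vector<int> coverage(n, 0);
  for (int i = 0; i < n; ++i) {
    // insertion before column i
    if (inscov[i] > 0) {
      const std::map<std::string, int>& m = ins[i];
      int best = 0; const std::string* bs = nullptr;
      for (auto& kv : m) {
        if (kv.first.empty()) continue;
        if (kv.second > best) { best = kv.second; bs = &kv.first; }
      }
      if (bs && 2 * best > inscov[i]) out += *bs;
    }
    int cov = 0;
    for (int c = 0; c < 5; ++c) cov += votes[i][c];
    coverage[i] = cov;
    if (cov == 0) { // uncovered: keep backbone
      if (A[i] < 4) out += letters[A[i]]; else out += 'N';
      continue;
    }
    int bestc = A[i] < 4 ? A[i] : 0, bestv = -1;
    for (int c = 0; c < 5; ++c) {
      int v = votes[i][c];
      if (v > bestv || (v == bestv && c == (int)A[i])) {
        // strict majority beats; ties resolved toward the backbone base
        if (v > bestv) { bestv = v; bestc = c; }
      }
    }
    if (A[i] < 4 && votes[i][A[i]] == bestv) bestc = A[i];
    if (bestc < 4) out += letters[bestc];
  }
  return List::create(_["seq"] = out, _["coverage"] = wrap(coverage));
}
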