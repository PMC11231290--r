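// Core combinatorial routines for mining ratio-coherent blocks from a
// three-way dataset: per-slice maximal bicluster enumeration over the
// ratio-range multigraph, and cross-time combination into temporally
// contiguous triclusters. Subject sets are 64-bit bitmasks; feature sets
// fit in a single word (|Y| <= 64).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

typedef std::vector<uint64_t> BitSet;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

static inline int bsCount(const BitSet &b) {
  int c = 0;
  for (uint64_t w : b) c += popcount64(w);
  return c;
}

static inline bool bsSubset(const BitSet &a, const BitSet &b) {
  // a subset of b
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] & ~b[i]) return false;
  return true;
}

static inline bool bsEqual(const BitSet &a, const BitSet &b) {
  return a == b;
}

static inline BitSet bsAnd(const BitSet &a, const BitSet &b) {
  BitSet r(a.size());
  for (size_t i = 0; i < a.size(); ++i) r[i] = a[i] & b[i];
  return r;
}

struct Block {
  BitSet I;
  uint64_t J;
  int nI, nJ;
};

// Remove blocks dominated by another block (I subset, J subset); exact
// duplicates collapse to one copy.
static void maximalFilter(std::vector<Block> &blocks) {
  const size_t n = blocks.size();
  if (n < 2) return;
  // sort by cell count descending so dominators come first
  std::vector<size_t> ord(n);
  std::iota(ord.begin(), ord.end(), (size_t)0);
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return (long)blocks[a].nI * blocks[a].nJ > (long)blocks[b].nI * blocks[b].nJ;
  });
  std::vector<bool> dead(n, false);
  std::vector<Block> kept;
  kept.reserve(n);
  for (size_t oi = 0; oi < n; ++oi) {
    const Block &cand = blocks[ord[oi]];
    bool dominated = false;
    for (const Block &k : kept) {
      if ((cand.J & ~k.J) == 0 && cand.nI <= k.nI && bsSubset(cand.I, k.I)) {
        dominated = true;
        break;
      }
    }
    if (!dominated) kept.push_back(cand);
  }
  blocks.swap(kept);
}

// Maximal filter restricted to a fixed J (candidate subject sets during DFS)
static void maximalFilterSameJ(std::vector<BitSet> &cands,
                               std::vector<int> &counts) {
  const size_t n = cands.size();
  if (n < 2) return;
  std::vector<size_t> ord(n);
  std::iota(ord.begin(), ord.end(), (size_t)0);
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return counts[a] > counts[b];
  });
  std::vector<BitSet> kept;
  std::vector<int> keptc;
  for (size_t oi = 0; oi < n; ++oi) {
    const BitSet &c = cands[ord[oi]];
    bool dom = false;
    for (const BitSet &k : kept)
      if (bsSubset(c, k)) { dom = true; break; }
    if (!dom) { kept.push_back(c); keptc.push_back(counts[ord[oi]]); }
  }
  cands.swap(kept);
  counts.swap(keptc);
}

// Maximal epsilon-coherent subject ranges for one feature pair: sort
// subjects by ratio, sweep maximal windows with max/min <= 1 + eps.
static std::vector<BitSet> pairRanges(const std::vector<double> &ratio,
                                      double eps, int minI, int nw) {
  const int n = (int)ratio.size();
  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return ratio[a] < ratio[b];
  });
  std::vector<BitSet> out;
  int lastHi = -1;
  int hi = 0;
  for (int lo = 0; lo < n; ++lo) {
    if (hi < lo) hi = lo;
    while (hi + 1 < n && ratio[ord[hi + 1]] <= (1.0 + eps) * ratio[ord[lo]])
      ++hi;
    if (hi > lastHi) { // maximal window (not nested in the previous one)
      if (hi - lo + 1 >= minI) {
        BitSet b(nw, 0ULL);
        for (int t = lo; t <= hi; ++t)
          b[ord[t] >> 6] |= (1ULL << (ord[t] & 63));
        out.push_back(std::move(b));
      }
      lastHi = hi;
    }
  }
  return out;
}

struct MineCtx {
  int nX, nY, nw, minI, minJ;
  // ranges[a * nY + b] for a < b
  std::vector<std::vector<BitSet>> ranges;
  std::vector<Block> out;
};

static void dfs(MineCtx &ctx, uint64_t J, int maxFeat, int nJ,
                std::vector<BitSet> &cands, std::vector<int> &counts) {
  for (int f = maxFeat + 1; f < ctx.nY; ++f) {
    std::vector<BitSet> cur = cands;
    std::vector<int> curc = counts;
    bool alive = true;
    for (int j = 0; j < ctx.nY && alive; ++j) {
      if (!(J & (1ULL << j))) continue;
      const std::vector<BitSet> &rng =
        ctx.ranges[(j < f ? j : f) * ctx.nY + (j < f ? f : j)];
      std::vector<BitSet> next;
      std::vector<int> nextc;
      for (const BitSet &c : cur) {
        for (const BitSet &r : rng) {
          BitSet x = bsAnd(c, r);
          int cnt = bsCount(x);
          if (cnt >= ctx.minI) {
            next.push_back(std::move(x));
            nextc.push_back(cnt);
          }
        }
      }
      maximalFilterSameJ(next, nextc);
      cur.swap(next);
      curc.swap(nextc);
      if (cur.empty()) alive = false;
    }
    if (!alive) continue;
    uint64_t J2 = J | (1ULL << f);
    int nJ2 = nJ + 1;
    if (nJ2 >= ctx.minJ) {
      for (size_t i = 0; i < cur.size(); ++i) {
        Block b;
        b.I = cur[i]; b.J = J2; b.nI = curc[i]; b.nJ = nJ2;
        ctx.out.push_back(std::move(b));
      }
    }
    dfs(ctx, J2, f, nJ2, cur, curc);
  }
}

static List blocksToR(const std::vector<Block> &blocks, int nX, int nY) {
  List out(blocks.size());
  for (size_t i = 0; i < blocks.size(); ++i) {
    std::vector<int> I, J;
    for (int s = 0; s < nX; ++s)
      if (blocks[i].I[s >> 6] & (1ULL << (s & 63))) I.push_back(s + 1);
    for (int f = 0; f < nY; ++f)
      if (blocks[i].J & (1ULL << f)) J.push_back(f + 1);
    out[i] = List::create(_["I"] = wrap(I), _["J"] = wrap(J));
  }
  return out;
}

static std::vector<Block> blocksFromR(List blocks, int nX) {
  int nw = (nX + 63) / 64;
  std::vector<Block> out;
  out.reserve(blocks.size());
  for (R_xlen_t i = 0; i < blocks.size(); ++i) {
    List bl = blocks[i];
    IntegerVector I = bl["I"], J = bl["J"];
    Block b;
    b.I.assign(nw, 0ULL);
    b.J = 0ULL;
    for (int s : I) b.I[(s - 1) >> 6] |= (1ULL << ((s - 1) & 63));
    for (int f : J) b.J |= (1ULL << (f - 1));
    b.nI = I.size();
    b.nJ = J.size();
    out.push_back(std::move(b));
  }
  return out;
}

// [[Rcpp::export(name = ".cppPairRanges")]]
List cppPairRanges(NumericVector ratio, double eps, int minI) {
  int nX = ratio.size();
  int nw = (nX + 63) / 64;
  std::vector<double> r(ratio.begin(), ratio.end());
  std::vector<BitSet> rng = pairRanges(r, eps, minI, nw);
  List out(rng.size());
  for (size_t i = 0; i < rng.size(); ++i) {
    std::vector<int> I;
    for (int s = 0; s < nX; ++s)
      if (rng[i][s >> 6] & (1ULL << (s & 63))) I.push_back(s + 1);
    out[i] = wrap(I);
  }
  return out;
}

// [[Rcpp::export(name = ".cppMineSlice")]]
List cppMineSlice(NumericMatrix slice, double eps, int minI, int minJ) {
  const int nX = slice.nrow(), nY = slice.ncol();
  if (nY > 64) stop("at most 64 features supported");
  MineCtx ctx;
  ctx.nX = nX; ctx.nY = nY; ctx.nw = (nX + 63) / 64;
  ctx.minI = std::max(minI, 1); ctx.minJ = std::max(minJ, 1);
  ctx.ranges.resize((size_t)nY * nY);
  std::vector<double> ratio(nX);
  for (int a = 0; a < nY; ++a) {
    for (int b = a + 1; b < nY; ++b) {
      for (int i = 0; i < nX; ++i)
        ratio[i] = slice(i, b) / slice(i, a);
      ctx.ranges[a * nY + b] = pairRanges(ratio, eps, ctx.minI, ctx.nw);
    }
  }
  BitSet full(ctx.nw, 0ULL);
  for (int s = 0; s < nX; ++s) full[s >> 6] |= (1ULL << (s & 63));
  if (nX >= ctx.minI) {
    for (int f = 0; f < nY; ++f) {
      uint64_t J = 1ULL << f;
      std::vector<BitSet> cands(1, full);
      std::vector<int> counts(1, nX);
      if (ctx.minJ <= 1) {
        Block b; b.I = full; b.J = J; b.nI = nX; b.nJ = 1;
        ctx.out.push_back(b);
      }
      dfs(ctx, J, f, 1, cands, counts);
    }
  }
  maximalFilter(ctx.out);
  return blocksToR(ctx.out, nX, nY);
}

// Pairwise intersection of two block families (used to extend a time
// window by one slice); keeps maximal intersections meeting size bounds.
// [[Rcpp::export(name = ".cppIntersectBlocks")]]
List cppIntersectBlocks(List blocksA, List blocksB, int nX, int nY,
                        int minI, int minJ) {
  std::vector<Block> A = blocksFromR(blocksA, nX);
  std::vector<Block> B = blocksFromR(blocksB, nX);
  std::vector<Block> out;
  for (const Block &a : A) {
    for (const Block &b : B) {
      uint64_t J = a.J & b.J;
      int nJ = popcount64(J);
      if (nJ < minJ) continue;
      BitSet I = bsAnd(a.I, b.I);
      int nI = bsCount(I);
      if (nI < minI) continue;
      Block c; c.I = std::move(I); c.J = J; c.nI = nI; c.nJ = nJ;
      out.push_back(std::move(c));
    }
  }
  maximalFilter(out);
  return blocksToR(out, nX, nY);
}

// Global maximality across windows: drop tricluster t if another tricluster
// contains it in all three dimensions. kstart/kend are window bounds.
// [[Rcpp::export(name = ".cppMaximalTriclusters")]]
LogicalVector cppMaximalTriclusters(List blocks, IntegerVector kstart,
                                    IntegerVector kend, int nX) {
  std::vector<Block> B = blocksFromR(blocks, nX);
  const int n = (int)B.size();
  LogicalVector keep(n, true);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (kstart[j] <= kstart[i] && kend[i] <= kend[j] &&
          (B[i].J & ~B[j].J) == 0 && bsSubset(B[i].I, B[j].I)) {
        bool identical = kstart[i] == kstart[j] && kend[i] == kend[j] &&
          B[i].J == B[j].J && bsEqual(B[i].I, B[j].I);
        // duplicates keep the earliest copy only
        if (!identical || j < i) { keep[i] = false; break; }
      }
    }
  }
  return keep;
}
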