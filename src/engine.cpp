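// Forward simulator of founder-origin chromosome mosaics in a constant-size,
// panmictic, monoecious diploid population without selfing (drift only).
// Chromosomes are continuous on [0, l] Morgan; meiosis follows the Haldane
// no-interference model (Poisson(l) crossovers, uniform positions). All
// randomness goes through R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Mos {
  std::vector<double> bp;  // breakpoints, incl. 0 and l
  std::vector<int> org;    // one founder-origin label per segment
};

// One gamete from a diploid parent (two mosaics). Starting homologue is a
// fair coin; homologue switches at each crossover. Adjacent equal origins
// are merged on the fly, so invisible crossovers leave no junction.
void meiosis(const Mos& m0, const Mos& m1, double l, Mos& out,
             std::vector<double>& xo) {
  int nxo = static_cast<int>(R::rpois(l));
  xo.clear();
  for (int i = 0; i < nxo; ++i) xo.push_back(unif_rand() * l);
  std::sort(xo.begin(), xo.end());
  // exact floating-point collisions are measure-zero: re-draw
  for (;;) {
    bool dup = false;
    for (size_t i = 1; i < xo.size(); ++i)
      if (xo[i] == xo[i - 1]) { xo[i] = unif_rand() * l; dup = true; }
    if (!dup) break;
    std::sort(xo.begin(), xo.end());
  }
  const Mos* P[2] = {&m0, &m1};
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  out.bp.clear(); out.org.clear();
  out.bp.push_back(0.0);
  size_t idx[2] = {0, 0};
  double a = 0.0;
  for (int c = 0; c <= nxo; ++c) {
    double b = (c < nxo) ? xo[c] : l;
    const Mos& M = *P[cur];
    size_t s = idx[cur];
    while (M.bp[s + 1] <= a) ++s;
    idx[cur] = s;
    size_t k = s;
    for (;;) {
      double segEnd = std::min(M.bp[k + 1], b);
      if (!out.org.empty() && out.org.back() == M.org[k]) {
        out.bp.back() = segEnd;
      } else {
        out.org.push_back(M.org[k]);
        out.bp.push_back(segEnd);
      }
      if (segEnd >= b) break;
      ++k;
    }
    a = b;
    cur = 1 - cur;
  }
}

struct Summ {
  double d;          // total relaxed-IBD length
  int k;             // relaxed block count
  int z;             // external junctions (carrier-counted)
  int tips;          // chromosome ends lying in an IBD tract
  int strictK;       // strict block count
  double strictLen;  // total strict-IBD length
};

// Two-pointer walk over the elementary decomposition of a homologous pair.
// d is accumulated per relaxed block and strictLen per strict block, so the
// strict/relaxed length identity is a real (floating-point) comparison, not
// a shared accumulator. z counts actual homologue breakpoints at which the
// IBD status flips, one count per carrier; the block-edge identity
// 2k = z + tips is therefore an emergent property, never assumed.
void pairSummary(const Mos& A, const Mos& B, double l, Summ& s,
                 std::vector<double>* blocks) {
  s.d = 0.0; s.k = 0; s.z = 0; s.tips = 0; s.strictK = 0; s.strictLen = 0.0;
  size_t i = 0, j = 0;
  double pos = 0.0;
  bool cur = (A.org[0] == B.org[0]);
  bool firstIbd = cur, lastIbd = false;
  double relStart = 0.0, strStart = 0.0;
  int curOrg = cur ? A.org[0] : -1;
  if (cur) { s.k = 1; s.strictK = 1; }
  for (;;) {
    double nxt = std::min(A.bp[i + 1], B.bp[j + 1]);
    bool atEnd = (nxt >= l);
    if (atEnd) {
      lastIbd = cur;
      if (cur) {
        s.d += l - relStart;
        s.strictLen += l - strStart;
        if (blocks) { blocks->push_back(relStart); blocks->push_back(l); }
      }
      break;
    }
    bool advA = (A.bp[i + 1] == nxt);
    bool advB = (B.bp[j + 1] == nxt);
    if (advA) ++i;
    if (advB) ++j;
    bool nxtIbd = (A.org[i] == B.org[j]);
    if (nxtIbd != cur) {
      s.z += (advA ? 1 : 0) + (advB ? 1 : 0);
      if (cur) {  // close a relaxed (and strict) block
        s.d += nxt - relStart;
        s.strictLen += nxt - strStart;
        if (blocks) { blocks->push_back(relStart); blocks->push_back(nxt); }
      } else {    // open a block
        ++s.k; relStart = nxt;
        ++s.strictK; strStart = nxt; curOrg = A.org[i];
      }
    } else if (nxtIbd && A.org[i] != curOrg) {
      // shared origin changes inside an IBD tract: strict subdivision
      s.strictLen += nxt - strStart;
      ++s.strictK; strStart = nxt; curOrg = A.org[i];
    }
    cur = nxtIbd;
    pos = nxt;
  }
  (void)pos;
  s.tips = (firstIbd ? 1 : 0) + (lastIbd ? 1 : 0);
}

}  // namespace

// Simulate one replicate: founders (generation 0) through nGen generations.
// Returns per-generation aggregates for every generation and per-individual
// summaries / relaxed-block records for the recorded generations.
// [[Rcpp::export]]
List sim_replicate_cpp(int N, double l, int nGen, IntegerVector recordGens,
                       bool recordBlocks, int pairing) {
  if (N < 2) stop("N must be >= 2");
  if (!(l > 0)) stop("chromosome length must be > 0 Morgan");
  std::set<int> rec(recordGens.begin(), recordGens.end());

  std::vector<Mos> cur(2 * N), nxt(2 * N);
  for (int c = 0; c < 2 * N; ++c) {
    cur[c].bp = {0.0, l};
    cur[c].org = {c + 1};
  }

  NumericMatrix genStats(nGen + 1, 6);
  int nRecInd = static_cast<int>(rec.size()) * N;
  NumericMatrix ind(nRecInd, 8);
  std::vector<double> blockRows;  // gen, individual, start, end
  int indRow = 0;

  std::vector<double> xoScratch, blkScratch;
  std::vector<int> perm(2 * N);

  auto summarizeGen = [&](int t) {
    bool recd = rec.count(t) > 0;
    for (int c = 0; c < 2 * N; ++c) perm[c] = c;
    if (pairing == 1) {
      for (int c = 2 * N - 1; c > 0; --c) {
        int j = static_cast<int>(unif_rand() * (c + 1));
        if (j > c) j = c;
        std::swap(perm[c], perm[j]);
      }
    }
    double sumD = 0, sumRatio = 0;
    int sumK = 0, sumZ = 0, sumTips = 0, nPos = 0;
    for (int o = 0; o < N; ++o) {
      Summ s;
      std::vector<double>* bl = nullptr;
      if (recd && recordBlocks) { blkScratch.clear(); bl = &blkScratch; }
      pairSummary(cur[perm[2 * o]], cur[perm[2 * o + 1]], l, s, bl);
      sumD += s.d; sumK += s.k; sumZ += s.z; sumTips += s.tips;
      if (s.k > 0) { ++nPos; sumRatio += s.d / s.k; }
      if (recd) {
        ind(indRow, 0) = t; ind(indRow, 1) = o + 1;
        ind(indRow, 2) = s.d; ind(indRow, 3) = s.k; ind(indRow, 4) = s.z;
        ind(indRow, 5) = s.tips; ind(indRow, 6) = s.strictK;
        ind(indRow, 7) = s.strictLen;
        ++indRow;
        if (bl) {
          for (size_t q = 0; q < bl->size(); q += 2) {
            blockRows.push_back(t);
            blockRows.push_back(o + 1);
            blockRows.push_back((*bl)[q]);
            blockRows.push_back((*bl)[q + 1]);
          }
        }
      }
    }
    genStats(t, 0) = sumD; genStats(t, 1) = sumK; genStats(t, 2) = sumZ;
    genStats(t, 3) = sumTips; genStats(t, 4) = nPos; genStats(t, 5) = sumRatio;
  };

  summarizeGen(0);
  for (int t = 1; t <= nGen; ++t) {
    for (int o = 0; o < N; ++o) {
      int p1 = static_cast<int>(unif_rand() * N);
      if (p1 >= N) p1 = N - 1;
      int p2 = static_cast<int>(unif_rand() * (N - 1));
      if (p2 >= N - 1) p2 = N - 2;
      if (p2 >= p1) ++p2;
      meiosis(cur[2 * p1], cur[2 * p1 + 1], l, nxt[2 * o], xoScratch);
      meiosis(cur[2 * p2], cur[2 * p2 + 1], l, nxt[2 * o + 1], xoScratch);
    }
    std::swap(cur, nxt);
    summarizeGen(t);
  }

  NumericMatrix blocks(static_cast<int>(blockRows.size() / 4), 4);
  for (int r = 0; r < blocks.nrow(); ++r)
    for (int c = 0; c < 4; ++c) blocks(r, c) = blockRows[4 * r + c];

  return List::create(_["genStats"] = genStats, _["ind"] = ind,
                      _["blocks"] = blocks);
}
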