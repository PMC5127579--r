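// Backward-in-time coalescent engine for split-from-pool demographies.
// Discrete Wright-Fisher parent sampling in gene-copy units; migration and
// pool exchange as backward per-lineage probabilities; stepwise mutations
// dropped on the realised genealogy with reflecting bounds. All randomness
// comes from R's RNG, so set.seed() makes replicates reproducible.
//
// Per generation, the number of emigrants per lineage class is drawn from
// the exact binomial and the emigrants are picked by partial Fisher-Yates;
// coalescence draws one parent slot per lineage within its population and
// merges lineages sharing a slot (exact multi-merger Wright-Fisher).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".cppSimReplicate")]]
List cppSimReplicate(int nRes, int nJoin,
                     NumericVector sizes,      // founding sizes, gene copies
                     NumericVector split,      // split times (Inf = island)
                     bool island,
                     double poolSize, double poolGrowth, double demeGrowth,
                     double q1, double q2, double snd, double rcv,
                     IntegerVector sampleSizes,
                     double mu, int K, int L) {
  const int D = nRes + nJoin;
  int nTips = 0;
  for (int d = 0; d < D; ++d) nTips += 2 * sampleSizes[d];
  const int maxN = 2 * nTips + 2;
  std::vector<int> parent(maxN + 1, 0);
  std::vector<double> birth(maxN + 1, 0.0);
  std::vector<int> act(nTips), pop(nTips);
  {
    int i = 0;
    for (int d = 0; d < D; ++d)
      for (int j = 0; j < 2 * sampleSizes[d]; ++j) { act[i] = i + 1; pop[i] = d + 1; ++i; }
  }
  int nextNode = nTips + 1;
  std::vector<bool> alive(D + 1, true);   // 1-based demes
  int k = nTips;
  double t = 0.0;
  std::vector<int> classBuf(nTips);       // scratch: members of one class
  std::vector<int> bucketOrd(nTips);      // scratch: lineages ordered by pop
  std::vector<int> bucketCnt(D + 2), bucketOff(D + 2);
  std::vector<std::pair<double, int> > slots(nTips);

  while (k > 1) {
    t += 1.0;
    if (t > 1e6) stop("coalescence did not complete within 1e6 generations");
    if (!island) {                        // deme -> pool merges at split times
      for (int d = 1; d <= D; ++d)
        if (alive[d] && split[d - 1] <= t) {
          alive[d] = false;
          for (int i = 0; i < k; ++i) if (pop[i] == d) pop[i] = 0;
        }
    }
    int nAliveR = 0, nAliveJ = 0;
    for (int d = 1; d <= nRes; ++d) if (alive[d]) ++nAliveR;
    for (int d = nRes + 1; d <= D; ++d) if (alive[d]) ++nAliveJ;
    const int nAlive = nAliveR + nAliveJ;
    const double pCls[3] = {
      rcv * nAlive,                                        // pool lineages
      q1 * std::max(nAliveR - 1, 0) + q2 * nAliveJ + snd,  // resident
      q2 * std::max(nAlive - 1, 0) + snd                   // joiner
    };
    // ---- migration: binomial emigrant counts per class ----
    for (int cls = 0; cls < 3; ++cls) {
      const double p = pCls[cls];
      if (p <= 0.0) continue;
      int kc = 0;
      for (int i = 0; i < k; ++i) {
        const int d = pop[i];
        const int ci = (d == 0) ? 0 : (d <= nRes ? 1 : 2);
        if (ci == cls) classBuf[kc++] = i;
      }
      if (kc == 0) continue;
      int nm = (int) R::rbinom(kc, p);
      for (int j = 0; j < nm; ++j) {      // partial Fisher-Yates selection
        int pick = j + (int)(unif_rand() * (kc - j));
        if (pick >= kc) pick = kc - 1;
        std::swap(classBuf[j], classBuf[pick]);
        const int i = classBuf[j];
        const int d = pop[i];
        if (d == 0) {                     // pool lineage -> uniform alive deme
          int sel = (int)(unif_rand() * nAlive);
          if (sel >= nAlive) sel = nAlive - 1;
          for (int dd = 1; dd <= D; ++dd)
            if (alive[dd] && sel-- == 0) { pop[i] = dd; break; }
        } else {
          // destination given emigration: weights q1 (other residents, for
          // residents), q2 (other group / other joiners), snd (pool)
          double w = unif_rand() * p;
          bool placed = false;
          if (d <= nRes) {
            for (int dd = 1; dd <= nRes && !placed; ++dd) {
              if (!alive[dd] || dd == d) continue;
              if (w < q1) { pop[i] = dd; placed = true; } else w -= q1;
            }
            for (int dd = nRes + 1; dd <= D && !placed; ++dd) {
              if (!alive[dd]) continue;
              if (w < q2) { pop[i] = dd; placed = true; } else w -= q2;
            }
          } else {
            for (int dd = 1; dd <= D && !placed; ++dd) {
              if (!alive[dd] || dd == d) continue;
              if (w < q2) { pop[i] = dd; placed = true; } else w -= q2;
            }
          }
          if (!placed && snd > 0.0) pop[i] = 0;  // remaining mass: the pool
        }
      }
    }
    // ---- coalescence: bucket lineages by population, sample WF slots ----
    std::fill(bucketCnt.begin(), bucketCnt.end(), 0);
    for (int i = 0; i < k; ++i) ++bucketCnt[pop[i]];
    bucketOff[0] = 0;
    for (int d = 1; d <= D + 1; ++d) bucketOff[d] = bucketOff[d - 1] + bucketCnt[d - 1];
    {
      std::vector<int> cur(bucketOff.begin(), bucketOff.end());
      for (int i = 0; i < k; ++i) bucketOrd[cur[pop[i]]++] = i;
    }
    const double Npool = (poolSize >= 2.0)
      ? std::max(2.0, std::round(poolSize * std::exp(-poolGrowth * t))) : 1.0;
    int nDrop = 0;
    for (int d = 0; d <= D; ++d) {
      const int kd = bucketCnt[d];
      if (kd < 2) continue;
      double N;
      if (d == 0) N = Npool;
      else if (island) N = sizes[d - 1];
      else N = std::max(2.0, std::round(sizes[d - 1] *
                 std::exp(demeGrowth * (split[d - 1] - t))));
      for (int j = 0; j < kd; ++j) {
        slots[j].first = std::floor(unif_rand() * N);
        slots[j].second = bucketOrd[bucketOff[d] + j];
      }
      std::sort(slots.begin(), slots.begin() + kd);
      int runStart = 0;
      for (int j = 1; j <= kd; ++j) {
        if (j == kd || slots[j].first != slots[runStart].first) {
          if (j - runStart > 1) {         // a merge group
            const int nd = nextNode++;
            birth[nd] = t;
            for (int r = runStart; r < j; ++r) {
              const int i = slots[r].second;
              parent[act[i]] = nd;
              if (r == runStart) act[i] = nd;    // survivor carries the node
              else { act[i] = -1; ++nDrop; }
            }
          }
          runStart = j;
        }
      }
    }
    if (nDrop > 0) {
      int w = 0;
      for (int i = 0; i < k; ++i)
        if (act[i] >= 0) { act[w] = act[i]; pop[w] = pop[i]; ++w; }
      k = w;
    }
  }
  // ---- mutations: free +/-1 walk down the tree, folded at the tips ----
  const int nN = nextNode - 1;
  IntegerMatrix a1((nTips / 2), L), a2((nTips / 2), L);
  std::vector<int> freeState((size_t)(nN + 1) * L, 0);
  // nodes were created in non-decreasing birth order; process parents first
  for (int nd = nN; nd >= 1; --nd) {
    const int pp = parent[nd];
    if (pp == 0) continue;
    const double bl = birth[pp] - birth[nd];
    for (int l = 0; l < L; ++l) {
      int net = 0;
      const int nm = (int) R::rpois(mu * bl);
      if (nm > 0) net = 2 * (int) R::rbinom(nm, 0.5) - nm;
      freeState[(size_t)nd * L + l] = freeState[(size_t)pp * L + l] + net;
    }
  }
  const int start = (K + 1) / 2;
  const int P = 2 * K - 2;
  for (int i = 0; i < nTips; ++i) {
    for (int l = 0; l < L; ++l) {
      int y = start + freeState[(size_t)(i + 1) * L + l];
      int m = ((y - 1) % P + P) % P;
      const int state = (m < K) ? m + 1 : 2 * K - 1 - m;
      if (i % 2 == 0) a1(i / 2, l) = state; else a2(i / 2, l) = state;
    }
  }
  IntegerVector popInd(nTips / 2);
  {
    int i = 0;
    for (int d = 0; d < D; ++d)
      for (int j = 0; j < sampleSizes[d]; ++j) popInd[i++] = d + 1;
  }
  return List::create(_["a1"] = a1, _["a2"] = a2, _["popInd"] = popInd,
                      _["D"] = D);
}
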