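// Exact per-segment solver for clone-level allele-specific copy numbers.
//
// Depth-first branch-and-bound over integer copy-number assignments of the
// tumour clones (visited in tree preorder, so every clone's parent is
// assigned before the clone itself). Constraints: root child of the diploid
// (1,1) clone; irreversible LOH per allele along edges; joint (0,0) states
// only where eligible; at most `maxruns` maximal same-sign runs of nonzero
// per-edge deltas along any root-to-clone path per allele; total events
// (sum of |delta| over edges and alleles) <= lambda.
//
// Objective is lexicographic: (1) number of samples whose predicted mixture
// falls outside the observed interval for either allele; (2) Manhattan
// distance between predicted and observed fractional copy numbers;
// (3) total event count (parsimony tie-break). Bounding uses interval
// arithmetic: an unassigned clone's copy number is confined to
// [max(0, a - B), min(cmax, a + B)] where a is its nearest assigned
// ancestor's value and B the remaining event budget (0 stays 0 under LOH).

#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Solver {
  int n, k;
  std::vector<int> parent;                    // -1 => diploid parent (1,1)
  std::vector<double> U;                      // n x k, row-major
  std::vector<double> fA, loA, hiA, fB, loB, hiB;
  std::vector<char> homdelOk;
  int cmax, lambda, maxruns;
  bool perAllele;                             // objective-1 counting unit
  double tol = 1e-9;
  double eps = 1e-9;                          // interval inclusion slack

  std::vector<int> cA, cB;
  std::vector<double> sA, sB;                 // partial mixture sums per sample
  std::vector<int> runsA, runsB, signA, signB;
  int usedEvents = 0;

  std::vector<int> bestA, bestB;
  int bestObj1; double bestObj2; int bestEvents;
  bool haveIncumbent = false;

  long long nodes = 0;
  std::chrono::steady_clock::time_point t0;
  double timeLimit;                           // seconds
  bool timedOut = false;

  // scratch buffers for bound(): copy-number ranges of unassigned clones
  std::vector<int> lbA_, ubA_, lbB_, ubB_, ancA_, ancB_;
  // sufMaxU_[d]: max over clones i >= d of the total proportion mass of the
  // subtree rooted at i (summed over samples); one budget unit (one event on
  // one edge) shifts the predictions of exactly one subtree, so it can
  // reduce the Manhattan objective by at most this much
  std::vector<double> sufMaxU_;

  bool worseOrEqual(int o1, double o2, int ev) const {
    if (!haveIncumbent) return false;
    if (o1 != bestObj1) return o1 > bestObj1;
    if (o2 > bestObj2 + tol) return true;
    if (o2 < bestObj2 - tol) return false;
    return ev >= bestEvents;
  }

  void leaf() {
    int o1 = 0; double o2 = 0.0;
    for (int r = 0; r < k; ++r) {
      bool vA = sA[r] < loA[r] - eps || sA[r] > hiA[r] + eps;
      bool vB = sB[r] < loB[r] - eps || sB[r] > hiB[r] + eps;
      if (perAllele) o1 += (vA ? 1 : 0) + (vB ? 1 : 0);
      else if (vA || vB) ++o1;
      o2 += std::fabs(fA[r] - sA[r]) + std::fabs(fB[r] - sB[r]);
    }
    bool better = !haveIncumbent;
    if (!better) {
      if (o1 != bestObj1) better = o1 < bestObj1;
      else if (o2 < bestObj2 - tol) better = true;
      else if (o2 > bestObj2 + tol) better = false;
      else better = usedEvents < bestEvents;
    }
    if (better) {
      bestObj1 = o1; bestObj2 = o2; bestEvents = usedEvents;
      bestA = cA; bestB = cB; haveIncumbent = true;
    }
  }

  // lexicographic lower bound over completions from depth d; true => prune
  bool bound(int d) {
    int remB = lambda - usedEvents;
    int lb1 = 0; double lb2 = 0.0;
    for (int i = d; i < n; ++i) {             // preorder: parent[i] < i
      int p = parent[i];
      ancA_[i] = p < 0 ? 1 : (p < d ? cA[p] : ancA_[p]);
      ancB_[i] = p < 0 ? 1 : (p < d ? cB[p] : ancB_[p]);
      lbA_[i] = ancA_[i] > 0 ? std::max(0, ancA_[i] - remB) : 0;
      ubA_[i] = ancA_[i] > 0 ? std::min(cmax, ancA_[i] + remB) : 0;
      lbB_[i] = ancB_[i] > 0 ? std::max(0, ancB_[i] - remB) : 0;
      ubB_[i] = ancB_[i] > 0 ? std::min(cmax, ancB_[i] + remB) : 0;
    }
    double baseDev = 0.0;   // deviation of the all-inherit completion
    for (int r = 0; r < k; ++r) {
      double mnA = sA[r], mxA = sA[r], mnB = sB[r], mxB = sB[r];
      double basA = sA[r], basB = sB[r];
      for (int i = d; i < n; ++i) {
        double u = U[(size_t)i * k + r];
        if (u <= 0.0) continue;
        mnA += u * lbA_[i]; mxA += u * ubA_[i];
        mnB += u * lbB_[i]; mxB += u * ubB_[i];
        basA += u * ancA_[i]; basB += u * ancB_[i];
      }
      bool vA = mxA < loA[r] - eps || mnA > hiA[r] + eps;
      bool vB = mxB < loB[r] - eps || mnB > hiB[r] + eps;
      if (perAllele) lb1 += (vA ? 1 : 0) + (vB ? 1 : 0);
      else if (vA || vB) ++lb1;
      if (fA[r] < mnA) lb2 += mnA - fA[r];
      else if (fA[r] > mxA) lb2 += fA[r] - mxA;
      if (fB[r] < mnB) lb2 += mnB - fB[r];
      else if (fB[r] > mxB) lb2 += fB[r] - mxB;
      baseDev += std::fabs(fA[r] - basA) + std::fabs(fB[r] - basB);
    }
    // each of the remaining <= remB unit changes moves the predictions of
    // one clone by its proportions, reducing the deviation by at most the
    // largest remaining clone mass per unit
    double lb2b = baseDev - remB * sufMaxU_[d];
    if (lb2b > lb2) lb2 = lb2b;
    return worseOrEqual(lb1, lb2, usedEvents);
  }

  void dfs(int d) {
    if (timedOut) return;
    if ((++nodes & 2047) == 0) {
      double el = std::chrono::duration<double>(
          std::chrono::steady_clock::now() - t0).count();
      if (el > timeLimit) { timedOut = true; return; }
    }
    if (d == n) { leaf(); return; }
    if (bound(d)) return;

    int p = parent[d];
    int pA = p < 0 ? 1 : cA[p], pB = p < 0 ? 1 : cB[p];
    int prA = p < 0 ? 0 : runsA[p], prB = p < 0 ? 0 : runsB[p];
    int psA = p < 0 ? 0 : signA[p], psB = p < 0 ? 0 : signB[p];
    int remB = lambda - usedEvents;

    // candidates ordered by total |dA|+|dB| (parsimonious states first),
    // then dA descending within the split, '+' sign before '-'
    for (int tot = 0; tot <= remB; ++tot) {
      for (int aAbs = std::min(tot, cmax); aAbs >= 0; --aAbs) {
        int bAbs = tot - aAbs;
        if (bAbs > cmax) continue;
        if (pA == 0 && aAbs != 0) continue;
        if (pB == 0 && bAbs != 0) continue;
        for (int sa = 0; sa < (aAbs == 0 ? 1 : 2); ++sa) {
          int dA = sa == 0 ? aAbs : -aAbs;
          int vA = pA + dA;
          if (vA < 0 || vA > cmax) continue;
          int nrA = prA, nsA = psA;
          if (dA != 0) {
            int s = dA > 0 ? 1 : -1;
            if (s != nsA) { ++nrA; nsA = s; }
            if (nrA > maxruns) continue;
          }
          for (int sb = 0; sb < (bAbs == 0 ? 1 : 2); ++sb) {
            int dB = sb == 0 ? bAbs : -bAbs;
            int vB = pB + dB;
            if (vB < 0 || vB > cmax) continue;
            if (vA == 0 && vB == 0 && !homdelOk[d]) continue;
            int nrB = prB, nsB = psB;
            if (dB != 0) {
              int s = dB > 0 ? 1 : -1;
              if (s != nsB) { ++nrB; nsB = s; }
              if (nrB > maxruns) continue;
            }
            cA[d] = vA; cB[d] = vB;
            runsA[d] = nrA; signA[d] = nsA;
            runsB[d] = nrB; signB[d] = nsB;
            usedEvents += tot;
            for (int r = 0; r < k; ++r) {
              double u = U[(size_t)d * k + r];
              sA[r] += vA * u; sB[r] += vB * u;
            }
            dfs(d + 1);
            usedEvents -= tot;
            for (int r = 0; r < k; ++r) {
              double u = U[(size_t)d * k + r];
              sA[r] -= vA * u; sB[r] -= vB * u;
            }
            if (timedOut) return;
          }
        }
      }
    }
  }

  void evaluate(const std::vector<int>& a, const std::vector<int>& b,
                int& o1, double& o2, int& ev) const {
    o1 = 0; o2 = 0.0; ev = 0;
    std::vector<double> tA(k, 0.0), tB(k, 0.0);
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      ev += std::abs(a[i] - (p < 0 ? 1 : a[p])) +
            std::abs(b[i] - (p < 0 ? 1 : b[p]));
      for (int r = 0; r < k; ++r) {
        double u = U[(size_t)i * k + r];
        tA[r] += a[i] * u; tB[r] += b[i] * u;
      }
    }
    for (int r = 0; r < k; ++r) {
      bool vA = tA[r] < loA[r] - eps || tA[r] > hiA[r] + eps;
      bool vB = tB[r] < loB[r] - eps || tB[r] > hiB[r] + eps;
      if (perAllele) o1 += (vA ? 1 : 0) + (vB ? 1 : 0);
      else if (vA || vB) ++o1;
      o2 += std::fabs(fA[r] - tA[r]) + std::fabs(fB[r] - tB[r]);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".solve_segment_bb")]]
List solve_segment_bb(IntegerVector parent, NumericMatrix u,
                      NumericVector fA, NumericVector loA, NumericVector hiA,
                      NumericVector fB, NumericVector loB, NumericVector hiB,
                      LogicalVector homdel_ok, int cmax, int lambda,
                      int maxruns, double time_limit, bool per_allele,
                      IntegerVector warmA, IntegerVector warmB) {
  Solver S;
  S.n = u.nrow(); S.k = u.ncol();
  S.parent.assign(parent.begin(), parent.end());
  S.U.resize((size_t)S.n * S.k);
  for (int i = 0; i < S.n; ++i)
    for (int r = 0; r < S.k; ++r) S.U[(size_t)i * S.k + r] = u(i, r);
  S.fA.assign(fA.begin(), fA.end()); S.loA.assign(loA.begin(), loA.end());
  S.hiA.assign(hiA.begin(), hiA.end());
  S.fB.assign(fB.begin(), fB.end()); S.loB.assign(loB.begin(), loB.end());
  S.hiB.assign(hiB.begin(), hiB.end());
  S.homdelOk.assign(homdel_ok.begin(), homdel_ok.end());
  S.cmax = cmax; S.lambda = lambda; S.maxruns = maxruns;
  S.perAllele = per_allele;
  S.cA.assign(S.n, 1); S.cB.assign(S.n, 1);
  S.sA.assign(S.k, 0.0); S.sB.assign(S.k, 0.0);
  S.runsA.assign(S.n, 0); S.runsB.assign(S.n, 0);
  S.signA.assign(S.n, 0); S.signB.assign(S.n, 0);
  S.timeLimit = time_limit;
  S.t0 = std::chrono::steady_clock::now();
  S.lbA_.assign(S.n, 0); S.ubA_.assign(S.n, 0);
  S.lbB_.assign(S.n, 0); S.ubB_.assign(S.n, 0);
  S.ancA_.assign(S.n, 1); S.ancB_.assign(S.n, 1);
  {
    std::vector<double> subMass(S.n, 0.0);
    for (int i = 0; i < S.n; ++i)
      for (int r = 0; r < S.k; ++r) subMass[i] += S.U[(size_t)i * S.k + r];
    for (int i = S.n - 1; i >= 1; --i)
      if (S.parent[i] >= 0) subMass[S.parent[i]] += subMass[i];
    S.sufMaxU_.assign(S.n + 1, 0.0);
    for (int i = S.n - 1; i >= 0; --i)
      S.sufMaxU_[i] = std::max(S.sufMaxU_[i + 1], subMass[i]);
  }

  for (int i = 0; i < S.n; ++i)
    if (S.parent[i] >= i)
      stop("clones must be supplied in preorder (parent before child)");

  if (warmA.size() == S.n && warmB.size() == S.n) {
    std::vector<int> wa(warmA.begin(), warmA.end());
    std::vector<int> wb(warmB.begin(), warmB.end());
    int o1, ev; double o2;
    S.evaluate(wa, wb, o1, o2, ev);
    if (ev <= lambda) {
      S.bestA = wa; S.bestB = wb;
      S.bestObj1 = o1; S.bestObj2 = o2; S.bestEvents = ev;
      S.haveIncumbent = true;
    }
  }

  S.dfs(0);

  if (!S.haveIncumbent) stop("segment solve found no feasible labelling");
  return List::create(
      _["cA"] = IntegerVector(S.bestA.begin(), S.bestA.end()),
      _["cB"] = IntegerVector(S.bestB.begin(), S.bestB.end()),
      _["obj1"] = S.bestObj1, _["obj2"] = S.bestObj2,
      _["events"] = S.bestEvents,
      _["status"] = S.timedOut ? "timeout" : "optimal",
      _["nodes"] = (double)S.nodes);
}
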