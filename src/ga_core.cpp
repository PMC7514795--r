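// Compiled hot path of the genetic attribute-reduction search: chromosome
// fitness (positive-region preservation per template) and the
// entropy-based repair operator. Column keys arrive pre-coded from R
// (missing entries already expanded to per-row codes, which realizes the
// singleton-block policy for missing data), so everything here is integer
// partition arithmetic. Both functions are deterministic: repair
// tie-breaks prefer currently unselected sites, then the lowest index.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double MI_TOL = 1e-9;

// combine a partition with one pre-coded column; keys renumbered 1..k by
// first occurrence. Flat lookup for small universes, map otherwise.
static void combineCol(std::vector<int> &part, const int *col, int n) {
  if (n <= 64) {
    int lut[65 * 65] = {0};
    int next = 1;
    for (int i = 0; i < n; ++i) {
      int z = part[i] * (n + 1) + col[i];
      if (!lut[z]) lut[z] = next++;
      part[i] = lut[z];
    }
  } else {
    std::map<long long, int> seen;
    int next = 1;
    for (int i = 0; i < n; ++i) {
      long long z = (long long)part[i] * (n + 1) + col[i];
      auto it = seen.find(z);
      if (it == seen.end()) { seen.emplace(z, next); part[i] = next++; }
      else part[i] = it->second;
    }
  }
}

static std::vector<int> partitionOf(const IntegerMatrix &colKeys,
                                    const std::vector<int> &B) {
  int n = colKeys.nrow();
  std::vector<int> part(n, 1);
  for (int a : B) combineCol(part, colKeys.begin() + (R_xlen_t)a * n, n);
  return part;
}

// size of the positive region: members of label-pure blocks
static int posSize(const std::vector<int> &part, const IntegerVector &labels) {
  int n = part.size();
  std::vector<int> nn, k1;
  for (int i = 0; i < n; ++i) {
    if ((int)nn.size() < part[i]) { nn.resize(part[i], 0); k1.resize(part[i], 0); }
    nn[part[i] - 1]++;
    if (labels[i] == 1) k1[part[i] - 1]++;
  }
  int pos = 0;
  for (size_t b = 0; b < nn.size(); ++b)
    if (k1[b] == 0 || k1[b] == nn[b]) pos += nn[b];
  return pos;
}

// conditional entropy H(D | partition), binary labels, bits
static double hCond(const std::vector<int> &part, const IntegerVector &labels) {
  int n = part.size();
  std::vector<int> nn, k1;
  for (int i = 0; i < n; ++i) {
    if ((int)nn.size() < part[i]) { nn.resize(part[i], 0); k1.resize(part[i], 0); }
    nn[part[i] - 1]++;
    if (labels[i] == 1) k1[part[i] - 1]++;
  }
  double h = 0.0;
  for (size_t b = 0; b < nn.size(); ++b) {
    if (k1[b] == 0 || k1[b] == nn[b]) continue;
    double p = (double)k1[b] / nn[b];
    h -= (p * std::log2(p) + (1 - p) * std::log2(1 - p)) * nn[b];
  }
  return h / n;
}

// templates decoded from the codes, ordered by smallest member index;
// attribute indices are 0-based here
static std::vector<std::vector<int>> decodeGroups(const IntegerVector &codes) {
  std::map<int, std::vector<int>> byCode;
  for (int a = 0; a < codes.size(); ++a)
    if (codes[a] != 0) byCode[codes[a]].push_back(a);
  std::vector<std::vector<int>> groups;
  for (auto &kv : byCode) groups.push_back(kv.second);
  std::sort(groups.begin(), groups.end(),
            [](const std::vector<int> &x, const std::vector<int> &y) {
              return x.front() < y.front();
            });
  return groups;
}

// summary of the full condition set: positive-region size and H(D|C)
// [[Rcpp::export(name = ".cppTableStats")]]
List cppTableStats(const IntegerMatrix &colKeys, const IntegerVector &labels) {
  int N = colKeys.ncol();
  std::vector<int> all(N);
  for (int a = 0; a < N; ++a) all[a] = a;
  std::vector<int> part = partitionOf(colKeys, all);
  return List::create(_["posC"] = posSize(part, labels),
                      _["hC"] = hCond(part, labels));
}

// conditional entropy of one attribute subset (1-based indices)
// [[Rcpp::export(name = ".cppHCond")]]
double cppHCond(const IntegerMatrix &colKeys, const IntegerVector &labels,
                const IntegerVector &B) {
  std::vector<int> B0;
  for (int a : B) B0.push_back(a - 1);
  return hCond(partitionOf(colKeys, B0), labels);
}

// [[Rcpp::export(name = ".cppFitness")]]
double cppFitness(const IntegerMatrix &colKeys, const IntegerVector &labels,
                  const IntegerVector &codes, int posC) {
  int N = colKeys.ncol();
  double f = 0.0;
  for (auto &B : decodeGroups(codes))
    if (posSize(partitionOf(colKeys, B), labels) == posC)
      f += (double)(N - (int)B.size()) / N;
  return f;
}

// entropy-based repair: grow each template whose mutual information with
// the decision falls short of I(C;D) by the attribute with maximal
// significance gain, joined under the template's shared code; an empty
// chromosome seeds a template with code a = a (1-based)
// [[Rcpp::export(name = ".cppModify")]]
IntegerVector cppModify(const IntegerMatrix &colKeys,
                        const IntegerVector &labels, IntegerVector codes_,
                        double hC) {
  IntegerVector codes = clone(codes_);
  int N = colKeys.ncol(), n = colKeys.nrow();

  // best candidate to join R among non-locked sites: maximal gain, ties
  // preferring unselected sites then the lowest index; -1 if none remains
  auto bestCandidate = [&](const std::vector<int> &R,
                           const std::vector<bool> &locked) {
    std::vector<int> base = R.empty() ? std::vector<int>(n, 1)
                                      : partitionOf(colKeys, R);
    double hR = hCond(base, labels);
    std::vector<bool> inR(N, false);
    for (int r : R) inR[r] = true;
    int bestA = -1;
    double bestGain = -1.0;
    bool bestFree = false;
    for (int a = 0; a < N; ++a) {
      if (inR[a] || locked[a]) continue;
      std::vector<int> part = base;
      combineCol(part, colKeys.begin() + (R_xlen_t)a * n, n);
      double gain = hR - hCond(part, labels);
      bool free = codes[a] == 0;
      if (gain > bestGain + MI_TOL ||
          (gain > bestGain - MI_TOL && free && !bestFree)) {
        bestGain = gain; bestA = a; bestFree = free;
      }
    }
    return bestA;
  };

  auto miComplete = [&](const std::vector<int> &R) {
    return hCond(partitionOf(colKeys, R), labels) <= hC + MI_TOL;
  };

  // sites belonging to an MI-complete template are locked against stealing
  auto lockedSites = [&]() {
    std::vector<bool> locked(N, false);
    for (auto &B : decodeGroups(codes))
      if (miComplete(B)) for (int a : B) locked[a] = true;
    return locked;
  };

  if (decodeGroups(codes).empty()) {
    // no template at all: grow one greedily, seeding site a with code a
    std::vector<int> R;
    std::vector<bool> locked(N, false);
    int repCode = 0;
    while ((int)R.size() < N) {
      if (!R.empty() && miComplete(R)) break;
      int a = bestCandidate(R, locked);
      if (a < 0) break;
      if (repCode == 0) repCode = a + 1;
      codes[a] = repCode;
      R.push_back(a);
    }
    return codes;
  }
  // One pass over the templates in decode order. A deficient template
  // grows by its max-SGF candidate among attributes that are NOT members
  // of an MI-complete template (so completed templates stay untouched).
  // When only complete-template members remain as candidates, the donor
  // template holding the best one is absorbed whole: the union's
  // partition refines the complete donor's, so H(D|union) = H(D|C) and
  // the deficient template completes immediately. Either way every
  // template is MI-complete on exit and none is damaged.
  auto groups = decodeGroups(codes);
  std::vector<int> reps;
  for (auto &B : groups) reps.push_back(codes[B.front()]);
  for (int rc : reps) {
    for (int iter = 0; iter <= N; ++iter) {
      std::vector<int> R;
      for (int a = 0; a < N; ++a) if (codes[a] == rc) R.push_back(a);
      if (R.empty()) break;                           // absorbed earlier
      if (miComplete(R)) break;
      int a = bestCandidate(R, lockedSites());
      if (a >= 0) { codes[a] = rc; continue; }
      // only complete-template members remain: absorb a donor whole.
      // Any complete donor completes R (its partition refines the
      // donor's), so SGF cannot discriminate; absorbing the largest
      // donor sacrifices the least fitness and spares small templates.
      int donor = 0, donorSize = -1;
      for (auto &B : decodeGroups(codes)) {
        if (codes[B.front()] == rc) continue;
        if ((int)B.size() > donorSize && miComplete(B)) {
          donor = codes[B.front()];
          donorSize = (int)B.size();
        }
      }
      if (donor == 0) break;                          // R already equals C
      for (int s = 0; s < N; ++s) if (codes[s] == donor) codes[s] = rc;
    }
  }
  return codes;
}
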