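#include <Rcpp.h>
using namespace Rcpp;

// Weighted Nussinov base-pair maximization. Energies are <= 0; the optimal
// structure minimizes total energy over nested pairings with hairpin loops
// of at least minLoop unpaired bases. Traceback is deterministic: pairing
// (i,j) is preferred over leaving i unpaired, and among equal-energy pairing
// partners the smallest bifurcation point wins.

static inline double pairWeight(int a, int b, double wGC, double wAU, double wGU) {
  // bases encoded 0=A 1=C 2=G 3=U
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return wGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return 1.0; // sentinel: not pairable
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector seq, double wGC, double wAU, double wGU,
                   int minLoop) {
  int n = seq.size();
  NumericMatrix E(n, n); // zero-initialized: empty intervals cost 0
  if (n > 1) {
    for (int span = minLoop + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        double best = E(i + 1, j); // i unpaired
        for (int k = i + minLoop + 1; k <= j; ++k) {
          double w = pairWeight(seq[i], seq[k], wGC, wAU, wGU);
          if (w > 0) continue;
          double cand = w + (k > i + 1 ? E(i + 1, k - 1) : 0.0) +
                        (k < j ? E(k + 1, j) : 0.0);
          if (cand < best) best = cand;
        }
        E(i, j) = best;
      }
    }
  }

  IntegerVector pairs(n, 0); // 1-based partner, 0 = unpaired
  // iterative traceback over interval stack
  std::vector<std::pair<int,int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double target = E(i, j);
    bool placed = false;
    // prefer pairing i; smallest partner k first
    for (int k = i + minLoop + 1; k <= j; ++k) {
      double w = pairWeight(seq[i], seq[k], wGC, wAU, wGU);
      if (w > 0) continue;
      double cand = w + (k > i + 1 ? E(i + 1, k - 1) : 0.0) +
                    (k < j ? E(k + 1, j) : 0.0);
      if (cand == target) {
        pairs[i] = k + 1;
        pairs[k] = i + 1;
        if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        placed = true;
        break;
      }
    }
    if (!placed) stack.push_back(std::make_pair(i + 1, j));
  }

  double energy = (n > 1) ? E(0, n - 1) : 0.0;
  return List::create(_["pairs"] = pairs, _["energy"] = energy);
}
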