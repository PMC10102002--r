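#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex folding by exact dynamic programming.
//
// A duplex is a list of base pairs (i, j) — i a position on the miRNA
// (1-based, 5'->3'), j a position on the target site (1-based, 5'->3') —
// strictly increasing in i and strictly decreasing in j (antiparallel
// helix, no pseudoknots).  The energy of a non-empty structure is
//
//   init + sum over adjacent pairs of (stack | bulge | internal loop)
//
// where two pairs adjacent in the list with gaps l1 (miRNA side) and
// l2 (target side) contribute:
//   l1 == 0 && l2 == 0 : -(w(p) + w(q)) / 2           (stack)
//   one gap zero       : bulge_open + bulge_per_nt * l      (bulge)
//   both gaps > 0      : iloop_open + iloop_per_nt*(l1+l2)
//                        + iloop_asym*|l1-l2|         (internal loop)
// Unpaired overhangs outside the first/last pair are free.  Gaps on
// either side are capped at max_loop nucleotides.
//
// S[i][j] = minimum energy (excluding init) over structures whose FIRST
// pair is (i, j); P[i][j] = maximum pair count among structures reaching
// that minimum.  Reconstruction walks greedily from the lexicographically
// smallest optimal first pair, which yields the tie-break order required:
// minimum energy, then maximum pairs, then lexicographically smallest
// pair list.

static inline int enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1;
  }
}

// pair class: -1 none, 0 = GC, 1 = AU, 2 = GU
static inline int pair_class(int a, int b, bool gu_allowed) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return 0;
  if (gu_allowed && ((a == 2 && b == 3) || (a == 3 && b == 2))) return 2;
  return -1;
}

// [[Rcpp::export(name = ".fold_duplex_cpp")]]
List fold_duplex_cpp(std::string mirna, std::string target,
                     double w_gc, double w_au, double w_gu,
                     double bulge_open, double bulge_per_nt,
                     double iloop_open, double iloop_per_nt, double iloop_asym,
                     double init, bool gu_allowed, int max_loop) {
  const int n = (int) mirna.size();
  const int m = (int) target.size();
  std::vector<int> a(n), b(m);
  for (int i = 0; i < n; ++i) {
    a[i] = enc(mirna[i]);
    if (a[i] < 0) stop("invalid character in miRNA sequence");
  }
  for (int j = 0; j < m; ++j) {
    b[j] = enc(target[j]);
    if (b[j] < 0) stop("invalid character in target sequence");
  }

  const double INF = 1e18;
  std::vector<double> W(n * m, -1.0);   // pair weight, <0 if unpairable
  std::vector<int> CLS(n * m, -1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int cl = pair_class(a[i], b[j], gu_allowed);
      CLS[i * m + j] = cl;
      if (cl == 0) W[i * m + j] = w_gc;
      else if (cl == 1) W[i * m + j] = w_au;
      else if (cl == 2) W[i * m + j] = w_gu;
    }

  std::vector<double> S(n * m, INF);
  std::vector<int> P(n * m, 0);

  // i descending, j ascending: successors have larger i, smaller j
  for (int i = n - 1; i >= 0; --i) {
    for (int j = 0; j < m; ++j) {
      if (W[i * m + j] < 0) continue;
      double best = 0.0;   // terminal: (i,j) is the last pair
      int bestp = 1;
      for (int i2 = i + 1; i2 <= i + 1 + max_loop && i2 < n; ++i2) {
        int l1 = i2 - i - 1;
        for (int j2 = j - 1; j2 >= j - 1 - max_loop && j2 >= 0; --j2) {
          if (S[i2 * m + j2] >= INF) continue;
          int l2 = j - j2 - 1;
          double tr;
          if (l1 == 0 && l2 == 0)
            tr = -(W[i * m + j] + W[i2 * m + j2]) / 2.0;
          else if (l1 == 0 || l2 == 0)
            tr = bulge_open + bulge_per_nt * (l1 + l2);
          else
            tr = iloop_open + iloop_per_nt * (l1 + l2) +
                 iloop_asym * std::abs(l1 - l2);
          double e = tr + S[i2 * m + j2];
          int p = 1 + P[i2 * m + j2];
          if (e < best - 1e-9 || (e < best + 1e-9 && p > bestp)) {
            best = e;
            bestp = p;
          }
        }
      }
      S[i * m + j] = best;
      P[i * m + j] = bestp;
    }
  }

  // global optimum over first pairs
  double bestE = INF;
  int bestP = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      if (S[i * m + j] >= INF) continue;
      if (S[i * m + j] < bestE - 1e-9 ||
          (S[i * m + j] < bestE + 1e-9 && P[i * m + j] > bestP)) {
        bestE = S[i * m + j];
        bestP = P[i * m + j];
      }
    }

  if (bestE >= INF) {   // nothing can pair
    return List::create(_["mirna_pos"] = IntegerVector(0),
                        _["target_pos"] = IntegerVector(0),
                        _["pair_class"] = IntegerVector(0),
                        _["dg"] = 0.0);
  }

  // reconstruct lexicographically smallest optimal pair list
  std::vector<int> pi, pj, pc;
  int ci = -1, cj = -1;
  for (int i = 0; i < n && ci < 0; ++i)
    for (int j = 0; j < m; ++j) {
      if (S[i * m + j] < INF &&
          std::abs(S[i * m + j] - bestE) < 1e-9 && P[i * m + j] == bestP) {
        ci = i; cj = j; break;
      }
    }
  double remE = bestE;
  int remP = bestP;
  while (true) {
    pi.push_back(ci + 1);
    pj.push_back(cj + 1);
    pc.push_back(CLS[ci * m + cj]);
    if (remP == 1) break;
    bool found = false;
    for (int i2 = ci + 1; i2 <= ci + 1 + max_loop && i2 < n && !found; ++i2) {
      int l1 = i2 - ci - 1;
      int j2lo = cj - 1 - max_loop < 0 ? 0 : cj - 1 - max_loop;
      for (int j2 = j2lo; j2 <= cj - 1; ++j2) {   // ascending: lexicographic
        if (S[i2 * m + j2] >= INF) continue;
        int l2 = cj - j2 - 1;
        double tr;
        if (l1 == 0 && l2 == 0)
          tr = -(W[ci * m + cj] + W[i2 * m + j2]) / 2.0;
        else if (l1 == 0 || l2 == 0)
          tr = bulge_open + bulge_per_nt * (l1 + l2);
        else
          tr = iloop_open + iloop_per_nt * (l1 + l2) +
               iloop_asym * std::abs(l1 - l2);
        if (std::abs(tr + S[i2 * m + j2] - remE) < 1e-9 &&
            1 + P[i2 * m + j2] == remP) {
          remE = S[i2 * m + j2];
          remP = P[i2 * m + j2];
          ci = i2; cj = j2;
          found = true;
          break;
        }
      }
    }
    if (!found) break;   // defensive; should not happen
  }

  return List::create(_["mirna_pos"] = wrap(pi),
                      _["target_pos"] = wrap(pj),
                      _["pair_class"] = wrap(pc),
                      _["dg"] = init + bestE);
}
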