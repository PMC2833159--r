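#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Intermolecular duplex minimum-free-energy scan.
//
// Bases are coded A=0 C=1 G=2 U=3. A duplex is an ordered set of base pairs
// (utr_pos increasing, mirna_pos decreasing; antiparallel, no crossings).
// Energy = init_dG + stacking terms for adjacent pairs + loop penalties for
// gapped steps. Pair types (utr base on top, mirna base below):
// 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG; -1 = not pairable.

static inline int pair_type(int top, int bottom) {
  if (top == 0 && bottom == 3) return 0; // A-U
  if (top == 3 && bottom == 0) return 1; // U-A
  if (top == 1 && bottom == 2) return 2; // C-G
  if (top == 2 && bottom == 1) return 3; // G-C
  if (top == 2 && bottom == 3) return 4; // G-U wobble
  if (top == 3 && bottom == 2) return 5; // U-G wobble
  return -1;
}

struct Cell {
  double e;      // best energy of a duplex ending at this pair (no init)
  int npairs;    // pairs in that duplex (tie-break: prefer more)
  int pj, pi;    // backpointer (previous pair), -1 if first pair
};

// One MFE pass over the (masked) UTR. Returns best cell or energy INF.
static bool dp_pass(const std::vector<int>& utr, const std::vector<int>& mir,
                    const NumericMatrix& stack, const NumericVector& bulge_pen,
                    const NumericVector& il_pen, int max_gap_u, int max_gap_m,
                    const std::vector<bool>& masked,
                    std::vector<std::vector<Cell> >& D, int& best_j, int& best_i) {
  const double INF = std::numeric_limits<double>::infinity();
  const int N = (int)utr.size(), M = (int)mir.size();
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < M; ++i) { D[j][i].e = INF; D[j][i].npairs = 0; }

  double best_e = INF; best_j = -1; best_i = -1; int best_np = 0;
  for (int j = 0; j < N; ++j) {
    if (masked[j]) continue;
    for (int i = M - 1; i >= 0; --i) {
      int pt = pair_type(utr[j], mir[i]);
      if (pt < 0) continue;
      Cell c; c.e = 0.0; c.npairs = 1; c.pj = -1; c.pi = -1;
      for (int dj = 1; dj <= max_gap_u + 1 && j - dj >= 0; ++dj) {
        if (masked[j - dj]) break; // gaps may not span a masked region
        for (int di = 1; di <= max_gap_m + 1 && i + di < M; ++di) {
          const Cell& p = D[j - dj][i + di];
          if (!std::isfinite(p.e)) continue;
          int gu = dj - 1, gm = di - 1;
          double step;
          if (gu == 0 && gm == 0) {
            int ppt = pair_type(utr[j - 1], mir[i + 1]);
            step = stack(ppt, pt);
          } else if (gm == 0) {
            step = bulge_pen[gu - 1];
          } else if (gu == 0) {
            step = bulge_pen[gm - 1];
          } else {
            step = il_pen[gu + gm - 1]; // il_pen[n-1] = internal loop total n
          }
          double e = p.e + step;
          if (e < c.e - 1e-12 ||
              (std::abs(e - c.e) <= 1e-12 && p.npairs + 1 > c.npairs)) {
            c.e = e; c.npairs = p.npairs + 1; c.pj = j - dj; c.pi = i + di;
          }
        }
      }
      D[j][i] = c;
      if (c.e < best_e - 1e-12 ||
          (std::abs(c.e - best_e) <= 1e-12 && c.npairs > best_np)) {
        best_e = c.e; best_j = j; best_i = i; best_np = c.npairs;
      }
    }
  }
  return std::isfinite(best_e);
}

// [[Rcpp::export(name = ".duplex_scan")]]
List duplex_scan_cpp(IntegerVector utr_codes, IntegerVector mirna_codes,
                     NumericMatrix stack, NumericVector bulge_pen,
                     NumericVector il_pen, double init_dG,
                     int max_gap_utr, int max_gap_mirna,
                     double dG_keep, int max_sites) {
  const int N = utr_codes.size(), M = mirna_codes.size();
  std::vector<int> utr(utr_codes.begin(), utr_codes.end());
  std::vector<int> mir(mirna_codes.begin(), mirna_codes.end());
  List out;
  if (N < 7 || M < 1) return out;

  std::vector<bool> masked(N, false);
  std::vector<std::vector<Cell> > D(N, std::vector<Cell>(M));

  for (int s = 0; s < max_sites; ++s) {
    int bj, bi;
    if (!dp_pass(utr, mir, stack, bulge_pen, il_pen, max_gap_utr,
                 max_gap_mirna, masked, D, bj, bi)) break;
    double dg = init_dG + D[bj][bi].e;
    if (dg >= dG_keep) break;
    // traceback (last pair -> first), then reverse to ascending utr_pos
    std::vector<int> uj, mi;
    int j = bj, i = bi;
    while (j >= 0) {
      uj.push_back(j); mi.push_back(i);
      int nj = D[j][i].pj, ni = D[j][i].pi;
      j = nj; i = ni;
    }
    int k = (int)uj.size();
    IntegerVector utr_pos(k), mirna_pos(k), pair_class(k);
    for (int t = 0; t < k; ++t) {
      int jj = uj[k - 1 - t], ii = mi[k - 1 - t];
      utr_pos[t] = jj + 1;
      mirna_pos[t] = ii + 1;
      pair_class[t] = pair_type(utr[jj], mir[ii]) >= 4 ? 1 : 0; // 1 = G-U
    }
    int site_start = utr_pos[0], site_end = utr_pos[k - 1];
    for (int jj = site_start - 1; jj < site_end; ++jj) masked[jj] = true;
    out.push_back(List::create(
      _["utr_pos"] = utr_pos, _["mirna_pos"] = mirna_pos,
      _["pair_class"] = pair_class, _["dG"] = dg,
      _["site_start"] = site_start, _["site_end"] = site_end));
  }
  return out;
}
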