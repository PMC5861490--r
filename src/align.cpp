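#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded Smith-Waterman with affine gaps, restricted to diagonals
// d = j - i (0-based ref minus query position) in [diag_lo, diag_hi].
// Match/mismatch counts along the optimal path are carried through the
// recursion (deterministic tie preference: diagonal, then gap-in-query,
// then gap-in-ref, then local restart) so identity can be reported
// without a traceback.  A gap of length L costs gap_open + L * gap_ext,
// matching the convention of Biostrings::pairwiseAlignment.
// [[Rcpp::export]]
List banded_local_align_cpp(std::string q, std::string r,
                            int diag_lo, int diag_hi,
                            double match, double mismatch,
                            double gap_open, double gap_ext) {
  const int n = (int) q.size(), m = (int) r.size();
  const int w = diag_hi - diag_lo + 1;
  if (w < 1) stop("band is empty");
  const double NEG = -1e18;

  // previous / current row, band coordinates b = j - i - diag_lo
  std::vector<double> Hp(w, NEG), Ep(w, NEG), Fp(w, NEG);
  std::vector<double> H(w), E(w), F(w);
  std::vector<int> Hmp(w, 0), Hcp(w, 0), Fmp(w, 0), Fcp(w, 0);
  std::vector<int> Hm(w), Hc(w), Em(w), Ec(w), Fm(w), Fc(w);

  // row 0: H = 0 at valid cells (alignment may start anywhere)
  for (int b = 0; b < w; ++b) {
    int j = diag_lo + b;           // i = 0
    if (j >= 0 && j <= m) { Hp[b] = 0.0; Hmp[b] = 0; Hcp[b] = 0; }
  }

  double best = 0.0; int best_m = 0, best_c = 0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int b = 0; b < w; ++b) {
      int j = i + diag_lo + b;
      H[b] = E[b] = F[b] = NEG;
      Hm[b] = Hc[b] = Em[b] = Ec[b] = Fm[b] = Fc[b] = 0;
      if (j < 1 || j > m) {
        if (j == 0) { H[b] = 0.0; }   // column 0: fresh local start
        continue;
      }
      // E: gap in query (consume ref), from (i, j-1) = same row, b-1
      if (b - 1 >= 0) {
        double openE = (H[b - 1] > NEG / 2) ? H[b - 1] - gap_open - gap_ext : NEG;
        double extE  = (E[b - 1] > NEG / 2) ? E[b - 1] - gap_ext : NEG;
        if (openE >= extE) { E[b] = openE; Em[b] = Hm[b - 1]; Ec[b] = Hc[b - 1] + 1; }
        else               { E[b] = extE;  Em[b] = Em[b - 1]; Ec[b] = Ec[b - 1] + 1; }
      }
      // F: gap in ref (consume query), from (i-1, j) = prev row, b+1
      if (b + 1 < w) {
        double openF = (Hp[b + 1] > NEG / 2) ? Hp[b + 1] - gap_open - gap_ext : NEG;
        double extF  = (Fp[b + 1] > NEG / 2) ? Fp[b + 1] - gap_ext : NEG;
        if (openF >= extF) { F[b] = openF; Fm[b] = Hmp[b + 1]; Fc[b] = Hcp[b + 1] + 1; }
        else               { F[b] = extF;  Fm[b] = Fmp[b + 1]; Fc[b] = Fcp[b + 1] + 1; }
      }
      // H: diagonal from (i-1, j-1) = prev row, same b
      char qa = q[i - 1], rb = r[j - 1];
      bool ismatch = (qa == rb && qa != 'N');
      double s = ismatch ? match : mismatch;
      double diag = (Hp[b] > NEG / 2) ? Hp[b] + s : NEG;

      double h = 0.0; int hm = 0, hc = 0;   // local restart
      if (F[b] > h) { h = F[b]; hm = Fm[b]; hc = Fc[b]; }
      if (E[b] >= h) { h = E[b]; hm = Em[b]; hc = Ec[b]; }
      if (diag >= h) { h = diag; hm = Hmp[b] + (ismatch ? 1 : 0); hc = Hcp[b] + 1; }
      H[b] = h; Hm[b] = hm; Hc[b] = hc;

      if (h > best) { best = h; best_m = hm; best_c = hc; best_i = i; best_j = j; }
    }
    std::swap(Hp, H); std::swap(Ep, E); std::swap(Fp, F);
    std::swap(Hmp, Hm); std::swap(Hcp, Hc); std::swap(Fmp, Fm); std::swap(Fcp, Fc);
  }

  double identity = best_c > 0 ? 100.0 * best_m / best_c : 0.0;
  return List::create(_["score"] = best, _["matches"] = best_m,
                      _["columns"] = best_c, _["identity"] = identity,
                      _["q_end"] = best_i, _["r_end"] = best_j);
}

// Longest suffix(a)/prefix(b) overlap with mismatch rate <= max_mm_rate.
// Scans overlap lengths from min(|a|,|b|) down to min_ov and returns the
// first (longest) admissible one; 0 when none qualifies.
// [[Rcpp::export]]
List best_overlap_cpp(std::string a, std::string b, int min_ov,
                      double max_mm_rate) {
  const int na = (int) a.size(), nb = (int) b.size();
  int lmax = na < nb ? na : nb;
  for (int L = lmax; L >= min_ov; --L) {
    int allowed = (int) (max_mm_rate * L);
    int mm = 0; bool ok = true;
    const char *pa = a.data() + (na - L), *pb = b.data();
    for (int i = 0; i < L; ++i) {
      if (pa[i] != pb[i] && ++mm > allowed) { ok = false; break; }
    }
    if (ok) return List::create(_["length"] = L, _["mismatches"] = mm);
  }
  return List::create(_["length"] = 0, _["mismatches"] = 0);
}
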