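#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Fitting (glocal) alignment score: the whole read is aligned against the
// best-scoring substring of the reference. Scoring follows the end-to-end
// short-read convention: match 0, mismatch -mm, and a gap of length k costs
// -(open + k * ext) on either sequence. The best attainable score is 0
// (perfect match), so scores are always <= 0.
//
// Gotoh affine-gap DP, three states:
//   M: read[i] aligned to ref[j]
//   I: gap in the reference (consumes read)
//   D: gap in the read (consumes reference)
static int fit_score_one(const std::string &read, const std::string &ref,
                         int mm, int open, int ext) {
  const int n = read.size(), m = ref.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> M0(m + 1), I0(m + 1), D0(m + 1);
  std::vector<int> M1(m + 1), I1(m + 1), D1(m + 1);
  for (int j = 0; j <= m; ++j) {  // empty read prefix: free start in ref
    M0[j] = 0; I0[j] = NEG; D0[j] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG;
    I1[0] = -(open + i * ext);
    D1[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int diag = std::max(M0[j - 1], std::max(I0[j - 1], D0[j - 1]));
      int sub = (read[i - 1] == ref[j - 1]) ? 0 : -mm;
      M1[j] = (diag <= NEG) ? NEG : diag + sub;
      int up = std::max(std::max(M0[j], D0[j]) - open - ext, I0[j] - ext);
      I1[j] = (up <= NEG - open) ? NEG : up;
      int left = std::max(std::max(M1[j - 1], I1[j - 1]) - open - ext,
                          D1[j - 1] - ext);
      D1[j] = (left <= NEG - open) ? NEG : left;
    }
    std::swap(M0, M1); std::swap(I0, I1); std::swap(D0, D1);
  }
  int best = NEG;  // free tail in ref: take the best column; D ends in a
  for (int j = 0; j <= m; ++j)  // ref gap and can never beat an earlier M
    best = std::max(best, std::max(M0[j], I0[j]));
  return best;
}

// [[Rcpp::export]]
IntegerMatrix fit_align_matrix(CharacterVector reads, CharacterVector refs,
                               int mismatch, int gap_open, int gap_extend) {
  IntegerMatrix out(reads.size(), refs.size());
  std::vector<std::string> R(refs.size());
  for (int k = 0; k < refs.size(); ++k) R[k] = as<std::string>(refs[k]);
  for (int i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    for (int k = 0; k < (int)R.size(); ++k)
      out(i, k) = fit_score_one(rd, R[k], mismatch, gap_open, gap_extend);
  }
  return out;
}
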