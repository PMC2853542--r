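#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman with Gotoh gap states).
//
// Scoring: +match for an identical A/C/G/T pair; mismatch (<= 0) for any
// other residue pair, including anything involving N (N never matches,
// not even N vs N). A gap run of length L costs gap_open + L * gap_extend
// (both passed as non-negative costs).
//
// Tie-breaking: the first optimal ending cell in row-major order
// (query index outer, subject index inner); traceback prefers the
// diagonal move, then the gap-in-subject state, then gap-in-query.

namespace {

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// traceback codes for the H state
enum : unsigned char { TB_NONE = 0, TB_DIAG = 1, TB_F = 2, TB_E = 3 };

} // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = static_cast<int>(query.size());
  const int m = static_cast<int>(subject.size());
  if (n == 0 || m == 0)
    stop("local alignment requires non-empty sequences");

  const double NEG = -1e30;
  const double gap_first = gap_open + gap_extend; // cost of opening a 1-long gap

  // Rolling rows for scores; full byte matrices for traceback.
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG); // E: gap in query (consumes subject)
  std::vector<double> Fcur(m + 1, NEG);                    // F: gap in subject (consumes query)
  std::vector<double> Fprev(m + 1, NEG);

  // tbH: move that produced H; tbE/tbF: 1 if the gap was extended (came
  // from E/F), 0 if freshly opened (came from H).
  std::vector<unsigned char> tbH(static_cast<size_t>(n + 1) * (m + 1), TB_NONE);
  std::vector<unsigned char> tbE(static_cast<size_t>(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF(static_cast<size_t>(n + 1) * (m + 1), 0);

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG;
    const char qc = query[static_cast<size_t>(i - 1)];
    const size_t row = static_cast<size_t>(i) * (m + 1);
    for (int j = 1; j <= m; ++j) {
      const char sc = subject[static_cast<size_t>(j - 1)];
      const double s = (qc == sc && is_acgt(qc)) ? match : mismatch;

      // E: gap in query, horizontal move (j-1 -> j on the same query row)
      double e_open = Hcur[j - 1] - gap_first;
      double e_ext  = Ecur[j - 1] - gap_extend;
      if (e_ext > e_open) { Ecur[j] = e_ext; tbE[row + j] = 1; }
      else                { Ecur[j] = e_open; tbE[row + j] = 0; }

      // F: gap in subject, vertical move (i-1 -> i in the same column)
      double f_open = Hprev[j] - gap_first;
      double f_ext  = Fprev[j] - gap_extend;
      if (f_ext > f_open) { Fcur[j] = f_ext; tbF[row + j] = 1; }
      else                { Fcur[j] = f_open; tbF[row + j] = 0; }

      double diag = Hprev[j - 1] + s;
      double h = 0.0;
      unsigned char tb = TB_NONE;
      if (diag > h)    { h = diag;    tb = TB_DIAG; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = TB_F; }
      if (Ecur[j] > h) { h = Ecur[j]; tb = TB_E; }
      Hcur[j] = h;
      tbH[row + j] = tb;

      if (h > best) { best = h; best_i = i; best_j = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0.0) {
    return List::create(
      _["score"] = 0.0, _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER,
      _["s_start"] = NA_INTEGER, _["s_end"] = NA_INTEGER,
      _["n_columns"] = 0L, _["n_matches"] = 0L, _["n_gap_columns"] = 0L,
      _["q_aln"] = "", _["s_aln"] = "");
  }

  // Traceback from (best_i, best_j) through the stored state moves.
  int i = best_i, j = best_j;
  int n_cols = 0, n_match = 0, n_gap = 0;
  std::string qa, sa;
  unsigned char state = 'H';
  while (i > 0 && j > 0) {
    const size_t idx = static_cast<size_t>(i) * (m + 1) + j;
    if (state == 'H') {
      unsigned char tb = tbH[idx];
      if (tb == TB_NONE) break; // local start
      if (tb == TB_DIAG) {
        char qc = query[static_cast<size_t>(i - 1)];
        char sc = subject[static_cast<size_t>(j - 1)];
        qa.push_back(qc); sa.push_back(sc);
        ++n_cols;
        if (qc == sc && is_acgt(qc)) ++n_match;
        --i; --j;
      } else if (tb == TB_F) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {
      // gap in subject: consume query base
      qa.push_back(query[static_cast<size_t>(i - 1)]);
      sa.push_back('-');
      ++n_cols; ++n_gap;
      unsigned char ext = tbF[idx];
      --i;
      state = ext ? 'F' : 'H';
    } else { // 'E': gap in query, consume subject base
      qa.push_back('-');
      sa.push_back(subject[static_cast<size_t>(j - 1)]);
      ++n_cols; ++n_gap;
      unsigned char ext = tbE[idx];
      --j;
      state = ext ? 'E' : 'H';
    }
  }

  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = best_i,
    _["s_start"] = j + 1, _["s_end"] = best_j,
    _["n_columns"] = n_cols, _["n_matches"] = n_match,
    _["n_gap_columns"] = n_gap,
    _["q_aln"] = qa, _["s_aln"] = sa);
}

// Score-only variant used for fast candidate ranking over long subjects:
// same recurrence without traceback storage, O(min memory).
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(std::string query, std::string subject,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int n = static_cast<int>(query.size());
  const int m = static_cast<int>(subject.size());
  if (n == 0 || m == 0)
    stop("local alignment requires non-empty sequences");
  const double NEG = -1e30;
  const double gap_first = gap_open + gap_extend;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Ecur(m + 1, NEG);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG;
    const char qc = query[static_cast<size_t>(i - 1)];
    for (int j = 1; j <= m; ++j) {
      const char sc = subject[static_cast<size_t>(j - 1)];
      const double s = (qc == sc && is_acgt(qc)) ? match : mismatch;
      double e = std::max(Hcur[j - 1] - gap_first, Ecur[j - 1] - gap_extend);
      double f = std::max(Hprev[j] - gap_first, Fprev[j] - gap_extend);
      double h = std::max(0.0, Hprev[j - 1] + s);
      h = std::max(h, std::max(e, f));
      Ecur[j] = e; Fcur[j] = f; Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}
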