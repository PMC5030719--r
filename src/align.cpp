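#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise DNA alignment (Gotoh three-state DP).
//   type: "local" (Smith-Waterman), "global" (Needleman-Wunsch, end gaps
//   penalized), "overlap" (ends-free in both sequences).
// Scoring: match/mismatch substitution scores; N scores 0 against anything;
// a gap of length L costs gap_open + L * gap_extend (Biostrings convention).

namespace {

const double NEG = -1e30;

inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

struct Aligner {
  const std::string &p, &s;
  int n, m;
  double match, mismatch, go, ge;
  int type; // 0 local, 1 global, 2 overlap
  // score matrices M (diagonal), X (gap in subject), Y (gap in pattern)
  std::vector<double> M, X, Y;
  // traceback: predecessor state (0=M,1=X,2=Y,3=start) per state
  std::vector<signed char> tM, tX, tY;

  Aligner(const std::string &p_, const std::string &s_, double match_,
          double mismatch_, double go_, double ge_, int type_)
      : p(p_), s(s_), n(p_.size()), m(s_.size()), match(match_),
        mismatch(mismatch_), go(go_), ge(ge_), type(type_) {}

  inline int at(int i, int j) const { return i * (m + 1) + j; }

  void fill() {
    M.assign((n + 1) * (m + 1), NEG);
    X.assign((n + 1) * (m + 1), NEG);
    Y.assign((n + 1) * (m + 1), NEG);
    tM.assign((n + 1) * (m + 1), 3);
    tX.assign((n + 1) * (m + 1), 3);
    tY.assign((n + 1) * (m + 1), 3);
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
      if (type == 1) { // global: leading gap in subject
        X[at(i, 0)] = -(go + ge * i);
        tX[at(i, 0)] = (i == 1) ? 0 : 1;
      } else {
        M[at(i, 0)] = 0.0;
      }
    }
    for (int j = 1; j <= m; ++j) {
      if (type == 1) {
        Y[at(0, j)] = -(go + ge * j);
        tY[at(0, j)] = (j == 1) ? 0 : 2;
      } else {
        M[at(0, j)] = 0.0;
      }
    }
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        int ij = at(i, j), dg = at(i - 1, j - 1);
        int up = at(i - 1, j), lf = at(i, j - 1);
        // M: consume p[i-1] and s[j-1]
        double sc = subscore(p[i - 1], s[j - 1], match, mismatch);
        double bm = M[dg];
        signed char bt = 0;
        if (X[dg] > bm) { bm = X[dg]; bt = 1; }
        if (Y[dg] > bm) { bm = Y[dg]; bt = 2; }
        double v = bm + sc;
        if (type == 0 && v < 0) { v = 0; bt = 3; }
        if (bm <= NEG / 2) { // unreachable predecessor
          if (type == 0) { v = (sc > 0) ? sc : 0; bt = 3; }
          else v = NEG;
        }
        M[ij] = v; tM[ij] = bt;
        // X: consume p[i-1], gap in subject
        double xo = std::max(M[up], Y[up]) - (go + ge);
        double xe = X[up] - ge;
        if (xe >= xo) { X[ij] = xe; tX[ij] = 1; }
        else { X[ij] = xo; tX[ij] = (M[up] >= Y[up]) ? 0 : 2; }
        // Y: consume s[j-1], gap in pattern
        double yo = std::max(M[lf], X[lf]) - (go + ge);
        double ye = Y[lf] - ge;
        if (ye >= yo) { Y[ij] = ye; tY[ij] = 2; }
        else { Y[ij] = yo; tY[ij] = (M[lf] >= X[lf]) ? 0 : 1; }
      }
    }
  }

  // find the end cell/state for traceback, returns score
  double endpoint(int &ei, int &ej, int &es) const {
    double best = NEG;
    ei = ej = es = 0;
    if (type == 0) { // local: best M anywhere
      for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j)
          if (M[at(i, j)] > best) { best = M[at(i, j)]; ei = i; ej = j; es = 0; }
      if (best <= 0) { ei = ej = 0; best = 0; }
      return best;
    }
    if (type == 1) { // global: (n, m), best state
      int ij = at(n, m);
      best = M[ij]; es = 0;
      if (X[ij] > best) { best = X[ij]; es = 1; }
      if (Y[ij] > best) { best = Y[ij]; es = 2; }
      ei = n; ej = m;
      return best;
    }
    // overlap: best M over last row and last column
    for (int i = 1; i <= n; ++i)
      if (M[at(i, m)] > best) { best = M[at(i, m)]; ei = i; ej = m; es = 0; }
    for (int j = 1; j <= m; ++j)
      if (M[at(n, j)] > best) { best = M[at(n, j)]; ei = n; ej = j; es = 0; }
    return best;
  }

  List traceback(bool with_strings) {
    int ei, ej, es;
    double sc = endpoint(ei, ej, es);
    std::string pa, sa;
    int i = ei, j = ej, st = es;
    while (true) {
      if (i == 0 && j == 0) break;
      if (type != 1 && (i == 0 || j == 0)) break; // free-end boundary
      signed char prev;
      if (st == 0) {
        if (type == 0 && M[at(i, j)] <= 0) break; // local fresh-start cell
        prev = tM[at(i, j)];
        pa.push_back(p[i - 1]); sa.push_back(s[j - 1]);
        --i; --j;
        if (prev == 3) break; // alignment started at the consumed cell
      } else if (st == 1) {
        prev = tX[at(i, j)];
        pa.push_back(p[i - 1]); sa.push_back('-');
        --i;
      } else {
        prev = tY[at(i, j)];
        pa.push_back('-'); sa.push_back(s[j - 1]);
        --j;
      }
      st = prev;
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(sa.begin(), sa.end());
    int ps = i, ss = j; // 0-based starts of aligned region
    int matches = 0, mismatches = 0, gaps = 0;
    for (size_t k = 0; k < pa.size(); ++k) {
      if (pa[k] == '-' || sa[k] == '-') ++gaps;
      else if (pa[k] == sa[k]) ++matches;
      else ++mismatches;
    }
    List out = List::create(
        _["score"] = sc, _["pat_start"] = ps, _["pat_end"] = ei,
        _["sub_start"] = ss, _["sub_end"] = ej,
        _["columns"] = (int)pa.size(), _["matches"] = matches,
        _["mismatches"] = mismatches, _["gaps"] = gaps);
    if (with_strings) {
      out["pat_aln"] = pa;
      out["sub_aln"] = sa;
    }
    return out;
  }
};

// score-only DP with rolling rows: O(m) memory, no traceback bookkeeping
double score_only(const std::string &p, const std::string &s, double match,
                  double mismatch, double go, double ge, int type) {
  int n = p.size(), m = s.size();
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1), M1(m + 1), X1(m + 1),
      Y1(m + 1);
  double best = (type == 0) ? 0.0 : NEG;
  M0[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X0[j] = NEG;
    if (type == 1) { M0[j] = NEG; Y0[j] = -(go + ge * j); }
    else { M0[j] = 0.0; Y0[j] = NEG; }
  }
  X0[0] = NEG; Y0[0] = NEG;
  for (int i = 1; i <= n; ++i) {
    if (type == 1) { M1[0] = NEG; X1[0] = -(go + ge * i); }
    else { M1[0] = 0.0; X1[0] = NEG; }
    Y1[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double sc = subscore(p[i - 1], s[j - 1], match, mismatch);
      double bm = std::max(M0[j - 1], std::max(X0[j - 1], Y0[j - 1]));
      double v = (bm <= NEG / 2) ? NEG : bm + sc;
      if (type == 0) v = std::max(v, sc > 0 ? sc : 0.0);
      if (type == 0 && v < 0) v = 0;
      M1[j] = v;
      X1[j] = std::max(std::max(M0[j], Y0[j]) - (go + ge), X0[j] - ge);
      Y1[j] = std::max(std::max(M1[j - 1], X1[j - 1]) - (go + ge),
                       Y1[j - 1] - ge);
      if (type == 0 && v > best) best = v;
    }
    if (type == 2 && M1[m] > best) best = M1[m];
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  if (type == 1)
    best = std::max(M0[m], std::max(X0[m], Y0[m]));
  else if (type == 2)
    for (int j = 1; j <= m; ++j) best = std::max(best, M0[j]);
  return best;
}

int type_code(const std::string &t) {
  if (t == "local") return 0;
  if (t == "global") return 1;
  if (t == "overlap") return 2;
  stop("unknown alignment type");
  return -1;
}

} // namespace

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string pattern, std::string subject, std::string type,
                    double match, double mismatch, double gap_open,
                    double gap_extend) {
  Aligner a(pattern, subject, match, mismatch, gap_open, gap_extend,
            type_code(type));
  a.fill();
  return a.traceback(true);
}

// [[Rcpp::export(name = ".align_scores_cpp")]]
NumericVector align_scores_cpp(CharacterVector patterns, std::string subject,
                               std::string type, double match, double mismatch,
                               double gap_open, double gap_extend) {
  int tc = type_code(type);
  NumericVector out(patterns.size());
  for (int k = 0; k < patterns.size(); ++k) {
    std::string p = as<std::string>(patterns[k]);
    out[k] = score_only(p, subject, match, mismatch, gap_open, gap_extend, tc);
  }
  return out;
}
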