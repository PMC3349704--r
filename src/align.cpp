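// Affine-gap local alignment (Smith-Waterman) used by the seeded homolog
// search. Gap cost follows the WU-BLAST Q/R convention: a gap of length k
// costs gap_open + (k - 1) * gap_extend, i.e. gap_open is the cost of the
// first gap character.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int) q.size();
  const int m = (int) s.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["q_aln"] = "", _["s_aln"] = "");
  }
  if ((double) n * (double) m > 8e7)
    stop("alignment problem too large (%d x %d)", n, m);

  const double NEG = -1e18;
  const size_t W = (size_t) m + 1;
  std::vector<double> H((size_t)(n + 1) * W, 0.0);
  std::vector<double> E((size_t)(n + 1) * W, NEG);  // gap in query (consumes s)
  std::vector<double> F((size_t)(n + 1) * W, NEG);  // gap in subject (consumes q)
  // pointers: how H/E/F at a cell was reached
  // ptrH: 0 stop, 1 diag, 2 from E, 3 from F
  // ptrE: 1 opened (from H), 2 extended; ptrF likewise
  std::vector<unsigned char> ptrH((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> ptrE((size_t)(n + 1) * W, 0);
  std::vector<unsigned char> ptrF((size_t)(n + 1) * W, 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t) i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      double e_open = H[row + j - 1] - gap_open;
      double e_ext  = E[row + j - 1] - gap_extend;
      if (e_open >= e_ext) { E[row + j] = e_open; ptrE[row + j] = 1; }
      else                 { E[row + j] = e_ext;  ptrE[row + j] = 2; }

      double f_open = H[prow + j] - gap_open;
      double f_ext  = F[prow + j] - gap_extend;
      if (f_open >= f_ext) { F[row + j] = f_open; ptrF[row + j] = 1; }
      else                 { F[row + j] = f_ext;  ptrF[row + j] = 2; }

      double sub = (q[i - 1] == s[j - 1] && q[i - 1] != 'N') ? match : mismatch;
      double diag = H[prow + j - 1] + sub;

      double h = 0.0; unsigned char p = 0;
      if (diag > h)        { h = diag;        p = 1; }
      if (E[row + j] > h)  { h = E[row + j];  p = 2; }
      if (F[row + j] > h)  { h = F[row + j];  p = 3; }
      H[row + j] = h; ptrH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["s_start"] = 0, _["s_end"] = 0,
                        _["q_aln"] = "", _["s_aln"] = "");
  }

  // traceback from (bi, bj) in state H until a stop pointer
  std::string qa, sa;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    size_t idx = (size_t) i * W + j;
    if (state == 0) {
      unsigned char p = ptrH[idx];
      if (p == 0) break;
      if (p == 1) {
        qa.push_back(q[i - 1]); sa.push_back(s[j - 1]);
        --i; --j;
      } else if (p == 2) { state = 1; }
      else               { state = 2; }
    } else if (state == 1) {  // E: gap in query, consume s[j-1]
      qa.push_back('-'); sa.push_back(s[j - 1]);
      unsigned char p = ptrE[idx];
      --j;
      state = (p == 1) ? 0 : 1;
    } else {                  // F: gap in subject, consume q[i-1]
      qa.push_back(q[i - 1]); sa.push_back('-');
      unsigned char p = ptrF[idx];
      --i;
      state = (p == 1) ? 0 : 2;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["q_aln"] = qa, _["s_aln"] = sa);
}
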