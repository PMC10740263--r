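#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Viterbi local alignment of a query against a profile HMM.
//
// lo:   L x M matrix of log2 match emission odds (query pos x match state)
// mm..dd: log2 transition probabilities per junction j (between match j and
//         j+1), each of length M-1.  Insert emissions are background (odds 0).
// mask: query positions excluded from the alignment (no M or I state there).
//
// Local model: free (score 0) entry into any match state, free exit from any
// match state; score is the best cell of the M matrix.  Ties are broken
// deterministically: entry < from-M < from-I < from-D, earliest (i, j) best
// cell wins.
//
// Returns the best score in bits and the traceback path as a 3-column
// integer matrix (0-based query index, state code 0=M/1=I, match column for
// M states / junction index for I states).
// [[Rcpp::export(name = "igp_viterbi")]]
List igp_viterbi(NumericMatrix lo,
                 NumericVector mm, NumericVector mi, NumericVector md,
                 NumericVector im, NumericVector ii, NumericVector dm,
                 NumericVector dd, LogicalVector mask) {
  const int L = lo.nrow(), M = lo.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  if (L == 0 || M == 0)
    return List::create(_["score"] = NEG,
                        _["path"] = IntegerMatrix(0, 3));

  NumericMatrix Vm(L, M), Vi(L, M), Vd(L, M);
  IntegerMatrix Pm(L, M), Pi(L, M), Pd(L, M);  // 0 entry, 1 M, 2 I, 3 D
  std::fill(Vm.begin(), Vm.end(), NEG);
  std::fill(Vi.begin(), Vi.end(), NEG);
  std::fill(Vd.begin(), Vd.end(), NEG);

  double best = NEG;
  int bi = -1, bj = -1;

  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < M; ++j) {
      if (!mask[i]) {
        // match state j consuming residue i
        double sc = 0.0;  // free local entry
        int ptr = 0;
        if (i > 0 && j > 0) {
          double c = Vm(i - 1, j - 1) + mm[j - 1];
          if (c > sc) { sc = c; ptr = 1; }
          c = Vi(i - 1, j - 1) + im[j - 1];
          if (c > sc) { sc = c; ptr = 2; }
          c = Vd(i - 1, j - 1) + dm[j - 1];
          if (c > sc) { sc = c; ptr = 3; }
        }
        Vm(i, j) = sc + lo(i, j);
        Pm(i, j) = ptr;
        if (Vm(i, j) > best) { best = Vm(i, j); bi = i; bj = j; }
        // insert state at junction j (between match j and j+1), j < M-1
        if (j < M - 1 && i > 0) {
          double cM = Vm(i - 1, j) + mi[j];
          double cI = Vi(i - 1, j) + ii[j];
          if (cM >= cI) { Vi(i, j) = cM; Pi(i, j) = 1; }
          else          { Vi(i, j) = cI; Pi(i, j) = 2; }
        }
      }
      // delete state j (no residue consumed)
      if (j > 0) {
        double cM = Vm(i, j - 1) + md[j - 1];
        double cD = Vd(i, j - 1) + dd[j - 1];
        if (cM >= cD) { Vd(i, j) = cM; Pd(i, j) = 1; }
        else          { Vd(i, j) = cD; Pd(i, j) = 3; }
      }
    }
  }

  if (bi < 0)
    return List::create(_["score"] = NEG,
                        _["path"] = IntegerMatrix(0, 3));

  // traceback from the best match cell
  std::vector<int> qp, st, col;
  int i = bi, j = bj, state = 1;  // 1=M, 2=I, 3=D
  while (true) {
    if (state == 1) {
      qp.push_back(i); st.push_back(0); col.push_back(j);
      int ptr = Pm(i, j);
      if (ptr == 0) break;
      state = ptr; --i; --j;
    } else if (state == 2) {
      qp.push_back(i); st.push_back(1); col.push_back(j);
      state = Pi(i, j); --i;
    } else {  // delete: no residue
      state = Pd(i, j); --j;
    }
  }
  const int n = (int) qp.size();
  IntegerMatrix path(n, 3);
  for (int k = 0; k < n; ++k) {
    path(k, 0) = qp[n - 1 - k];
    path(k, 1) = st[n - 1 - k];
    path(k, 2) = col[n - 1 - k];
  }
  return List::create(_["score"] = best, _["path"] = path);
}
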