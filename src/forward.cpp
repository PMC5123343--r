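#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward / Viterbi DP over the reference profile HMM in odds space
// (emission ratios e/bg), so the returned value is directly the log2
// likelihood ratio against the i.i.d. background null.
//
// States: M_1..M_M (free uniform entry), I_1..I_M (background emissions,
// ratio 1), D_2..D_M (silent), E.  tIM[M-1] (0-based) holds I_M -> E and
// tDM[M-1] holds D_M -> E (= 1).  The query is consumed in full
// (model-local, query-global alignment).
//
// `ratio` is an M x 21 matrix: column 0 is the ambiguity-code ratio (1,
// background emission cancels against the null), columns 1..20 are
// e_match(k, a) / bg(a) for the 20 standard residues.
static double phmm_dp(const std::vector<double>& ratio, int M,
                      const double* tMM, const double* tMI,
                      const double* tMD, const double* tME,
                      const double* tII, const double* tIM,
                      const double* tDM, const double* tDD,
                      const IntegerVector& q, bool viterbi) {
  const int L = q.size();
  if (L == 0) return R_NegInf;

  std::vector<double> FMp(M), FIp(M), FDp(M), FMc(M), FIc(M), FDc(M);
  double log2scale = 0.0;
  const double entry = 1.0 / M;

  // i = 1: entry emits the first residue from some match state
  {
    const double* r0 = &ratio[(q[0] + 1) * M];
    for (int k = 0; k < M; ++k) {
      FMc[k] = entry * r0[k];
      FIc[k] = 0.0;
    }
  }
  FDc[0] = 0.0;
  for (int k = 1; k < M; ++k) {
    double a = FMc[k - 1] * tMD[k - 1];
    double b = FDc[k - 1] * tDD[k - 1];
    FDc[k] = viterbi ? std::max(a, b) : (a + b);
  }

  for (int i = 1; i < L; ++i) {
    // rescale previous row
    double mx = 0.0;
    for (int k = 0; k < M; ++k) {
      if (FMc[k] > mx) mx = FMc[k];
      if (FIc[k] > mx) mx = FIc[k];
      if (FDc[k] > mx) mx = FDc[k];
    }
    if (mx <= 0.0) return R_NegInf;
    const double inv = 1.0 / mx;
    for (int k = 0; k < M; ++k) {
      FMp[k] = FMc[k] * inv; FIp[k] = FIc[k] * inv; FDp[k] = FDc[k] * inv;
    }
    log2scale += std::log2(mx);

    const double* ri = &ratio[(q[i] + 1) * M];
    FMc[0] = 0.0;
    FIc[0] = viterbi ? std::max(FMp[0] * tMI[0], FIp[0] * tII[0])
                     : (FMp[0] * tMI[0] + FIp[0] * tII[0]);
    for (int k = 1; k < M; ++k) {
      double a = FMp[k - 1] * tMM[k - 1];
      double b = FIp[k - 1] * tIM[k - 1];
      double c = FDp[k - 1] * tDM[k - 1];
      double s = viterbi ? std::max(a, std::max(b, c)) : (a + b + c);
      FMc[k] = ri[k] * s;
      double d = FMp[k] * tMI[k];
      double e = FIp[k] * tII[k];
      FIc[k] = viterbi ? std::max(d, e) : (d + e);  // insert emits at bg
    }
    FDc[0] = 0.0;
    for (int k = 1; k < M; ++k) {
      double a = FMc[k - 1] * tMD[k - 1];
      double b = FDc[k - 1] * tDD[k - 1];
      FDc[k] = viterbi ? std::max(a, b) : (a + b);
    }
  }

  // termination: exits to E
  double total = 0.0;
  for (int k = 0; k < M; ++k) {
    double v = FMc[k] * tME[k];
    total = viterbi ? std::max(total, v) : (total + v);
  }
  {
    double v = FIc[M - 1] * tIM[M - 1];          // I_M -> E
    total = viterbi ? std::max(total, v) : (total + v);
    if (M > 1) {
      double w = FDc[M - 1] * tDM[M - 1];        // D_M -> E
      total = viterbi ? std::max(total, w) : (total + w);
    }
  }
  if (total <= 0.0) return R_NegInf;
  return std::log2(total) + log2scale;
}

// emission-ratio matrix, column-major with M rows and 21 columns
// (ambiguity first, then the 20 residues)
static std::vector<double> make_ratio(const NumericMatrix& em,
                                      const NumericVector& bg) {
  const int M = em.nrow();
  std::vector<double> ratio(21 * M);
  for (int k = 0; k < M; ++k) ratio[k] = 1.0;  // ambiguity column
  for (int a = 0; a < 20; ++a)
    for (int k = 0; k < M; ++k)
      ratio[(a + 1) * M + k] = em(k, a) / bg[a];
  return ratio;
}

// [[Rcpp::export]]
double phmm_score_cpp(NumericMatrix em, NumericVector bg,
                      NumericVector tMM, NumericVector tMI,
                      NumericVector tMD, NumericVector tME,
                      NumericVector tII, NumericVector tIM,
                      NumericVector tDM, NumericVector tDD,
                      IntegerVector q, bool viterbi) {
  std::vector<double> ratio = make_ratio(em, bg);
  return phmm_dp(ratio, em.nrow(), tMM.begin(), tMI.begin(), tMD.begin(),
                 tME.begin(), tII.begin(), tIM.begin(), tDM.begin(),
                 tDD.begin(), q, viterbi);
}

// [[Rcpp::export]]
NumericVector phmm_score_batch_cpp(NumericMatrix em, NumericVector bg,
                                   NumericVector tMM, NumericVector tMI,
                                   NumericVector tMD, NumericVector tME,
                                   NumericVector tII, NumericVector tIM,
                                   NumericVector tDM, NumericVector tDD,
                                   List queries, bool viterbi) {
  std::vector<double> ratio = make_ratio(em, bg);
  const int M = em.nrow();
  const int n = queries.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector q = queries[i];
    out[i] = phmm_dp(ratio, M, tMM.begin(), tMI.begin(), tMD.begin(),
                     tME.begin(), tII.begin(), tIM.begin(), tDM.begin(),
                     tDD.begin(), q, viterbi);
  }
  return out;
}
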