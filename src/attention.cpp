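#include <Rcpp.h>
using namespace Rcpp;

// Scaled-dot-product multi-head attention core.  All token matrices are
// feature-major (d x N with N = B*m, token column index r = j*B + b for
// position j, batch element b), so each token's feature vector is
// contiguous.  keyMask is B x m; masked keys receive exactly zero weight
// and queries with an empty key set produce a zero output column.
// P is returned in [j, i, b, h] order (key index fastest).

// [[Rcpp::export]]
List attn_fwd_cpp(NumericMatrix Qt, NumericMatrix Kt, NumericMatrix Vt,
                  LogicalMatrix keyMask, int B, int m, int heads) {
  const int d = Qt.nrow();
  const int dh = d / heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  NumericMatrix At(d, Qt.ncol());
  NumericVector P((R_xlen_t)m * m * B * heads);
  const double *q = Qt.begin(), *k = Kt.begin(), *v = Vt.begin();
  double *a = At.begin(), *pp = P.begin();
  std::vector<double> S(m);
  for (int h = 0; h < heads; ++h) {
    const int c0 = h * dh;
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < m; ++i) {
        const double *qi = q + (R_xlen_t)(i * B + b) * d + c0;
        double mx = R_NegInf;
        for (int j = 0; j < m; ++j) {
          if (!keyMask(b, j)) { S[j] = R_NegInf; continue; }
          const double *kj = k + (R_xlen_t)(j * B + b) * d + c0;
          double s = 0.0;
          for (int t = 0; t < dh; ++t) s += qi[t] * kj[t];
          s *= scl;
          S[j] = s;
          if (s > mx) mx = s;
        }
        double den = 0.0;
        for (int j = 0; j < m; ++j) {
          const double e = (S[j] == R_NegInf) ? 0.0 : std::exp(S[j] - mx);
          S[j] = e;
          den += e;
        }
        if (den <= 0.0) den = 1.0;
        double *ai = a + (R_xlen_t)(i * B + b) * d + c0;
        double *pr = pp + (R_xlen_t)m * (i + (R_xlen_t)m * (b + (R_xlen_t)B * h));
        for (int j = 0; j < m; ++j) {
          const double p = S[j] / den;
          pr[j] = p;
          if (p != 0.0) {
            const double *vj = v + (R_xlen_t)(j * B + b) * d + c0;
            for (int t = 0; t < dh; ++t) ai[t] += p * vj[t];
          }
        }
      }
    }
  }
  P.attr("dim") = IntegerVector::create(m, m, B, heads);
  return List::create(_["At"] = At, _["P"] = P);
}

// [[Rcpp::export]]
List attn_bwd_cpp(NumericMatrix dAt, NumericMatrix Qt, NumericMatrix Kt,
                  NumericMatrix Vt, NumericVector P, int B, int m,
                  int heads) {
  const int d = Qt.nrow();
  const int dh = d / heads;
  const double scl = 1.0 / std::sqrt((double)dh);
  NumericMatrix dQt(d, Qt.ncol()), dKt(d, Qt.ncol()), dVt(d, Qt.ncol());
  const double *q = Qt.begin(), *k = Kt.begin(), *v = Vt.begin();
  const double *da = dAt.begin(), *pp = P.begin();
  double *dq = dQt.begin(), *dk = dKt.begin(), *dv = dVt.begin();
  std::vector<double> dPv(m);
  for (int h = 0; h < heads; ++h) {
    const int c0 = h * dh;
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < m; ++i) {
        const double *dai = da + (R_xlen_t)(i * B + b) * d + c0;
        const double *pr = pp + (R_xlen_t)m * (i + (R_xlen_t)m * (b + (R_xlen_t)B * h));
        double inner = 0.0;
        for (int j = 0; j < m; ++j) {
          const double p = pr[j];
          double dp = 0.0;
          if (p != 0.0) {
            const R_xlen_t oj = (R_xlen_t)(j * B + b) * d + c0;
            const double *vj = v + oj;
            double *dvj = dv + oj;
            for (int t = 0; t < dh; ++t) {
              dp += dai[t] * vj[t];
              dvj[t] += p * dai[t];
            }
          }
          dPv[j] = dp;
          inner += p * dp;
        }
        double *dqi = dq + (R_xlen_t)(i * B + b) * d + c0;
        const double *qi = q + (R_xlen_t)(i * B + b) * d + c0;
        for (int j = 0; j < m; ++j) {
          const double p = pr[j];
          if (p == 0.0) continue;
          const double ds = p * (dPv[j] - inner) * scl;
          const R_xlen_t oj = (R_xlen_t)(j * B + b) * d + c0;
          const double *kj = k + oj;
          double *dkj = dk + oj;
          for (int t = 0; t < dh; ++t) {
            dqi[t] += ds * kj[t];
            dkj[t] += ds * qi[t];
          }
        }
      }
    }
  }
  return List::create(_["dQt"] = dQt, _["dKt"] = dKt, _["dVt"] = dVt);
}
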