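#include <Rcpp.h>
using namespace Rcpp;

// Hot inner operations of the CNN layers. All index matrices are 1-based
// per-plane linear indices, expanded over samples/planes here so the R side
// never materialises large index arrays.

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector xv, IntegerMatrix P, int N,
                         int plane) {
  const int npos = P.nrow(), K = P.ncol();
  NumericMatrix out((R_xlen_t)npos * N, K);
  for (int q = 0; q < K; ++q) {
    const int *pq = &P(0, q);
    double *oq = &out(0, q);
    for (int n = 0; n < N; ++n) {
      const double *xn = xv.begin() + (R_xlen_t)n * plane;
      double *on = oq + (R_xlen_t)n * npos;
      for (int i = 0; i < npos; ++i) on[i] = xn[pq[i] - 1];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix dcols, IntegerMatrix P, int N,
                         int plane) {
  const int npos = P.nrow(), K = P.ncol();
  NumericVector dx((R_xlen_t)plane * N);
  for (int q = 0; q < K; ++q) {
    const int *pq = &P(0, q);
    const double *dq = &dcols(0, q);
    for (int n = 0; n < N; ++n) {
      double *xn = dx.begin() + (R_xlen_t)n * plane;
      const double *dn = dq + (R_xlen_t)n * npos;
      for (int i = 0; i < npos; ++i) xn[pq[i] - 1] += dn[i];
    }
  }
  return dx;
}

// max pooling over every (channel, sample) plane; returns pooled values and
// the 1-based linear argmax index into the input array
// [[Rcpp::export(name = ".pool_fwd_cpp")]]
List pool_fwd_cpp(NumericVector xv, IntegerMatrix P, int planes, int plane) {
  const int npos = P.nrow(), K = P.ncol();
  NumericVector vals((R_xlen_t)npos * planes);
  IntegerVector arg((R_xlen_t)npos * planes);
  for (int pl = 0; pl < planes; ++pl) {
    const double *xp = xv.begin() + (R_xlen_t)pl * plane;
    const R_xlen_t base = (R_xlen_t)pl * npos;
    const int off = pl * plane;
    for (int i = 0; i < npos; ++i) {
      int best = P(i, 0) - 1;
      double m = xp[best];
      for (int q = 1; q < K; ++q) {
        const int ix = P(i, q) - 1;
        if (xp[ix] > m) { m = xp[ix]; best = ix; }
      }
      vals[base + i] = m;
      arg[base + i] = best + off + 1;
    }
  }
  return List::create(_["values"] = vals, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".selu_fwd_cpp")]]
NumericVector selu_fwd_cpp(NumericVector x, double s, double alpha,
                           bool printed) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    if (v > 0) out[i] = s * v;
    else out[i] = printed ? s * (alpha * std::exp(v) - 1)
                          : s * alpha * (std::exp(v) - 1);
  }
  return out;
}

// gradient of the (continuous) SELU times an incoming gradient
// [[Rcpp::export(name = ".selu_bwd_cpp")]]
NumericVector selu_bwd_cpp(NumericVector x, NumericVector d, double s,
                           double alpha) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = d[i] * (x[i] > 0 ? s : s * alpha * std::exp(x[i]));
  }
  return out;
}

// [[Rcpp::export(name = ".leaky_fwd_cpp")]]
NumericVector leaky_fwd_cpp(NumericVector x, double slope) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = x[i] > 0 ? x[i] : slope * x[i];
  }
  return out;
}

// incoming gradient through a leaky ReLU evaluated at pre-activation x
// [[Rcpp::export(name = ".leaky_bwd_cpp")]]
NumericVector leaky_bwd_cpp(NumericVector x, NumericVector d, double slope) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    out[i] = d[i] * (x[i] > 0 ? 1.0 : slope);
  }
  return out;
}

// fused ReLU (from conv2) followed by leaky ReLU: since relu(x) >= 0 the
// leaky layer is the identity on its output; gradient needs only x > 0
// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector x, NumericVector d) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = x[i] > 0 ? d[i] : 0.0;
  return out;
}
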