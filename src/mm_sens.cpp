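#include <Rcpp.h>
using namespace Rcpp;

// Two-uptake Michaelis-Menten evoked-release model
//   dC/dt = R(t)(1 - A) - a V1 C/(K1+C) - b V2 C/(K2+C)
// with R(t) a rectangular pulse of height rmax over [stim_start, stim_end)
// and A = 0 (the fitter's assumption). Integrated with fixed-step RK4
// together with the forward sensitivities dC/dp for all seven parameters
// (vmax1, km1, vmax2, km2, alpha, beta, rmax).
//
// params: vmax1, km1, vmax2, km2, alpha, beta, rmax
// times:  uniform output grid (s); integration starts at times[0] with C=c0.
// oversample: RK4 sub-steps per output interval.

static inline void mm_rhs(const double *p, double ind, double C,
                          const double *S, double *dC, double *dS) {
  const double v1 = p[0], k1 = p[1], v2 = p[2], k2 = p[3];
  const double a = p[4], b = p[5];
  const double d1 = k1 + C, d2 = k2 + C;
  const double u1 = a * v1 * C / d1, u2 = b * v2 * C / d2;
  *dC = ind * p[6] - u1 - u2;
  const double J = -a * v1 * k1 / (d1 * d1) - b * v2 * k2 / (d2 * d2);
  // parameter partials of the RHS
  double fp[7];
  fp[0] = -a * C / d1;             // vmax1
  fp[1] = a * v1 * C / (d1 * d1);  // km1
  fp[2] = -b * C / d2;             // vmax2
  fp[3] = b * v2 * C / (d2 * d2);  // km2
  fp[4] = -v1 * C / d1;            // alpha
  fp[5] = -v2 * C / d2;            // beta
  fp[6] = ind;                     // rmax
  for (int j = 0; j < 7; ++j) dS[j] = J * S[j] + fp[j];
}

// [[Rcpp::export(name = ".mm_sens_cpp")]]
List mm_sens_cpp(NumericVector params, double c0, double stim_start,
                 double stim_dur, NumericVector times, int oversample = 5) {
  const int n = times.size();
  if (n < 2) stop("need at least two output times");
  const double dt = times[1] - times[0];
  const double h = dt / oversample;
  const double stim_end = stim_start + stim_dur;
  const double *p = REAL(params);

  NumericVector conc(n);
  NumericMatrix sens(n, 7);
  double C = c0, S[7] = {0, 0, 0, 0, 0, 0, 0};
  conc[0] = C;
  double k1C, k2C, k3C, k4C;
  double k1S[7], k2S[7], k3S[7], k4S[7], Ct, St[7];

  for (int i = 1; i < n; ++i) {
    double t = times[i - 1];
    for (int s = 0; s < oversample; ++s) {
      // release indicator held constant over the sub-step (classified by its
      // left endpoint); exact when the stimulation edges align with the grid
      const double ind =
          (t >= stim_start - 1e-12 && t < stim_end - 1e-12) ? 1.0 : 0.0;
      mm_rhs(p, ind, C, S, &k1C, k1S);
      Ct = C + 0.5 * h * k1C;
      for (int j = 0; j < 7; ++j) St[j] = S[j] + 0.5 * h * k1S[j];
      mm_rhs(p, ind, Ct, St, &k2C, k2S);
      Ct = C + 0.5 * h * k2C;
      for (int j = 0; j < 7; ++j) St[j] = S[j] + 0.5 * h * k2S[j];
      mm_rhs(p, ind, Ct, St, &k3C, k3S);
      Ct = C + h * k3C;
      for (int j = 0; j < 7; ++j) St[j] = S[j] + h * k3S[j];
      mm_rhs(p, ind, Ct, St, &k4C, k4S);
      C += h / 6.0 * (k1C + 2 * k2C + 2 * k3C + k4C);
      for (int j = 0; j < 7; ++j)
        S[j] += h / 6.0 * (k1S[j] + 2 * k2S[j] + 2 * k3S[j] + k4S[j]);
      if (C < 0) C = 0; // concentration cannot go negative
      t += h;
    }
    conc[i] = C;
    for (int j = 0; j < 7; ++j) sens(i, j) = S[j];
  }
  return List::create(_["concentration"] = conc, _["sensitivity"] = sens);
}
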