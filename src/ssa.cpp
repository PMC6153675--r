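#include <Rcpp.h>
using namespace Rcpp;

// Exact direct-method simulation of the gene / mRNA / protein jump process.
//
// Channels (unscaled propensities):
//   1 activation    off -> on     l1p * x_off            (neutral, negative)
//                                 l1op * x_p * x_off     (positive)
//   2 deactivation  on -> off     l1m * x_on             (neutral, positive)
//                                 l1om * x_p * x_on      (negative)
//   3 transcription               l2 * x_on
//   4 mRNA decay                  mu2 * x_r
//   5 translation                 l3 * x_r    (simple model: l3 * x_on)
//   6 protein decay               mu3 * x_p
//
// mode: 0 neutral, 1 negative, 2 positive.
// simple: two-species reduction (no mRNA; production driven by gene state).
// clamp_protein: freeze x_p and disable channels 5-6 (fast-subsystem runs).
// record: store every jump; otherwise only endpoint + accumulators.
//
// Uses R's RNG stream (set.seed on the R side gives full reproducibility).
// Time-averages of x_p, x_on, x_r and per-channel event counts are
// accumulated over [burn_in, T].

// [[Rcpp::export]]
List ssa_run_cpp(int mode, bool simple, bool clamp_protein,
                 double l1p, double l1m, double l1om, double l1op,
                 double l2, double mu2, double l3, double mu3,
                 int x_off0, int x_on0, int x_r0, int x_p0,
                 double T, double burn_in, bool record) {
  double t = 0.0;
  double x_off = x_off0, x_on = x_on0, x_r = x_r0, x_p = x_p0;
  bool absorbed = false;

  std::vector<double> ts;
  std::vector<int> r_off, r_on, r_r, r_p;
  if (record) {
    ts.reserve(1024);
    r_off.reserve(1024); r_on.reserve(1024);
    r_r.reserve(1024); r_p.reserve(1024);
    ts.push_back(0.0);
    r_off.push_back(x_off0); r_on.push_back(x_on0);
    r_r.push_back(x_r0); r_p.push_back(x_p0);
  }

  double w = 0.0, s_p = 0.0, s_p2 = 0.0, s_on = 0.0, s_r = 0.0;
  std::vector<double> counts(6, 0.0);
  double a[6];

  while (t < T) {
    a[0] = (mode == 2) ? l1op * x_p * x_off : l1p * x_off;
    a[1] = (mode == 1) ? l1om * x_p * x_on : l1m * x_on;
    a[2] = l2 * x_on;
    a[3] = mu2 * x_r;
    if (clamp_protein) {
      a[4] = 0.0; a[5] = 0.0;
    } else {
      a[4] = simple ? l3 * x_on : l3 * x_r;
      a[5] = mu3 * x_p;
    }
    double a0 = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    if (a0 <= 0.0) { absorbed = true; break; }

    double t_next = t + exp_rand() / a0;
    double hi = (t_next < T) ? t_next : T;
    double lo = (t > burn_in) ? t : burn_in;
    if (hi > lo) {
      double dw = hi - lo;
      w += dw;
      s_p += dw * x_p; s_p2 += dw * x_p * x_p;
      s_on += dw * x_on; s_r += dw * x_r;
    }
    if (t_next > T) { t = T; break; }
    t = t_next;

    double u = unif_rand() * a0;
    int k = 0;
    double acc = a[0];
    while (u > acc && k < 5) acc += a[++k];
    switch (k) {
      case 0: x_off -= 1; x_on += 1; break;
      case 1: x_off += 1; x_on -= 1; break;
      case 2: x_r += 1; break;
      case 3: x_r -= 1; break;
      case 4: x_p += 1; break;
      case 5: x_p -= 1; break;
    }
    if (t >= burn_in) counts[k] += 1.0;
    if (record) {
      ts.push_back(t);
      r_off.push_back((int)x_off); r_on.push_back((int)x_on);
      r_r.push_back((int)x_r); r_p.push_back((int)x_p);
    }
  }

  // an absorbed trajectory stays frozen up to T
  if (absorbed && t < T) {
    double lo = (t > burn_in) ? t : burn_in;
    if (T > lo) {
      double dw = T - lo;
      w += dw;
      s_p += dw * x_p; s_p2 += dw * x_p * x_p;
      s_on += dw * x_on; s_r += dw * x_r;
    }
  }

  List out = List::create(
    _["final"] = IntegerVector::create((int)x_off, (int)x_on,
                                       (int)x_r, (int)x_p),
    _["t_final"] = T,
    _["absorbed"] = absorbed,
    _["counts"] = NumericVector(counts.begin(), counts.end()),
    _["tavg"] = List::create(
      _["w"] = w,
      _["mean_p"] = (w > 0) ? s_p / w : NA_REAL,
      _["m2_p"] = (w > 0) ? s_p2 / w : NA_REAL,
      _["mean_on"] = (w > 0) ? s_on / w : NA_REAL,
      _["mean_r"] = (w > 0) ? s_r / w : NA_REAL));
  if (record) {
    out["t"] = NumericVector(ts.begin(), ts.end());
    out["x_off"] = IntegerVector(r_off.begin(), r_off.end());
    out["x_on"] = IntegerVector(r_on.begin(), r_on.end());
    out["x_r"] = IntegerVector(r_r.begin(), r_r.end());
    out["x_p"] = IntegerVector(r_p.begin(), r_p.end());
  }
  return out;
}
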