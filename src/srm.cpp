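// Core simulation and learning loops for SRM spiking layers.
//
// Weight tensors for a spiking layer are R arrays v[q, j, k] (presynaptic q,
// postsynaptic j, synapse k) passed as flat column-major vectors.
// Time is simulated on a uniform grid t = 0, dt, ..., T; the reported firing
// time is the first threshold crossing, by default refined by linear
// interpolation inside the crossing cell so that firing times vary
// continuously with the weights (SpikeProp differentiates this relation).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double eps_kernel(double s, double tau) {
  if (s <= 0.0) return 0.0;
  return (s / tau) * std::exp(1.0 - s / tau);
}

// d/ds of eps_kernel for s > 0; 0 for s <= 0 (kernel identically zero there)
static inline double eps_kernel_deriv(double s, double tau) {
  if (s <= 0.0) return 0.0;
  double e = std::exp(1.0 - s / tau);
  return (e - (s / tau) * e) / tau;
}

// Denominator guard for SpikeProp deltas. At a genuine upward threshold
// crossing the slope is positive; |D| is floored with its sign kept. A
// silent neuron carries no crossing — its clamped time T sits where the
// potential may be decaying — so its slope is forced positive to keep the
// update direction "raise the weights until it fires".
static inline double guard_denom(double x, double fl, bool fired, int *count) {
  if (!fired) {
    if (x < fl) { if (count) ++(*count); return fl; }
    return x;
  }
  if (std::fabs(x) < fl) {
    if (count) ++(*count);
    return (x < 0.0) ? -fl : fl;
  }
  return x;
}

struct LayerOut {
  std::vector<double> times;  // firing time, T when silent
  std::vector<bool> fired;
  std::vector<double> peak;   // max membrane potential over the window
};

// Simulate one fully connected SRM layer on the grid.
// v is [npre x npost x K] column-major; in_times length npre.
static LayerOut forward_srm(const double *in_times, int npre,
                            const double *v, int npost, int K,
                            const double *delays,
                            double tau, double theta, double Twin, double dt,
                            bool refine) {
  int n = (int)std::floor(Twin / dt + 1e-9) + 1;
  std::vector<double> U((size_t)npost * n, 0.0);
  // shared exponential table: eg[i] = exp(1 - t_i / tau)
  std::vector<double> eg(n);
  for (int i = 0; i < n; ++i) eg[i] = std::exp(1.0 - (i * dt) / tau);
  std::vector<double> psp(n);
  for (int q = 0; q < npre; ++q) {
    for (int k = 0; k < K; ++k) {
      double s0 = in_times[q] + delays[k];
      int i0 = (int)std::floor(s0 / dt) + 1;
      if (i0 < 0) i0 = 0;
      if (i0 >= n) continue;
      double es0 = std::exp(s0 / tau);
      for (int i = i0; i < n; ++i) {
        double s = i * dt - s0;
        psp[i] = (s / tau) * eg[i] * es0;  // == eps_kernel(s, tau)
      }
      for (int j = 0; j < npost; ++j) {
        double w = v[q + (size_t)npre * j + (size_t)npre * npost * k];
        if (w == 0.0) continue;
        double *uj = &U[(size_t)j * n];
        for (int i = i0; i < n; ++i) uj[i] += w * psp[i];
      }
    }
  }
  LayerOut out;
  out.times.assign(npost, Twin);
  out.fired.assign(npost, false);
  out.peak.assign(npost, 0.0);
  for (int j = 0; j < npost; ++j) {
    const double *uj = &U[(size_t)j * n];
    double pk = uj[0];
    int ic = -1;
    for (int i = 0; i < n; ++i) {
      if (uj[i] > pk) pk = uj[i];
      if (ic < 0 && uj[i] >= theta) ic = i;
    }
    out.peak[j] = pk;
    if (ic >= 0) {
      out.fired[j] = true;
      if (refine && ic > 0) {
        double u0 = uj[ic - 1], u1 = uj[ic];
        double frac = (u1 > u0) ? (theta - u0) / (u1 - u0) : 1.0;
        out.times[j] = (ic - 1) * dt + frac * dt;
      } else {
        out.times[j] = ic * dt;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List srm_forward_cpp(NumericVector in_times, NumericVector v,
                     int npost, int K, NumericVector delays,
                     double tau, double theta, double Twin, double dt,
                     bool refine) {
  int npre = in_times.size();
  if ((int)v.size() != npre * npost * K)
    stop("weight tensor size does not match (npre, npost, K)");
  LayerOut o = forward_srm(REAL(in_times), npre, REAL(v), npost, K,
                           REAL(delays), tau, theta, Twin, dt, refine);
  return List::create(_["times"] = NumericVector(o.times.begin(), o.times.end()),
                      _["fired"] = LogicalVector(o.fired.begin(), o.fired.end()),
                      _["peak"]  = NumericVector(o.peak.begin(), o.peak.end()));
}

// first-spike decision: earliest fired neuron; ties -> larger peak potential;
// all silent -> largest peak; remaining ties -> lowest index. 0-based result.
static int first_spike_class(const LayerOut &o) {
  int J = (int)o.times.size();
  int best = -1;
  for (int j = 0; j < J; ++j) {
    if (!o.fired[j]) continue;
    if (best < 0 || o.times[j] < o.times[best] ||
        (o.times[j] == o.times[best] && o.peak[j] > o.peak[best]))
      best = j;
  }
  if (best >= 0) return best;
  best = 0;
  for (int j = 1; j < J; ++j)
    if (o.peak[j] > o.peak[best]) best = j;
  return best;
}

// [[Rcpp::export]]
int first_spike_class_cpp(NumericVector times, LogicalVector fired,
                          NumericVector peak) {
  LayerOut o;
  o.times.assign(times.begin(), times.end());
  o.peak.assign(peak.begin(), peak.end());
  o.fired.resize(fired.size());
  for (int i = 0; i < fired.size(); ++i) o.fired[i] = fired[i];
  return first_spike_class(o) + 1;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// elementwise per-sample step clip (see learning_config max_step)
static inline double clip_step(double d, double mx) {
  if (d > mx) return mx;
  if (d < -mx) return -mx;
  return d;
}

// One online-learning epoch of the concatenated network.
// X: nsamp x Nb (bias column already appended, value 1)
// targets: nsamp x J expected firing times; y: 0-based labels
// w: Nb x Q sigmoid weights; v: Q x J x K output SRM weights (flat)
// ord: 0-based presentation order
// [[Rcpp::export]]
List cstnet_epoch_cpp(NumericMatrix X, IntegerVector y, NumericMatrix targets,
                      NumericMatrix w, NumericVector v,
                      NumericVector delays, double tau, double beta,
                      double Twin, double theta, double dt,
                      double eta, double denom_floor, double r_floor,
                      double max_step,
                      IntegerVector ord, bool refine, bool update) {
  int nsamp = X.nrow(), Nb = X.ncol(), Q = w.ncol(), J = targets.ncol();
  int K = delays.size();
  NumericMatrix w2 = clone(w);
  NumericVector v2 = clone(v);
  NumericVector sse(nsamp);
  IntegerVector pred(nsamp);
  LogicalVector correct(nsamp);
  int n_silent_out = 0, n_clamped = 0, n_floored = 0;

  std::vector<double> a(Q), tq(Q), dlt(J), gq(Q);
  std::vector<bool> clamped(Q);
  const double *dl = REAL(delays);

  for (int s = 0; s < nsamp; ++s) {
    int i = ord[s];
    // ANN forward + reciprocal coding
    for (int q = 0; q < Q; ++q) {
      double z = 0.0;
      for (int nx = 0; nx < Nb; ++nx) z += w2(nx, q) * X(i, nx);
      a[q] = sigmoid(z);
      double t = beta / a[q];
      clamped[q] = (t > Twin);
      if (clamped[q]) { t = Twin; ++n_clamped; }
      tq[q] = t;
    }
    LayerOut o = forward_srm(tq.data(), Q, REAL(v2), J, K, dl,
                             tau, theta, Twin, dt, refine);
    int cls = first_spike_class(o);
    pred[i] = cls + 1;
    correct[i] = (cls == y[i]);
    double e2 = 0.0;
    for (int j = 0; j < J; ++j) {
      double d = o.times[j] - targets(i, j);
      e2 += d * d;
      if (!o.fired[j]) ++n_silent_out;
    }
    sse[i] = e2;
    if (!update) continue;

    // output-layer SpikeProp deltas
    for (int j = 0; j < J; ++j) {
      double D = 0.0;
      for (int q = 0; q < Q; ++q)
        for (int k = 0; k < K; ++k)
          D += v2[q + (size_t)Q * j + (size_t)Q * J * k] *
               eps_kernel_deriv(o.times[j] - tq[q] - dl[k], tau);
      D = guard_denom(D, denom_floor, o.fired[j], &n_floored);
      dlt[j] = (targets(i, j) - o.times[j]) / D;
    }
    // dE/dt_q for coding neurons
    for (int q = 0; q < Q; ++q) {
      double g = 0.0;
      for (int j = 0; j < J; ++j) {
        double s2 = 0.0;
        for (int k = 0; k < K; ++k)
          s2 += v2[q + (size_t)Q * j + (size_t)Q * J * k] *
                (-eps_kernel_deriv(o.times[j] - tq[q] - dl[k], tau));
        g += dlt[j] * s2;
      }
      gq[q] = g;
    }
    // apply output weight updates
    for (int j = 0; j < J; ++j)
      for (int q = 0; q < Q; ++q)
        for (int k = 0; k < K; ++k)
          v2[q + (size_t)Q * j + (size_t)Q * J * k] += clip_step(
              -eta * dlt[j] * eps_kernel(o.times[j] - tq[q] - dl[k], tau),
              max_step);
    // ANN weight updates through the reciprocal coding (flat where clamped)
    for (int q = 0; q < Q; ++q) {
      if (clamped[q] || gq[q] == 0.0) continue;
      double af = (a[q] < r_floor) ? r_floor : a[q];
      double f = eta * beta * gq[q] * a[q] * (1.0 - a[q]) / (af * af);
      for (int nx = 0; nx < Nb; ++nx)
        w2(nx, q) += clip_step(f * X(i, nx), max_step);
    }
  }
  return List::create(_["w"] = w2, _["v"] = v2, _["sse"] = sse,
                      _["pred"] = pred, _["correct"] = correct,
                      _["n_silent_out"] = n_silent_out,
                      _["n_clamped"] = n_clamped,
                      _["n_floored"] = n_floored);
}

// One online-learning epoch of the parallel network.
// S: nsamp x M upper-path input spike times (population/linear encoded)
// X: nsamp x Nb lower-path features with bias
// b: M x P x K upper SRM weights; w: Nb x Q; v: (P+Q) x J x K
// [[Rcpp::export]]
List pstnet_epoch_cpp(NumericMatrix S, NumericMatrix X, IntegerVector y,
                      NumericMatrix targets,
                      NumericVector b, NumericMatrix w, NumericVector v,
                      int P, NumericVector delays, double tau, double beta,
                      double Twin, double theta, double dt,
                      double eta, double denom_floor, double r_floor,
                      double max_step,
                      IntegerVector ord, bool refine, bool update) {
  int nsamp = X.nrow(), Nb = X.ncol(), Q = w.ncol(), J = targets.ncol();
  int M = S.ncol(), K = delays.size(), C = P + Q;
  NumericVector b2 = clone(b);
  NumericMatrix w2 = clone(w);
  NumericVector v2 = clone(v);
  NumericVector sse(nsamp);
  IntegerVector pred(nsamp);
  LogicalVector correct(nsamp);
  int n_silent_out = 0, n_silent_hidden = 0, n_clamped = 0, n_floored = 0;

  std::vector<double> a(Q), cvec(C), dlt(J), gi(C), sm(M);
  std::vector<bool> clamped(Q);
  const double *dl = REAL(delays);

  for (int s = 0; s < nsamp; ++s) {
    int i = ord[s];
    for (int m = 0; m < M; ++m) sm[m] = S(i, m);
    // upper path: SRM hidden layer on encoded input spikes
    LayerOut hid = forward_srm(sm.data(), M, REAL(b2), P, K, dl,
                               tau, theta, Twin, dt, refine);
    for (int p = 0; p < P; ++p) {
      cvec[p] = hid.times[p];
      if (!hid.fired[p]) ++n_silent_hidden;
    }
    // lower path: ANN + reciprocal coding
    for (int q = 0; q < Q; ++q) {
      double z = 0.0;
      for (int nx = 0; nx < Nb; ++nx) z += w2(nx, q) * X(i, nx);
      a[q] = sigmoid(z);
      double t = beta / a[q];
      clamped[q] = (t > Twin);
      if (clamped[q]) { t = Twin; ++n_clamped; }
      cvec[P + q] = t;
    }
    LayerOut o = forward_srm(cvec.data(), C, REAL(v2), J, K, dl,
                             tau, theta, Twin, dt, refine);
    int cls = first_spike_class(o);
    pred[i] = cls + 1;
    correct[i] = (cls == y[i]);
    double e2 = 0.0;
    for (int j = 0; j < J; ++j) {
      double d = o.times[j] - targets(i, j);
      e2 += d * d;
      if (!o.fired[j]) ++n_silent_out;
    }
    sse[i] = e2;
    if (!update) continue;

    for (int j = 0; j < J; ++j) {
      double D = 0.0;
      for (int c = 0; c < C; ++c)
        for (int k = 0; k < K; ++k)
          D += v2[c + (size_t)C * j + (size_t)C * J * k] *
               eps_kernel_deriv(o.times[j] - cvec[c] - dl[k], tau);
      D = guard_denom(D, denom_floor, o.fired[j], &n_floored);
      dlt[j] = (targets(i, j) - o.times[j]) / D;
    }
    // dE/dt_c for every coding-layer position
    for (int c = 0; c < C; ++c) {
      double g = 0.0;
      for (int j = 0; j < J; ++j) {
        double s2 = 0.0;
        for (int k = 0; k < K; ++k)
          s2 += v2[c + (size_t)C * j + (size_t)C * J * k] *
                (-eps_kernel_deriv(o.times[j] - cvec[c] - dl[k], tau));
        g += dlt[j] * s2;
      }
      gi[c] = g;
    }
    // upper-path hidden updates (SpikeProp hidden rule); silent neurons skipped
    for (int p = 0; p < P; ++p) {
      if (!hid.fired[p] || gi[p] == 0.0) continue;
      double D = 0.0;
      for (int m = 0; m < M; ++m)
        for (int k = 0; k < K; ++k)
          D += b2[m + (size_t)M * p + (size_t)M * P * k] *
               eps_kernel_deriv(hid.times[p] - sm[m] - dl[k], tau);
      D = guard_denom(D, denom_floor, true, &n_floored);
      double f = eta * gi[p] / D;
      for (int m = 0; m < M; ++m)
        for (int k = 0; k < K; ++k)
          b2[m + (size_t)M * p + (size_t)M * P * k] += clip_step(
              f * eps_kernel(hid.times[p] - sm[m] - dl[k], tau), max_step);
    }
    // output weights
    for (int j = 0; j < J; ++j)
      for (int c = 0; c < C; ++c)
        for (int k = 0; k < K; ++k)
          v2[c + (size_t)C * j + (size_t)C * J * k] += clip_step(
              -eta * dlt[j] * eps_kernel(o.times[j] - cvec[c] - dl[k], tau),
              max_step);
    // lower-path ANN weights
    for (int q = 0; q < Q; ++q) {
      if (clamped[q] || gi[P + q] == 0.0) continue;
      double af = (a[q] < r_floor) ? r_floor : a[q];
      double f = eta * beta * gi[P + q] * a[q] * (1.0 - a[q]) / (af * af);
      for (int nx = 0; nx < Nb; ++nx)
        w2(nx, q) += clip_step(f * X(i, nx), max_step);
    }
  }
  return List::create(_["b"] = b2, _["w"] = w2, _["v"] = v2, _["sse"] = sse,
                      _["pred"] = pred, _["correct"] = correct,
                      _["n_silent_out"] = n_silent_out,
                      _["n_silent_hidden"] = n_silent_hidden,
                      _["n_clamped"] = n_clamped,
                      _["n_floored"] = n_floored);
}
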