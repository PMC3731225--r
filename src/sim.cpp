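#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sparse additive-Hill force field for a signed regulatory network.
// f_i = -k x_i + sum_{act j->i} w * x_j^n/(S^n + x_j^n)
//               + sum_{rep j->i} w * S^n/(S^n + x_j^n)
// Edge weights are passed resolved (global a/b already substituted for
// unset strengths). `mask` marks edges whose weight is overridden by a
// time schedule (activation annealing).
struct HillNet {
  int N;
  const int *src, *tgt;   // 0-based
  const int *act;         // 1 activation, 0 repression
  const double *w;
  const int *mask;
  double k, Sn, n;        // Sn = S^n
  int n_int;              // fast path when the Hill coefficient is integral
  std::vector<double> hu, hd;

  HillNet(int N_, const IntegerVector& src_, const IntegerVector& tgt_,
          const IntegerVector& act_, const NumericVector& w_,
          const IntegerVector& mask_, double k_, double S_, double n_)
    : N(N_), src(src_.size() ? &src_[0] : nullptr),
      tgt(tgt_.size() ? &tgt_[0] : nullptr),
      act(act_.size() ? &act_[0] : nullptr),
      w(w_.size() ? &w_[0] : nullptr),
      mask(mask_.size() ? &mask_[0] : nullptr),
      k(k_), Sn(std::pow(S_, n_)), n(n_),
      n_int(n_ == std::floor(n_) && n_ >= 1 && n_ <= 64 ? (int)n_ : 0),
      hu(N_), hd(N_), ne(src_.size()) {}

  int ne;

  inline double pown(double x) const {
    if (!n_int) return std::pow(x, n);
    double r = 1.0, b = x;
    int e = n_int;
    while (e) { if (e & 1) r *= b; b *= b; e >>= 1; }
    return r;
  }

  void force(const double* x, double* f, double wsched) {
    for (int i = 0; i < N; ++i) {
      double xn = pown(x[i] > 0 ? x[i] : 0.0);
      double den = Sn + xn;
      hu[i] = xn / den;
      hd[i] = Sn / den;
      f[i] = -k * x[i];
    }
    for (int e = 0; e < ne; ++e) {
      double we = mask[e] ? wsched : w[e];
      f[tgt[e]] += we * (act[e] ? hu[src[e]] : hd[src[e]]);
    }
  }
};

// Deterministic RK4 integration from many starts; returns endpoints.
// [[Rcpp::export]]
NumericMatrix integrate_grn_cpp(NumericMatrix x0, IntegerVector src,
                                IntegerVector tgt, IntegerVector act,
                                NumericVector w, double k, double S, double n,
                                double dt, int steps) {
  int N = x0.ncol(), ns = x0.nrow();
  IntegerVector mask(src.size());
  HillNet net(N, src, tgt, act, w, mask, k, S, n);
  NumericMatrix out(ns, N);
  std::vector<double> x(N), k1(N), k2(N), k3(N), k4(N), xt(N);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < N; ++i) x[i] = x0(s, i);
    for (int st = 0; st < steps; ++st) {
      net.force(&x[0], &k1[0], 0.0);
      for (int i = 0; i < N; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
      net.force(&xt[0], &k2[0], 0.0);
      for (int i = 0; i < N; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
      net.force(&xt[0], &k3[0], 0.0);
      for (int i = 0; i < N; ++i) xt[i] = x[i] + dt * k3[i];
      net.force(&xt[0], &k4[0], 0.0);
      for (int i = 0; i < N; ++i) {
        x[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        if (x[i] < 0) x[i] = 0;
      }
    }
    for (int i = 0; i < N; ++i) out(s, i) = x[i];
  }
  return out;
}

// Euler-Maruyama trajectory. sched: per-step weight for masked edges
// (length >= steps, or length 1 for a constant, or length 0 if no mask).
// Returns recorded states (step 0 and every record_every-th step).
// [[Rcpp::export]]
NumericMatrix simulate_grn_cpp(NumericVector x0, IntegerVector src,
                               IntegerVector tgt, IntegerVector act,
                               NumericVector w, IntegerVector mask,
                               NumericVector sched, double k, double S,
                               double n, double dt, double steps, double D,
                               int record_every, double lower) {
  int N = x0.size();
  HillNet net(N, src, tgt, act, w, mask, k, S, n);
  long nsteps = (long)steps;
  long nrec = nsteps / record_every + 1;
  NumericMatrix out(nrec, N);
  std::vector<double> x(N), f(N);
  for (int i = 0; i < N; ++i) { x[i] = x0[i]; out(0, i) = x[i]; }
  double sig = std::sqrt(2.0 * D * dt);
  bool have_sched = sched.size() > 0;
  long slen = sched.size();
  long r = 1;
  for (long st = 0; st < nsteps; ++st) {
    double ws = have_sched ? sched[st < slen ? st : slen - 1] : 0.0;
    net.force(&x[0], &f[0], ws);
    for (int i = 0; i < N; ++i) {
      x[i] += f[i] * dt + (D > 0 ? sig * norm_rand() : 0.0);
      if (x[i] < lower) x[i] = lower;
      if (!std::isfinite(x[i]))
        stop("non-finite state at step %ld (component %d)", st + 1, i + 1);
    }
    if ((st + 1) % record_every == 0 && r < nrec) {
      for (int i = 0; i < N; ++i) out(r, i) = x[i];
      ++r;
    }
  }
  return out;
}

// First passage times: repeated restarts from x0 until the max-norm ball
// of `radius` around `target` is entered. NA when the step budget runs out.
// [[Rcpp::export]]
NumericVector mfpt_grn_cpp(NumericVector x0, NumericVector target,
                           double radius, IntegerVector src, IntegerVector tgt,
                           IntegerVector act, NumericVector w, double k,
                           double S, double n, double dt, double D,
                           double max_steps, int n_passages) {
  int N = x0.size();
  IntegerVector mask(src.size());
  NumericVector sched(0);
  HillNet net(N, src, tgt, act, w, mask, k, S, n);
  NumericVector times(n_passages);
  std::vector<double> x(N), f(N);
  double sig = std::sqrt(2.0 * D * dt);
  long budget = (long)max_steps;
  for (int p = 0; p < n_passages; ++p) {
    for (int i = 0; i < N; ++i) x[i] = x0[i];
    double t = NA_REAL;
    for (long st = 0; st < budget; ++st) {
      net.force(&x[0], &f[0], 0.0);
      double dmax = 0.0;
      for (int i = 0; i < N; ++i) {
        x[i] += f[i] * dt + sig * norm_rand();
        if (x[i] < 0) x[i] = 0;
        double d = std::fabs(x[i] - target[i]);
        if (d > dmax) dmax = d;
      }
      if (dmax <= radius) { t = (st + 1) * dt; break; }
    }
    times[p] = t;
    if (p % 8 == 0) checkUserInterrupt();
  }
  return times;
}

// 1-D quartic double well V(x) = h (x^2 - 1)^2, force -V'(x).
// [[Rcpp::export]]
NumericVector simulate_dw_cpp(double h, double D, double x0, double dt,
                              double steps, int record_every) {
  long nsteps = (long)steps;
  long nrec = nsteps / record_every + 1;
  NumericVector out(nrec);
  double x = x0, sig = std::sqrt(2.0 * D * dt);
  out[0] = x;
  long r = 1;
  for (long st = 0; st < nsteps; ++st) {
    x += -4.0 * h * x * (x * x - 1.0) * dt + sig * norm_rand();
    if ((st + 1) % record_every == 0 && r < nrec) out[r++] = x;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mfpt_dw_cpp(double h, double D, double x0, double target,
                          double radius, double dt, double max_steps,
                          int n_passages) {
  NumericVector times(n_passages);
  double sig = std::sqrt(2.0 * D * dt);
  long budget = (long)max_steps;
  for (int p = 0; p < n_passages; ++p) {
    double x = x0, t = NA_REAL;
    for (long st = 0; st < budget; ++st) {
      x += -4.0 * h * x * (x * x - 1.0) * dt + sig * norm_rand();
      if (std::fabs(x - target) <= radius) { t = (st + 1) * dt; break; }
    }
    times[p] = t;
    if (p % 8 == 0) checkUserInterrupt();
  }
  return times;
}
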