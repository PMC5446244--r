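#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All rate-model times are in units of the membrane time constant tau (= 1).
// Inputs are sampled on their own grid (input_dt) and held piecewise
// constant, which keeps memory bounded for long training runs.

static inline double sigm(double v, double lam) {
  return 1.0 / (1.0 + std::exp(-lam * v));
}

static inline int input_row(double t, double input_dt, int n_rows) {
  int r = (int)std::floor(t / input_dt);
  if (r < 0) r = 0;
  if (r >= n_rows) r = n_rows - 1;
  return r;
}

// Euler integration of the depressing winner-take-all rate network:
//   dx_i/dt  = -x_i + phi(sum_j W_ij x_j y_j + xin_i)
//   tau_y dy_j/dt = -(y_j - 1)(1 - x_j) - (y_j - beta) x_j
// [[Rcpp::export]]
List rate_sim_cpp(NumericMatrix W, NumericVector x0, NumericVector y0,
                  NumericMatrix input, double input_dt,
                  double dt, int n_steps, double beta, double tau_y,
                  double lam, int record_every) {
  const int N = W.nrow();
  const int M = input.nrow();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xn(N);

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix xr(n_rec, N), yr(n_rec, N);
  NumericVector tr(n_rec);
  int rec = 0;
  for (int i = 0; i < N; ++i) { xr(0, i) = x[i]; yr(0, i) = y[i]; }
  tr[0] = 0.0; rec = 1;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = (step - 1) * dt;
    const int row = input_row(t, input_dt, M);
    for (int i = 0; i < N; ++i) {
      double drive = input(row, i);
      for (int j = 0; j < N; ++j) drive += W(i, j) * x[j] * y[j];
      xn[i] = x[i] + dt * (-x[i] + sigm(drive, lam));
    }
    for (int j = 0; j < N; ++j)
      y[j] += (dt / tau_y) * (-(y[j] - 1.0) * (1.0 - x[j]) - (y[j] - beta) * x[j]);
    x.swap(xn);
    if (step % record_every == 0) {
      for (int i = 0; i < N; ++i) { xr(rec, i) = x[i]; yr(rec, i) = y[i]; }
      tr[rec] = step * dt;
      ++rec;
    }
  }
  return List::create(_["t"] = tr, _["x"] = xr, _["y"] = yr);
}

// Rate network co-integrated with the anti-Hebbian weight dynamics
//   dW_ij/dt = -a1 W_ij x_i xbar_j - a2 (W_ij + 1)(1 - x_i) xbar_j
// where xbar is x low-pass filtered with time constant tau_w.  `plastic`
// switches learning off during probe segments (one flag per input row).
// [[Rcpp::export]]
List train_sim_cpp(NumericMatrix W0, NumericVector x0, NumericVector y0,
                   NumericMatrix input, double input_dt,
                   LogicalVector plastic,
                   double dt, int n_steps, double beta, double tau_y,
                   double lam, double alpha1, double alpha2, double tau_w,
                   IntegerVector snapshot_steps, int record_every) {
  const int N = W0.nrow();
  const int M = input.nrow();
  NumericMatrix W = clone(W0);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xbar(N, 0.0), xn(N);

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix xr(n_rec, N);
  NumericVector tr(n_rec);
  int rec = 0;
  for (int i = 0; i < N; ++i) xr(0, i) = x[i];
  tr[0] = 0.0; rec = 1;

  List snaps(snapshot_steps.size());
  int next_snap = 0;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = (step - 1) * dt;
    const int row = input_row(t, input_dt, M);
    for (int i = 0; i < N; ++i) {
      double drive = input(row, i);
      for (int j = 0; j < N; ++j) drive += W(i, j) * x[j] * y[j];
      xn[i] = x[i] + dt * (-x[i] + sigm(drive, lam));
    }
    for (int j = 0; j < N; ++j)
      y[j] += (dt / tau_y) * (-(y[j] - 1.0) * (1.0 - x[j]) - (y[j] - beta) * x[j]);
    x.swap(xn);
    for (int j = 0; j < N; ++j) xbar[j] += (dt / tau_w) * (x[j] - xbar[j]);

    if (plastic[row]) {
      for (int j = 0; j < N; ++j) {
        const double xbj = xbar[j];
        if (xbj < 1e-12) continue;
        for (int i = 0; i < N; ++i) {
          double w = W(i, j);
          w += dt * (-alpha1 * w * x[i] * xbj
                     - alpha2 * (w + 1.0) * (1.0 - x[i]) * xbj);
          if (w > 0.0) w = 0.0;
          if (w < -1.0) w = -1.0;
          W(i, j) = w;
        }
      }
    }

    if (next_snap < snapshot_steps.size() && step == snapshot_steps[next_snap]) {
      snaps[next_snap] = clone(W);
      ++next_snap;
    }
    if (step % record_every == 0) {
      for (int i = 0; i < N; ++i) xr(rec, i) = x[i];
      tr[rec] = step * dt;
      ++rec;
    }
  }
  return List::create(_["t"] = tr, _["x"] = xr, _["W"] = W,
                      _["snapshots"] = snaps, _["xbar"] = NumericVector(xbar.begin(), xbar.end()));
}

// Excitatory network with one shared inhibitory unit; depressing excitatory
// synapses enter as x_j y_j in both the E->E and E->I drives:
//   tau   dx_i/dt = -x_i + phi(sum_j J_ij x_j y_j - J_EI x_I + xin_i)
//   tau_I dx_I/dt = -x_I + phi_I(J_IE sum_j x_j y_j)
// phi_I is rectified tanh by default, or linear (phi_linear = true).
// [[Rcpp::export]]
List ei_sim_cpp(NumericMatrix J, double J_EI, double J_IE,
                NumericVector x0, double xI0, NumericVector y0,
                NumericMatrix input, double input_dt,
                double dt, int n_steps, double beta, double tau_y,
                double lam, double tau_I, bool phi_linear, int record_every) {
  const int N = J.nrow();
  const int M = input.nrow();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> xn(N);
  double xI = xI0;

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix xr(n_rec, N), yr(n_rec, N);
  NumericVector tr(n_rec), xIr(n_rec);
  int rec = 0;
  for (int i = 0; i < N; ++i) { xr(0, i) = x[i]; yr(0, i) = y[i]; }
  tr[0] = 0.0; xIr[0] = xI; rec = 1;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = (step - 1) * dt;
    const int row = input_row(t, input_dt, M);
    double tot = 0.0;
    for (int j = 0; j < N; ++j) tot += x[j] * y[j];
    for (int i = 0; i < N; ++i) {
      double drive = input(row, i) - J_EI * xI;
      for (int j = 0; j < N; ++j) drive += J(i, j) * x[j] * y[j];
      xn[i] = x[i] + dt * (-x[i] + sigm(drive, lam));
    }
    double vI = J_IE * tot;
    double phiI = phi_linear ? vI : (vI > 0.0 ? std::tanh(vI) : 0.0);
    xI += (dt / tau_I) * (-xI + phiI);
    for (int j = 0; j < N; ++j)
      y[j] += (dt / tau_y) * (-(y[j] - 1.0) * (1.0 - x[j]) - (y[j] - beta) * x[j]);
    x.swap(xn);
    if (step % record_every == 0) {
      for (int i = 0; i < N; ++i) { xr(rec, i) = x[i]; yr(rec, i) = y[i]; }
      tr[rec] = step * dt; xIr[rec] = xI;
      ++rec;
    }
  }
  return List::create(_["t"] = tr, _["x"] = xr, _["y"] = yr, _["x_I"] = xIr);
}

// Clustered exponential integrate-and-fire network with per-synapse
// short-term depression and (optionally) anti-Hebbian STDP on the signed
// inhibitory weights.  Units: V in mV, t in ms, C in pF, g_L in nS,
// currents in nA, Q in pC.  The depression variable of a synapse (i,j)
// depends only on presynaptic spikes of j and is therefore stored once per
// presynaptic neuron.
// [[Rcpp::export]]
List spiking_sim_cpp(NumericMatrix W0, LogicalMatrix conn, IntegerVector cluster,
                     NumericMatrix input, double input_dt,
                     double dt, int n_steps,
                     double Cm, double gL, double EL, double VT, double DeltaT,
                     double Vpeak, double tau_x, double u, double Q,
                     bool stdp_on, double A, double a,
                     double tau_pre, double tau_post,
                     NumericVector V0) {
  const int N = W0.nrow();
  const int M = input.nrow();
  NumericMatrix W = clone(W0);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> xs(N, 1.0);           // depression, per presynaptic neuron
  std::vector<double> pre_tr(N, 0.0), post_tr(N, 0.0);

  // adjacency lists: out[j] = postsynaptic targets of j, in[i] = presyn of i
  std::vector<std::vector<int> > out(N), in(N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (conn(i, j)) { out[j].push_back(i); in[i].push_back(j); }

  const double dec_pre = std::exp(-dt / tau_pre);
  const double dec_post = std::exp(-dt / tau_post);
  const double dec_x = std::exp(-dt / tau_x);   // exact recovery toward 1
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<int> spikers;
  spikers.reserve(N);

  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    const int row = input_row(t - dt, input_dt, M);
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      double ex_arg = (V[i] - VT) / DeltaT;
      if (ex_arg > 20.0) ex_arg = 20.0;        // numerical guard; spike fires anyway
      const double I_pA = 1000.0 * input(row, cluster[i] - 1);
      V[i] += (dt / Cm) * (gL * (EL - V[i]) + gL * DeltaT * std::exp(ex_arg) + I_pA);
      if (!std::isfinite(V[i])) stop("non-finite membrane potential at t = %f ms", t);
      if (V[i] >= Vpeak) { spikers.push_back(i); V[i] = EL; }
    }
    for (size_t k = 0; k < spikers.size(); ++k) {
      const int s = spikers[k];
      spike_t.push_back(t);
      spike_id.push_back(s + 1);
      // synaptic delivery as an instantaneous voltage jump, then depress
      const double scale = 1000.0 * u * Q * xs[s] / Cm;   // pC/pF -> V, so x1000 mV
      for (size_t m = 0; m < out[s].size(); ++m) {
        const int i = out[s][m];
        V[i] += scale * W(i, s);
      }
      if (stdp_on) {
        // s as presynaptic: depotentiate toward 0 by A * post trace,
        // constant potentiation -a toward -1 per presynaptic spike
        for (size_t m = 0; m < out[s].size(); ++m) {
          const int i = out[s][m];
          double w = W(i, s) - a + A * post_tr[i];
          if (w > 0.0) w = 0.0;
          if (w < -1.0) w = -1.0;
          W(i, s) = w;
        }
        // s as postsynaptic: depotentiate by A * pre trace (post after pre)
        for (size_t m = 0; m < in[s].size(); ++m) {
          const int j = in[s][m];
          double w = W(s, j) + A * pre_tr[j];
          if (w > 0.0) w = 0.0;
          if (w < -1.0) w = -1.0;
          W(s, j) = w;
        }
      }
      xs[s] *= (1.0 - u);
    }
    for (size_t k = 0; k < spikers.size(); ++k) {
      pre_tr[spikers[k]] += 1.0;
      post_tr[spikers[k]] += 1.0;
    }
    for (int i = 0; i < N; ++i) {
      pre_tr[i] *= dec_pre;
      post_tr[i] *= dec_post;
      xs[i] = 1.0 - (1.0 - xs[i]) * dec_x;
    }
  }

  return List::create(_["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
                      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
                      _["W"] = W,
                      _["x_syn"] = NumericVector(xs.begin(), xs.end()),
                      _["V"] = NumericVector(V.begin(), V.end()));
}
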