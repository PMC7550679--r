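// Core integration loop: synchronous Euler update of all leaky units with
// in-step plasticity (thresholded Hebbian LTP/LTD, endocannabinoid DSI/DSE),
// stimulus schedules, perturbations and session-boundary transient resets.
// Step order: (1) synaptic + external input from previous activations,
// (2) potential update, (3) transfer, (4) output clamps, (5) plasticity.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double U_MAX = M_PI;

// [[Rcpp::export]]
List sim_core_cpp(List net, NumericVector cs_amp, NumericVector us_amp,
                  double dt,
                  NumericVector u_init, NumericVector w_init,
                  NumericVector timer_init, NumericVector w_ref,
                  IntegerVector reset_steps,
                  bool freeze,
                  IntegerVector uc_unit, IntegerVector uc_start,
                  IntegerVector uc_end, IntegerVector uc_mode,
                  NumericVector uc_value,
                  IntegerVector co_conn, IntegerVector co_start,
                  IntegerVector co_end, IntegerVector co_mode,
                  NumericVector co_value,
                  IntegerVector pb_conn, IntegerVector pb_start,
                  IntegerVector pb_end,
                  int record_every) {
  const int n = as<int>(net["n"]);
  NumericVector tau = net["tau"], tonic = net["tonic"], phi = net["phi"],
                psi = net["psi"];
  IntegerVector pre = net["pre"], post = net["post"], rule = net["rule"];
  NumericVector sign = net["sign"], eta = net["eta"], eta_ltd = net["eta_ltd"],
                M = net["M"], sigma = net["sigma"];
  LogicalVector transient = net["transient"];
  const double theta = as<double>(net["theta_dsi"]);
  const double trigger_s = as<double>(net["trigger_s"]);
  const int nc = pre.size();
  const int steps = cs_amp.size();
  const double dt_scale = dt / 10.0;  // eta is defined per 10 ms reference step

  std::vector<double> u(u_init.begin(), u_init.end());
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> timer(timer_init.begin(), timer_init.end());
  std::vector<double> a(n), a_prev(n), drive(n);
  for (int j = 0; j < n; ++j) {
    double t0 = std::tanh(u[j] - psi[j]);
    a[j] = phi[j] * (t0 > 0 ? t0 : 0);
  }

  const int n_uc = uc_unit.size(), n_co = co_conn.size(), n_pb = pb_conn.size();
  std::vector<bool> reset_at(steps + 2, false);
  for (int k = 0; k < reset_steps.size(); ++k) {
    int s = reset_steps[k];
    if (s >= 1 && s <= steps) reset_at[s] = true;
  }

  const int n_rec = steps / record_every + ((steps % record_every) ? 1 : 0);
  NumericMatrix A_tr(n_rec, n), W_tr(n_rec, nc);
  NumericVector t_rec(n_rec);
  int r = 0;

  for (int t = 1; t <= steps; ++t) {
    if (reset_at[t]) {
      for (int c = 0; c < nc; ++c)
        if (transient[c]) w[c] = w_ref[c];
    }
    const double cs = cs_amp[t - 1], us = us_amp[t - 1];

    // (1) summed input from previous-step activations
    std::fill(drive.begin(), drive.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      double w_eff = w[c];
      int out_mode = -1;  // -1 none, 1 zero, 2 max
      for (int k = 0; k < n_co; ++k) {
        if (co_conn[k] == c + 1 && t >= co_start[k] && t <= co_end[k]) {
          if (co_mode[k] == 0) w_eff = co_value[k];
          else out_mode = co_mode[k];
        }
      }
      double a_pre;
      if (pre[c] == n + 1) a_pre = cs;
      else if (pre[c] == n + 2) a_pre = us;
      else a_pre = a[pre[c] - 1];
      double contrib;
      if (out_mode == 1) contrib = 0.0;
      else if (out_mode == 2) {
        double a_max = (pre[c] <= n) ? phi[pre[c] - 1] : a_pre;
        contrib = sign[c] * w_eff * a_max;
      } else contrib = sign[c] * w_eff * a_pre;
      drive[post[c] - 1] += contrib;
    }

    // (2) potential update, (3) transfer
    a_prev = a;
    for (int j = 0; j < n; ++j) {
      double uj = u[j] + (dt / tau[j]) * (-u[j] + tonic[j] + drive[j]);
      if (uj < 0) uj = 0; else if (uj > U_MAX) uj = U_MAX;
      u[j] = uj;
      double tv = std::tanh(uj - psi[j]);
      a[j] = phi[j] * (tv > 0 ? tv : 0);
    }

    // (4) output clamps (lesion / maximal stimulation / fixed value)
    for (int k = 0; k < n_uc; ++k) {
      if (t >= uc_start[k] && t <= uc_end[k]) {
        int j = uc_unit[k] - 1;
        if (uc_mode[k] == 0) a[j] = 0.0;
        else if (uc_mode[k] == 1) a[j] = phi[j];
        else a[j] = uc_value[k];
      }
    }

    // depolarization timers (continuous accumulation, reset on dips)
    for (int j = 0; j < n; ++j)
      timer[j] = (a[j] >= theta * phi[j]) ? timer[j] + dt / 1000.0 : 0.0;

    // (5) plasticity
    if (!freeze) {
      for (int c = 0; c < nc; ++c) {
        if (rule[c] == 0) continue;
        bool blocked = false;
        for (int k = 0; k < n_pb; ++k)
          if (pb_conn[k] == c + 1 && t >= pb_start[k] && t <= pb_end[k]) {
            blocked = true; break;
          }
        for (int k = 0; k < n_co; ++k)
          if (co_conn[k] == c + 1 && co_mode[k] == 0 &&
              t >= co_start[k] && t <= co_end[k]) {
            blocked = true; break;  // weight held by an override
          }
        if (blocked) continue;
        // pre rate: the signal the postsynaptic unit integrated this step
        // (previous-step activation for unit afferents; current amplitude
        // for the external channels, which act without synaptic delay)
        double a_pre;
        if (pre[c] == n + 1) a_pre = cs;
        else if (pre[c] == n + 2) a_pre = us;
        else a_pre = a_prev[pre[c] - 1];
        if (a_pre <= 0) continue;
        int pj = post[c] - 1;
        double dw = 0.0;
        if (rule[c] == 1 || rule[c] == 2) {           // LTP / LTP+LTD
          double hebb = (a[pj] - phi[pj] * sigma[c]) * a_pre * (M[c] - w[c]);
          if (hebb >= 0) dw = eta[c] * hebb;
          else dw = (rule[c] == 2) ? eta_ltd[c] * hebb : 0.0;
        } else {                                      // DSI / DSE
          if (timer[pj] >= trigger_s) dw = -eta[c] * w[c] * a_pre;
        }
        w[c] += dw * dt_scale;
        if (w[c] < 0) w[c] = 0;
        if ((rule[c] == 1 || rule[c] == 2) && w[c] > M[c]) w[c] = M[c];
      }
    }

    if (t % record_every == 0 || t == steps) {
      if (r < n_rec) {
        for (int j = 0; j < n; ++j) A_tr(r, j) = a[j];
        for (int c = 0; c < nc; ++c) W_tr(r, c) = w[c];
        t_rec[r] = t * dt / 1000.0;
        ++r;
      }
    }
  }

  return List::create(_["A"] = A_tr, _["W"] = W_tr, _["time_s"] = t_rec,
                      _["u_final"] = NumericVector(u.begin(), u.end()),
                      _["w_final"] = NumericVector(w.begin(), w.end()),
                      _["timer_final"] = NumericVector(timer.begin(),
                                                       timer.end()));
}
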