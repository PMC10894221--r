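#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK2 (explicit midpoint) integrator for N capacitively coupled
// relaxation oscillators in capacitance-matrix form:
//
//   M dV/dt = b(V),  b_i = (v_dd - V_i)/r_load_i - V_i / R_dev_i(state_i)
//
// M collects the parallel and coupling capacitances and is constant, so its
// inverse is factorised once in R and passed in. Device switching events
// (HRS->LRS at the effective threshold, LRS->HRS at the effective hold
// voltage) are located by bisection on the sub-step length to |dt_err| <
// dt/100 before the state flips; simultaneous crossings resolve in ascending
// node order. Cycle-to-cycle jitter redraws the effective thresholds from
// R's RNG on every transition, so results are reproducible under set.seed().

namespace {

struct SimSys {
  int n;
  const NumericMatrix &minv;   // inverse capacitance matrix
  const NumericVector &r_load;
  const NumericVector &r_on;
  const NumericVector &r_off;
  double v_dd;

  SimSys(const NumericMatrix &minv_, const NumericVector &rl,
         const NumericVector &ron, const NumericVector &roff, double vdd)
      : n(minv_.nrow()), minv(minv_), r_load(rl), r_on(ron), r_off(roff),
        v_dd(vdd) {}

  // dV/dt = Minv %*% b(V); phase[i]: 0 = HRS, 1 = LRS
  void deriv(const std::vector<double> &v, const std::vector<int> &phase,
             std::vector<double> &dv) const {
    std::vector<double> b(n);
    for (int i = 0; i < n; ++i) {
      double rdev = phase[i] == 0 ? r_off[i] : r_on[i];
      b[i] = (v_dd - v[i]) / r_load[i] - v[i] / rdev;
    }
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += minv(i, j) * b[j];
      dv[i] = acc;
    }
  }

  void rk2(const std::vector<double> &v, const std::vector<int> &phase,
           double h, std::vector<double> &out) const {
    std::vector<double> k1(n), vm(n), k2(n);
    deriv(v, phase, k1);
    for (int i = 0; i < n; ++i) vm[i] = v[i] + 0.5 * h * k1[i];
    deriv(vm, phase, k2);
    for (int i = 0; i < n; ++i) out[i] = v[i] + h * k2[i];
  }
};

// indices of nodes whose hysteretic threshold is crossed at voltage v
inline void crossings(const std::vector<double> &v,
                      const std::vector<int> &phase,
                      const std::vector<double> &vth_eff,
                      const std::vector<double> &vhold_eff,
                      std::vector<int> &out) {
  out.clear();
  for (size_t i = 0; i < v.size(); ++i) {
    if (phase[i] == 0 && v[i] >= vth_eff[i]) out.push_back((int)i);
    else if (phase[i] == 1 && v[i] <= vhold_eff[i]) out.push_back((int)i);
  }
}

// redraw the effective thresholds of node i after a transition
inline void redraw_thresholds(int i, const NumericVector &vth,
                              const NumericVector &vhold,
                              const NumericVector &sig_vth,
                              const NumericVector &sig_vhold,
                              std::vector<double> &vth_eff,
                              std::vector<double> &vhold_eff) {
  if (sig_vth[i] <= 0.0 && sig_vhold[i] <= 0.0) {
    vth_eff[i] = vth[i];
    vhold_eff[i] = vhold[i];
    return;
  }
  for (int tries = 0; tries < 100; ++tries) {
    double t = vth[i] * (1.0 + sig_vth[i] * norm_rand());
    double h = vhold[i] * (1.0 + sig_vhold[i] * norm_rand());
    if (h < t) { vth_eff[i] = t; vhold_eff[i] = h; return; }
  }
  stop("invalid-state: effective thresholds violate v_hold < v_th after 100 redraws (node %d)", i + 1);
}

} // namespace

// [[Rcpp::export]]
List onn_simulate_cpp(NumericMatrix minv, NumericVector r_load,
                      NumericVector r_on, NumericVector r_off,
                      NumericVector vth, NumericVector vhold,
                      NumericVector sig_vth, NumericVector sig_vhold,
                      double v_dd, NumericVector v0, IntegerVector phase0,
                      double dt, int n_steps, int record_stride,
                      double max_dv_frac) {
  RNGScope rng;
  const int n = minv.nrow();
  SimSys sys(minv, r_load, r_on, r_off, v_dd);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> phase(phase0.begin(), phase0.end());
  std::vector<double> vth_eff(vth.begin(), vth.end());
  std::vector<double> vhold_eff(vhold.begin(), vhold.end());

  const int n_rec = n_steps / record_stride + 1;
  NumericVector t_out(n_rec);
  NumericMatrix v_out(n_rec, n);

  std::vector<double> vtry(n), vlo(n), vhi(n);
  std::vector<int> crossed;
  long n_events = 0;

  // resolve any crossings implied by the initial condition
  crossings(v, phase, vth_eff, vhold_eff, crossed);
  for (int idx : crossed) {
    phase[idx] = 1 - phase[idx];
    redraw_thresholds(idx, vth, vhold, sig_vth, sig_vhold, vth_eff, vhold_eff);
    ++n_events;
  }

  t_out[0] = 0.0;
  for (int i = 0; i < n; ++i) v_out(0, i) = v[i];
  int rec = 1;

  const double tol = dt / 100.0;
  for (int step = 0; step < n_steps; ++step) {
    double t_local = 0.0;
    int guard = 0;
    while (t_local < dt * (1.0 - 1e-12)) {
      if (++guard > 200)
        stop("event cascade: more than 200 switching events inside one step; decrease dt");
      double h = dt - t_local;
      sys.rk2(v, phase, h, vtry);
      crossings(vtry, phase, vth_eff, vhold_eff, crossed);
      if (crossed.empty()) {
        for (int i = 0; i < n; ++i) {
          if (std::fabs(vtry[i] - v[i]) > max_dv_frac * (vth_eff[i] - vhold_eff[i]))
            stop("step-too-large: node %d moved %.3g V in one step; decrease dt", i + 1,
                 std::fabs(vtry[i] - v[i]));
        }
        v = vtry;
        t_local += h;
        break;
      }
      // bisection on the sub-step length: lo = no crossing, hi = crossing
      double lo = 0.0, hi = h;
      while (hi - lo > tol) {
        double mid = 0.5 * (lo + hi);
        sys.rk2(v, phase, mid, vtry);
        crossings(vtry, phase, vth_eff, vhold_eff, crossed);
        if (crossed.empty()) lo = mid; else hi = mid;
      }
      sys.rk2(v, phase, hi, vhi);
      crossings(vhi, phase, vth_eff, vhold_eff, crossed); // ascending node order
      v = vhi;
      for (int idx : crossed) {
        phase[idx] = 1 - phase[idx];
        redraw_thresholds(idx, vth, vhold, sig_vth, sig_vhold, vth_eff, vhold_eff);
        ++n_events;
      }
      t_local += hi;
    }
    if ((step + 1) % record_stride == 0) {
      t_out[rec] = (step + 1) * dt;
      for (int i = 0; i < n; ++i) v_out(rec, i) = v[i];
      ++rec;
    }
    if (step % 4096 == 0) checkUserInterrupt();
  }

  IntegerVector phase_final(phase.begin(), phase.end());
  return List::create(_["time"] = t_out, _["voltages"] = v_out,
                      _["n_events"] = (double)n_events,
                      _["phase_final"] = phase_final);
}
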