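#include <Rcpp.h>
using namespace Rcpp;

// Add amplitude-scaled copies of `kernel` into a length-n trace at 1-based
// onset indices. Events starting before sample 1 or running past the end are
// clipped, not wrapped.
// [[Rcpp::export]]
NumericVector deposit_events_cpp(int n, IntegerVector idx, NumericVector amp,
                                 NumericVector kernel) {
  NumericVector out(n);
  const int kl = kernel.size();
  const int ne = idx.size();
  for (int e = 0; e < ne; ++e) {
    const double a = amp[e];
    if (a == 0.0 || IntegerVector::is_na(idx[e])) continue;
    const int i0 = idx[e] - 1;
    int k0 = i0 < 0 ? -i0 : 0;
    for (int k = k0; k < kl; ++k) {
      const int i = i0 + k;
      if (i >= n) break;
      out[i] += a * kernel[k];
    }
  }
  return out;
}

// Forward-Euler integration of a conductance-driven leaky integrate-and-fire
// membrane. g in nS, r_m in MOhm (scale r_m*g*1e-3 is dimensionless), times in
// ms, voltages in mV. Returns the Vm trace (spike samples pinned at threshold)
// and 1-based spike sample indices. Vm is clamped at v_reset for ref_ms after
// each spike.
// [[Rcpp::export]]
List lif_integrate_cpp(NumericVector g_exc, NumericVector g_inh, double dt,
                       double v_rest, double v_thresh, double v_reset,
                       double ref_ms, double r_m, double tau_m, double e_exc,
                       double e_inh) {
  const int n = g_exc.size();
  const bool has_inh = g_inh.size() == n;
  NumericVector vm(n);
  std::vector<int> spikes;
  double v = v_rest;
  const int ref_steps = (int)std::round(ref_ms / dt);
  int ref_count = 0;
  const double sc = r_m * 1e-3;
  for (int i = 0; i < n; ++i) {
    if (ref_count > 0) {
      v = v_reset;
      --ref_count;
      vm[i] = v;
      continue;
    }
    double drive = (v_rest - v) + sc * g_exc[i] * (e_exc - v);
    if (has_inh) drive += sc * g_inh[i] * (e_inh - v);
    v += (dt / tau_m) * drive;
    if (v >= v_thresh) {
      spikes.push_back(i + 1);
      vm[i] = v_thresh;
      v = v_reset;
      ref_count = ref_steps;
    } else {
      vm[i] = v;
    }
  }
  return List::create(_["vm"] = vm, _["spike_idx"] = wrap(spikes));
}
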