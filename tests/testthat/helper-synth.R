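# shared fixtures: small synthetic pairs built in code

# one-row synapse table with explicit overrides
mk_syn <- function(mean_amp = 1.2, amp_cv = 0.2, p_fail = 0.37,
                   latency_ms = 2.5, latency_jitter_ms = 0.3,
                   stsd_depress = 0, stsd_tau_ms = 60) {
  tibble::tibble(
    synapse_id = 1L, mean_amp = mean_amp, amp_cv = amp_cv, p_fail = p_fail,
    latency_ms = latency_ms, latency_jitter_ms = latency_jitter_ms,
    stsd_depress = stsd_depress, stsd_tau_ms = stsd_tau_ms
  )
}

# Poisson-ish presynaptic train as a spike table
mk_train <- function(n_spikes, duration_s, seed = NULL, jittered_n = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (jittered_n) stats::rpois(1, n_spikes) else n_spikes
  tibble::tibble(
    cell_id = 1L,
    spike_time_s = sort(stats::runif(n, 0.05, duration_s - 0.05))
  )
}

# complete synthetic connected pair
mk_pair_rec <- function(n_spikes = 600, rate_hz = 10, syn = mk_syn(),
                        seed = 1, noise = noise_params(white_sd = 0.03,
                                                       ou_sd = 0.3), ...) {
  dur <- n_spikes / rate_hz
  st <- mk_train(n_spikes, dur, seed = seed)
  synthesize_recording(st, syn, duration_s = dur, noise = noise,
                       seed = seed + 1, ...)
}

# zero-noise trace with one EPSP-like double-exponential event per spike
mk_clean_vm <- function(spikes, duration_s, fs = 10000, amp = 1,
                        latency_ms = 2.5, tau_rise = 0.5, tau_decay = 4,
                        rest = -65) {
  n <- round(duration_s * fs) + 1L
  t <- seq(0, 10 * tau_decay, by = 1000 / fs)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k <- k / max(k)
  vm <- rep(rest, n)
  for (s in spikes) {
    i0 <- round((s + latency_ms / 1000) * fs) + 1L
    idx <- i0:min(i0 + length(k) - 1L, n)
    vm[idx] <- vm[idx] + amp * k[seq_along(idx)]
  }
  vm
}
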