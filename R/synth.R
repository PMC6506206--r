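#' Draw a cohort of ground-truth thalamocortical synapses
#'
#' Generates per-synapse parameter triplets (mean transmitted-event amplitude,
#' event-amplitude CV, per-spike failure probability) with the monotone
#' coupling seen in vivo: synapses with larger mean amplitudes have lower
#' failure probabilities and lower amplitude CVs. Defaults approximate the
#' population marginals of connected LGN-V1 pairs: detectable-EPSP means near
#' 0.89 +/- 0.24 mV and failure (undetectable) probabilities near 37 +/- 12%.
#' About half the cohort carries short-term depression and a small minority
#' facilitation, mirroring the observed mix.
#'
#' @param n_synapses Cohort size.
#' @param mean_amp_mu,mean_amp_sd Mean and SD (mV) of the truncated-normal
#'   distribution of per-synapse mean transmitted amplitudes.
#' @param p_fail_center Population-center failure probability at the mean
#'   amplitude.
#' @param coupling Logit-scale strength of the negative amplitude-failure
#'   coupling (per SD of mean amplitude).
#' @param p_fail_noise_sd Logit-scale scatter of failure probabilities.
#' @param amp_cv_mu Center of the transmitted-event amplitude CV.
#' @param stsd Logical; include short-term plasticity parameters (depressing /
#'   facilitating / static mix) or set them all to zero.
#' @param latency_ms,latency_jitter_ms Mean synaptic latency and its per-spike
#'   jitter SD (ms); defaults sit inside the 1.0-4.5 ms monosynaptic range.
#' @param stsd_tau_ms Recovery time constant for short-term plasticity, ms.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `synapse_id`, `mean_amp`, `amp_cv`, `p_fail`,
#'   `latency_ms`, `latency_jitter_ms`, `stsd_depress`, `stsd_tau_ms`.
#'   `stsd_depress > 0` depresses (short-ISI amplitudes shrink by
#'   `stsd_depress * exp(-ISI/tau)`), `< 0` facilitates.
#' @export
synapse_cohort <- function(n_synapses = 36, mean_amp_mu = 0.89,
                           mean_amp_sd = 0.24, p_fail_center = 0.37,
                           coupling = 0.55, p_fail_noise_sd = 0.28,
                           amp_cv_mu = 0.30, stsd = TRUE,
                           latency_ms = 2.5, latency_jitter_ms = 0.3,
                           stsd_tau_ms = 60, seed = NULL) {
  if (n_synapses < 1) abort("`n_synapses` must be >= 1.")
  seed_if(seed)
  m <- rnorm(n_synapses, mean_amp_mu, mean_amp_sd)
  m <- pmin(pmax(m, mean_amp_mu - 2.5 * mean_amp_sd, 0.15),
            mean_amp_mu + 3 * mean_amp_sd)
  z <- (m - mean_amp_mu) / mean_amp_sd
  p_fail <- plogis(qlogis(p_fail_center) - coupling * z +
                     rnorm(n_synapses, 0, p_fail_noise_sd))
  p_fail <- pmin(pmax(p_fail, 0.02), 0.85)
  amp_cv <- pmin(pmax(amp_cv_mu - 0.10 * z + rnorm(n_synapses, 0, 0.06),
                      0.08), 0.60)
  if (stsd) {
    u <- runif(n_synapses)
    depress <- dplyr::case_when(
      u < 0.50 ~ pmin(pmax(rnorm(n_synapses, 0.45, 0.15), 0.15), 0.70),
      u < 0.58 ~ -runif(n_synapses, 0.15, 0.35),
      TRUE ~ 0
    )
  } else {
    depress <- rep(0, n_synapses)
  }
  tibble::tibble(
    synapse_id = seq_len(n_synapses),
    mean_amp = m,
    amp_cv = amp_cv,
    p_fail = p_fail,
    latency_ms = pmin(pmax(rnorm(n_synapses, latency_ms, 0.4), 1.2), 4.2),
    latency_jitter_ms = latency_jitter_ms,
    stsd_depress = depress,
    stsd_tau_ms = stsd_tau_ms
  )
}

#' Membrane-noise settings for synthetic recordings
#'
#' The synthetic Vm noise is the sum of (a) white Gaussian sampling noise,
#' (b) an Ornstein-Uhlenbeck process emulating ongoing synaptic bombardment,
#' and (c) a slow stimulus-locked modulation. Defaults are calibrated so the
#' detector's jittered-trace noise threshold lands near 0.2 mV, the scale
#' reported for in vivo L4 recordings.
#'
#' @param white_sd White-noise SD, mV.
#' @param ou_sd Stationary SD of the OU component, mV.
#' @param ou_tau_ms OU correlation time, ms.
#' @param slow_amp Amplitude of the slow stimulus-locked modulation, mV.
#' @param slow_freq_hz Frequency used for the modulation when no stimulus is
#'   supplied.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(white_sd = 0.05, ou_sd = 0.25, ou_tau_ms = 10,
                         slow_amp = 0.3, slow_freq_hz = 2.5) {
  structure(
    list(white_sd = white_sd, ou_sd = ou_sd, ou_tau_ms = ou_tau_ms,
         slow_amp = slow_amp, slow_freq_hz = slow_freq_hz),
    class = "noise_params"
  )
}

# unit-peak double-exponential kernel sampled at fs, truncated at 10 decay taus
epsp_kernel <- function(tau_rise_ms, tau_decay_ms, fs) {
  if (tau_decay_ms <= 0 || tau_rise_ms < 0) abort("EPSP taus must be positive.")
  t <- seq(0, 10 * tau_decay_ms, by = 1000 / fs)
  k <- exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms)
  k[!is.finite(k)] <- 0
  k / max(k)
}

ou_noise <- function(n, sd, tau_ms, fs) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1000 / (fs * tau_ms))
  innov_sd <- sd * sqrt(1 - a^2)
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), a, method = "recursive"))
}

#' Synthesize a ground-truth-labeled intracellular recording
#'
#' Builds a somatic Vm trace from presynaptic spike trains: each spike of cell
#' `i` is transmitted with probability `1 - p_fail[i]`; transmitted spikes add
#' a double-exponential EPSP whose amplitude is drawn from a zero-truncated
#' log-normal with the synapse's mean and CV, scaled by short-term plasticity
#' `1 - stsd_depress * exp(-ISI/stsd_tau)`, at `latency_ms` (+ per-spike
#' jitter) after the spike. Failed spikes add nothing. Noise per
#' [noise_params()] and optional IPSP-like negative deflections are added on
#' top of the resting potential, and a per-spike ground-truth table is
#' returned for validating the downstream detector.
#'
#' @param spike_trains Tibble `cell_id`, `spike_time_s` (one train per
#'   synapse).
#' @param synapses Tibble from [synapse_cohort()], one row per `cell_id`
#'   present in `spike_trains` (matched by position of sorted unique ids).
#' @param duration_s Trace length; defaults to last spike + 0.1 s.
#' @param fs Sampling rate, Hz (>= 1000; the detector needs sub-ms
#'   resolution).
#' @param rest_vm Resting potential, mV.
#' @param noise A [noise_params()] object.
#' @param epsp_tau_rise_ms,epsp_tau_decay_ms EPSP kernel time constants, ms.
#' @param ipsp_rate_hz Poisson rate of contaminating IPSP-like events (0
#'   disables them).
#' @param ipsp_amp_mv Mean IPSP amplitude (mV, applied negative).
#' @param vm_dependence If `TRUE`, scale each transmitted amplitude by the
#'   instantaneous driving force `(e_syn - Vm_slow)/(e_syn - rest_vm)`.
#' @param e_syn Synaptic reversal potential for the driving-force option, mV.
#' @param stimulus Optional [wn_stimulus()] used to phase-lock the slow
#'   modulation to block onsets.
#' @param seed Optional integer seed.
#'
#' @return An object of class `synthetic_recording`: list with `vm` (mV),
#'   `fs`, `rest_vm`, `spikes` (the input trains), `truth` (tibble `cell_id`,
#'   `spike_time_s`, `isi_prev_ms`, `transmitted`, `amplitude_mv`,
#'   `latency_ms`), `noise`, `duration_s`.
#' @export
synthesize_recording <- function(spike_trains, synapses, duration_s = NULL,
                                 fs = 10000, rest_vm = -65,
                                 noise = noise_params(),
                                 epsp_tau_rise_ms = 0.5, epsp_tau_decay_ms = 4,
                                 ipsp_rate_hz = 0, ipsp_amp_mv = 0.4,
                                 vm_dependence = FALSE, e_syn = 0,
                                 stimulus = NULL, seed = NULL) {
  if (fs < 1000) abort("`fs` below 1 kHz: the EPSP detector needs sub-ms resolution.")
  seed_if(seed)
  spike_trains <- dplyr::arrange(spike_trains, .data$cell_id, .data$spike_time_s)
  ids <- sort(unique(spike_trains$cell_id))
  if (nrow(synapses) < length(ids)) {
    abort("need one synapse row per presynaptic cell in `spike_trains`.")
  }
  syn <- synapses[seq_along(ids), ]
  syn$cell_id <- ids
  if (is.null(duration_s)) {
    duration_s <- if (nrow(spike_trains)) max(spike_trains$spike_time_s) + 0.1 else 1
  }
  n <- round(duration_s * fs) + 1L

  truth <- spike_trains %>%
    dplyr::inner_join(syn, by = "cell_id") %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::mutate(isi_prev_ms = c(NA_real_, diff(.data$spike_time_s)) * 1000) %>%
    dplyr::ungroup()

  ns <- nrow(truth)
  if (ns) {
    sdlog <- sqrt(log(1 + truth$amp_cv^2))
    meanlog <- log(truth$mean_amp) - sdlog^2 / 2
    amp <- rlnorm(ns, meanlog, sdlog)
    stp <- ifelse(
      is.na(truth$isi_prev_ms), 1,
      1 - truth$stsd_depress * exp(-truth$isi_prev_ms / truth$stsd_tau_ms)
    )
    amp <- pmax(amp * stp, 0)
    transmitted <- runif(ns) >= truth$p_fail
    lat <- truth$latency_ms + rnorm(ns, 0, truth$latency_jitter_ms)
  } else {
    amp <- numeric(0); transmitted <- logical(0); lat <- numeric(0)
  }

  # slow stimulus-locked modulation + OU + white noise
  tt <- (seq_len(n) - 1) / fs
  slow <- if (noise$slow_amp > 0) {
    if (!is.null(stimulus)) {
      lum <- apply(stimulus$frames, 1, mean)
      fi <- frame_index_at(stimulus, tt)
      s <- ifelse(is.na(fi), 0, lum[pmax(fi, 1)])
      # low-pass the frame luminance (50 ms) into a slow Vm modulation
      a <- exp(-1000 / (fs * 50))
      s <- as.numeric(stats::filter(s, a, method = "recursive")) * (1 - a)
      if (sd(s) > 0) s <- s / sd(s)
      noise$slow_amp * s
    } else {
      noise$slow_amp * sin(2 * pi * noise$slow_freq_hz * tt + runif(1, 0, 2 * pi))
    }
  } else numeric(n)

  vm_noise <- slow + ou_noise(n, noise$ou_sd, noise$ou_tau_ms, fs)
  if (noise$white_sd > 0) vm_noise <- vm_noise + rnorm(n, 0, noise$white_sd)

  if (vm_dependence && ns) {
    idx0 <- pmin(pmax(round(truth$spike_time_s * fs) + 1L, 1L), n)
    scale <- (e_syn - (rest_vm + slow[idx0])) / (e_syn - rest_vm)
    amp <- amp * pmax(scale, 0)
  }

  kernel <- epsp_kernel(epsp_tau_rise_ms, epsp_tau_decay_ms, fs)
  ev_amp <- ifelse(transmitted, amp, 0)
  idx <- round((truth$spike_time_s + lat / 1000) * fs) + 1L
  vm <- rest_vm + vm_noise +
    deposit_events_cpp(n, as.integer(idx), ev_amp, kernel)

  if (ipsp_rate_hz > 0) {
    n_ipsp <- stats::rpois(1, ipsp_rate_hz * duration_s)
    if (n_ipsp > 0) {
      it <- runif(n_ipsp, 0, duration_s)
      ia <- -pmax(rnorm(n_ipsp, ipsp_amp_mv, ipsp_amp_mv / 3), 0)
      ik <- epsp_kernel(1, 10, fs)
      vm <- vm + deposit_events_cpp(n, as.integer(round(it * fs) + 1L), ia, ik)
    }
  }

  truth_out <- tibble::tibble(
    cell_id = truth$cell_id,
    spike_time_s = truth$spike_time_s,
    isi_prev_ms = truth$isi_prev_ms,
    transmitted = transmitted,
    amplitude_mv = ifelse(transmitted, amp, NA_real_),
    latency_ms = ifelse(transmitted, lat, NA_real_)
  )

  structure(
    list(vm = vm, fs = fs, rest_vm = rest_vm, spikes = spike_trains,
         truth = truth_out, synapses = syn, noise = noise,
         duration_s = duration_s),
    class = "synthetic_recording"
  )
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %.3g s at %g Hz, %d presynaptic cells, %d spikes (%d transmitted)\n",
    x$duration_s, x$fs, length(unique(x$spikes$cell_id)), nrow(x$truth),
    sum(x$truth$transmitted)
  ))
  invisible(x)
}

#' @export
tidy.synthetic_recording <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$vm) - 1) / x$fs,
    vm = x$vm
  )
}
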