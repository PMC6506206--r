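#' Unit-peak excitatory postsynaptic conductance kernel
#'
#' Difference-of-exponentials EPSG waveform, `exp(-t/tau_decay) -
#' exp(-t/tau_rise)`, normalized to unit peak and truncated at
#' `10 * tau_decay`. With the default 0.5 / 2 ms time constants the kernel
#' peaks at `log(tau_d/tau_r) * tau_r * tau_d / (tau_d - tau_r)` ~ 0.462 ms;
#' the membrane then smooths it into an EPSP with in vivo-like kinetics.
#'
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants, ms
#'   (`tau_rise < tau_decay`).
#' @param dt_ms Sample step, ms.
#' @return An object of class `epsg_kernel`: `samples` (unit peak),
#'   `time_ms`, `peak_ms`, the taus and `dt_ms`.
#' @export
epsg_kernel <- function(tau_rise_ms = 0.5, tau_decay_ms = 2, dt_ms = 0.1) {
  if (tau_decay_ms <= 0 || tau_rise_ms < 0) abort("kernel taus must be positive.")
  if (tau_rise_ms >= tau_decay_ms) abort("`tau_rise_ms` must be < `tau_decay_ms`.")
  t <- seq(0, 10 * tau_decay_ms, by = dt_ms)
  k <- exp(-t / tau_decay_ms) -
    if (tau_rise_ms > 0) exp(-t / tau_rise_ms) else c(1, numeric(length(t) - 1))
  k <- k / max(k)
  peak_ms <- if (tau_rise_ms > 0) {
    log(tau_decay_ms / tau_rise_ms) * tau_rise_ms * tau_decay_ms /
      (tau_decay_ms - tau_rise_ms)
  } else 0
  structure(
    list(samples = k, time_ms = t, peak_ms = peak_ms,
         tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
         dt_ms = dt_ms),
    class = "epsg_kernel"
  )
}

#' Leaky integrate-and-fire membrane parameters
#'
#' Defaults describe a layer-4 regular-spiking simple cell: rest -65 mV,
#' threshold -55 mV, reset -60 mV, 2 ms refractory period, input resistance
#' 47 MOhm, membrane time constant 6 ms, integrated by forward Euler at
#' 0.1 ms. Conductance drives current as `g * (e_exc - Vm)` with an AMPA-like
#' 0 mV reversal.
#'
#' @param v_rest,v_thresh,v_reset Membrane potentials, mV.
#' @param refractory_ms Absolute refractory period, ms.
#' @param r_m_mohm Input resistance, MOhm.
#' @param tau_m_ms Membrane time constant, ms.
#' @param dt_ms Integration step, ms (<= 0.1).
#' @param e_exc,e_inh Excitatory / inhibitory reversal potentials, mV.
#' @param duration_s Simulated duration, seconds.
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(v_rest = -65, v_thresh = -55, v_reset = -60,
                       refractory_ms = 2, r_m_mohm = 47, tau_m_ms = 6,
                       dt_ms = 0.1, e_exc = 0, e_inh = -75, duration_s = 89) {
  if (v_reset >= v_thresh) abort("`v_reset` must be below `v_thresh`.")
  if (dt_ms > 0.1) abort("`dt_ms` must be <= 0.1 ms.")
  structure(
    list(v_rest = v_rest, v_thresh = v_thresh, v_reset = v_reset,
         refractory_ms = refractory_ms, r_m_mohm = r_m_mohm,
         tau_m_ms = tau_m_ms, dt_ms = dt_ms, e_exc = e_exc, e_inh = e_inh,
         duration_s = duration_s),
    class = "lif_params"
  )
}

#' Draw synaptic property triplets for the model's thalamic inputs
#'
#' Each input synapse gets a jointly drawn triplet (mean EPSG amplitude,
#' event-amplitude CV, failure probability) with the empirical monotone
#' coupling: larger synapses fail less and vary less. Triplets are never
#' mixed across synapses. In parametric mode amplitudes are specified in nS
#' directly and the cohort is normalized so the mean EPSG across inputs hits
#' `mean_epsg_ns` (0.89 nS by default). With `source = "table"` the triplets
#' come from a user-supplied table of measured values (mV amplitudes times an
#' opaque dataset calibration factor); rows are randomly permuted across
#' synapses.
#'
#' @param n_inputs Number of thalamic inputs, 1..50.
#' @param source `"parametric"` or `"table"`.
#' @param table For `source = "table"`: a data frame with columns `mean_epsg`,
#'   `amp_cv`, `p_fail`.
#' @param mean_epsg_ns Target mean EPSG over the cohort, nS.
#' @param normalize_mean Rescale drawn means so the cohort mean is exactly
#'   `mean_epsg_ns`.
#' @param stsd Include short-term-depression parameters in the specs.
#' @param seed Optional integer seed.
#' @return Tibble `synapse_id`, `mean_epsg`, `amp_cv`, `p_fail`,
#'   `stsd_depress`, `stsd_tau_ms`.
#' @export
assign_synapses <- function(n_inputs = 50, source = c("parametric", "table"),
                            table = NULL, mean_epsg_ns = 0.89,
                            normalize_mean = TRUE, stsd = FALSE, seed = NULL) {
  source <- match.arg(source)
  if (n_inputs < 1 || n_inputs > 50) abort("`n_inputs` must be in 1..50.")
  seed_if(seed)
  if (source == "table") {
    if (is.null(table)) {
      abort(paste(
        "source = \"table\" needs a triplet table; the measured per-pair",
        "triplets ship with the archived dataset",
        "(http://dx.doi.org/10.5061/dryad.57pv818)."
      ))
    }
    idx <- if (nrow(table) >= n_inputs) {
      sample.int(nrow(table), n_inputs)
    } else {
      sample.int(nrow(table), n_inputs, replace = TRUE)
    }
    tb <- tibble::as_tibble(table[idx, c("mean_epsg", "amp_cv", "p_fail")])
    tb$stsd_depress <- if (stsd) rep_len(table$stsd_depress %||% 0.3, n_inputs) else 0
    tb$stsd_tau_ms <- 60
    return(dplyr::mutate(tb, synapse_id = dplyr::row_number(),
                         .before = "mean_epsg"))
  }
  coh <- synapse_cohort(n_inputs, mean_amp_mu = mean_epsg_ns,
                        mean_amp_sd = 0.24, stsd = stsd)
  m <- coh$mean_amp
  if (normalize_mean) m <- m * mean_epsg_ns / mean(m)
  # the model injects the raw measured single-spike amplitude variability
  # (broad, CV ~0.85), not the narrow noise-corrected event CV; larger
  # synapses vary (and fail) less
  amp_cv <- pmin(pmax(0.85 - 0.4 * (m - mean_epsg_ns) +
                        rnorm(n_inputs, 0, 0.08), 0.4), 1.2)
  tibble::tibble(
    synapse_id = seq_len(n_inputs),
    mean_epsg = m,
    amp_cv = amp_cv,
    p_fail = coh$p_fail,
    stsd_depress = coh$stsd_depress,
    stsd_tau_ms = coh$stsd_tau_ms
  )
}

#' Calibrate reliable synapses to match the unreliable model's drive
#'
#' Builds the reliable counterpart of a set of unreliable synapse specs.
#' In `"equal_drive"` mode (default) each reliable synapse delivers a
#' constant EPSG equal to the unreliable synapse's event mean times
#' `(1 - p_fail)`, so the expected total injected conductance matches; in
#' `"event_mean"` mode the constant amplitude equals the event mean itself.
#'
#' @param specs An [assign_synapses()] tibble (unreliable).
#' @param mode `"equal_drive"` or `"event_mean"`.
#' @return Specs with `p_fail = 0`, `amp_cv = 0` and adjusted `mean_epsg`.
#' @export
calibrate_equal_drive <- function(specs, mode = c("equal_drive", "event_mean")) {
  mode <- match.arg(mode)
  out <- specs
  if (mode == "equal_drive") out$mean_epsg <- specs$mean_epsg * (1 - specs$p_fail)
  out$p_fail <- 0
  out$amp_cv <- 0
  out
}

#' Designate presynaptic spikes as synaptic failures
#'
#' Random mode draws i.i.d. Bernoulli(`p_fail`) failures. Correlated mode
#' makes a spike more likely to fail when at least one spike from another
#' input occurs within `coincidence_ms`, boosting the coincident failure
#' probability by `boost` and rescaling the non-coincident probability so the
#' marginal failure rate still equals `p_fail`.
#'
#' @param spike_times Spike times of this input, seconds.
#' @param p_fail Marginal failure probability in `[0, 1)`.
#' @param mode `"random"` or `"correlated"`.
#' @param other_spikes Pooled spike times of the other inputs (required for
#'   correlated mode).
#' @param coincidence_ms Coincidence window, ms.
#' @param boost Multiplier on `p_fail` for coincident spikes (capped at
#'   0.95).
#' @param seed Optional integer seed.
#' @return Logical vector, `TRUE` = failed spike.
#' @export
apply_failures <- function(spike_times, p_fail, mode = c("random", "correlated"),
                           other_spikes = NULL, coincidence_ms = 5, boost = 2,
                           seed = NULL) {
  mode <- match.arg(mode)
  seed_if(seed)
  n <- length(spike_times)
  if (p_fail <= 0) return(rep(FALSE, n))
  if (mode == "random") return(runif(n) < p_fail)
  if (is.null(other_spikes)) abort("correlated mode needs `other_spikes`.")
  os <- sort(other_spikes)
  w <- coincidence_ms / 1000
  lo <- findInterval(spike_times - w, os)
  hi <- findInterval(spike_times + w, os)
  coincident <- hi > lo
  q <- mean(coincident)
  # cap the boosted probability so the marginal failure rate is preserved
  # exactly; when nearly every spike is coincident the boost degrades
  # gracefully toward the uncorrelated model
  p_c <- min(boost * p_fail, 0.95, if (q > 0) p_fail / q else Inf)
  p_nc <- if (q < 1) max((p_fail - q * p_c) / (1 - q), 0) else p_fail
  p <- ifelse(coincident, p_c, p_nc)
  runif(n) < p
}

#' Simulate the conductance-driven LIF V1 cell
#'
#' Converts each (non-failed) presynaptic spike into an EPSG kernel scaled by
#' its drawn amplitude, sums conductances over inputs, and integrates the
#' membrane with forward Euler: `tau_m dV/dt = (v_rest - V) + R g_e (e_exc -
#' V) [+ R g_i (e_inh - V)]`, threshold/reset spiking with an absolute
#' refractory period. Synapse modes: `"reliable"` (every spike transmits at
#' constant amplitude), `"unreliable"` (Bernoulli failures, log-normal
#' amplitude variability), `"unreliable_const_amp"` (failures but constant
#' amplitude), `"correlated_failure"` (failures clustered on coincident
#' presynaptic spikes).
#'
#' @param spike_trains Tibble `cell_id`, `spike_time_s`.
#' @param synapses [assign_synapses()] specs; matched to cells by random
#'   assignment (one spec per presynaptic cell, permuted under `seed`).
#' @param params A [lif_params()] list.
#' @param mode Synapse mode, see Details.
#' @param kernel An [epsg_kernel()]; rebuilt at `params$dt_ms` when NULL.
#' @param stsd Apply each spec's short-term depression to event amplitudes.
#' @param background Optional high-conductance background: a list
#'   `list(g_e0, g_i0, sd_e, sd_i, tau_ms)` of balanced
#'   Ornstein-Uhlenbeck excitatory/inhibitory conductances (nS); NULL (the
#'   default) disables it.
#' @param coincidence_ms,boost Correlated-failure parameters.
#' @param keep_g Keep per-synapse conductance traces (memory heavy).
#' @param seed Integer seed controlling assignment, amplitude draws and
#'   failures.
#' @return An object of class `lif_sim`: `vm` (mV), `spike_times_s`,
#'   `rate_hz`, `vm_mean` / `vm_sd` (subthreshold, refractory samples
#'   excluded), `g_total` (nS), `n_inputs`, `mode`, `params`,
#'   `n_presyn_spikes`, `n_failures`, and optionally `g_per_synapse`.
#' @export
simulate_lif <- function(spike_trains, synapses, params = lif_params(),
                         mode = c("unreliable", "reliable",
                                  "unreliable_const_amp", "correlated_failure"),
                         kernel = NULL, stsd = FALSE, background = NULL,
                         coincidence_ms = 5, boost = 2, keep_g = FALSE,
                         seed = NULL) {
  mode <- match.arg(mode)
  seed_if(seed)
  dt <- params$dt_ms
  n <- round(params$duration_s * 1000 / dt) + 1L
  if (is.null(kernel)) kernel <- epsg_kernel(dt_ms = dt)
  ids <- sort(unique(spike_trains$cell_id))
  if (nrow(synapses) < length(ids)) abort("need one synapse spec per input cell.")
  spec <- synapses[sample.int(nrow(synapses))[seq_along(ids)], ]
  spec$cell_id <- ids

  if (mode == "reliable") spec <- calibrate_equal_drive(spec)
  if (mode == "unreliable_const_amp") spec$amp_cv <- 0

  trains <- purrr::map(ids, function(id) {
    sort(spike_trains$spike_time_s[spike_trains$cell_id == id])
  })
  g_total <- numeric(n)
  g_list <- if (keep_g) vector("list", length(ids)) else NULL
  n_fail <- 0L
  n_spk <- 0L
  for (i in seq_along(ids)) {
    st <- trains[[i]]
    if (!length(st)) next
    n_spk <- n_spk + length(st)
    s <- spec[i, ]
    failed <- if (s$p_fail > 0) {
      if (mode == "correlated_failure") {
        others <- unlist(trains[-i], use.names = FALSE)
        apply_failures(st, s$p_fail, "correlated", other_spikes = others,
                       coincidence_ms = coincidence_ms, boost = boost)
      } else {
        apply_failures(st, s$p_fail, "random")
      }
    } else rep(FALSE, length(st))
    n_fail <- n_fail + sum(failed)
    amp <- if (s$amp_cv > 0) {
      sdlog <- sqrt(log(1 + s$amp_cv^2))
      rlnorm(length(st), log(s$mean_epsg) - sdlog^2 / 2, sdlog)
    } else rep(s$mean_epsg, length(st))
    if (stsd && s$stsd_depress != 0) {
      isi_ms <- c(NA_real_, diff(st)) * 1000
      f <- ifelse(is.na(isi_ms), 1,
                  1 - s$stsd_depress * exp(-isi_ms / s$stsd_tau_ms))
      amp <- pmax(amp * f, 0)
    }
    amp[failed] <- 0
    gi <- deposit_events_cpp(n, as.integer(round(st * 1000 / dt) + 1L), amp,
                             kernel$samples)
    if (keep_g) g_list[[i]] <- gi
    g_total <- g_total + gi
  }

  g_inh <- numeric(0)
  if (!is.null(background)) {
    fs_eq <- 1000 / dt
    g_total <- g_total + background$g_e0 +
      ou_noise(n, background$sd_e, background$tau_ms, fs_eq)
    g_inh <- background$g_i0 + ou_noise(n, background$sd_i, background$tau_ms, fs_eq)
    g_total <- pmax(g_total, 0)
    g_inh <- pmax(g_inh, 0)
  }

  res <- lif_integrate_cpp(
    g_total, g_inh, dt, params$v_rest, params$v_thresh, params$v_reset,
    params$refractory_ms, params$r_m_mohm, params$tau_m_ms, params$e_exc,
    params$e_inh
  )
  vm <- res$vm
  if (any(!is.finite(vm))) abort("Vm became non-finite: check parameters.")
  spike_idx <- res$spike_idx
  # exclude spike samples and a post-spike blanking window (the clamped
  # refractory period) from subthreshold statistics
  sub <- rep(TRUE, n)
  if (length(spike_idx)) {
    blank <- round(params$refractory_ms / dt)
    drop <- unique(pmin(rep(spike_idx, each = blank + 1L) + 0:blank, n))
    sub[drop] <- FALSE
  }
  structure(
    list(
      vm = vm, spike_times_s = (spike_idx - 1L) * dt / 1000,
      rate_hz = length(spike_idx) / params$duration_s,
      vm_mean = mean(vm[sub]), vm_sd = sd(vm[sub]),
      g_total = g_total, g_per_synapse = g_list,
      n_inputs = length(ids), mode = mode, params = params,
      n_presyn_spikes = n_spk, n_failures = n_fail, synapses = spec
    ),
    class = "lif_sim"
  )
}

#' @export
print.lif_sim <- function(x, ...) {
  cat(sprintf(
    "<lif_sim> %s, %d inputs, %.3g s: rate %.2f Hz, Vm %.2f +/- %.2f mV\n",
    x$mode, x$n_inputs, x$params$duration_s, x$rate_hz, x$vm_mean, x$vm_sd
  ))
  invisible(x)
}

#' @export
tidy.lif_sim <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$vm) - 1) * x$params$dt_ms / 1000,
    vm = x$vm, g_total = x$g_total
  )
}

#' @export
glance.lif_sim <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n_inputs = x$n_inputs, rate_hz = x$rate_hz,
    vm_mean = x$vm_mean, vm_sd = x$vm_sd,
    n_presyn_spikes = x$n_presyn_spikes, n_failures = x$n_failures,
    pct_failed = 100 * x$n_failures / max(x$n_presyn_spikes, 1L)
  )
}

#' Compare reliable and unreliable synapse models across trials
#'
#' Runs the LIF cell `n_trials` times per mode on the same presynaptic spike
#' trains, each trial with a fresh random assignment of synaptic triplets
#' (and fresh amplitude/failure draws), and collects firing rate and
#' subthreshold Vm statistics.
#'
#' @inheritParams simulate_lif
#' @param modes Synapse modes to run.
#' @param n_trials Trials per mode.
#' @param seed Base seed; trial `t` uses `seed + t` so paired modes share
#'   the assignment stream.
#' @return Tibble `trial`, `mode`, `rate_hz`, `vm_mean`, `vm_sd`,
#'   `pct_failed`.
#' @export
compare_reliability <- function(spike_trains, synapses, params = lif_params(),
                                modes = c("reliable", "unreliable"),
                                n_trials = 10, stsd = FALSE, seed = 1) {
  purrr::map_dfr(seq_len(n_trials), function(tr) {
    purrr::map_dfr(modes, function(md) {
      sim <- simulate_lif(spike_trains, synapses, params, mode = md,
                          stsd = stsd, seed = seed + tr)
      dplyr::mutate(glance(sim), trial = tr, .before = 1)
    })
  })
}

#' Vm statistics and firing rate as a function of the number of inputs
#'
#' For each `n` in `n_list`, draws a random subset of `n` presynaptic cells
#' per trial and simulates each requested synapse mode, returning per-run
#' statistics plus per-`n` means with 95% confidence intervals.
#'
#' @inheritParams compare_reliability
#' @param n_list Numbers of inputs to simulate (>= 2 values).
#' @return A list of tibbles: `runs` (per trial) and `curves` (per `n` and
#'   mode: means with 95% CI half-widths).
#' @export
sweep_inputs <- function(spike_trains, synapses, n_list = c(10, 25, 50),
                         modes = c("reliable", "unreliable"),
                         n_trials = 5, params = lif_params(), seed = 1) {
  if (length(n_list) < 2) abort("`n_list` needs >= 2 values.")
  ids <- sort(unique(spike_trains$cell_id))
  runs <- purrr::map_dfr(n_list, function(nn) {
    purrr::map_dfr(seq_len(n_trials), function(tr) {
      set.seed(seed + 1000 * nn + tr)
      sub_ids <- if (nn >= length(ids)) ids else sample(ids, nn)
      st <- dplyr::filter(spike_trains, .data$cell_id %in% sub_ids)
      purrr::map_dfr(modes, function(md) {
        sim <- simulate_lif(st, synapses, params, mode = md,
                            seed = seed + 1000 * nn + tr)
        dplyr::mutate(glance(sim), n_requested = nn, trial = tr, .before = 1)
      })
    })
  })
  curves <- runs %>%
    dplyr::group_by(.data$n_requested, .data$mode) %>%
    dplyr::summarise(
      dplyr::across(c("rate_hz", "vm_mean", "vm_sd"),
                    list(mean = mean,
                         ci = ~ 1.96 * sd(.x) / sqrt(dplyr::n()))),
      n_trials = dplyr::n(), .groups = "drop"
    )
  list(runs = runs, curves = curves)
}

#' Reverse-correlation receptive field of the model Vm
#'
#' Averages the stimulus contrast at each pixel and lag, weighted by the
#' subthreshold Vm deviation from its mean -- the linear spatiotemporal RF of
#' the model cell. Spike and refractory samples are excluded from the weight.
#'
#' @param sim A [simulate_lif()] result (or a bare numeric Vm at
#'   `1000/params$dt_ms` Hz with `fs` supplied).
#' @param stim The [wn_stimulus()] that drove the presynaptic cells.
#' @param lags_ms Lags (stimulus preceding Vm) to evaluate, ms.
#' @param fs Sampling rate when `sim` is a bare vector.
#' @return A list of class `rf_map`: `rf` array `(lag, y, x)`, `lags_ms`,
#'   `peak_lag_ms` (lag of the strongest-magnitude pixel).
#' @export
reverse_correlation_rf <- function(sim, stim, lags_ms = seq(0, 160, by = 16),
                                   fs = NULL) {
  if (inherits(sim, "lif_sim")) {
    vm <- sim$vm
    fs <- 1000 / sim$params$dt_ms
    dur <- sim$params$duration_s
  } else {
    vm <- sim
    if (is.null(fs)) abort("`fs` is required for a bare Vm vector.")
    dur <- (length(vm) - 1) / fs
  }
  if (abs(dur - stim$duration_s) > 1) abort("stimulus and Vm durations differ.")
  vdev <- vm - mean(vm)
  n_fr <- dim(stim$frames)[1]
  fmat <- matrix(stim$frames, nrow = n_fr)
  frame_n <- round(stim$frame_ms * fs / 1000)
  rf <- array(0, dim = c(length(lags_ms), stim$n_px, stim$n_px))
  for (li in seq_along(lags_ms)) {
    i0 <- round((stim$frame_onset_s + lags_ms[li] / 1000) * fs) + 1L
    ok <- i0 >= 1L & (i0 + frame_n - 1L) <= length(vm)
    if (!any(ok)) next
    offs <- seq_len(frame_n) - 1L
    m <- matrix(vdev[rep(i0[ok], each = frame_n) + offs],
                nrow = sum(ok), byrow = TRUE)
    w <- rowMeans(m)
    rf[li, , ] <- matrix(colMeans(fmat[ok, , drop = FALSE] * w), stim$n_px)
  }
  peak <- which(abs(rf) == max(abs(rf)), arr.ind = TRUE)[1, ]
  structure(
    list(rf = rf, lags_ms = lags_ms, peak_lag_ms = lags_ms[peak[1]],
         n_px = stim$n_px),
    class = "rf_map"
  )
}

#' @export
tidy.rf_map <- function(x, ...) {
  grid <- expand.grid(y = seq_len(x$n_px), x = seq_len(x$n_px),
                      lag_ms = x$lags_ms)
  grid$value <- as.vector(aperm(x$rf, c(2, 3, 1)))
  tibble::as_tibble(grid)
}

#' Closed-form steady-state Vm under constant conductance
#'
#' For a constant excitatory conductance `g` the leak + synapse balance
#' gives `V = (v_rest + R g e_exc) / (1 + R g)` with `R g` dimensionless
#' (`r_m_mohm * g_ns * 1e-3`). Used to verify the integrator.
#'
#' @param g_ns Constant conductance, nS.
#' @param params A [lif_params()].
#' @return Steady-state Vm, mV.
#' @export
lif_steady_state <- function(g_ns, params = lif_params()) {
  rg <- params$r_m_mohm * g_ns * 1e-3
  (params$v_rest + rg * params$e_exc) / (1 + rg)
}
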