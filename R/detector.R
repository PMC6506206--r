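#' Derive the monosynaptic window from a corrected STA
#'
#' Implements the STA half of the single-spike EPSP detector: the derivative
#' of the corrected STA (3-point smoothed) is searched for its positive peak
#' within the 0-6 ms span; the onset `t1` and termination `t2` of the average
#' EPSP are found by marching out from that peak to the first derivative
#' valley or zero-crossing on each side. `[t1, t2]` is the expected
#' monosynaptic window for the pair -- the interval in which a direct EPSP
#' must begin and peak.
#'
#' @param sta_post Corrected STA samples from the spike time onward (t = 0 at
#'   the first sample), or an [sta_connection()] fit.
#' @param fs Sampling rate, Hz (ignored when `sta_post` is an `sta_fit`).
#' @param span_ms Analysis span after the spike, ms.
#' @param smooth_pts Moving-average width for the STA derivative (samples).
#' @return A list of class `monosyn_window`: `t1_ms`, `t2_ms`, `peak_ms`
#'   (time of the steepest rise), plus sample indices `t1_idx`, `t2_idx` into
#'   the post-spike trace. Errors with class `tc_no_peak` when the STA has no
#'   positive derivative peak in the span.
#' @export
monosynaptic_window <- function(sta_post, fs = NULL, span_ms = 6,
                                smooth_pts = 3) {
  if (inherits(sta_post, "sta_fit")) {
    fs <- sta_post$fs
    sta_post <- sta_post$corrected_sta[sta_post$time_ms >= 0]
  }
  if (is.null(fs)) abort("`fs` is required for a bare STA vector.")
  dt_ms <- 1000 / fs
  span_n <- min(round(span_ms / dt_ms), length(sta_post) - 1L)
  d <- diff(sta_post[seq_len(span_n + 1L)])
  if (smooth_pts > 1) {
    ds <- as.numeric(stats::filter(d, rep(1 / smooth_pts, smooth_pts),
                                   sides = 2))
    d <- ifelse(is.na(ds), d, ds)
  }
  peak <- which.max(d)
  if (!is.finite(d[peak]) || d[peak] <= 0 || peak == 1L || peak == length(d)) {
    abort("no positive dVm/dt peak inside the analysis span.",
          class = "tc_no_peak")
  }
  v1 <- march_valley(d, peak, -1L)
  v2 <- march_valley(d, peak, +1L)
  structure(
    list(
      t1_ms = (v1 - 1L) * dt_ms,
      t2_ms = v2 * dt_ms,
      peak_ms = (peak - 0.5) * dt_ms,
      t1_idx = v1,
      t2_idx = v2 + 1L
    ),
    class = "monosyn_window"
  )
}

#' @export
print.monosyn_window <- function(x, ...) {
  cat(sprintf("<monosyn_window> t1 = %.2f ms, t2 = %.2f ms (dVm/dt peak %.2f ms)\n",
              x$t1_ms, x$t2_ms, x$peak_ms))
  invisible(x)
}

# march from a derivative peak toward `dir` to the valley flanking the rise:
# the last sample of the contiguous positive-derivative run (the derivative
# zero-crossing marks the Vm extremum bounding the EPSP rise)
march_valley <- function(d, peak, dir) {
  v <- peak
  repeat {
    nxt <- v + dir
    if (nxt < 1L || nxt > length(d)) break
    if (d[nxt] <= 0) break
    v <- nxt
  }
  v
}

#' Amplitudes of jittered single-spike traces
#'
#' Draws surrogate traces by displacing real spike times with a uniform
#' 0..`jitter_ms` jitter, zeroes each at its (jittered) spike time, and
#' measures the mean Vm deviation across the pair's monosynaptic window --
#' the same amplitude definition used for undetectable EPSPs. These
#' alignment-free amplitudes characterize intrinsic Vm fluctuations.
#'
#' @param rec A [paired_recording()].
#' @param window A [monosynaptic_window()].
#' @param n_traces Number of surrogate traces (>= 100 recommended).
#' @param jitter_ms Jitter range, ms.
#' @param span_ms Post-spike span, ms.
#' @param seed Optional integer seed.
#' @return Numeric vector of amplitudes (mV).
#' @export
jittered_trace_amplitudes <- function(rec, window, n_traces = 200,
                                      jitter_ms = rec$frame_ms, span_ms = 6,
                                      seed = NULL) {
  seed_if(seed)
  sp <- rep_len(rec$spikes, n_traces) + runif(n_traces, 0, jitter_ms / 1000)
  m <- segment_matrix(rec$vm, rec$fs, sp, span_ms, center = FALSE)
  m <- m - m[, 1]
  rowMeans(m[, window$t1_idx:window$t2_idx, drop = FALSE])
}

#' Detection threshold from jittered-trace amplitudes
#'
#' The per-pair amplitude threshold of the EPSP detector: 1 SD above the mean
#' of the jittered spike-triggered Vm amplitudes.
#'
#' @param jittered_amps Amplitudes from [jittered_trace_amplitudes()].
#' @return Threshold in mV.
#' @export
detection_threshold <- function(jittered_amps) {
  if (length(jittered_amps) < 100) {
    warn("fewer than 100 jittered traces: threshold estimate is noisy.")
  }
  s <- sd(jittered_amps)
  if (!is.finite(s) || s == 0) {
    warn("zero-variance jittered amplitudes: threshold equals their mean.")
    s <- 0
  }
  mean(jittered_amps) + s
}

# detector core for one zeroed trial (numeric vector from t = 0, length
# span_n + 1). Returns label/amplitude/refined window.
detect_one <- function(trial, fs, window, threshold, sd_d, prom_sd) {
  dt_ms <- 1000 / fs
  d <- diff(trial)
  win_lo <- max(window$t1_idx, 1L)
  win_hi <- min(window$t2_idx - 1L, length(d))
  undet_amp <- mean(trial[window$t1_idx:window$t2_idx])
  fail <- function() list(
    label = "undetectable", amplitude_mv = undet_amp, t1p_ms = NA_real_,
    t2p_ms = NA_real_, peak_slope = NA_real_
  )
  if (win_hi < win_lo) return(fail())
  rel <- which.max(d[win_lo:win_hi])
  peak <- win_lo + rel - 1L
  if (!is.finite(d[peak]) || d[peak] <= 0) return(fail())
  if (peak == 1L || peak == length(d)) return(fail()) # peak at span edge
  v1 <- march_valley(d, peak, -1L)
  v2 <- march_valley(d, peak, +1L)
  # prominence against the first samples beyond the positive-slope run
  flank_lo <- if (v1 > 1L) d[v1 - 1L] else 0
  flank_hi <- if (v2 < length(d)) d[v2 + 1L] else 0
  prominence <- d[peak] - max(flank_lo, flank_hi, 0)
  if (prominence < prom_sd * sd_d) return(fail())
  amp <- trial[v2 + 1L] - trial[v1]
  if (amp < threshold) return(fail())
  list(
    label = "detectable", amplitude_mv = amp, t1p_ms = (v1 - 1L) * dt_ms,
    t2p_ms = v2 * dt_ms, peak_slope = d[peak] / dt_ms
  )
}

#' Label every single-spike trace as a detectable or undetectable EPSP
#'
#' Applies the automated binary detector to the 0-6 ms Vm trace following
#' each presynaptic spike: the trace is zeroed at the spike time, its
#' derivative is searched for a peak inside the pair's monosynaptic window,
#' the onset/end are refined per trace (`t1'`, `t2'`), and the amplitude
#' `Vm(t2') - Vm(t1')` must reach the jittered-trace threshold for the trace
#' to count as detectable. Traces without a usable peak, or below threshold,
#' are undetectable and their amplitude is the mean Vm deviation across the
#' monosynaptic window. Detection itself is deterministic; randomness enters
#' only through the jittered threshold (seeded).
#'
#' @param rec A [paired_recording()].
#' @param fit Optional [sta_connection()] fit; supplies the monosynaptic
#'   window when `window` is NULL.
#' @param window A [monosynaptic_window()]; derived from `fit` (or from the
#'   pair's corrected STA) when NULL.
#' @param threshold Detection threshold, mV; computed from
#'   `n_jitter_traces` jittered traces when NULL.
#' @param span_ms Post-spike analysis span, ms.
#' @param n_jitter_traces Surrogate traces for the threshold.
#' @param jitter_ms Jitter range, ms.
#' @param prom_sd Minimum derivative-peak prominence, in units of the
#'   trace-derivative noise SD.
#' @param smooth_trial Smooth each trial with the same 3-point average used
#'   for the STA derivative before differentiating (default `TRUE`; at 10 kHz
#'   the raw sample-to-sample derivative is dominated by recording noise).
#' @param seed Seed for the jittered threshold.
#' @return A tibble with one row per usable spike: `spike_time_s`,
#'   `isi_prev_ms`, `label`, `amplitude_mv`, `t1p_ms`, `t2p_ms`,
#'   `peak_slope`. The window, threshold and jittered amplitudes are attached
#'   as attributes `window`, `threshold`, `jittered_amps`.
#' @export
detect_epsps <- function(rec, fit = NULL, window = NULL, threshold = NULL,
                         span_ms = 6, n_jitter_traces = 200,
                         jitter_ms = rec$frame_ms, prom_sd = 1,
                         smooth_trial = TRUE, seed = NULL) {
  seed_if(seed)
  if (is.null(window)) {
    if (!is.null(fit)) {
      window <- fit$window %||% monosynaptic_window(fit, span_ms = span_ms)
    } else {
      raw <- compute_sta(rec)
      jit <- compute_jittered_sta(rec, jitter_ms = jitter_ms)
      post <- (raw - jit)[attr(raw, "time_ms") >= 0]
      window <- monosynaptic_window(post, rec$fs, span_ms = span_ms)
    }
  }
  jittered_amps <- NULL
  if (is.null(threshold)) {
    jittered_amps <- jittered_trace_amplitudes(
      rec, window, n_traces = n_jitter_traces, jitter_ms = jitter_ms,
      span_ms = span_ms
    )
    threshold <- detection_threshold(jittered_amps)
  }

  m <- segment_matrix(rec$vm, rec$fs, rec$spikes, span_ms, center = FALSE)
  if (anyNA(m)) abort("NaN/NA in single-spike traces.")
  used <- round(rec$spikes * rec$fs) + 1L + round(span_ms * rec$fs / 1000) <=
    length(rec$vm) & round(rec$spikes * rec$fs) >= 0
  spikes <- rec$spikes[used]
  m <- m - m[, 1]
  if (smooth_trial) {
    m <- t(apply(m, 1, function(x) {
      s <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
      ifelse(is.na(s), x, s)
    }))
  }
  sd_d <- stats::mad(diff(rec$vm))
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    detect_one(m[i, ], rec$fs, window, threshold, sd_d, prom_sd)
  })
  out <- tibble::tibble(
    spike_time_s = spikes,
    isi_prev_ms = c(NA_real_, diff(spikes)) * 1000,
    label = purrr::map_chr(res, "label"),
    amplitude_mv = purrr::map_dbl(res, "amplitude_mv"),
    t1p_ms = purrr::map_dbl(res, "t1p_ms"),
    t2p_ms = purrr::map_dbl(res, "t2p_ms"),
    peak_slope = purrr::map_dbl(res, "peak_slope")
  )
  attr(out, "window") <- window
  attr(out, "threshold") <- threshold
  attr(out, "jittered_amps") <- jittered_amps
  attr(out, "pair_id") <- rec$pair_id
  out
}

#' Audit detectable labels for sustained depolarization
#'
#' Flags traces labeled detectable whose refined window lacks a contiguous
#' positive-slope run of at least `min_run_ms` -- the signature of amplitude
#' crossings produced by noise rather than a smooth EPSP rise. With
#' `relabel = TRUE` the flagged traces are reclassified as undetectable (with
#' window-mean amplitude), automating the manual correction of such false
#' positives.
#'
#' @param rec The [paired_recording()] the detections came from.
#' @param detections A [detect_epsps()] tibble.
#' @param min_run_ms Required positive-slope run, ms.
#' @param relabel Apply the correction instead of only flagging.
#' @return `detections` with an added logical `audit_flag` column (and
#'   corrected labels when `relabel = TRUE`).
#' @export
audit_detections <- function(rec, detections, min_run_ms = 0.3,
                             relabel = FALSE) {
  window <- attr(detections, "window")
  span_ms <- 6
  m <- segment_matrix(rec$vm, rec$fs, detections$spike_time_s, span_ms,
                      center = FALSE)
  m <- m - m[, 1]
  need <- max(round(min_run_ms * rec$fs / 1000), 1L)
  flag <- purrr::map_lgl(seq_len(nrow(detections)), function(i) {
    if (detections$label[i] != "detectable") return(FALSE)
    i1 <- max(round(detections$t1p_ms[i] * rec$fs / 1000) + 1L, 1L)
    i2 <- min(round(detections$t2p_ms[i] * rec$fs / 1000) + 1L, ncol(m))
    if (i2 - i1 < 1L) return(TRUE)
    max_run(diff(m[i, i1:i2]) > 0) < need
  })
  out <- dplyr::mutate(detections, audit_flag = flag)
  if (relabel && any(flag)) {
    wm <- rowMeans(m[, window$t1_idx:window$t2_idx, drop = FALSE])
    out$label[flag] <- "undetectable"
    out$amplitude_mv[flag] <- wm[flag]
    out$t1p_ms[flag] <- NA_real_
    out$t2p_ms[flag] <- NA_real_
  }
  attributes(out)[c("window", "threshold", "jittered_amps", "pair_id")] <-
    attributes(detections)[c("window", "threshold", "jittered_amps", "pair_id")]
  out
}
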