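#' Construct a paired LGN-V1 recording
#'
#' Couples one presynaptic spike train with the postsynaptic membrane
#' potential it may influence. Spikes are sorted; spikes whose full analysis
#' window would fall outside the trace are kept here and dropped by the
#' window-based operations.
#'
#' @param vm Membrane potential trace, mV.
#' @param fs Sampling rate, Hz.
#' @param spikes Presynaptic spike times, seconds from trace start.
#' @param pair_id Optional identifier.
#' @param frame_ms Stimulus frame duration (16 or 24 ms); sets the default
#'   jitter range.
#' @return An object of class `paired_recording`.
#' @export
paired_recording <- function(vm, fs, spikes, pair_id = NULL, frame_ms = 16) {
  if (!is.numeric(vm) || !length(vm)) abort("`vm` must be a non-empty numeric trace.")
  if (any(!is.finite(vm))) abort("`vm` contains non-finite samples.")
  if (is.unsorted(spikes)) spikes <- sort(spikes)
  dur <- (length(vm) - 1) / fs
  if (length(spikes) && (min(spikes) < -0.01 || max(spikes) > dur + 0.01)) {
    abort("spike times fall outside the trace extent (beyond a 10 ms margin).")
  }
  structure(
    list(vm = vm, fs = fs, spikes = spikes, pair_id = pair_id,
         frame_ms = frame_ms),
    class = "paired_recording"
  )
}

#' Extract one pair from a synthetic recording
#'
#' @param rec A [synthesize_recording()] result.
#' @param cell_id Which presynaptic cell to pair with the Vm trace.
#' @return A [paired_recording()].
#' @export
extract_pair <- function(rec, cell_id) {
  sp <- rec$spikes$spike_time_s[rec$spikes$cell_id == cell_id]
  if (!length(sp)) abort(sprintf("no spikes for cell_id %s.", cell_id))
  paired_recording(rec$vm, rec$fs, sp, pair_id = cell_id)
}

# matrix of aligned Vm segments (one row per usable spike)
segment_matrix <- function(vm, fs, spikes, window_ms, center = TRUE) {
  w <- round(window_ms * fs / 1000)
  idx0 <- round(spikes * fs) + 1L
  lo <- if (center) -w else 0L
  ok <- idx0 + lo >= 1L & idx0 + w <= length(vm)
  idx0 <- idx0[ok]
  if (!length(idx0)) {
    return(structure(matrix(numeric(0), 0, w - lo + 1L), dropped = sum(!ok)))
  }
  offs <- seq.int(lo, w)
  m <- matrix(vm[rep(idx0, each = length(offs)) + offs],
              nrow = length(idx0), byrow = TRUE)
  structure(m, dropped = sum(!ok))
}

#' Time axis for an STA window
#' @param window_ms Half-window, ms.
#' @param fs Sampling rate, Hz.
#' @return Sample times in ms, `-window_ms` to `window_ms`.
#' @export
sta_time <- function(window_ms, fs) {
  w <- round(window_ms * fs / 1000)
  seq.int(-w, w) * 1000 / fs
}

#' Raw spike-triggered average of membrane potential
#'
#' Arithmetic mean of +/- `window_ms` Vm windows centered on each presynaptic
#' spike. Spikes whose window exceeds the trace are dropped.
#'
#' @param rec A [paired_recording()].
#' @param window_ms Half-window, ms.
#' @return Numeric STA (mV) with attributes `time_ms`, `n_spikes`.
#' @export
compute_sta <- function(rec, window_ms = 10) {
  m <- segment_matrix(rec$vm, rec$fs, rec$spikes, window_ms)
  if (nrow(m) < 2) abort("fewer than 2 usable spikes after margin trimming.")
  structure(colMeans(m), time_ms = sta_time(window_ms, rec$fs),
            n_spikes = nrow(m))
}

# per-spike jitter-averaged segments: row i = mean over draws of the segment
# at spike i displaced by U(0, jitter_ms). Rows align with usable raw spikes.
jittered_segments <- function(rec, window_ms, jitter_ms, n_draws) {
  fs <- rec$fs
  w <- round(window_ms * fs / 1000)
  guard <- jitter_ms / 1000 + w / fs
  ok <- round(rec$spikes * fs) + 1L - w >= 1L &
    round((rec$spikes + guard) * fs) + 1L <= length(rec$vm)
  spikes <- rec$spikes[ok]
  n <- length(spikes)
  acc <- matrix(0, n, 2L * w + 1L)
  for (d in seq_len(n_draws)) {
    sp <- spikes + runif(n, 0, jitter_ms / 1000)
    acc <- acc + segment_matrix(rec$vm, fs, sp, window_ms)
  }
  structure(acc / n_draws, dropped = sum(!ok))
}

#' Jittered spike-triggered average
#'
#' STA recomputed after displacing every spike by an i.i.d. uniform jitter of
#' 0 to `jitter_ms` (the stimulus frame duration), averaged over
#' `n_draws` independent draws. The jitter preserves slow stimulus-locked Vm
#' modulation but destroys sub-frame synaptic alignment, so subtracting it
#' from the raw STA isolates the monosynaptic EPSP.
#'
#' @inheritParams compute_sta
#' @param jitter_ms Jitter range (ms); defaults to the recording's stimulus
#'   frame duration.
#' @param n_draws Number of jitter draws averaged.
#' @param seed Optional integer seed.
#' @return Numeric jittered STA with attributes `time_ms`, `n_spikes`,
#'   `n_dropped` (spikes whose jittered window left the trace).
#' @export
compute_jittered_sta <- function(rec, jitter_ms = rec$frame_ms, n_draws = 100,
                                 seed = NULL) {
  seed_if(seed)
  m <- jittered_segments(rec, 10, jitter_ms, n_draws)
  structure(colMeans(m), time_ms = sta_time(10, rec$fs), n_spikes = nrow(m),
            n_dropped = attr(m, "dropped"))
}

#' Fit a jitter-corrected STA and classify the connection
#'
#' Computes the raw, jittered and jitter-corrected (raw minus jittered) STA,
#' a bootstrap null band for the corrected STA (spike-level resampling with
#' replacement), and the three connection gates: (1) a run of supra-band
#' samples of at least `run_ms` within the 0-6 ms span, (2) EPSP onset
#' latency inside `latency_window_ms`, (3) 10-90% rise time below
#' `max_rise_ms`.
#'
#' @inheritParams compute_jittered_sta
#' @param window_ms STA half-window, ms.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param alpha Band level (0.05 gives 95% limits).
#' @param run_ms Required supra-band run length, ms (10 consecutive samples at
#'   10 kHz).
#' @param latency_window_ms Allowed EPSP onset window, ms after the spike.
#' @param max_rise_ms Maximum 10-90% rise time, ms.
#' @param span_ms Post-spike span searched for the EPSP, ms.
#' @return An object of class `sta_fit`; see [tidy.sta_fit()] and
#'   [glance.sta_fit()].
#' @export
sta_connection <- function(rec, window_ms = 10, jitter_ms = rec$frame_ms,
                           n_draws = 100, n_boot = 1000, alpha = 0.05,
                           run_ms = 1, latency_window_ms = c(1, 4.5),
                           max_rise_ms = 2, span_ms = 6, seed = NULL) {
  seed_if(seed)
  if (n_boot < 100) abort("`n_boot` must be >= 100.")
  fs <- rec$fs
  raw_m <- segment_matrix(rec$vm, fs, rec$spikes, window_ms)
  jit_m <- jittered_segments(rec, window_ms, jitter_ms, n_draws)
  # jittered_segments trims with a stricter guard; re-trim raw rows to match
  if (nrow(jit_m) != nrow(raw_m)) {
    guard <- jitter_ms / 1000 + round(window_ms * fs / 1000) / fs
    w <- round(window_ms * fs / 1000)
    ok <- round(rec$spikes * fs) + 1L - w >= 1L &
      round((rec$spikes + guard) * fs) + 1L <= length(rec$vm)
    raw_m <- segment_matrix(rec$vm, fs, rec$spikes[ok], window_ms)
  }
  n <- nrow(raw_m)
  if (n < 2) abort("fewer than 2 usable spikes after margin trimming.")
  if (n < 10) warn("fewer than 10 spikes: confidence bands will be wide.")
  time_ms <- sta_time(window_ms, fs)
  raw_sta <- colMeans(raw_m)
  jit_sta <- colMeans(jit_m)
  corrected <- raw_sta - jit_sta

  # bootstrap corrected STAs on spike-resampled sets via a count matrix
  D <- raw_m - jit_m
  W <- matrix(0L, n_boot, n)
  for (b in seq_len(n_boot)) {
    W[b, ] <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
  }
  B <- (W %*% D) / n
  dev <- sweep(B, 2, corrected)
  band_lower <- apply(dev, 2, quantile, probs = alpha / 2, names = FALSE)
  band_upper <- apply(dev, 2, quantile, probs = 1 - alpha / 2, names = FALSE)
  sem <- apply(B, 2, sd)

  fit <- structure(
    list(time_ms = time_ms, raw_sta = raw_sta, jittered_sta = jit_sta,
         corrected_sta = corrected, band_lower = band_lower,
         band_upper = band_upper, sem = sem, n_spikes = n,
         n_dropped = attr(jit_m, "dropped"), fs = fs, alpha = alpha,
         n_boot = n_boot, run_ms = run_ms,
         latency_window_ms = latency_window_ms, max_rise_ms = max_rise_ms,
         span_ms = span_ms, pair_id = rec$pair_id),
    class = "sta_fit"
  )
  cls <- classify_connection(fit)
  fit$connected <- cls$connected
  fit$reasons <- cls$reasons
  fit$latency_ms <- cls$latency_ms
  fit$rise_time_10_90_ms <- cls$rise_time_10_90_ms
  fit$peak_amp_mv <- cls$peak_amp_mv
  fit$window <- cls$window
  fit
}

#' Bootstrap confidence band for a jitter-corrected STA
#'
#' Convenience wrapper returning the per-sample 95% (or `1 - alpha`) null
#' band from [sta_connection()].
#'
#' @inheritParams sta_connection
#' @return A tibble `time_ms`, `corrected`, `band_lower`, `band_upper`, `sem`.
#' @export
bootstrap_confidence <- function(rec, n_boot = 1000, alpha = 0.05,
                                 jitter_ms = rec$frame_ms, n_draws = 100,
                                 seed = NULL) {
  fit <- sta_connection(rec, n_boot = n_boot, alpha = alpha,
                        jitter_ms = jitter_ms, n_draws = n_draws, seed = seed)
  tibble::tibble(
    time_ms = fit$time_ms, corrected = fit$corrected_sta,
    band_lower = fit$band_lower, band_upper = fit$band_upper, sem = fit$sem
  )
}

# 10-90% rise time of the corrected STA between onset and peak (ms)
rise_time_10_90 <- function(sta_post, fs, onset_idx, peak_idx) {
  if (peak_idx <= onset_idx) return(NA_real_)
  seg <- sta_post[onset_idx:peak_idx] - sta_post[onset_idx]
  pk <- seg[length(seg)]
  if (pk <= 0) return(NA_real_)
  tt <- (seq_along(seg) - 1) * 1000 / fs
  t10 <- approx(seg, tt, xout = 0.1 * pk, ties = "ordered")$y
  t90 <- approx(seg, tt, xout = 0.9 * pk, ties = "ordered")$y
  t90 - t10
}

#' Apply the three monosynaptic-connection gates to an STA fit
#'
#' A pair is classified as connected when the corrected STA (i) stays above
#' the upper confidence band for a run of at least `run_ms` within the 0-6 ms
#' span, (ii) has an EPSP onset latency inside the monosynaptic window
#' (default 1.0-4.5 ms), and (iii) rises from 10% to 90% of its peak in under
#' `max_rise_ms`.
#'
#' @param fit An [sta_connection()] result (band fields populated).
#' @return A list: `connected`, `reasons` (character, failed gates),
#'   `latency_ms`, `rise_time_10_90_ms`, `peak_amp_mv`, `window`.
#' @export
classify_connection <- function(fit) {
  fs <- fit$fs
  run_needed <- max(round(fit$run_ms * fs / 1000), 1L)
  in_span <- fit$time_ms >= 0 & fit$time_ms <= fit$span_ms
  supra <- fit$corrected_sta > fit$band_upper & in_span
  reasons <- character()
  if (max_run(supra) < run_needed) reasons <- c(reasons, "no supra-band run")

  post <- fit$corrected_sta[fit$time_ms >= 0]
  win <- tryCatch(
    monosynaptic_window(post, fs, span_ms = fit$span_ms),
    tc_no_peak = function(e) NULL
  )
  if (is.null(win)) {
    reasons <- c(reasons, "no positive dVm/dt peak in span")
    latency <- NA_real_
    rise <- NA_real_
    peak_amp <- NA_real_
  } else {
    latency <- win$t1_ms
    onset_idx <- win$t1_idx
    peak_idx <- win$t2_idx
    rise <- rise_time_10_90(post, fs, onset_idx, peak_idx)
    peak_amp <- post[peak_idx] - post[onset_idx]
    if (latency < fit$latency_window_ms[1] || latency > fit$latency_window_ms[2]) {
      reasons <- c(reasons, sprintf(
        "latency outside %.1f-%.1f ms", fit$latency_window_ms[1],
        fit$latency_window_ms[2]
      ))
    }
    if (!is.na(rise) && rise >= fit$max_rise_ms) {
      reasons <- c(reasons, sprintf("rise time >= %g ms", fit$max_rise_ms))
    }
  }
  list(connected = length(reasons) == 0L, reasons = reasons,
       latency_ms = latency, rise_time_10_90_ms = rise,
       peak_amp_mv = peak_amp, window = win)
}

#' @export
print.sta_fit <- function(x, ...) {
  cat(sprintf(
    "<sta_fit> %s, n_spikes = %d; peak %.3g mV, latency %.2f ms, rise %.2f ms\n",
    if (isTRUE(x$connected)) "CONNECTED" else
      paste("not connected:", paste(x$reasons, collapse = "; ")),
    x$n_spikes, x$peak_amp_mv %||% NA, x$latency_ms %||% NA,
    x$rise_time_10_90_ms %||% NA
  ))
  invisible(x)
}

#' Tidy an STA fit into a per-sample tibble
#'
#' @param x An `sta_fit`.
#' @param ... Unused.
#' @return Tibble `time_ms`, `raw`, `jittered`, `corrected`, `band_lower`,
#'   `band_upper`, `sem`.
#' @export
tidy.sta_fit <- function(x, ...) {
  tibble::tibble(
    time_ms = x$time_ms, raw = x$raw_sta, jittered = x$jittered_sta,
    corrected = x$corrected_sta, band_lower = x$band_lower,
    band_upper = x$band_upper, sem = x$sem
  )
}

#' One-row summary of an STA fit
#'
#' @param x An `sta_fit`.
#' @param ... Unused.
#' @return Tibble with `connected`, `peak_amp_mv`, `latency_ms`,
#'   `rise_time_10_90_ms`, `n_spikes`, `n_boot`, `reasons`.
#' @export
glance.sta_fit <- function(x, ...) {
  tibble::tibble(
    pair_id = x$pair_id %||% NA, connected = x$connected,
    peak_amp_mv = x$peak_amp_mv %||% NA_real_,
    latency_ms = x$latency_ms %||% NA_real_,
    rise_time_10_90_ms = x$rise_time_10_90_ms %||% NA_real_,
    n_spikes = x$n_spikes, n_boot = x$n_boot,
    reasons = paste(x$reasons, collapse = "; ")
  )
}
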