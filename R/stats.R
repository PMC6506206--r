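#' Noise-corrected coefficient of variation of single-spike amplitudes
#'
#' `CV = sqrt(|var(all) - var(jittered)|) / mean(all)`: the amplitude CV with
#' the variance of alignment-free Vm fluctuations (jittered-trace amplitudes)
#' subtracted, so that it reflects synaptic variability rather than ongoing
#' membrane noise.
#'
#' @param amps_all Amplitudes of all single-spike traces, mV.
#' @param amps_jittered Amplitudes of jittered (alignment-free) traces, mV.
#' @return The noise-corrected CV (dimensionless, >= 0).
#' @export
#' @examples
#' noise_corrected_cv(c(0, 1, 2), c(-0.6, 0, 0.6)) # sqrt(1 - 0.36) / 1 = 0.8
noise_corrected_cv <- function(amps_all, amps_jittered) {
  if (!length(amps_all) || !length(amps_jittered)) {
    abort("both amplitude samples must be nonempty.")
  }
  mu <- mean(amps_all)
  if (mu == 0) abort("mean amplitude is zero: CV undefined.")
  sqrt(abs(var(amps_all) - var(amps_jittered))) / mu
}

#' Per-pair reliability and variability summary
#'
#' Aggregates a pair's detections into the standard per-connection
#' statistics: category amplitude means, percent undetectable, and
#' noise-corrected CVs computed from all traces and from detectable traces
#' only.
#'
#' @param detections A [detect_epsps()] tibble.
#' @param jittered_amps Jittered-trace amplitudes (defaults to the attribute
#'   stored on `detections`).
#' @param lgn_rate_hz Presynaptic firing rate, Hz (metadata).
#' @param cell_class `"RS"` or `"FS"` postsynaptic class (input label, never
#'   inferred).
#' @param pair_id Optional identifier.
#' @return A one-row tibble: `pair_id`, `n_spikes`, `pct_undetectable`,
#'   `avg_amp_all`, `avg_amp_detectable`, `avg_amp_undetectable`,
#'   `sd_amp_all`, `cv_all`, `cv_detectable`, `lgn_rate_hz`, `cell_class`.
#'   `cv_detectable` is `NA` (with a warning) when no detectable events
#'   exist.
#' @export
summarize_pair <- function(detections, jittered_amps = NULL,
                           lgn_rate_hz = NA_real_, cell_class = NA_character_,
                           pair_id = NULL) {
  jittered_amps <- jittered_amps %||% attr(detections, "jittered_amps")
  if (is.null(jittered_amps)) {
    abort("`jittered_amps` not supplied and not stored on `detections`.")
  }
  pair_id <- pair_id %||% attr(detections, "pair_id") %||% NA
  det <- detections$amplitude_mv[detections$label == "detectable"]
  und <- detections$amplitude_mv[detections$label == "undetectable"]
  all_amp <- detections$amplitude_mv
  cv_det <- if (length(det) >= 2) {
    noise_corrected_cv(det, jittered_amps)
  } else {
    warn("no (or a single) detectable event: cv_detectable undefined.")
    NA_real_
  }
  tibble::tibble(
    pair_id = pair_id,
    n_spikes = nrow(detections),
    pct_undetectable = 100 * length(und) / nrow(detections),
    avg_amp_all = mean(all_amp),
    avg_amp_detectable = if (length(det)) mean(det) else NA_real_,
    avg_amp_undetectable = if (length(und)) mean(und) else NA_real_,
    sd_amp_all = sd(all_amp),
    cv_all = noise_corrected_cv(all_amp, jittered_amps),
    cv_detectable = cv_det,
    noise_threshold_mv = attr(detections, "threshold") %||% NA_real_,
    lgn_rate_hz = lgn_rate_hz,
    cell_class = cell_class
  )
}

#' Short-term synaptic plasticity analysis for one pair
#'
#' Splits single-spike trace amplitudes (all spikes, detectable or not) by
#' the preceding presynaptic interspike interval at `isi_split_ms` (short
#' 0-50 ms vs long > 50 ms by default, roughly the median ISI), quantifies
#' plasticity as `%change = (short - long)/long * 100`, and tests (a) the
#' short- vs long-ISI amplitude distributions and (b) the ISI distributions
#' of detectable vs undetectable traces, each with a two-sample KS test
#' (primary) and a t-test. Negative significant %change is short-term
#' depression (STSD), positive facilitation (STSF).
#'
#' @param detections A [detect_epsps()] tibble.
#' @param isi_split_ms Short/long ISI boundary, ms.
#' @param alpha Significance level for the classification.
#' @param min_n Minimum spikes per ISI class before the pair is flagged
#'   under-powered.
#' @return One-row tibble: `n_short`, `n_long`, `amp_short`, `amp_long`,
#'   `pct_change`, `p_amp_ks`, `p_amp_t`, `p_isi_by_label_ks`,
#'   `p_isi_by_label_t`, `classification` (`"STSD"`, `"STSF"` or `"none"`),
#'   `underpowered`.
#' @export
stsp_analysis <- function(detections, isi_split_ms = 50, alpha = 0.05,
                          min_n = 20) {
  d <- dplyr::filter(detections, !is.na(.data$isi_prev_ms))
  short <- d$amplitude_mv[d$isi_prev_ms <= isi_split_ms]
  long <- d$amplitude_mv[d$isi_prev_ms > isi_split_ms]
  underpowered <- length(short) < min_n || length(long) < min_n
  if (!length(short) || !length(long)) {
    warn("empty ISI class: pct_change undefined.")
    return(tibble::tibble(
      n_short = length(short), n_long = length(long),
      amp_short = NA_real_, amp_long = NA_real_, pct_change = NA_real_,
      p_amp_ks = NA_real_, p_amp_t = NA_real_, p_isi_by_label_ks = NA_real_,
      p_isi_by_label_t = NA_real_, classification = "none",
      underpowered = TRUE
    ))
  }
  amp_short <- mean(short)
  amp_long <- mean(long)
  pct_change <- (amp_short - amp_long) / amp_long * 100
  p_amp_ks <- suppressWarnings(ks.test(short, long)$p.value)
  p_amp_t <- t.test(short, long)$p.value
  isi_det <- d$isi_prev_ms[d$label == "detectable"]
  isi_und <- d$isi_prev_ms[d$label == "undetectable"]
  if (length(isi_det) >= 2 && length(isi_und) >= 2) {
    p_iks <- suppressWarnings(ks.test(isi_det, isi_und)$p.value)
    p_it <- t.test(isi_det, isi_und)$p.value
  } else {
    p_iks <- NA_real_
    p_it <- NA_real_
  }
  classification <- if (is.na(p_amp_ks) || p_amp_ks >= alpha) {
    "none"
  } else if (pct_change < 0) "STSD" else "STSF"
  tibble::tibble(
    n_short = length(short), n_long = length(long),
    amp_short = amp_short, amp_long = amp_long, pct_change = pct_change,
    p_amp_ks = p_amp_ks, p_amp_t = p_amp_t, p_isi_by_label_ks = p_iks,
    p_isi_by_label_t = p_it, classification = classification,
    underpowered = underpowered
  )
}

#' ISI-binned average EPSPs
#'
#' Groups presynaptic spikes by preceding ISI and reports the mean
#' single-spike amplitude per bin, plus the per-bin STA trace, normalized to
#' the longest-ISI bin -- the amplitude-vs-ISI curve of a depressing synapse
#' rises toward 1 with ISI.
#'
#' @param rec A [paired_recording()].
#' @param detections A [detect_epsps()] tibble for the pair.
#' @param bin_edges_ms ISI bin edges (ms); the last bin may be `Inf`.
#' @param window_ms STA half-window per bin, ms.
#' @return A tibble: `isi_lo`, `isi_hi`, `n`, `mean_amp`, `norm_amp`, `sta`
#'   (list column of per-bin STA vectors; empty bins are dropped with a
#'   warning).
#' @export
isi_binned_sta <- function(rec, detections,
                           bin_edges_ms = c(0, 10, 25, 50, 100, 200, Inf),
                           window_ms = 10) {
  d <- dplyr::filter(detections, !is.na(.data$isi_prev_ms))
  bin <- cut(d$isi_prev_ms, bin_edges_ms, right = TRUE)
  lv <- levels(bin)
  out <- purrr::map_dfr(seq_along(lv), function(i) {
    sel <- which(bin == lv[i])
    if (!length(sel)) {
      return(tibble::tibble(
        isi_lo = bin_edges_ms[i], isi_hi = bin_edges_ms[i + 1], n = 0L,
        mean_amp = NA_real_, sta = list(NULL)
      ))
    }
    sta <- if (length(sel) >= 2) {
      m <- segment_matrix(rec$vm, rec$fs, d$spike_time_s[sel], window_ms)
      if (nrow(m) >= 2) colMeans(m) else NULL
    } else NULL
    tibble::tibble(
      isi_lo = bin_edges_ms[i], isi_hi = bin_edges_ms[i + 1],
      n = length(sel), mean_amp = mean(d$amplitude_mv[sel]), sta = list(sta)
    )
  })
  if (any(out$n == 0)) {
    warn(sprintf("%d empty ISI bin(s) dropped.", sum(out$n == 0)))
    out <- dplyr::filter(out, .data$n > 0)
  }
  ref <- out$mean_amp[which.max(out$isi_lo)]
  dplyr::mutate(out, norm_amp = .data$mean_amp / ref, .before = "sta")
}

#' Population correlations among per-pair synaptic statistics
#'
#' Pearson correlations across connected pairs between percent-undetectable,
#' average amplitude and CV -- with and without undetectable events.
#'
#' @param summaries Row-bound [summarize_pair()] tibbles (>= 3 pairs).
#' @return A tibble `x`, `y`, `r`, `p`, `n`. Variable pairs with zero
#'   variance yield `NA` with a warning.
#' @export
population_correlations <- function(summaries) {
  if (nrow(summaries) < 3) abort("need >= 3 pairs for population correlations.")
  pairs <- list(
    c("pct_undetectable", "avg_amp_all"),
    c("pct_undetectable", "cv_all"),
    c("cv_all", "avg_amp_all"),
    c("cv_detectable", "avg_amp_detectable")
  )
  purrr::map_dfr(pairs, function(p) {
    x <- summaries[[p[1]]]
    y <- summaries[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warn(sprintf("correlation %s ~ %s undefined (zero variance or n < 3).",
                   p[1], p[2]))
      return(tibble::tibble(x = p[1], y = p[2], r = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble::tibble(x = p[1], y = p[2], r = unname(ct$estimate),
                   p = ct$p.value, n = sum(ok))
  })
}

#' Dependence of EPSP amplitude and reliability on pre-spike Vm
#'
#' Correlates the membrane potential just before each presynaptic spike
#' (mean over `baseline_ms`, a driving-force proxy) with the single-spike
#' amplitude, and stratifies percent-undetectable and amplitude CV by
#' pre-spike Vm quartile.
#'
#' @param rec A [paired_recording()].
#' @param detections A [detect_epsps()] tibble.
#' @param baseline_ms Pre-spike window, ms (default -5 to 0).
#' @param jittered_amps Optional jittered amplitudes; when given the
#'   quartile CVs are noise-corrected, otherwise they are plain SD/mean.
#' @return A list: `r` and `p` (amplitude ~ Vm correlation over all spikes)
#'   and `quartiles`, a tibble `quartile`, `vm_lo`, `vm_hi`, `n`,
#'   `pct_undetectable`, `cv`.
#' @export
vm_dependence <- function(rec, detections, baseline_ms = c(-5, 0),
                          jittered_amps = NULL) {
  fs <- rec$fs
  i0 <- round(detections$spike_time_s * fs) + 1L
  lo <- round(baseline_ms[1] * fs / 1000)
  hi <- round(baseline_ms[2] * fs / 1000)
  offs <- seq.int(lo, hi)
  ok <- i0 + lo >= 1L & i0 + hi <= length(rec$vm)
  pre_vm <- rep(NA_real_, nrow(detections))
  if (any(ok)) {
    m <- matrix(rec$vm[rep(i0[ok], each = length(offs)) + offs],
                nrow = sum(ok), byrow = TRUE)
    pre_vm[ok] <- rowMeans(m)
  }
  d <- dplyr::mutate(tibble::as_tibble(detections), pre_vm = pre_vm) %>%
    dplyr::filter(is.finite(.data$pre_vm))
  ct <- if (nrow(d) >= 3 && sd(d$pre_vm) > 0 && sd(d$amplitude_mv) > 0) {
    cor.test(d$pre_vm, d$amplitude_mv)
  } else NULL
  q <- quantile(d$pre_vm, probs = seq(0, 1, 0.25), names = FALSE)
  d$quartile <- cut(d$pre_vm, unique(q), include.lowest = TRUE,
                    labels = FALSE)
  quart <- d %>%
    dplyr::group_by(.data$quartile) %>%
    dplyr::summarise(
      vm_lo = min(.data$pre_vm), vm_hi = max(.data$pre_vm), n = dplyr::n(),
      pct_undetectable = 100 * mean(.data$label == "undetectable"),
      cv = if (!is.null(jittered_amps)) {
        noise_corrected_cv(.data$amplitude_mv, jittered_amps)
      } else {
        sd(.data$amplitude_mv) / abs(mean(.data$amplitude_mv))
      },
      .groups = "drop"
    )
  list(
    r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
    p = if (is.null(ct)) NA_real_ else ct$p.value,
    quartiles = quart
  )
}

#' Contrast per-pair statistics between RS and FS target cells
#'
#' Two-sample KS and t tests of a per-pair statistic between connections onto
#' regular-spiking and fast-spiking cortical cells (class labels are input
#' metadata).
#'
#' @param summaries Row-bound [summarize_pair()] tibbles with `cell_class`.
#' @param vars Columns to contrast.
#' @return Tibble `variable`, `mean_rs`, `mean_fs`, `p_ks`, `p_t`, `n_rs`,
#'   `n_fs`.
#' @export
cell_class_contrast <- function(summaries,
                                vars = c("avg_amp_all", "avg_amp_detectable",
                                         "pct_undetectable", "cv_all",
                                         "cv_detectable")) {
  purrr::map_dfr(vars, function(v) {
    rs <- summaries[[v]][summaries$cell_class == "RS"]
    fs <- summaries[[v]][summaries$cell_class == "FS"]
    rs <- rs[is.finite(rs)]
    fs <- fs[is.finite(fs)]
    if (length(rs) < 2 || length(fs) < 2) {
      return(tibble::tibble(variable = v, mean_rs = mean(rs), mean_fs = mean(fs),
                            p_ks = NA_real_, p_t = NA_real_,
                            n_rs = length(rs), n_fs = length(fs)))
    }
    tibble::tibble(
      variable = v, mean_rs = mean(rs), mean_fs = mean(fs),
      p_ks = suppressWarnings(ks.test(rs, fs)$p.value),
      p_t = t.test(rs, fs)$p.value, n_rs = length(rs), n_fs = length(fs)
    )
  })
}

#' Paired comparison of the same synapses across two stimulus epochs
#'
#' Paired t-tests (plus Pearson r) of per-pair statistics measured for the
#' same connections under two stimuli or epochs (e.g. white noise vs drifting
#' gratings); rows are matched by `pair_id`.
#'
#' @param summaries_a,summaries_b Summary tibbles for the two epochs.
#' @param vars Columns to compare.
#' @return Tibble `variable`, `mean_a`, `mean_b`, `r`, `p_paired_t`, `n`.
#' @export
epoch_contrast <- function(summaries_a, summaries_b,
                           vars = c("avg_amp_all", "pct_undetectable")) {
  m <- dplyr::inner_join(summaries_a, summaries_b, by = "pair_id",
                         suffix = c("_a", "_b"))
  purrr::map_dfr(vars, function(v) {
    a <- m[[paste0(v, "_a")]]
    b <- m[[paste0(v, "_b")]]
    ok <- is.finite(a) & is.finite(b)
    tibble::tibble(
      variable = v, mean_a = mean(a[ok]), mean_b = mean(b[ok]),
      r = if (sum(ok) >= 3) cor(a[ok], b[ok]) else NA_real_,
      p_paired_t = if (sum(ok) >= 2) t.test(a[ok], b[ok], paired = TRUE)$p.value
        else NA_real_,
      n = sum(ok)
    )
  })
}
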