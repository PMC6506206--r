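test_that("noise-corrected CV matches hand-computed and degenerate cases", {
  # sample SDs of c(0,1,2) and c(-0.6,0,0.6) are exactly 1 and 0.6
  expect_equal(noise_corrected_cv(c(0, 1, 2), c(-0.6, 0, 0.6)),
               sqrt(1 - 0.36) / 1, tolerance = 1e-14)
  # exact cancellation when the variances match
  expect_equal(noise_corrected_cv(c(0, 1, 2), c(1, 2, 3)), 0)
  expect_error(noise_corrected_cv(numeric(0), 1), "nonempty")
  expect_error(noise_corrected_cv(c(-1, 1), c(0, 1)), "zero")
})

test_that("noise-corrected CV equals an independent recomputation", {
  set.seed(1)
  for (i in 1:200) {
    a <- rnorm(sample(5:200, 1), runif(1, 0.2, 2), runif(1, 0.1, 1.5))
    j <- rnorm(sample(5:200, 1), 0, runif(1, 0.05, 1))
    oracle <- sqrt(abs(stats::var(a) - stats::var(j))) / mean(a)
    expect_equal(noise_corrected_cv(a, j), oracle, tolerance = 1e-12)
  }
})

test_that("pair summary respects category accounting identities", {
  rec <- mk_pair_rec(n_spikes = 600, seed = 2)
  det <- detect_epsps(extract_pair(rec, 1L), seed = 3)
  s <- summarize_pair(det, lgn_rate_hz = 10, cell_class = "RS")
  n_det <- sum(det$label == "detectable")
  n_und <- sum(det$label == "undetectable")
  # mean(all) = weighted mean of category means, exactly
  expect_equal(
    s$avg_amp_all,
    (n_det * s$avg_amp_detectable + n_und * s$avg_amp_undetectable) /
      (n_det + n_und),
    tolerance = 1e-12
  )
  expect_equal(s$pct_undetectable, 100 * n_und / nrow(det), tolerance = 1e-12)
  expect_true(s$cv_all >= 0)
  expect_identical(s$cell_class, "RS")
})

test_that("excluding undetectable events shrinks the corrected CV", {
  # undetectable amplitudes are noise-like, so removing them must not
  # increase the CV (the in vivo direction: a ~tenfold reduction)
  set.seed(4)
  for (i in 1:5) {
    syn <- synapse_cohort(1, seed = 40 + i)
    syn$stsd_depress <- 0
    rec <- mk_pair_rec(n_spikes = 700, syn = syn, seed = 50 + i)
    det <- detect_epsps(extract_pair(rec, 1L), seed = 60 + i)
    s <- summarize_pair(det)
    expect_lte(s$cv_detectable, s$cv_all + 1e-9)
  }
})

test_that("constant fully-transmitting synapse yields zero CV and failures", {
  syn <- mk_syn(mean_amp = 1.5, amp_cv = 0, p_fail = 0,
                latency_jitter_ms = 0)
  # regular train: no temporal summation between events
  st <- tibble::tibble(cell_id = 1L, spike_time_s = seq(0.5, 60, by = 0.2))
  rec <- synthesize_recording(st, syn, duration_s = 60.5,
                              noise = noise_params(1e-5, 0, 10, 0), seed = 6)
  det <- detect_epsps(extract_pair(rec, 1L), seed = 7)
  # alignment-free fluctuation amplitudes, sampled midway between events so
  # they are uncontaminated by the EPSPs themselves
  pr_mid <- paired_recording(rec$vm, rec$fs, st$spike_time_s + 0.1)
  ja <- jittered_trace_amplitudes(pr_mid, attr(det, "window"),
                                  n_traces = 150, jitter_ms = 0.5, seed = 8)
  s <- summarize_pair(det, jittered_amps = ja)
  expect_equal(s$pct_undetectable, 0)
  expect_lt(s$cv_all, 0.05)
})

test_that("STSP analysis recovers depression and its ISI signature", {
  syn <- mk_syn(mean_amp = 1.2, amp_cv = 0.2, p_fail = 0.3,
                stsd_depress = 0.4, stsd_tau_ms = 60)
  rec <- mk_pair_rec(n_spikes = 1500, rate_hz = 15, syn = syn, seed = 8)
  det <- detect_epsps(extract_pair(rec, 1L), seed = 9)
  r <- stsp_analysis(det)
  expect_identical(r$classification, "STSD")
  expect_lt(r$pct_change, 0)
  expect_lt(r$p_amp_ks, 0.05)
  # depressing synapses fail more at short ISIs
  expect_lt(r$p_isi_by_label_ks, 0.05)
  expect_false(r$underpowered)

  # facilitation flips the sign
  syn_f <- mk_syn(mean_amp = 1, amp_cv = 0.2, p_fail = 0.2,
                  stsd_depress = -0.4, stsd_tau_ms = 60)
  rec_f <- mk_pair_rec(n_spikes = 1500, rate_hz = 15, syn = syn_f, seed = 10)
  det_f <- detect_epsps(extract_pair(rec_f, 1L), seed = 11)
  r_f <- stsp_analysis(det_f)
  expect_identical(r_f$classification, "STSF")
  expect_gt(r_f$pct_change, 0)

  # under-powered flagging
  few <- det[1:30, ]
  attr(few, "window") <- attr(det, "window")
  expect_true(stsp_analysis(few)$underpowered)
})

test_that("ISI-binned amplitudes rise with ISI for a depressing synapse", {
  syn <- mk_syn(mean_amp = 1.5, amp_cv = 0, p_fail = 0,
                stsd_depress = 0.5, stsd_tau_ms = 80, latency_jitter_ms = 0)
  rec <- mk_pair_rec(n_spikes = 1200, rate_hz = 15, syn = syn, seed = 12,
                     noise = noise_params(1e-4, 0, 10, 0))
  det <- detect_epsps(extract_pair(rec, 1L), seed = 13)
  bins <- suppressWarnings(
    isi_binned_sta(extract_pair(rec, 1L), det,
                   bin_edges_ms = c(0, 25, 50, 100, 200, Inf))
  )
  expect_true(all(diff(bins$mean_amp) > -0.02)) # non-decreasing with ISI
  expect_equal(bins$norm_amp[nrow(bins)], 1, tolerance = 1e-12)
  # non-plastic, zero-noise synapse: identical per-bin amplitudes
  syn0 <- mk_syn(mean_amp = 1.5, amp_cv = 0, p_fail = 0, stsd_depress = 0,
                 latency_jitter_ms = 0)
  rec0 <- mk_pair_rec(n_spikes = 800, rate_hz = 15, syn = syn0, seed = 14,
                      noise = noise_params(1e-4, 0, 10, 0))
  det0 <- detect_epsps(extract_pair(rec0, 1L), seed = 15)
  bins0 <- suppressWarnings(isi_binned_sta(extract_pair(rec0, 1L), det0))
  # flat to within ~5% of the event size (short-ISI bins carry a small
  # temporal-summation bias from the preceding EPSP's decay)
  expect_lt(diff(range(bins0$mean_amp)), 0.08)
})

test_that("population correlations recover the generator coupling", {
  set.seed(16)
  coh <- synapse_cohort(24, seed = 17)
  sums <- purrr::map_dfr(seq_len(nrow(coh)), function(i) {
    p <- coh$p_fail[i]
    amps_det <- rlnorm(300, log(coh$mean_amp[i]) - 0.02, 0.2)
    amps_und <- rnorm(round(300 * p / (1 - p)), -0.1, 0.2)
    all_amp <- c(amps_det, amps_und)
    jit <- rnorm(300, 0, 0.2)
    tibble::tibble(
      pair_id = i,
      pct_undetectable = 100 * length(amps_und) / length(all_amp),
      avg_amp_all = mean(all_amp), avg_amp_detectable = mean(amps_det),
      cv_all = noise_corrected_cv(all_amp, jit),
      cv_detectable = noise_corrected_cv(amps_det, jit)
    )
  })
  ct <- population_correlations(sums)
  expect_lt(ct$r[ct$x == "pct_undetectable" & ct$y == "avg_amp_all"], 0)
  expect_gt(ct$r[ct$x == "pct_undetectable" & ct$y == "cv_all"], 0)
  # degenerate population: zero variance flagged
  sums0 <- sums
  sums0$pct_undetectable <- 50
  expect_warning(population_correlations(sums0), "zero variance")
  expect_error(population_correlations(sums[1:2, ]), ">= 3 pairs")
})

test_that("Vm dependence is null when amplitudes ignore driving force", {
  rec <- mk_pair_rec(n_spikes = 700, seed = 18)
  det <- detect_epsps(extract_pair(rec, 1L), seed = 19)
  vd <- vm_dependence(extract_pair(rec, 1L), det)
  expect_lt(abs(vd$r), 0.15)
  expect_equal(nrow(vd$quartiles), 4)
  expect_named(vd$quartiles,
               c("quartile", "vm_lo", "vm_hi", "n", "pct_undetectable", "cv"))
})

test_that("Vm dependence recovers a built-in driving-force relation", {
  syn <- mk_syn(mean_amp = 1.5, amp_cv = 0.05, p_fail = 0,
                latency_jitter_ms = 0)
  rec <- mk_pair_rec(
    n_spikes = 700, syn = syn, seed = 20,
    noise = noise_params(white_sd = 0.01, ou_sd = 0, slow_amp = 4,
                         slow_freq_hz = 1),
    vm_dependence = TRUE, e_syn = 0
  )
  det <- detect_epsps(extract_pair(rec, 1L), seed = 21)
  vd <- vm_dependence(extract_pair(rec, 1L), det)
  expect_lt(vd$r, -0.2) # depolarized Vm -> smaller driving force -> smaller EPSP
  expect_lt(vd$p, 0.01)
})

test_that("class and epoch contrasts return the expected table shapes", {
  set.seed(22)
  sums <- tibble::tibble(
    pair_id = 1:12,
    avg_amp_all = rnorm(12, 0.5, 0.1),
    avg_amp_detectable = rnorm(12, 0.9, 0.1),
    pct_undetectable = runif(12, 20, 50),
    cv_all = runif(12, 0.8, 1.5),
    cv_detectable = runif(12, 0.1, 0.3),
    cell_class = rep(c("RS", "FS"), each = 6)
  )
  cc <- cell_class_contrast(sums)
  expect_equal(nrow(cc), 5)
  expect_true(all(is.finite(cc$p_ks)))
  b <- sums
  b$avg_amp_all <- b$avg_amp_all * 0.8
  ec <- epoch_contrast(sums, b)
  expect_equal(nrow(ec), 2)
  expect_lt(ec$p_paired_t[ec$variable == "avg_amp_all"], 0.05)
  expect_gt(ec$r[1], 0.9)
})
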