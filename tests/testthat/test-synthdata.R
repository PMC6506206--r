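test_that("white-noise stimulus has the configured geometry and duration", {
  stim <- wn_stimulus(n_blocks = 18, seed = 1)
  expect_equal(stim$duration_s, 89)
  expect_equal(dim(stim$frames), c(18 * 250, 16, 16))
  expect_true(all(stim$frames %in% c(-1, -1 / 3, 1 / 3, 1)))
  # determinism: identical seed, identical frames
  stim2 <- wn_stimulus(n_blocks = 18, seed = 1)
  expect_identical(stim$frames, stim2$frames)
  # level-count guard
  expect_error(wn_stimulus(levels = c(-1, 0, 1)), "4 contrast")
  expect_silent(wn_stimulus(n_blocks = 1, levels = c(-1, 0, 0.5, 1),
                            strict_levels = FALSE))
  # gray gaps: no frame on screen between blocks
  t_gap <- stim$frame_onset_s[250] + 0.5 # mid first gap
  expect_true(is.na(tcsynapse:::frame_index_at(stim, t_gap)))
})

test_that("zero-contrast stimulus drives LGN cells at their baseline rate", {
  cells <- lgn_population(3, seed = 2)
  cells$baseline_rate_hz <- 10
  cells$refractory_ms <- 1
  sp <- simulate_lgn_spikes(NULL, cells, duration_s = 100, seed = 3)
  rates <- attr(sp, "rates_hz")$rate_hz
  # 10 Hz +/- sampling error (SE ~ 0.32 Hz per cell)
  expect_true(all(abs(rates - 10) < 1.5))
  expect_gte(min(diff(sp$spike_time_s[sp$cell_id == 1])) * 1000, 1)
})

test_that("refractory thinning matches the dead-time-corrected rate", {
  # closed-form oracle: renewal process with dead time fires at r/(1 + r*ref)
  cells <- lgn_population(1, seed = 1)
  cells$baseline_rate_hz <- 20
  cells$refractory_ms <- 5
  r_expected <- 20 / (1 + 20 * 0.005)
  set.seed(4)
  counts <- vapply(1:150, function(i) {
    nrow(simulate_lgn_spikes(NULL, cells, duration_s = 20))
  }, numeric(1))
  rate <- mean(counts) / 20
  se <- sd(counts / 20) / sqrt(length(counts))
  expect_lt(abs(rate - r_expected), 4 * se + 0.05)
  # count dispersion stays near Poisson (dead time mildly under-disperses)
  expect_gt(var(counts) / mean(counts), 0.6)
  expect_lt(var(counts) / mean(counts), 1.15)
})

test_that("population RF reflects the banded ON/OFF layout", {
  cells <- lgn_population(4, n_bands = 2, seed = 5)
  rf <- population_rf(cells, n_px = 16)
  field <- attr(cells, "field_deg")
  px <- field * (seq_len(16) - 0.5) / 16
  # direct evaluation oracle: sign of the row-mean RF must match the sign of
  # the nearest cells' band
  for (b in 1:2) {
    ys <- cells$y_deg[cells$sign == c(1, -1)[b]]
    rows <- which(abs(px - mean(ys)) < field / 8)
    expect_true(all(sign(rowMeans(rf)[rows]) == c(1, -1)[b]))
  }
  # single cell: population RF equals that cell's own RF
  one <- lgn_population(1, seed = 6)
  w <- tcsynapse:::rf_weights(one, 16, attr(one, "field_deg"))
  expect_equal(population_rf(one, 16), matrix(w[, 1], 16, 16))
  expect_error(lgn_population(0), "between 1 and 50")
})

test_that("stimulus-driven LGN rates stay in the physiological range", {
  stim <- wn_stimulus(n_blocks = 4, seed = 7)
  cells <- lgn_population(20, seed = 8)
  sp <- simulate_lgn_spikes(stim, cells, seed = 9)
  rates <- attr(sp, "rates_hz")$rate_hz
  expect_true(all(rates >= 2 & rates <= 24))
  expect_gte(min(diff(sp$spike_time_s[sp$cell_id == sp$cell_id[1]])) * 1000,
             cells$refractory_ms[1])
})

test_that("synthetic recording obeys superposition and conservation", {
  # single event, zero noise: peak - rest equals the drawn amplitude
  st <- tibble::tibble(cell_id = 1L, spike_time_s = 0.5)
  syn <- mk_syn(mean_amp = 1, amp_cv = 0, p_fail = 0, latency_jitter_ms = 0)
  rec <- synthesize_recording(
    st, syn, duration_s = 1, seed = 1,
    noise = noise_params(white_sd = 0, ou_sd = 0, slow_amp = 0)
  )
  expect_equal(max(rec$vm) - rec$rest_vm, 1, tolerance = 1e-10)
  pk <- (which.max(rec$vm) - 1) / rec$fs
  # event peaks at spike + latency + closed-form double-exponential rise
  t_peak_ms <- log(4 / 0.5) * 0.5 * 4 / (4 - 0.5)
  expect_equal(pk, 0.5 + 0.0025 + t_peak_ms / 1000, tolerance = 3e-4)

  # all failures, zero noise: trace is flat at rest
  syn2 <- mk_syn(p_fail = 1)
  rec2 <- synthesize_recording(
    mk_train(50, 5, seed = 2), syn2, duration_s = 5, seed = 3,
    noise = noise_params(white_sd = 0, ou_sd = 0, slow_amp = 0)
  )
  expect_true(all(rec2$vm == rec2$rest_vm))

  # conservation: one truth record per presynaptic spike, always
  rec3 <- mk_pair_rec(n_spikes = 300, seed = 4)
  expect_equal(nrow(rec3$truth), nrow(rec3$spikes))
  expect_equal(sum(rec3$truth$transmitted) + sum(!rec3$truth$transmitted),
               nrow(rec3$truth))

  # per-event measured amplitude equals drawn amplitude (zero noise,
  # non-overlapping events) to < 1%
  st4 <- tibble::tibble(cell_id = 1L, spike_time_s = seq(0.5, 9.5, by = 0.5))
  syn4 <- mk_syn(mean_amp = 1.2, amp_cv = 0.4, p_fail = 0,
                 latency_jitter_ms = 0)
  rec4 <- synthesize_recording(
    st4, syn4, duration_s = 10, seed = 5,
    noise = noise_params(white_sd = 0, ou_sd = 0, slow_amp = 0)
  )
  for (i in seq_len(nrow(rec4$truth))) {
    i0 <- round(rec4$truth$spike_time_s[i] * rec4$fs)
    win <- rec4$vm[i0:(i0 + 100)]
    expect_lt(abs((max(win) - rec4$rest_vm) - rec4$truth$amplitude_mv[i]) /
                rec4$truth$amplitude_mv[i], 0.01)
  }
})

test_that("mean superposed amplitude matches mean_amp * (1 - p_fail)", {
  syn <- mk_syn(mean_amp = 1.2, amp_cv = 0.3, p_fail = 0.37)
  rec <- mk_pair_rec(n_spikes = 2000, rate_hz = 8, syn = syn, seed = 6,
                     noise = noise_params(white_sd = 0, ou_sd = 0,
                                          slow_amp = 0))
  got <- mean(rec$truth$amplitude_mv[rec$truth$transmitted]) *
    mean(rec$truth$transmitted)
  expect_equal(got, 1.2 * (1 - 0.37), tolerance = 0.05)
})

test_that("recordings are reproducible under a fixed seed", {
  a <- mk_pair_rec(n_spikes = 100, seed = 11)
  b <- mk_pair_rec(n_spikes = 100, seed = 11)
  expect_identical(a$vm, b$vm)
  expect_identical(a$truth, b$truth)
  expect_error(synthesize_recording(mk_train(10, 2, seed = 1), mk_syn(),
                                    fs = 500), "1 kHz")
})

test_that("cohort couples failure probability negatively to amplitude", {
  coh <- synapse_cohort(200, seed = 12)
  expect_true(all(coh$p_fail >= 0 & coh$p_fail < 1))
  expect_true(all(coh$mean_amp > 0))
  expect_lt(cor(coh$p_fail, coh$mean_amp), -0.3)
  expect_lt(cor(coh$amp_cv, coh$mean_amp), 0)
  # marginals near the in vivo population
  expect_equal(mean(coh$mean_amp), 0.89, tolerance = 0.08)
  expect_equal(mean(coh$p_fail), 0.37, tolerance = 0.06)
})

test_that("STSD scaling in the generator follows the configured kinetics", {
  syn <- mk_syn(amp_cv = 0, p_fail = 0, stsd_depress = 0.4, stsd_tau_ms = 60,
                latency_jitter_ms = 0)
  st <- tibble::tibble(cell_id = 1L,
                       spike_time_s = c(0.5, 0.52, 0.8, 1.6))
  rec <- synthesize_recording(
    st, syn, duration_s = 2, seed = 1,
    noise = noise_params(white_sd = 0, ou_sd = 0, slow_amp = 0)
  )
  amps <- rec$truth$amplitude_mv
  isi <- c(NA, diff(st$spike_time_s)) * 1000
  expected <- 1.2 * c(1, 1 - 0.4 * exp(-isi[-1] / 60))
  expect_equal(amps, expected, tolerance = 1e-8)
})
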