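test_that("EPSG kernel matches the closed-form difference of exponentials", {
  k <- epsg_kernel(0.5, 2, dt_ms = 0.01)
  # closed-form peak time of exp(-t/td) - exp(-t/tr)
  t_peak <- log(2 / 0.5) * 0.5 * 2 / (2 - 0.5)
  expect_equal(k$peak_ms, t_peak, tolerance = 1e-12)
  expect_equal(k$time_ms[which.max(k$samples)], t_peak, tolerance = 0.011)
  expect_equal(max(k$samples), 1)
  expect_true(all(k$samples >= 0))
  expect_gt(sum(k$samples) * k$dt_ms, 0) # finite positive integral
  # tau_rise -> 0 limit: single exponential decay from the first nonzero
  # sample (which becomes the unit peak)
  k0 <- epsg_kernel(1e-9, 2, dt_ms = 0.1)
  expect_equal(k0$samples[2:50], exp(-(k0$time_ms[2:50] - 0.1) / 2),
               tolerance = 1e-6)
  expect_error(epsg_kernel(2, 0.5), "must be <")
  expect_error(epsg_kernel(0.5, -1), "positive")
})

test_that("steady-state Vm under constant conductance matches closed form", {
  p <- lif_params(duration_s = 0.5)
  # conductances kept below the threshold-crossing level (~3.9 nS)
  for (g in c(0.5, 1.5, 3)) {
    gv <- rep(g, 5001)
    r <- tcsynapse:::lif_integrate_cpp(
      gv, numeric(0), p$dt_ms, p$v_rest, p$v_thresh, p$v_reset,
      p$refractory_ms, p$r_m_mohm, p$tau_m_ms, p$e_exc, p$e_inh
    )
    vss <- lif_steady_state(g, p)
    # after >> 5 effective time constants, within 0.1%
    expect_lt(abs(tail(r$vm, 1) - vss) / abs(vss), 0.001)
  }
})

test_that("no input leaves the membrane at rest; Vm never exceeds threshold", {
  p <- lif_params(duration_s = 1)
  empty <- tibble::tibble(cell_id = integer(), spike_time_s = numeric())
  sim <- simulate_lif(empty, assign_synapses(1, seed = 1), p, seed = 2)
  expect_true(all(sim$vm == p$v_rest))
  expect_equal(sim$rate_hz, 0)
  expect_equal(sim$vm_mean, p$v_rest)
})

test_that("synapse assignment targets the configured mean conductance", {
  sp <- assign_synapses(50, seed = 3)
  expect_equal(mean(sp$mean_epsg), 0.89, tolerance = 1e-9)
  expect_true(all(sp$p_fail >= 0 & sp$p_fail < 1))
  expect_lt(cor(sp$p_fail, sp$mean_epsg), 0) # monotone coupling kept
  # single triplet reproducible
  expect_identical(assign_synapses(1, seed = 4), assign_synapses(1, seed = 4))
  expect_error(assign_synapses(0), "1..50")
  expect_error(assign_synapses(5, source = "table"), "dryad")
  # table source: marginal set preserved as a permutation
  tb <- tibble::tibble(mean_epsg = runif(10, 0.3, 1.5),
                       amp_cv = runif(10, 0.4, 1), p_fail = runif(10, 0.1, 0.6))
  got <- assign_synapses(10, source = "table", table = tb, seed = 5)
  expect_setequal(got$mean_epsg, tb$mean_epsg)
})

test_that("equal-drive calibration balances the expected conductance", {
  sp <- tibble::tibble(synapse_id = 1L, mean_epsg = 1, amp_cv = 0.7,
                       p_fail = 0.4, stsd_depress = 0, stsd_tau_ms = 60)
  rel <- calibrate_equal_drive(sp)
  expect_equal(rel$mean_epsg, 0.6)
  expect_equal(rel$p_fail, 0)
  expect_equal(rel$amp_cv, 0)
  # event-mean mode keeps the per-event mean
  expect_equal(calibrate_equal_drive(sp, "event_mean")$mean_epsg, 1)
  # p_fail = 0: both calibrations identical
  sp0 <- dplyr::mutate(sp, p_fail = 0)
  expect_equal(calibrate_equal_drive(sp0), calibrate_equal_drive(sp0, "event_mean"))
})

test_that("failure designation matches its Bernoulli/correlated contracts", {
  st <- sort(runif(10000, 0, 1000))
  expect_false(any(apply_failures(st, 0, seed = 1)))
  f <- apply_failures(st, 0.4, seed = 2)
  ci <- stats::qbinom(c(0.025, 0.975), length(st), 0.4) / length(st)
  expect_gte(mean(f), ci[1])
  expect_lte(mean(f), ci[2])
  # correlated mode: coincident spikes fail more, marginal preserved
  set.seed(3)
  others <- sort(runif(60000, 0, 1000))
  fc <- apply_failures(st, 0.4, "correlated", other_spikes = others, seed = 4)
  os <- others
  lo <- findInterval(st - 0.005, os)
  hi <- findInterval(st + 0.005, os)
  coincident <- hi > lo
  expect_gt(mean(fc[coincident]), mean(fc[!coincident]))
  expect_gte(mean(fc), ci[1] - 0.01)
  expect_lte(mean(fc), ci[2] + 0.01)
})

test_that("refractoriness caps the output rate and ISIs", {
  # strong constant drive: ISIs pinned near the refractory period
  p <- lif_params(duration_s = 0.5)
  gv <- rep(30, 5001)
  r <- tcsynapse:::lif_integrate_cpp(
    gv, numeric(0), p$dt_ms, p$v_rest, p$v_thresh, p$v_reset,
    p$refractory_ms, p$r_m_mohm, p$tau_m_ms, p$e_exc, p$e_inh
  )
  isi <- diff(r$spike_idx) * p$dt_ms
  expect_gte(min(isi), p$refractory_ms)
})

test_that("unreliable variants order firing and fluctuations correctly", {
  stim <- wn_stimulus(n_blocks = 5, seed = 10)
  cells <- lgn_population(50, seed = 11)
  trains <- simulate_lgn_spikes(stim, cells, seed = 12)
  specs <- assign_synapses(50, seed = 13)
  p <- lif_params(duration_s = stim$duration_s)
  stats_of <- function(md, sd_seed) {
    s <- simulate_lif(trains, specs, p, mode = md, seed = sd_seed)
    c(rate = s$rate_hz, sd = s$vm_sd, vm = s$vm_mean)
  }
  res <- sapply(c("reliable", "unreliable_const_amp", "unreliable"),
                stats_of, sd_seed = 14)
  # Vm SD: reliable < constant-amplitude unreliable < fully unreliable
  expect_lt(res["sd", "reliable"], res["sd", "unreliable_const_amp"])
  expect_lt(res["sd", "unreliable_const_amp"], res["sd", "unreliable"])
  expect_lt(res["rate", "reliable"], res["rate", "unreliable"])
  # correlated failures still boost firing over the reliable model
  sc <- simulate_lif(trains, specs, p, mode = "correlated_failure", seed = 14)
  expect_gt(sc$vm_sd, res["sd", "reliable"])
  # STSD variant leaves the reliable-vs-unreliable ordering unchanged
  s_rel <- simulate_lif(trains, specs, p, mode = "reliable", stsd = TRUE,
                        seed = 15)
  s_unr <- simulate_lif(trains, specs, p, mode = "unreliable", stsd = TRUE,
                        seed = 15)
  expect_lt(s_rel$vm_sd, s_unr$vm_sd)
  expect_lte(s_rel$rate_hz, s_unr$rate_hz)
  # accounting: transmitted + failed = total presynaptic spikes
  expect_equal(s_unr$n_presyn_spikes, nrow(trains))
  expect_true(s_unr$n_failures > 0 && s_unr$n_failures < s_unr$n_presyn_spikes)
})

test_that("depolarization grows ~linearly with input count in both modes", {
  stim <- wn_stimulus(n_blocks = 3, seed = 20)
  cells <- lgn_population(40, seed = 21)
  trains <- simulate_lgn_spikes(stim, cells, seed = 22)
  specs <- assign_synapses(40, seed = 23)
  sw <- sweep_inputs(trains, specs, n_list = c(10, 25, 40), n_trials = 2,
                     params = lif_params(duration_s = stim$duration_s),
                     seed = 24)
  for (md in c("reliable", "unreliable")) {
    cv <- dplyr::filter(sw$curves, .data$mode == md)
    depol <- cv$vm_mean_mean + 65
    expect_true(all(diff(depol) > 0))
    fit <- stats::lm(depol ~ cv$n_requested)
    expect_gt(summary(fit)$r.squared, 0.85)
    expect_true(all(cv$vm_mean_mean < -55))
  }
  wide <- tidyr::pivot_wider(
    sw$curves[, c("n_requested", "mode", "vm_sd_mean")],
    names_from = "mode", values_from = "vm_sd_mean"
  )
  expect_true(all(wide$unreliable > wide$reliable))
})

test_that("reverse correlation recovers the stimulus geometry and lag", {
  stim <- wn_stimulus(n_blocks = 4, seed = 30)
  cells <- lgn_population(30, n_bands = 2, seed = 31)
  trains <- simulate_lgn_spikes(stim, cells, seed = 32)
  specs <- assign_synapses(30, seed = 33)
  sim <- simulate_lif(trains, specs, lif_params(duration_s = stim$duration_s),
                      seed = 34)
  rf <- reverse_correlation_rf(sim, stim)
  # Vm independent of the stimulus: RF ~ 0 everywhere
  sim0 <- sim
  set.seed(35)
  sim0$vm <- rnorm(length(sim$vm), -65, 2)
  rf0 <- reverse_correlation_rf(sim0, stim)
  expect_lt(max(abs(rf0$rf)), max(abs(rf$rf)) / 3)
  # strongest lag near the LGN temporal kernel peak (derived from the kernel)
  tk <- attr(cells, "temporal_kernel")
  expected_lag <- (which.max(tk) - 0.5) * stim$frame_ms + stim$frame_ms / 2
  expect_lt(abs(rf$peak_lag_ms - expected_lag), 2.5 * stim$frame_ms)
  # sign map follows the ON/OFF rows: correlate RF at peak lag with the
  # population RF of the driving cells
  pop <- population_rf(cells, stim$n_px)
  rf_pk <- rf$rf[which(rf$lags_ms == rf$peak_lag_ms), , ]
  expect_gt(cor(as.vector(rf_pk), as.vector(pop)), 0.4)
  expect_error(reverse_correlation_rf(sim, wn_stimulus(n_blocks = 2, seed = 1)),
               "durations differ")
})

test_that("simulation summaries are reproducible and well-formed", {
  stim <- wn_stimulus(n_blocks = 2, seed = 40)
  cells <- lgn_population(10, seed = 41)
  trains <- simulate_lgn_spikes(stim, cells, seed = 42)
  specs <- assign_synapses(10, seed = 43)
  p <- lif_params(duration_s = stim$duration_s)
  a <- simulate_lif(trains, specs, p, seed = 44)
  b <- simulate_lif(trains, specs, p, seed = 44)
  expect_identical(a$vm, b$vm)
  expect_identical(a$spike_times_s, b$spike_times_s)
  g <- glance(a)
  expect_named(g, c("mode", "n_inputs", "rate_hz", "vm_mean", "vm_sd",
                    "n_presyn_spikes", "n_failures", "pct_failed"))
  td <- tidy(a)
  expect_equal(nrow(td), length(a$vm))
  expect_true(all(a$vm <= p$v_thresh + 1e-12))
})
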