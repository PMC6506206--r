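---
title: "Characterizing thalamocortical synaptic transmission: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing thalamocortical synaptic transmission: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(tcsynapse)
library(dplyr)
```

`tcsynapse` analyzes paired recordings in which the spike train of a thalamic
(LGN) relay cell is recorded simultaneously with the membrane potential (Vm)
of a cortical (V1) simple cell, and asks three questions about the synapse
that may join them: is the pair monosynaptically connected, how reliable and
how variable are the single-spike EPSPs the connection produces, and what do
those properties do to cortical firing. This vignette explains the methods,
their assumptions, the tunable parameters, and the numerical choices the
implementation makes. Everything shown here runs on synthetic data produced
by the package's own generator; no recordings are required.

## The synthetic-data generator

Real paired recordings are scarce, so every stage of the pipeline is
exercised against a generator whose statistical structure mirrors the in
vivo setting:

* **Stimulus** (`wn_stimulus()`): spatiotemporal white noise, 16 x 16 pixels,
  four contrast levels, 16 ms frames in 250-frame blocks separated by 1 s of
  gray. Eighteen blocks give the standard 89 s run.
* **LGN population** (`lgn_population()`, `simulate_lgn_spikes()`): a
  linear-nonlinear-Poisson stand-in for relay cells. Gaussian center RFs are
  arranged along parallel ON/OFF bands so their sign-weighted sum forms the
  elongated subregions of a simple cell. Each cell filters the stimulus
  through its RF and a biphasic temporal kernel (transient excitatory lobe
  peaking about 3 frames back, delayed suppressive lobe), adds a 2-6 Hz
  baseline, rectifies at zero, and fires as an inhomogeneous Bernoulli
  process with an absolute refractory period. Defaults (gain 700 Hz per unit
  filtered contrast, RF width 0.5 degrees) were fixed once so that realized
  rates fall in the physiological 2-24 Hz range and the downstream membrane
  operates in the fluctuation-driven regime described below; they are not
  re-tuned per analysis.
* **Synapse cohort** (`synapse_cohort()`): per-synapse triplets of mean
  transmitted-event amplitude, event CV and failure probability, jointly
  drawn with the empirically observed monotone coupling — larger synapses
  fail less and vary less. Defaults center the detectable-EPSP mean near
  0.89 mV and the failure probability near 37%, with about half the cohort
  depressing (`stsd_depress > 0`), a small minority facilitating, and
  latencies near 2.5 ms with 0.3 ms jitter (inside the 1.0-4.5 ms
  monosynaptic window).
* **Membrane trace** (`synthesize_recording()`): transmitted spikes add a
  double-exponential EPSP (0.5 ms rise, 4 ms decay by default) whose
  amplitude comes from a zero-truncated log-normal scaled by short-term
  plasticity `1 - d * exp(-ISI/tau)`; failed spikes add nothing. Noise is
  the sum of white sampling noise (0.05 mV), an Ornstein-Uhlenbeck process
  (0.25 mV, tau = 10 ms) standing in for background synaptic bombardment,
  and a slow stimulus-locked modulation (0.3 mV). These defaults put the
  detector's jittered-trace threshold near 0.2 mV, the scale seen in vivo.
  Optional ingredients: IPSP-like negative events at a Poisson rate, and a
  driving-force dependence that scales amplitudes by `(E_syn - Vm)`.

What the generator does *not* emulate: dendritic filtering and
location-dependent attenuation, true vesicular release statistics (failures
are a single Bernoulli probability, not binomial N/p/q), spike-frequency
adaptation or bursting in the presynaptic train, and eye-movement or
state-dependent nonstationarities. Tests passing on synthetic cohorts
therefore validate the *estimators* — that the pipeline recovers known
ground truth under realistic noise — not the biological claims themselves.

```{r cohort}
cohort <- synapse_cohort(36, seed = 1)
summary(cohort[, c("mean_amp", "amp_cv", "p_fail")])
cor(cohort$p_fail, cohort$mean_amp)
```

## Detecting connected pairs: the jitter-corrected STA

`compute_sta()` averages +-10 ms windows of Vm around each presynaptic
spike. Because LGN and V1 share the visual stimulus, the raw STA mixes the
monosynaptic EPSP with slow stimulus-locked Vm modulation. The correction
(`compute_jittered_sta()`) displaces every spike by a uniform 0-16 ms jitter
(one stimulus frame; 0-24 ms for 24 ms frames) and re-averages: the jitter
preserves modulation slower than a frame but destroys sub-frame synaptic
alignment, so the difference `raw - jittered` isolates the EPSP. One hundred
jitter draws are averaged so the jittered STA contributes negligible extra
noise (the count is a package choice; any value above a few tens behaves the
same).

`sta_connection()` then applies three gates:

1. **Significance.** Spike-level bootstrap (default 1000 resamples with
   replacement) of the corrected STA gives per-sample quantiles; the band is
   centered so it represents the null hypothesis of no alignment-locked
   deflection, and the corrected STA must exceed the upper 95% limit for at
   least 10 consecutive samples (1 ms at 10 kHz; the run length scales with
   the sampling rate). The run is searched within the 0-6 ms post-spike
   span, the same span the EPSP detector uses, which anchors false-positive
   control to the monosynaptic region.
2. **Latency.** The EPSP onset — `t1` of the monosynaptic window derived
   below — must fall between 1.0 and 4.5 ms after the spike.
3. **Kinetics.** The 10-90% rise time from onset to the window peak must be
   below 2 ms.

The corrected-STA **peak amplitude** is reported relative to the STA value
at the onset `t1` rather than relative to zero. The jittered STA retains a
smeared copy of the event (roughly `integral(kernel)/16 ms` of its mass), so
a peak measured against zero would systematically under-estimate the
effective connection strength; measuring against the onset cancels that
smear, and on synthetic pairs the peak then recovers
`mean amplitude x (1 - p_fail)` to within 15% for membrane noise up to 2 mV.

```{r sta, warning = FALSE}
syn <- synapse_cohort(1, seed = 42)
st <- tibble(cell_id = 1L, spike_time_s = sort(runif(800, 0.05, 79.9)))
rec <- synthesize_recording(st, syn, duration_s = 80, seed = 43)
fit <- sta_connection(extract_pair(rec, 1L), n_boot = 500, seed = 44)
glance(fit)
autoplot(fit)
```

## Labeling single-spike EPSPs

Not every presynaptic spike produces a visible somatic depolarization. The
binary detector (`detect_epsps()`) classifies each 0-6 ms post-spike trace
as a *detectable* or *undetectable* EPSP:

1. The pair's **monosynaptic window** `[t1, t2]` comes from the corrected
   STA: its derivative (first differences, smoothed by a 3-point average) is
   searched for its positive peak, and the window edges are found by
   marching out from that peak to the flanking derivative valleys. A valley
   is taken as the end of the contiguous positive-slope run (the first
   non-positive derivative sample). At 10 kHz a literal "first local
   minimum" rule trips over single-sample noise wiggles mid-rise; the
   zero-crossing form is robust and, on an ideal double-exponential EPSP,
   lands `t1` on the onset and `t2` on the EPSP peak exactly as intended.
2. Each trace is zeroed at the spike time, and the **same peak-and-valley
   search** runs on the trial derivative inside the window, giving refined
   per-trial bounds `t1'`, `t2'` and the amplitude `Vm(t2') - Vm(t1')`. The
   trial is smoothed with the same 3-point average before differentiating
   (`smooth_trial = TRUE` by default): raw sample-to-sample derivatives at
   10 kHz are dominated by recording noise and truncate the rise at the
   first wiggle, which would halve measured amplitudes. A derivative peak
   must also clear a prominence of one trace-derivative noise SD
   (`prom_sd`), which rejects micro-peaks in flat traces.
3. The amplitude must reach the pair's **threshold**: one SD above the mean
   of jittered-trace amplitudes (`jittered_trace_amplitudes()`), where the
   jittered amplitude is the mean Vm deviation across `[t1, t2]` — the same
   definition used for undetectable traces. The threshold is per-pair by
   default, as the connection strengths span an order of magnitude; a fixed
   global threshold can be supplied instead.

Undetectable traces get the window-mean amplitude, so their distribution
matches the alignment-free fluctuation distribution when no event is
present. One caveat worth knowing: for very reliable, very strong synapses
the jittered traces often contain the pair's own EPSP (for a 0-16 ms jitter
roughly a third of windows are contaminated regardless of firing rate),
which inflates the threshold for precisely those pairs where detection is
easiest. An optional audit (`audit_detections()`) flags detectable labels
whose refined window lacks a sustained positive-slope run, mirroring the
manual correction of occasional noise-driven detections; it is off by
default because the smoothed detector meets its ground-truth recovery
targets without it.

Detection is deterministic given the window and threshold; randomness enters
only through the seeded jittered threshold.

## Reliability, variability and short-term plasticity

`summarize_pair()` aggregates detections into the per-connection statistics:
percent undetectable, category amplitude means, and the noise-corrected
coefficient of variation

CV = sqrt(|var(all) - var(jittered)|) / mean(all),

which subtracts the variance of intrinsic Vm fluctuations from the measured
amplitude variance. The absolute value keeps the expression defined when
sampling noise makes the difference negative; in that regime the CV should
be read as "at or below the noise floor". `population_correlations()`
computes the standard cross-pair Pearson correlations (percent-undetectable
vs amplitude, CV vs amplitude, with and without undetectable events), and
`cell_class_contrast()` / `epoch_contrast()` run the RS-vs-FS and
stimulus-epoch comparisons on input metadata labels — cell class is never
inferred from the data.

Short-term plasticity (`stsp_analysis()`) splits single-spike amplitudes by
the preceding ISI at 50 ms (about the median ISI at these firing rates) and
quantifies the percent change of the short-ISI mean relative to the long-ISI
mean; `isi_binned_sta()` gives the finer amplitude-vs-ISI curve. A pair is
classified depressing (STSD) or facilitating (STSF) when the two-sample KS
test on the amplitude distributions is significant at alpha = 0.05; the
t-test is always reported alongside, and the detectable-vs-undetectable ISI
distributions are tested the same way (depressing synapses fail more after
short intervals). No multiplicity correction is applied across pairs by
default, matching standard practice for these per-synapse characterizations;
a Benjamini-Hochberg adjustment can be applied to the returned p-values if
desired.

```{r stsp, warning = FALSE}
det <- detect_epsps(extract_pair(rec, 1L), fit = fit, seed = 45)
summarize_pair(det)
stsp_analysis(det)
```

## The leaky integrate-and-fire model

`simulate_lif()` implements a conductance-driven point neuron for a layer-4
simple cell: rest -65 mV, threshold -55 mV, reset -60 mV, 2 ms refractory
period, input resistance 47 MOhm, membrane time constant 6 ms, forward-Euler
integration at 0.1 ms. Each presynaptic spike injects an EPSG — a
difference of exponentials with 0.5 ms rise and 2 ms decay, unit peak,
truncated at ten decay constants — scaled by the synapse's drawn amplitude,
and the total conductance drives current `g (E_exc - Vm)` with an AMPA-like
0 mV reversal (the driving-force form is the package's choice; the
literature also uses fixed-driving-force injection). Halving the step to
0.05 ms changes the firing rate by under 1%, and the integrator matches the
closed-form steady state `(v_rest + Rg E) / (1 + Rg)` to numerical
precision.

`assign_synapses()` draws per-synapse triplets in nS, normalized so the
mean EPSG across inputs is 0.89 nS. The model's amplitude CV defaults to
about 0.85 — the breadth of the *measured* single-spike amplitude
distribution that the in vivo characterization feeds into the model — which
is deliberately wider than the noise-corrected transmitted-event CV (~0.3)
used when synthesizing membrane traces; measured amplitudes carry the
membrane noise with them, and it is the measured distribution the model
injects.

Two model variants are compared at **equal mean drive**
(`calibrate_equal_drive()`): *reliable* synapses transmit every spike at the
constant amplitude `mean x (1 - p_fail)`, while *unreliable* synapses fail
with probability `p_fail` and draw log-normal amplitudes — so the expected
injected conductance is identical and any output difference is due to
fluctuations. An `event_mean` calibration (reliable amplitude = event mean)
is available as a switch; it injects ~60% more conductance and depolarizes
the cell about 1 mV further, which is exactly the confound equal-drive
removes. Both models operate in the fluctuation-driven (high-conductance
style) regime: the mean subthreshold Vm stays several millivolts below
threshold even with 50 inputs, and spikes are triggered by Vm fluctuations.
Unreliable synapses produce larger Vm SD and a several-fold higher firing
rate; `sweep_inputs()` traces both statistics against the number of inputs,
and the firing rate is a monotone function of Vm SD across that sweep. With
the default synthetic LGN drive the reliable model fires near 2 Hz and the
unreliable model near 5 Hz at 50 inputs.

Two subtleties in the comparison are worth stating. First, the trial-to-trial
variability of the mean Vm is tiny (~0.03 mV) because all trials share the
presynaptic trains, while the driving-force covariance and spike resets
leave a real but small (~0.2 mV) systematic offset between the models; the
package's tests therefore check *equivalence within 0.25 mV* — about 6% of
the depolarization — rather than exact equality, which is the resolution at
which "depolarized equally" is meaningful here. Second, rank correlations
between rate and Vm SD are evaluated across the input-count sweep, where
both quantities vary over a wide range, not within a cluster of same-size
runs.

Further variants: `unreliable_const_amp` (failures but constant amplitude)
lands between the reliable and fully unreliable models, showing that
amplitude variability contributes more than failures per se;
`correlated_failure` boosts the failure probability of spikes coincident
(within 5 ms, configurable) with spikes of other inputs, rescaled to
preserve the marginal failure rate — when nearly every spike has a
coincident partner the boost saturates and the variant degrades gracefully
toward the random model; `stsd = TRUE` applies the measured short-term
depression to event amplitudes and leaves the reliable-vs-unreliable
ordering unchanged; and a balanced Ornstein-Uhlenbeck background
conductance (`background =`) reproduces the comparison in an explicit
high-conductance state. `reverse_correlation_rf()` recovers the model cell's
spatiotemporal RF from the stimulus and subthreshold Vm; its strongest lag
sits at the LGN temporal-kernel peak (~3 frames, about 50-70 ms with the
synaptic and membrane delays).

```{r lif}
stim <- wn_stimulus(n_blocks = 5, seed = 2)
cells <- lgn_population(50, seed = 3)
trains <- simulate_lgn_spikes(stim, cells, seed = 4)
specs <- assign_synapses(50, seed = 5)
cmp <- compare_reliability(trains, specs,
                           lif_params(duration_s = stim$duration_s),
                           n_trials = 3, seed = 6)
cmp %>% group_by(mode) %>%
  summarise(rate_hz = mean(rate_hz), vm_mean = mean(vm_mean),
            vm_sd = mean(vm_sd))
```

## Numerical choices and degenerate inputs

* Time is in seconds from recording start; analysis windows are expressed in
  ms; windows are half-open on deposit (`[t, t + w)`).
* Spikes whose full STA window would leave the trace are dropped, not
  padded; the count is recorded on the fit.
* A corrected STA with no positive derivative peak in 0-6 ms raises a typed
  rejection (`tc_no_peak`); flat traces, empty spike tables, sub-kHz
  sampling rates, and NaNs in trials are all refused with explicit errors.
* Zero-variance jittered amplitudes make the threshold equal their mean,
  with a warning; pairs without detectable events get `NA` for the
  detectable-only CV, with a warning.
* Bootstrap, jitter draws, failure draws and amplitude draws all consume
  explicitly passed seeds; identical seeds reproduce recordings and
  simulations bit-for-bit.
* Vm traces are serialized as plain-text CSV with a commented header
  carrying the sampling rate and units; 33 kHz acquisitions are resampled to
  10 kHz with a zero-phase FIR anti-alias filter (unit DC gain, mirrored
  edge padding) followed by interpolation.

## Problem sizes used in the test suite

The shipped tests exercise the estimators at desk scale: cohorts of 36
synthetic pairs with ~1000-2000 spikes each for detector and STSP recovery,
100 unconnected pairs for false-positive control, 500 non-plastic pairs for
the STSP type-I rate, and ten 89 s LIF trials per synapse model (plus an
input-count sweep) for the reliability comparison. These sizes give the
statistical resolution the checks need — binomial confidence intervals a
few percentage points wide, type-I estimates with ~1% standard error —
while a full run of the suite stays in the tens of minutes on one core.

## Known limitations

* Reliability here is *detectability at the soma*: the pipeline cannot
  separate vesicular release failure from dendritic attenuation or
  coincident inhibition, and does not attempt quantal (binomial N/p/q)
  fitting.
* The per-pair threshold couples weakly to connection strength through
  jittered-trace contamination (see above), a property shared by any
  jitter-based noise estimate at these firing rates.
* The LNP stand-in lacks the precise temporal structure of real relay-cell
  trains; absolute model firing rates depend on its calibration, so the
  reliable-vs-unreliable comparison should be read as a controlled contrast,
  not a rate prediction.
* The feedforward model has no intracortical recurrence, inhibition (beyond
  the optional background), or dendrites.
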