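# dpteflow

Directed phase transfer entropy (dPTE) connectivity between cortical
parcels, with a permutation-calibrated mixed-model comparison for detecting
condition-related changes in directed flow.

## What problem this solves

In attention research, alpha-band (8–13 Hz) activity is thought to route
information: task-irrelevant sensory regions are inhibited through local
alpha power increases, and directed alpha connectivity from higher-order
(parietal/motor) hubs to task-relevant sensory cortices weakens when a task
engages those cortices. Testing this requires (i) a *directed* spectral
connectivity measure on source/parcel time series, (ii) a statistical
engine that can compare thousands of connections across conditions with
proper multiplicity control, and (iii) targeted post-hoc models linking
directed flow to local power trial by trial. `dpteflow` provides all three
for anyone working with epoched, parcel-level MEG/EEG-like time series,
plus a synthetic cohort generator with known directed coupling so the whole
chain can be validated against ground truth.

## The measure and the statistics

Phase transfer entropy between discretized instantaneous phases (delay
`d`, entropies in bits from within-epoch histograms):

    PTE(x→y) = H(y_t, y_{t−d}) + H(y_{t−d}, x_{t−d}) − H(y_{t−d}) − H(y_t, y_{t−d}, x_{t−d})
    dPTE(x→y) = PTE(x→y) / (PTE(x→y) + PTE(y→x))   ∈ [0, 1],  0.5 = no preferred direction

Phase comes from a zero-mean complex Morlet wavelet per band (theta 4–8 Hz /
3 cycles, low alpha 8–10 / 5, high alpha 10–13 / 5, beta 13–30 / 7, gamma
31–48 / 9). The delay is `round(N·S/X0)` (N valid samples, S signals, X0
sign changes of the band-limited signal) and the bin count is
`round(exp(0.626 + 0.4·ln(N−1)))`.

For every connection, each epoch's dPTE is one data point in a ladder of
three maximum-likelihood mixed models with a participant random intercept —
intercept-only, rest-vs-task, full condition factor — compared by AIC. The
AIC-delta significance thresholds are calibrated by shuffling condition
labels within participants, keeping each connection's largest permuted
reduction, and taking the upper 0.025 quantile of those maxima across all
connections (max-statistic familywise control). Post-hoc tools summarize a
hub's zero-centred outflow, model `log power ~ flow × condition`, and run a
condition-vs-power AIC comparison to rule out SNR artefacts.

## Worked example

Six parcels; parcels 1–2 form a "hub" driving sensory parcels 5 and 6 with
gain 0.8; the 1→5 edge collapses (×0.1) in the audio condition and the
2→6 edge in the visual condition:

```r
library(dpteflow)

net <- make_network(
  6,
  edges = data.frame(from = c(1, 2), to = c(5, 6), lag = 9, gain = c(0.8, 0.8)),
  condition_gains = list(rest = 1, audio = c(0.1, 1), visual = c(1, 0.1)),
  power_coupling = 0.5)
spec <- cohort_spec(n_participants = 6, conditions = c("rest", "audio", "visual"),
                    epochs_per_condition = 20, seed = 7)
cohort <- generate_cohort(net, spec)

conn <- cohort_connections(cohort, spec$band)   # phase + per-epoch dPTE
fits <- fit_all_ladders(conn$table)             # null / simple / full AICs
thr  <- permutation_thresholds(conn$table, n_perm = 100, seed = 7)
cls  <- classify_connections(fits, thr)
cls[cls$class != "null", c("pair", "delta_simple", "delta_full", "class")]
#>   pair delta_simple delta_full     class
#> 4  1-5     11.58688   38.19408 full_task
#> 9  2-6     12.47353   51.23255 full_task

hub_summary(conn$table, hub = 1:2, n_parcels = 6)$model[, c("term", "estimate", "lower", "upper")]
#>              term estimate   lower   upper
#> 1     (Intercept)   0.1465  0.0985  0.1945
#> 2  conditionaudio  -0.0432 -0.1111  0.0247
#> 3 conditionvisual  -0.0798 -0.1477 -0.0119
```

Reading the output: out of all 15 connections, exactly the two planted
condition-modulated edges are classified `full_task` — their AIC drops
(38.2 and 51.2) clear the permutation threshold (12.8), and the full model
wins because the gain change is condition-specific, not a uniform task
effect. The hub summary shows net resting outflow (total zero-centred dPTE
0.147) that decreases under both tasks. `run_pipeline(run_config(...))`
wraps these stages, writes stamped TSV/JSON outputs, and adds the
flow-power and SNR-confound models when a hub and destinations are
configured.

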