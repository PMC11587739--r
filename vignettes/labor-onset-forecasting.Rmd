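---
title: "Forecasting labor onset from continuous skin temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting labor onset from continuous skin temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The clinical estimated date of delivery (EDD, 280 days of gestational age)
misses the true day of birth by a week on average, and no routine tool says
whether an individual pregnancy will deliver on the early or late side of
the five-week "term" window. Across many mammal species, core and skin
temperature fall in the days before parturition, and the strength of the
circadian temperature rhythm declines with it. `thermolabor` implements an
analysis pipeline built on that observation for humans wearing a smart
ring that records finger skin temperature once per minute: it extracts
daily temperature patterns, relates them to urinary hormone trajectories,
and trains a deep sequence model that outputs, every day, an estimate of
the number of days remaining until spontaneous labor onset, together with
a calibrated calendar window around that estimate.

Because raw cohorts of this kind are not publicly distributable, the
package is organised around a synthetic-data module that generates
cohorts carrying the same statistical structure the analysis assumes. All
downstream stages are exercised and validated against these synthetic
cohorts; the sections below say exactly what that does and does not
establish.

## The synthetic cohort generator

`generateCohort()` draws, for each participant, a per-minute temperature
series from gestational day 240 (the study's input window) to a labor
onset day sampled from a truncated normal: mean 279.3 d (39.9 wk), SD
7.7 d (1.1 wk), truncated to 261.8–293.3 d for spontaneous labors, and
mean 276.5 d, SD 8.4 d, truncated to 252.7–288.4 d for induced or
pre-labor cesarean deliveries. The deterministic part of the signal is

* a per-participant baseline (mean 35.5 °C, SD 0.3 °C across
  participants) plus a slow gestational warming trend (0.01 °C/day);
* a 24-h cosine with amplitude 0.35 °C by default and acrophase at 03:00
  local time (distal skin temperature peaks during sleep); over the final
  10 days before spontaneous labor the amplitude shrinks linearly at
  `circadianDampingRate` per day (default 0.05/day, i.e. half the
  amplitude is lost by the onset day) — the source data show declining
  circadian power without committing to a functional form, so linear
  damping is the simplest choice consistent with it;
* a linear pre-labor decline totalling 0.44 °C across the final 7 days
  (spontaneous labors only), matching the reported spontaneous-versus-
  induced temperature difference of 0.44 ± 0.08 °C;
* a constant +0.44 °C level offset for non-spontaneous pregnancies.

White Gaussian noise (default SD 0.25 °C, the scale of minute-level finger
temperature jitter) is added on top. Non-wear is simulated as a Poisson
number of gaps per day (default 1/day) with exponential lengths (mean
60 min) aligned to 5-minute epochs; during non-wear the ring keeps
recording ambient-contaminated values (~28 °C), which is why removal must
use the activity labels rather than a range rule, and a small fraction of
minutes (2%) is missing outright. Every participant also receives a
10-day urinary hormone panel (E1, E2, E3, α- and β-pregnanediol,
cortisol, melatonin) with multiplicative log-normal noise at a 12% CV —
the scale of the reported inter-assay CVs (7.4–14.9%) — in which
α-pregnanediol declines by 40% across the window for spontaneous labors
and the E3:αPg ratio is elevated two-fold relative to induced
pregnancies.

By default induced participants carry *no* intrinsic pre-labor signature
(their series is baseline + trend + rhythm + offset). Setting
`inducedIntrinsicDelay` to a finite value instead makes them interrupted
spontaneous trajectories whose intrinsic labor day falls an
exponentially-distributed number of days after the induction date; the
late-skew evaluation uses this mode, since an induction that interrupts a
pregnancy before its physiological endpoint is precisely the hypothesis
being probed.

Reproducibility is strict: per-participant seeds are derived by integer
mixing of (master seed, participant index), so the same configuration and
seed yield byte-identical cohorts regardless of generation order.

What the generator does *not* emulate: thermoregulatory physiology (no
ODEs, no sleep architecture, no fever events), ultradian rhythms,
behavioural confounds (showers, exercise), assay drift, or any real
between-participant heterogeneity beyond baseline level and labor-day
variation. Tests passing on these cohorts therefore demonstrate that the
pipeline recovers the structure it assumes when that structure is
present — parameter recovery and calibration — not that real pregnancies
carry signals of this strength.

## Preprocessing

`preprocessParticipant()` mirrors the study's cleaning order: average
minutes into 5-minute epochs (out-of-range readings beyond 20–45 °C are
treated as missing first); blank epochs labeled non-wear; compute data
density as the fraction of expected epochs observed — *before* any
interpolation; segment into 24-h civil days starting at 10:00 local
clock time (288 slots of 5 min), dropping partial leading/trailing days;
apply the inclusion filters; and finally fill gaps by linear
interpolation across day boundaries, extending flat at the series edges.

Decisions worth making explicit:

* Exclusion thresholds are strict less-than ("fewer than 21 contiguous
  days", "less than 75% density"), so a participant at exactly 21 days
  and 0.75 density is included.
* "Contiguous days" is not defined numerically in the source; here it is
  the longest run of consecutive days each with at least 50% of epochs
  observed. The 50% per-day floor is configurable.
* Density is computed at epoch level; a day-level definition is arguably
  admissible but epoch level is finer-grained and monotone in the same
  quantity.
* Day boundaries follow civil clock labels, so daylight-saving
  transitions keep days aligned at 10:00 rather than drifting by an hour.

## Circadian rhythm analysis

`morseWaveletPower()` computes a continuous wavelet transform with the
generalized Morse mother wavelet, evaluated in the frequency domain as
a(β,γ)·ω^β·e^(−ω^γ) on the positive frequencies (an analytic wavelet),
peak-normalized so a unit-amplitude cosine at the wavelet's center period
gives unit transform magnitude — hence band power scales exactly with
amplitude squared, which the tests assert. Shape defaults are β = 5,
γ = 3: a low oscillation count that favours detecting transitions over
frequency resolution. The period grid is log-spaced at 32 voices per
octave over 2–48 h; the source cites toolbox code without a grid, and 32
voices is the conventional density at which ridge location errors are
below 2.2%. Circadian power is the mean of the power surface over grid
periods in the 23–25 h band at each time point; "power per minute" is
read as a units convention, not a resampling mandate, and the band
average is computed on the 5-minute series. No cone-of-influence
correction is applied; edge effects inflate the first and last ~day of
the power series symmetrically and do not change trend directions on
multi-week windows.

Trend labels for the temperature–hormone comparison use the OLS slope of
the 72-h centered moving average over the last 10 days; a slope exactly
zero is grouped with "no trend/upward", matching the grouping used in the
source analysis. `mannKendall()` returns S, τ and a two-sided p-value —
exact (by the inversion-count recursion over all permutations) for
tie-free series up to n = 10, normal approximation with tie and
continuity corrections otherwise. Friedman tests compare two groups' mean
series blocked by time point; Kruskal–Wallis tests compare
per-participant means, both via the standard `stats` implementations.

## Hormone panels

`preparePanel()` drops panels with at most one sampling day (as the
source did for its two such cases), removes analytes observed on fewer
than two days, interpolates linearly onto the daily grid −10..−1 with
flat edge extension, and min–max normalizes each analyte to [0, 1]. The
source says only "normalized"; min–max is chosen (z-scores would put
different participants on incomparable scales for the group-mean plots)
and the choice is configurable in spirit: the prepared object retains the
raw grid, and the E3:αPg ratio is always computed on raw concentrations,
because a ratio of independently rescaled quantities would be
meaningless. "The week prior" is days −7..−1 inclusive throughout.

## The model

The forecaster is a two-stage network trained by staged optimization,
implemented in this package as plain batched matrix algebra (the
environment provides no deep-learning framework, and the model *is* the
contribution, so forward and backward passes are hand-derived and
gradient-checked against numerical differentiation in the test suite).

**Autoencoder.** Each day is a 288-vector in °C, centered by the
participant's training-period mean. The encoder is three blocks of 1-D
convolution (kernel width 5; 64, 32, 16 filters; ReLU) each followed by
stride-2 max pooling (288 → 144 → 72 → 36), a flatten (36 × 16 = 576) and
a linear projection to a 64-dimensional latent code. The decoder mirrors
it with ×2 up-sampling in place of pooling and a final linear
convolution back to one channel. The filter counts are not documented in
the source; 64/32/16 with kernel 5 is the natural three-block geometry
that reconstructs 288 exactly. Training minimizes mean absolute
reconstruction error (reported in °C — centering is a shift, so the scale
is unchanged) with Adam at learning rate 10⁻³, batch 64, early stopping
on a held-out 10% with patience 10. Days from all participants are
treated as independent observations.

**Sequence model.** Latent day codes are consumed by an LSTM with 128
tanh units behind a masking layer, followed by layer normalization, a
128-unit linear dense layer and a scalar head. Masking is implemented by
carrying state and ignoring loss wherever the mask is zero, so zero
padding of any length, before or after the content, provably cannot
change valid outputs (asserted exactly in tests). Training is
sequence-to-sequence: the head is applied to the hidden state after every
consumed day, giving the prediction for the next day, and the MAE over
all valid steps is minimized — mathematically identical to predicting
once per prefix, because the recurrence is causal (also asserted by
perturbing future days), at a twentieth of the cost. Targets are
y_k = (labor day) − k, not clipped, so predictions may go negative past
the due date, which the window outcome semantics require. The first
prediction day is the day after the first observed day, since the model
conditions on strictly-past days only.

The autoencoder is trained first and frozen; each cross-validation fold
trains its own autoencoder on the training fold only, which is stricter
about subject-wise separation than the source's description and can only
cost, never inflate, reported performance.

## Calibrated windows and clinical accounting

Cross-validated signed errors e = y − ŷ at a fixed days-to-labor T are
pooled into a kernel density estimate (Gaussian kernel, Silverman
bandwidth — undocumented in the source; Shapiro–Wilk normality p is
recorded alongside). The window at coverage P is equal-tailed: each tail
outside (−ε₁, ε₂) holds (1−P)/2 of the KDE mass, which reduces to
symmetric bounds for symmetric error distributions; a shortest-interval
mode would be a drop-in alternative but is harder to reason about
clinically. The window is [ŷ − ε₁, ŷ + ε₂] in days from the prediction,
closed at both edges: labor exactly on an edge counts as a true positive.
Labor after the window is a false positive (prediction too early),
measured from the right edge; labor before the window is a false negative,
measured from the left edge. (The source's edge-convention sentence pairs
"FP" with the right edge and then says "TP" where "FN" is plainly meant;
the implementation uses FP→right, FN→left.) Outcome percentages are
reported to one decimal with ordinary rounding, which is what the
source's own printed tables do despite an apparent truncation in one
cell. Coverage calibration — the empirical rate at which fresh errors
drawn from the same distribution fall inside W(P) — is asserted within
±3 points of P at n = 1000 for P ∈ {0.7, 0.8, 0.9, 0.95}.

## Validation experiments and problem sizes

The standing validation (`recoveryExperiment()`) generates a
30-participant spontaneous cohort at low noise (SD 0.05 °C), amplitude
0.5 °C, damping 0.09/day and the 0.44 °C drop, preprocesses it, holds out
6 participants subject-wise, and trains with 20 autoencoder epochs on a
400-day subsample and 150 LSTM epochs — sizes chosen so one run takes
about two minutes on a single CPU while leaving the architecture at full
default dimensions. Success is held-out Spearman ≥ 0.8 between predicted
and true days-to-labor over the final 14 days and a final-week mean
signed error within ±2 days, over three independent seeds. The trained
model is reused for the ablation ordering check (flatlining the last 5
input days must degrade final-week MAE more than flatlining the first 10)
and for the induced-cohort late-skew check. The qualitative
trend/group-pattern checks run the wavelet and hormone stages on
default-noise cohorts of the hormone-subset size (18 spontaneous vs 10
induced).

## Known limitations

* Synthetic validation shows recovery of assumed structure, not clinical
  performance; headline accuracies from the motivating study are not
  reproducible without its private cohort and are not claimed.
* The LSTM stage is trained full-batch without regularization beyond
  early stopping and staged freezing; on noisy real data dropout and
  weight decay (accepted by the config but off by default) would matter.
* The wavelet surface carries no significance contours or
  cone-of-influence masking.
* Single-timezone timestamps are assumed; day segmentation handles DST
  by clock labels but true timezone-crossing travel is out of scope.
* Hormone values are taken as already creatinine-normalized; assay
  chemistry is out of scope.
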