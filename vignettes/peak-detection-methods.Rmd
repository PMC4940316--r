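---
title: "Time-domain EEG peak detection with an extreme learning machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain EEG peak detection with an extreme learning machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakelm)
```

## The problem

Event-related peaks in a single-channel EEG trace — here, the deflection that
accompanies a commanded horizontal eye movement — must be told apart from the
innumerable local maxima that baseline drift and residual noise produce in
any sampled recording. The classical time-domain approach proceeds in three
stages: screen the signal for *candidate* peaks (cheap, high-recall), reduce
each candidate to a small vector of amplitude/width/slope features, and hand
the feature vectors to a trained classifier. `peakelm` implements that
pipeline with a single-hidden-layer extreme learning machine (ELM) as the
classifier and four published *peak models* — feature subsets named after
Dumpala, Dingle, Acir and Liu — evaluated under one common protocol.

## Candidate detection

A candidate peak point `PP` is any interior sample strictly greater than both
neighbours (the three-point sliding window test); its flanking valley points
`VP1` and `VP2` are the nearest interior samples strictly smaller than both
neighbours on each side. Two practical rules sit on top of the bare
definition:

* **Plateau collapse.** Quantised signals contain runs of equal samples that
  break strict inequalities. Runs are collapsed to their first index before
  the three-point test, so a flat-topped peak yields exactly one candidate
  and maxima/minima strictly alternate.
* **Boundary valleys.** A maximum whose half wave runs into the signal edge
  without crossing an interior minimum may use the boundary sample as its
  valley when that sample does not exceed the peak (configurable off). Short
  test records frequently begin or end mid-slope, and discarding such maxima
  would silently drop real peaks; dropped maxima are counted and reported.

An optional Billauer-style prominence threshold `delta` can suppress shallow
maxima before feature extraction. Its default is 0 (disabled): the reference
protocol describes the pure three-point test, and the classifier — not the
detector — is responsible for rejecting noise candidates.

## The eight points and sixteen features

Each candidate is characterised by eight points: `PP`, `VP1`, `VP2`, the half
points `HP1`/`HP2` at the index midpoint of each half wave (`.5` midpoints
round toward the peak), the turning points `TP1`/`TP2`, and the value of the
moving-average curve (MAC) at the peak index. The turning point is found by
walking from the peak toward the valley and firing at the first one-sample
step whose slope magnitude falls to *strictly less than half* of the
preceding step's; if no step qualifies the valley itself is the fallback.
Walking outward from the peak reads "preceding" as "nearer the peak" and
guarantees the degenerate case `TP = PP` cannot arise.

The MAC is a centered moving mean with a 100-sample window (about 390 ms at
256 Hz). Near the boundaries the window is truncated to the samples that
exist, so a window longer than the record reduces to the global mean; a
trailing variant is available but the centered form matches the intended
phase-free baseline under the peak.

From these points come 16 features: amplitudes f1–f5 (peak against each
valley, each turning point, and the MAC), widths f6–f12 in samples (full
width, half-wave widths, turning-point and half-point spans) and slopes
f13–f16 (peak-to-valley and peak-to-turning-point). All are absolute values,
hence non-negative; f6 = f7 + f8 exactly; all 16 are invariant under adding a
constant to the signal, and amplitude scaling by `c > 0` scales amplitudes
and slopes by `c` while leaving widths untouched — properties the test suite
checks on random signals. Widths stay in samples; millisecond conversion is
presentation, not computation.

The peak models are fixed subsets: Dumpala (f1, f6, f13, f14), Dingle
(f5, f6, f13, f14), Acir (f1, f2, f7, f8, f13, f14), Liu (f1, f2, f3, f4,
f6, f9, f12, f13, f14, f15, f16), plus `all16`.

## The classifier

The ELM is a single-hidden-layer feedforward network whose input weights
(uniform on [−1, 1]) and hidden biases (uniform on [0, 1]) are drawn once and
never trained. With hidden output `H[n, j] = g(a_j · x_n + b_j)`, the output
weights solve the linear system `H β = T` in one shot as the minimum-norm
least-squares solution `β = H⁺ T`. Defaults follow the reference settings:
500 hidden neurons, bipolar sigmoid (tanh — the stated [−1, 1] range) in the
hidden layer, linear output neurons, two output classes with one-hot {1, 0}
targets, and the predicted label taken as the arg-max output neuron.

Numerical choices the closed form leaves open:

* **Pseudo-inverse.** `H⁺` is computed by SVD with singular values below
  `1e-10` of the largest treated as zero. The textbook normal-equations form
  `(HᵀH)⁻¹Hᵀ` fails outright on rank-deficient `H`; the SVD route returns
  the same answer on well-conditioned systems (asserted to `1e-8` relative
  in the tests) and the minimum-norm solution otherwise.
* **Feature scaling.** Features are min–max scaled to [0, 1] using
  *training-set* extrema; test features reuse those extrema and are clipped
  to [0, 1]. A constant training feature maps to 0. Some normalisation is
  clearly intended by the protocol but no scheme is fixed there; min–max is
  the simplest choice compatible with the sigmoid's sensitive range, and the
  train-only extrema keep the test phase leak-free.
* **Ties.** Equal output scores resolve to the non-peak class, making
  prediction deterministic.
* **Imbalance.** Candidates outnumber annotated peaks by orders of
  magnitude. The reference protocol does nothing about this and neither does
  the default here; `train_elm()` accepts optional per-sample weights and
  the experiment configuration exposes `balance_classes` for exploration.

When the hidden layer has at least as many neurons as there are distinct
training samples, the least-squares fit interpolates the targets and training
G_mean reaches exactly 1 — the test suite exercises this interpolation
property directly.

## Evaluation protocol

Candidates are labelled against the annotations by a matching rule: a
candidate is a true peak when its index lies within `tolerance` samples of an
annotated location, each annotation claiming at most one candidate (nearest,
ties to the earlier). The default tolerance of 5 samples (~20 ms at 256 Hz)
is a package choice — no matching rule is stated in the reference protocol —
and is configurable.

Performance is the geometric mean `G_mean = sqrt(TPR × TNR)` of the
true-peak and true-non-peak rates, which collapses to 0 whenever the rare
peak class is entirely missed, however good the non-peak accuracy — exactly
the failure mode plain accuracy hides under imbalance. Sensitivity and
specificity are reported as percentages alongside. Multi-run summaries give
average, maximum, minimum and the sample (n−1) standard deviation.

Experiments run `runs` times with fresh random input weights per run (run
`r` seeds its draw with `seed + r`, so the whole sweep is reproducible while
runs stay independent); the collection of signals is split across its
ordering, first `ceiling(n/2)` to training. The split is per-collection, not
within signals: every recording holds exactly one annotated peak, and
splitting a record in half would strand its peak on one side. This reading
of the 50/50 protocol is a deliberate design decision and is flagged here
because the opposite reading is conceivable.

Model comparison uses the Friedman rank test on the runs × models matrix of
test G_means (rank 1 = best within each run, ties averaged), with the
uncorrected chi-square statistic `12N/(k(k+1)) Σ R̄_j² − 3N(k+1)` — the form
rank-based comparison suites print — so a totally tied matrix gives
statistic 0 and p = 1 rather than 0/0. Post-hoc pairwise p-values come from
paired Wilcoxon signed-rank tests over runs (normal approximation; a pair
identical in every run gets p = 1), stepped down through Holm–Bonferroni
thresholds `α/(k − i + 1)` at both α = 0.05 and α = 0.10. Wilcoxon-feeding-
Holm is itself a documented choice: it is the standard companion to the
Friedman test in comparison software, but the protocol names only the
software, not the test.

## The synthetic corpus

No recordings ship with the package; the generator emulates the corpus the
protocol describes: 40 signals (20 per channel label), 10 s at 256 Hz
(2560 samples), exactly one annotated peak each. A signal is built as

* slow sinusoidal baseline drift (amplitude 1, frequency drawn from
  0.1–0.5 Hz) — the wandering baseline of a slow cortical recording;
* Gaussian noise smoothed by a 9-sample (~35 ms) moving average and rescaled
  to `noise_sd` — the corpus is described as already filtered, and raw white
  noise at 256 Hz would be far rougher than any filtered EEG;
* one asymmetric peak: two truncated half-Gaussians of independent widths
  meeting at a sharp apex, total width drawn from 20–70 ms, amplitude from
  5–10 (unit-free, as the original amplitude units are unstated), asymmetry
  ratio from 0.5–2, at a uniform location leaving a margin of at least one
  peak width. Each half ends in a slight (~0.4 % of amplitude) undershoot,
  so the flanking valleys sit exactly at the drawn half-widths: on noiseless
  signals the realised f6 equals the drawn width, which the tests assert.

`noise_sd` defaults to 0.2, calibrated to the separability requirement that
annotated peak amplitudes be at least five times the amplitude of any
noise-induced local maximum: across 2560 samples the largest excursion of
the smoothed noise is about five of its standard deviations, so noise-born
candidates stay below 1 amplitude unit against a minimum peak amplitude
of 5. Every draw is deterministic given `(seed, index)`.

What the generator does **not** emulate: rhythmic EEG bands, blink and
muscle artifacts, inter-subject feature variability, or any correlation
between channels. Performance on this corpus therefore bounds what the
pipeline can do when its assumptions hold; it does not predict performance
on real recordings, where reported test accuracies for these models are far
lower than on separable synthetic data. The acceptance checks are
property-based for exactly this reason: they verify the machinery
(definitions, closed forms, statistics, recovery under separability and
monotone degradation under noise), not the irreplicable corpus numbers.

## Problem sizes and degenerate inputs

The shipped experiments use the 40-signal corpus with 10 runs per model —
enough for stable rank statistics while keeping the full sweep to a couple
of minutes on one CPU; `runs = 30` reproduces the reference protocol when
more time is available. Degenerate inputs are handled explicitly: signals
shorter than 3 samples, empty datasets, non-positive dimensions and
out-of-range annotations raise errors; a single-run summary warns and
reports a standard deviation of 0; maxima without flanking valleys are
dropped with a count rather than an error. Indices are 1-based everywhere,
including annotation files (stated in their header comment).

## Known limitations

* Candidate labelling depends on the matching tolerance; annotations denser
  than the tolerance window would need a cost-based assignment, not the
  greedy nearest rule.
* The uncorrected Friedman statistic is conservative under heavy ties
  (frequent when several models saturate near G_mean = 1).
* ELM performance under extreme class imbalance is poor by design fidelity:
  the closed-form fit weighs every candidate equally, so the rare peak class
  contributes almost nothing to the objective. `balance_classes` mitigates
  this but departs from the reference protocol.
* The pipeline is offline: candidates, features and the MAC are computed on
  complete records, not streamed.
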