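---
title: "Phase-synchrony connectivity and SOM anomaly detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchrony connectivity and SOM anomaly detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery behind **phasesom**: how
multichannel EEG is reduced to per-band phase-synchrony connectivity
matrices, how a one-class self-organizing-map (SOM) detector turns those
matrices into an anomaly score, and how the pipeline is validated. It also
records the design decisions that were genuinely open, and what the
synthetic cohort generator does and does not emulate.

## The problem

Two-group EEG studies (here: control children vs children with
developmental dyslexia listening to amplitude-modulated noise) often have
small, imbalanced cohorts and large between-subject variability. Instead of
fitting a discriminative classifier to both groups, the method models
*only* the majority (control) group and treats the minority group as
anomalies: a control-trained vector quantizer represents control
connectivity patterns well and anomalous patterns poorly, so its
quantization error becomes the diagnostic score.

## From raw signal to phase synchrony

**Zero-phase band decomposition.** Phase estimates are meaningless if the
filters distort phase, so all filtering is linear-phase FIR applied
forward and backward (`filter_zero_phase()`): the effective magnitude
response is squared and the net phase response is identically zero. IIR
filters are deliberately not offered. Filters are designed by closed-form
least squares (`design_fir_ls()`) for the five canonical bands (Delta
1.5–4, Theta 4–8, Alpha 8–13, Beta 13–30, Gamma 30–80 Hz), after a 50 Hz
FIR notch and an 80 Hz low-pass. Two defaults matter:

* *Transition width*: 25% of the band's lower edge on each side. This keeps
  the Delta filter realizable at typical EEG sampling rates while keeping
  adjacent bands nearly disjoint.
* *Filter length*: the next odd integer above
  `max(3 fs / f_lo, 3.3 fs / transition_width)`. The first term guarantees
  at least three cycles of the slowest passband component; the second ties
  the length to the requested transition so the least-squares fit has
  enough degrees of freedom — without it the passband ripple of the narrow
  low bands exceeds 5%, with it all five band filters sit within 0.5% of
  unit passband gain.

Each filtered recording carries an `edge_margin` of `n_taps` samples per
end; every phase statistic downstream excludes those samples, because
reflection padding only attenuates, never removes, edge transients.

**Instantaneous phase.** The analytic signal $z(t) = x(t) + i\,H\{x\}(t)$
is computed by FFT half-spectrum doubling; its angle is the instantaneous
phase $\phi(t)$, its magnitude the instantaneous amplitude. Phase is
undefined where $|z| = 0$; such samples are flagged `NA` with a warning
rather than silently assigned an angle.

**Synchrony measures.** For channels $x, y$ with phases
$\phi_x^t, \phi_y^t$:

* Phase locking value:
  $\mathrm{PLV} = \left|\tfrac1n \sum_t e^{i(\phi_x^t - \phi_y^t)}\right|$,
  the resultant length of the phase-difference phasor.
* Circular correlation:
  $r_c = \frac{\sum_t \sin(\phi_x^t - \bar\phi_x)\sin(\phi_y^t - \bar\phi_y)}
  {\sqrt{\sum_t \sin^2(\phi_x^t - \bar\phi_x)\sum_t \sin^2(\phi_y^t - \bar\phi_y)}}$,
  with circular means $\bar\phi$ computed via the four-quadrant
  arctangent (a single-argument arctangent is quadrant-ambiguous).

PLV measures the *consistency* of the phase difference; circular
correlation measures the *co-variation* of phase deviations, which is less
prone to calling two merely phase-stable channels "connected". Both are
invariant to constant phase offsets. The connectivity matrix stores
$|r_c|$ (so entries live in $[0,1]$) and keeps the raw signed values
alongside, because the sign carries information; the default feature set
uses the absolute values. Connectivity is computed over the full trimmed
recording by default; an epoch-average mode (`window_s`) exists for
protocols where stationarity over minutes is implausible.

The feature vector of a matrix is its row-major upper triangle
(`connectivity_vector()`), giving $C(C-1)/2$ "connections"; the ordering is
fixed and round-trips through `connectivity_from_vector()`.

## One-class anomaly detection

**SOM.** `fit_som()` trains a 2-D lattice of prototype vectors by online
competitive learning: present a sample, find its best matching unit (BMU,
Euclidean; ties go to the lowest linear index), and move every unit toward
the sample with step
$\alpha(t)\, e^{-d_{grid}^2 / 2\sigma(t)^2}$, where both the learning rate
$\alpha$ and the neighbourhood width $\sigma$ decay exponentially.
Prototypes are initialized on the plane of the first two principal
components (deterministic; a $1\times1$ grid is the data mean), and the
presentation order is drawn from the stored seed, so training is
bit-reproducible. The inner loop is compiled (Rcpp) because
cross-validated permutation tests retrain the map tens of thousands of
times.

Schedule defaults: $\alpha_0 = 0.5$ decaying to $0.01$,
$\sigma_0 = \max(\text{grid})/2$ decaying to $0.5$ lattice spacings,
$500N$ presentations. The final $\sigma = 0.5$ leaves enough inter-unit
coupling for topological order while permitting a fine final quantization
(training QE is never worse than at initialization in our tests). The grid
defaults to $8\times8$; for small cohorts the $d \approx 5\sqrt{N}$ rule of
thumb is the better guide — with ~16 training subjects a $4\times4$ map
avoids the regime where units outnumber samples and the map simply
memorizes them.

**Quantization error.** A sample's QE is its distance to its BMU. Trained
on controls only, the map represents control connectivity well; anomalous
(case) vectors land far from every prototype and score high. Receptive
fields partition the scored samples; `activation_map()` reports per-unit
mean QE with empty units flagged `NA`, not zero.

**Band relevance.** Which band separates the groups best is quantified by
the symmetrized Kullback–Leibler divergence between the control and case QE
histograms (`band_relevance()`): shared equal-width bins spanning the
pooled range, bin count by Freedman–Diaconis on the pooled sample,
additive smoothing $10^{-9}$ per bin before renormalization, and
$\hat D = \tfrac12(D_{KL}(P\|Q) + D_{KL}(Q\|P))$ in nats with the standard
$\sum_i p_i \log(p_i/q_i)$ definition.

**Bayesian threshold.** QE within each class is modelled as Gaussian with
priors from the training frequencies. The decision threshold $\tau$ is the
QE at which the class posteriors cross between the two class means (with
equal variances and priors, exactly the midpoint); the marginal is the
two-component mixture $P(x) = \sum_c P(x|c)P(c)$. The crossing is solved in
closed form from the quadratic in $x$; if the discriminant is negative
(possible with extreme priors) the point of closest posterior approach
between the means is used. A sample is classified as an anomaly iff its QE
*strictly* exceeds $\tau$ — a tie counts as control — and the posterior of
the anomaly class is reported for ROC construction.

## Evaluation

* **Cross-validation** is stratified *by subject* (`stratified_folds()`);
  with epoched data all epochs of a subject share its fold, so no subject
  appears in both training and test sets. Each fold retrains the SOM on
  its control training subjects, refits the threshold on all training QE,
  and scores the held-out subjects. Metrics (accuracy,
  sensitivity = case detection rate, specificity, AUC) are reported as
  mean ± across-fold sd.
* **AUC** uses the rank (Mann–Whitney) formulation with midrank tie
  correction.
* **Permutation test**: the full CV pipeline is rerun on $B$ label
  permutations; the empirical p is the fraction of null mean accuracies
  strictly above the observed one, and the smoothed $(b+1)/(B+1)$ variant
  is reported alongside because a plain zero p-value is degenerate.
* **Per-edge tests**: two-sided Mann–Whitney per connection with
  Benjamini–Hochberg FDR across all $C(C-1)/2$ edges at $\alpha = 0.05$
  (exact enumeration when both groups have $\le 8$ subjects, normal
  approximation with tie/continuity correction otherwise), plus a stricter
  adjusted $p < 0.01$ display flag for sparse connection maps.

## The synthetic cohort generator

Real cohorts of this kind are rarely shareable, so `generate_cohort()`
plants known effects for end-to-end validation. The model is shared-source
linear mixing: per band, each channel receives an independent narrowband
background (band-pass-filtered white noise, unit variance, with a tight
0.5 Hz transition so essentially all source power is inside the nominal
band); a pair coupled at weight $w$ additionally shares a common source,
mixed as $w \cdot s + \sqrt{1 - w}\cdot \eta_i$; independent broadband
Gaussian noise (sd `noise_sd`) is added on top. The $\sqrt{1-w}$
background scale makes the shared fraction of band power grow steeply
enough with $w$ that phase synchrony spans the weak-to-strong range; with
the default `noise_sd = 0.5` (calibrated once, at design time), a planted
weight of 0.8 produces Beta-band circular correlations around 0.5–0.8,
weight 1 with no noise gives identical signals ($r_c = 1$), and unplanted
pairs stay near 0. Kuramoto-style oscillator dynamics were considered and
rejected: a single tunable coupling scalar is all the downstream tests
need. Per-subject seeds are derived from the master seed, so cohorts are
reproducible while subjects stay independent. Optional 100% amplitude
modulation of the sources (4.8/16 Hz stimulus analogue) is available but
off by default — it does not change phase-synchrony ground truth.

What the generator does **not** emulate — and hence what passing tests do
not establish about real EEG: volume conduction (no spurious
near-neighbour synchrony), ocular/muscular/cardiac artefacts, 1/f
background spectra, inter-subject variability beyond sampling noise
(within a group, all subjects share the same true coupling), nonstationary
coupling, and electrode placement effects. Results on synthetic cohorts
validate the *machinery*, not clinical performance.

Validation problem sizes (the package's own choice of scale): recovery and
classification checks use 20 control + 10 case subjects, 16 channels, 60 s
at 250 Hz with Beta coupling 0.8 vs 0.3 on 8 planted pairs; calibration
checks use null cohorts of 12 + 12 subjects and 99-permutation tests over
100 repetitions. The epoch/session structure of any specific acquisition
protocol is not baked in; `duration` and the epoching window are free
parameters.

## Known limitations

* The Gaussian QE class-conditional is a modelling convenience; heavily
  skewed QE distributions would misplace the threshold (the AUC, computed
  directly from QE ranks, is unaffected).
* With lattices much larger than the training set the SOM interpolates the
  training subjects and the threshold inherits an optimistic training QE;
  use the $5\sqrt N$ grid guidance.
* Absolute circular correlation discards the sign of co-variation by
  default; pass `signed = TRUE` to keep it.
* EDF support is deliberately minimal (uniform rate, standard EDF); EDF+
  annotations are ignored territory.
* Artefact removal (e.g. ocular ICA) is out of scope; insert cleaned
  recordings at the `recording()` boundary.
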