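---
title: "Methods: state-dependent analysis of targeted photostimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent analysis of targeted photostimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optocoupling)
```

## Overview

`optocoupling` analyses all-optical experiments in which a co-tuned ensemble
of layer 2/3 V1 neurons is photostimulated while a head-fixed mouse performs
a contrast-varying visual detection task. One behavioral session combines a
trial table (five contrasts with and without photostimulation, plus catch
trials, in 40/40/20 proportions), ROI positions over a 710 x 710 um field of
view imaged at a 7 Hz volume rate, matched ROI and neuropil fluorescence
matrices, and a pupil-area trace. The pipeline asks two linked questions:
does added cortical activity change what the animal reports, and does the
local network's response to that activity explain the behavioral change —
and are both gated by the animal's engagement state?

The package is organised as a chain of stages, each usable on its own:

1. **Preprocessing** — neuropil correction, a windowed trial-response
   metric, activity proxies, spatial exclusion masks.
2. **State indexing** — per-trial engagement from pre-trial pupil size and
   population synchrony, median-split into two states.
3. **Behavior metrics** — outcome classification, session truncation,
   trial exclusions, d-prime, fixed-asymptote Weibull psychometrics.
4. **Ensemble selection** — responsivity criteria and co-tuned group
   selection from mapping blocks.
5. **Network response** — hit:miss ratio matching, split-half
   cross-validated contrast-similarity binning, suppression-slope and
   spatial-influence summaries.
6. **Coupling statistics** — per-bin neural-behavioral coupling, its slope
   over similarity, session bootstrap, and a contrast-label shuffle null.

Because the in-vivo dataset this design targets has no public accession, the
package ships a synthetic-session generator whose every injected quantity is
recorded as ground truth, so each stage is validated by recovery tests.

## The response metric

Neuronal responses are windowed delta-F/F values: the mean fluorescence in a
~500 ms (4-frame) window starting immediately after stimulus /
photostimulation offset, minus the mean of the ~1 s (7-frame) pre-onset
baseline, divided by the baseline mean. Photostimulation-artifact frames
never enter either window; with a slow indicator this postponed window
underestimates amplitudes, which the generator compensates for exactly (see
below). The same window is used on visual-only trials so the two trial types
are comparable.

Neuropil contamination is removed per ROI by robust linear regression of the
ROI trace on its neuropil trace — iteratively reweighted least squares with
Tukey bisquare weights (tuning constant 4.685), implemented in-package in
vectorised form (validated against `MASS::rlm` in the test suite), with a
subsampled Theil-Sen estimator as a config alternative. The fitted slope is
clipped to [0, 2] and used to subtract scaled neuropil; after correction the
baseline-period trace is uncorrelated with the neuropil. A
`neuropil_stride` option subsamples frames for the slope estimate only — the
correction always uses all frames.

## Engagement state

Each trial is indexed by the 4 s window before stimulus onset:

* **pupil**: mean pupil area, normalized by the session median;
* **synchrony**: the mean of all pairwise Pearson correlations between
  cells' activity proxies in the window. The proxy is the positive part of
  the first difference of the corrected trace, Gaussian-smoothed with
  sigma = 0.5 s — a fast-timescale activity estimate standing in for spike
  deconvolution, which the windowed analyses do not require.

The combined score is `z(synchrony) - z(pupil)` (z-scored within session),
so low scores mean a large pupil and low synchrony; the session is
median-split into *more engaged* (score below the median) and *less engaged*
halves, ties broken by alternation so group sizes differ by at most one.

One numerical choice deserves emphasis: the smoothing kernel is symmetric
while the synchrony window ends immediately before onset, so evoked
transients would otherwise bleed backwards into the window and couple the
state label to the upcoming trial's own type (high-contrast and
photostimulation trials would spuriously look "synchronous"). The
session-level proxy therefore zeroes the first-difference contribution of
stimulus and photostimulation frames before smoothing
(`session_activity_proxy()`). A `sync_max_cells` option computes synchrony
on an evenly spaced cell subset; the pairwise-correlation mean converges
quickly with the number of pairs.

## Behavior

Licks within (0.15 s, 1.5 s] of stimulus onset are hits (or false alarms on
catch trials); a first lick at or under 150 ms marks the trial excluded.
Sessions are truncated when the 20-trial rolling hit rate on the
highest-contrast trials drops below 80% of its starting value, and
photostimulation trials are excluded when more than half the targets fail to
respond (windowed delta-F/F <= 0.3, reusing the mapping responsivity
criterion); a session is invalid if any of the 12 trial types retains fewer
than 10 trials.

Sensitivity is `d' = qnorm(HR) - qnorm(FAR)` with rates clipped to
`[1/(2n), 1 - 1/(2n)]`; the false-alarm rate comes from the same state's
catch trials without photostimulation (a config switch uses
photostimulation catch trials instead). Psychometric curves are
fixed-asymptote Weibull fits,

$$W(c) = \gamma + (1 - \gamma - \lambda)\,(1 - e^{-(c/\alpha)^\beta}),$$

with gamma fixed to the condition's catch false-alarm rate and lambda fixed
to 0.01 (both configurable; the asymptotes are not estimated). `(alpha,
beta)` maximise the binomial likelihood over `log(alpha), log(beta)` from a
deterministic start grid with BFGS/Nelder-Mead polishing. The threshold is
the contrast at 50% normalized performance, `alpha * log(2)^(1/beta)`; the
width is the contrast span between 5% and 95% normalized performance,
`alpha * ((-log .05)^(1/beta) - (-log .95)^(1/beta))`. Reading "5%/95%
performance" as *normalized* performance keeps the width defined when the
guess rate exceeds 5%. Fits are on the linear contrast axis, matching
reported widths in stimulus units.

## Network response and functional similarity

A cell's functional similarity to the stimulated ensemble is the Pearson
correlation of its contrast-response curve (mean delta-F/F per contrast on
visual-only trials) with the target-average curve. Because similarity and
the photostimulation-induced change (`delta = mean(visual+stim) -
mean(visual)`) would share trials, the analysis is split-half
cross-validated: each of `n_splits` random splits (stratified by contrast x
photostimulation x state, so no stratum empties) measures similarity on one
half and delta on the other, bins cells into 20 fixed, evenly spaced
similarity bins on [-1, 1], and the outputs average over splits. Targets
stay out of the bins and are reported as a separate row. Strata with fewer
than two trials make a session unsplittable and raise an error rather than
silently degrade.

Within each split, delta is computed with **hit:miss ratio matching** across
the photostimulation factor (within state and contrast): with `m_h` the
minimum hit count and `m_m` the minimum miss count across the two
conditions, resamples draw `m_h` hits and `m_m` misses without replacement
from each condition so both means reflect the identical lick fraction,
removing motor/reward confounds. The averaged-over-resamples mean has an
exact closed form (each hit weighted `m_h/n_h`, each miss `m_m/n_m`);
`match_hit_miss()` implements both, the cross-validation loop uses the exact
limit, and the test suite verifies the resampled estimate converges to an
exhaustive enumeration.

The **suppression slope** analysis pools delta across sessions per bin
(weighted by contributing cell counts), fits each bin's delta against
log10 contrast by ordinary least squares, and regresses those per-bin slopes
on normalized similarity (bin centers mapped to [0, 1]), excluding the
target row; standard errors and percentile intervals come from a
session-level bootstrap. Log10 contrast is the regressor because contrasts
span two decades and the axis is treated as ratio-scaled.

The **spatial influence profile** aligns every cell to its nearest target
(lateral offset, planes collapsed) and averages the spontaneous-period
change (photostimulation-catch minus catch trials) in 5 x 5 um bins; the
Gaussian-smoothed map (SD 10 um) is for display only, and the 1D annular
profile uses unsmoothed values.

## Neural-behavioral coupling

For the three intermediate contrasts (2, 5, 10%) — the lowest contrast being
far below threshold and the highest saturated — each similarity bin of each
session contributes three points: its cross-validated delta and the
session's `dd' = d'(visual+stim) - d'(visual)` at that contrast and state.
The per-bin coupling is the Pearson correlation over points pooled across
sessions; the across-bin OLS slope of coupling against normalized
similarity (targets excluded) summarises whether functionally similar
neurons couple more tightly to behavior. Uncertainty comes from resampling
sessions with replacement; the null distribution comes from shuffling trial
contrast identity among the intermediate contrasts, within session x
photostimulation x state strata, so every marginal count is preserved and a
trial keeps its behavioral outcome and neural responses together — only the
label moves.

Three choices matter here. First, each shuffle yields one slope and the
null is the distribution of those slopes (the alternative reading —
averaging shuffled responses before coupling — would not produce a null
distribution at all). Second, the shuffle is a *session-level block
permutation*: within each session the three intermediate contrast labels
are permuted as wholes, independently for the behavioral and the neural
coordinate, over the tables the observed statistic is computed from. This
makes the p-value an exact conditional permutation test (the observed slope
is the identity permutation). The obvious alternative — relabeling single
trials and recomputing everything — was implemented first and found to be
badly miscalibrated: relabeled groups mix trials of different true
contrasts, and that composition noise loads on every similarity bin with a
sign following the bin's contrast tuning, so any chance correlation between
the two coordinates' composition draws turns into a large spurious slope.
The measured type-I rejection rate of the trial-level null was 0.0025 at a
nominal 0.05; the block-permutation null is calibrated. Third, the p-value
uses the add-one convention, so its resolution floor is
`1/(n_shuffle + 1)`.

## The synthetic-session generator

The generator emulates the statistical structure the analyses assume, with
every injected quantity recorded:

* **Engagement** is a logistic-squashed Ornstein-Uhlenbeck latent with a
  60 s timescale. Pupil follows it positively; the variance of a shared
  "common input" to all cells scales with (1 - engagement), producing the
  large-pupil/low-synchrony anticorrelation the state index exploits.
* **Contrast responses** are Naka-Rushton curves (the standard V1 contrast
  model) with a signed amplitude (30% of cells suppressed by contrast) plus
  a second, opposing high-contrast component of variable strength
  (`contrast_surround_max`). The surround component gives the population a
  continuum of curve shapes — monotone through band-pass — so functional
  similarity genuinely spans [-1, 1] and all 20 bins are populated; with
  pure monotone curves similarity degenerates to +/-1.
* **Targets** are the largest group of photostimulation-responsive,
  monotonically driven cells sharing the session orientation (re-tuning the
  strongest remaining cells when a small simulated population would
  otherwise leave the ensemble infeasible).
* **Behavior** follows per-state Weibull curves whose parameters invert the
  closed forms to engaged threshold/width 3.9/7.4 and less-engaged 4.6/15.0
  (alpha = 4.70/6.23, beta = 1.90/1.20), guess rate 0.12, and a
  state-dependent lapse rate (0.02 engaged, 0.08 less engaged — with fixed
  asymptotes, threshold and width differences alone would make the two
  state curves cross at low contrast, whereas less-engaged animals perform
  worse at every contrast). On photostimulation trials in the engaged state
  only, hit probability shifts by +0.15 at 2% and -0.15 at 10% contrast.
* **Traces**: per-cell rates (baseline, state-gained visual drive, common
  input, direct drive of 0.68/0.81 delta-F/F to targets in the
  less-/more-engaged state, a center-surround spatial kernel, and
  similarity-scaled suppression growing with log10 contrast at `b_true`
  delta-F/F per decade, default -0.01) are convolved with a 1.5 s
  exponential indicator kernel and contaminated with neuropil. All injected
  amplitudes are pre-divided by the exact pulse attenuation of the windowed
  metric (`pulse_response_factor()`), so configured effect sizes are what
  the analysis recovers. The neuropil is a shared slow background plus
  per-cell slow and fast components and never contains a cell's own signal,
  keeping the contamination coefficient identifiable.

What the generator does **not** emulate: spiking biophysics, shot noise and
motion artifacts, plane-timing offsets, eye movements, or reward/licking
dynamics in the traces. Passing recovery tests therefore demonstrate that
the analysis chain is correct and calibrated for data with this covariance
structure, not that it is robust to every artifact of real imaging.

## Problem sizes, seeds and numerical choices

All stochastic stages take explicit seeds; cohort stages derive per-session
sub-seeds with `derive_seed()`, so adding a session never perturbs
another's draws, and identical configurations reproduce outputs
byte-for-byte. Resample counts default to the full analysis profile (10000
matching resamples via their exact limit, 5000 cross-validation splits,
5000 bootstrap and shuffle iterations); the test suite runs scaled-down
profiles (typically 40-200 splits, 100-1000 bootstrap, 50-200 shuffles).

Simulation sizes in the validation suite are the package's own choices,
sized to each check: sessions with compressed trial timing (2-3 s
inter-trial period instead of 7 s) and 40-300 cells; 840-trial sessions for
per-state psychometric comparisons, where per-contrast d-prime differences
need many trials per condition to have usable sampling error; 10
default-population sessions for suppression-slope recovery; small 132-trial
sessions for the shuffle-test calibration, which needs hundreds of replicate
datasets. Degenerate inputs (constant traces, empty strata, unsplittable
sessions, missing conditions) raise errors or propagate missing values
explicitly — never silent zeros.

The pipeline-facing modules are exposed as plain R functions
(`run_pipeline()`, `report()` and the stage functions); this package's
users drive it from R or Rscript, so no shell wrapper is shipped.

## Known limitations

* The pupil is generated and stored at the imaging volume rate; real
  pupillometry at camera rate would need resampling before these analyses.
* The state index is a binary median split; trials near the median are
  intrinsically ambiguous, which caps label agreement with the latent
  ground truth around 80-90% and attenuates state-specific effect
  estimates accordingly. The same label leakage deposits a diluted copy of
  engaged-only effects into the less-engaged estimates: in large, low-noise
  cohorts the less-engaged coupling can reach nominal significance even
  though the generator injects no less-engaged effect.
* Fixed-asymptote Weibull fits on ~14 trials per contrast occasionally go
  nearly flat (tiny shape parameter), producing extreme width estimates;
  cohort summaries of psychometric width are better read as medians.
* With two states, five contrasts and two stimulation conditions, small
  sessions can leave strata too thin to split; the cross-validation
  deliberately refuses to analyse such sessions.
* Per-bin couplings in sparsely populated similarity bins are noisy; they
  are kept (with their three-point minimum) rather than reweighted, matching
  the plain OLS definition of the across-bin slope.
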