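---
title: "Separating saccade-related from externally driven cortical transients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating saccade-related from externally driven cortical transients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(saccsupp)
```

## The scientific problem

When the eyes make a small saccade, the image sweeps across the retina
exactly as it would if the stimulus itself had jumped on the screen —
yet the two events are perceived completely differently. `saccsupp`
implements an analysis that asks *where along the visual cortical
hierarchy* the distinction between self-generated and external retinal
displacements arises, using continuous intracranial recordings: it
contrasts high-frequency broadband (HFB, 70–150 Hz) transients
following small saccades (1.3°–3.7°) with transients following
magnitude-matched on-screen displacements of the stimulus, electrode by
electrode, and aggregates the result over retinotopic and high-level
regions of interest (ROIs).

Because raw patient recordings of this kind are not publicly
distributable, the package pairs every analysis stage with a
synthetic-data generator that realizes the same paradigm with known
ground truth. Every claim the test suite makes is a claim about
recovering quantities that were injected by construction.

## Signal model and deconvolution

The recorded HFB envelope of an electrode is modeled as a linear
superposition of event-locked transients plus stationary noise:

$$ y(t) \;=\; \beta_0 \;+\; \sum_{c}\sum_{i \in c} h_c(t - t_i) \;+\;
\varepsilon(t), $$

where $c$ ranges over event types (stimulus onsets, external
displacements, saccades in three magnitude strata, blinks, blank-frame
gaps), $t_i$ are alignment points and $h_c$ is the unknown response
kernel of type $c$. Each $h_c$ is estimated non-parametrically with a
finite impulse response (FIR) basis: one regression coefficient per
10-ms lag over a window from 300 ms before to 500 ms after the event
offset (stimulus kernels are onset-aligned over 0–500 ms). Ordinary
least squares on the indicator design separates temporally overlapping
responses — the "unique contribution" of each event type — which plain
event-locked averaging cannot do. The tests demonstrate this directly:
on noiseless synthetic data with overlapping events, the FIR fit
recovers every injected kernel to machine precision while the naive
average is biased by more than one baseline SD.

Numerical choices:

* **Alignment.** Displacement, saccade, blink and gap kernels are
  locked to event *offsets*; onset-locking is available (a property
  test checks that, for saccades shorter than ~30 ms, onset- and
  offset-aligned estimates correlate above 0.9).
* **Bin width / analysis rate.** 10 ms at 100 Hz. This resolves the
  ~165–175 ms peak latencies comfortably; nothing in the method depends
  on the exact value.
* **Solver.** The normal equations are solved by Cholesky on the sparse
  Gram matrix; a rank-deficient design (possible under pathological
  event schedules) falls back to the minimum-norm solution with the
  inestimable lags flagged and a warning.
* **Edge events.** Windows extending past the recording are truncated;
  the affected lags are estimated from the remaining events rather than
  dropping the event.
* **Intercept.** A single per-recording intercept. Slow-drift
  regressors are deliberately left out of the default model so that the
  exact-recovery oracles stay exact; drifts can be emulated in the
  generator if needed.
* **Uncertainty.** Per-lag standard errors come from the residual
  variance and the Gram inverse; per-timepoint two-sided p-values are
  Benjamini–Hochberg corrected across all coefficients within the
  electrode. The noise is AR(1) while OLS assumes white noise; a
  simulation test confirms that 95% CIs still cover the true kernels at
  roughly nominal rate (the binned envelope decorrelates quickly), which
  is why no GLS machinery is used.

## The cluster-area permutation contrast

Whether an electrode responds more to displacements than to saccades is
tested without distributional assumptions. The statistic is

$$ T \;=\; \text{area of the largest strictly positive run of }
\hat h_{\text{disp}} \;-\; \text{area of the largest strictly positive
run of } \hat h_{\text{sacc}}, $$

with area = (sum of coefficients) × bin width. Using the largest
positive cluster avoids positive responses being cancelled by negative
excursions elsewhere in the window, and does not assume the two
responses are temporally registered. Ties between equal-area runs are
broken toward the earliest run (deterministic); the cluster search
spans the full FIR window.

The null distribution reassigns the pooled displacement and in-range
saccade events to the two labels uniformly at random, preserving group
sizes, and re-estimates both FIR sets for every shuffle; all other
conditions stay in the model as fixed nuisance regressors. P-values use
the add-one estimator $(1 + \#\{T^* \ge T\})/(n_{\text{perm}} + 1)$,
which cannot return zero; both one-sided p-values are computed from the
same null, and each direction's family is FDR-corrected across
electrodes separately.

Refitting the full model 10,000 times per electrode is the literal
procedure but wasteful. The package instead partials the nuisance set
out of the recording and of the two shuffled FIR sets once
(Frisch–Waugh–Lovell) and solves only the two sets' reduced normal
equations per shuffle, after precomputing all Gram contributions
indexed by event pairs. This path is *algebraically identical* to the
full refit — a unit test verifies equality to 1e-10 on coefficients —
and roughly 50× faster.

The test's operating characteristics are measured, not assumed: on 200
null electrodes (identical kernels) the empirical type-I error at
$\alpha = 0.05$ must fall inside the binomial 95% band, and under
complete suppression (saccade kernel zero, 5-SD displacement kernel, 40
events per condition) detection at $p < 0.01$ must exceed 90%. The
calibration electrodes carry only the two contrasted event types plus
the intercept: the exchangeability being tested concerns the shuffled
pair, and the lean design keeps 100,000 refits tractable on one CPU.
The full nuisance model is exercised by the end-to-end pipeline run.

## Suppression indices and their comparison

Scalar response magnitudes are the mean of the *cross-validated*
coefficient trace over 0–500 ms post-offset. Cross-validation splits
blocks into folds, refits with each fold's samples held out, and
averages the per-fold traces; this keeps the scalars free of the
selection optimism that a single in-sample fit would carry. The scalar
window is a documented choice (the transient kernels have essentially
no mass beyond 500 ms); it is configurable.

Two indices summarize each electrode:

$$ \text{saccade index} = \frac{\text{disp} - \text{sacc}}
{\text{disp} + \text{sacc}}, \qquad
\text{blink index} = \frac{\text{gap} - \text{blink}}
{\text{gap} + \text{blink}}. $$

0 means no suppression, 1 complete suppression, and values above 1 are
legal when the self-generated response is negative. Indices with a
near-zero denominator (|den| < 1e-8) are flagged undefined and excluded
from ROI means with a log message.

The overlap of the two significance maps (displacement > saccade and
gap > blink) is measured by the Sørensen–Dice coefficient
$2|A \cap B| / (|A| + |B|)$, tested by permuting one map's labels over
the shared electrode universe. Under that null the intersection size is
hypergeometric, and a test verifies the permutation p against the exact
hypergeometric tail on a 12-electrode universe.

The ROI-level association between the two indices is a correlation
computed after removing one designated outlying ROI (the V4 analog).
Because opportunistic outlier removal inflates a correlation, its
significance uses a bias-corrected randomization: each shuffle of the
null also takes the *maximum* correlation over all single-point
removals, so the null enjoys exactly the same advantage. This null is
centered well above zero — the package reproduces that positive bias on
generic data — and the p-value compares like with like. When $n!$ does
not exceed the shuffle budget the permutations are enumerated
exhaustively and the p-value is exact.

The ROI-independence of significance counts is tested by Pearson
chi-square with a label-shuffle randomization null rather than the
asymptotic reference distribution, since per-ROI counts are small; a
test checks the randomization p against exhaustive enumeration on six
electrodes in two ROIs.

## Eye-event processing

* **Geometry.** Pixels convert to visual degrees by the full arctangent
  formula $2\arctan(px \cdot 2.54 / (\text{DPI} \cdot 2d))$ at 78.5 DPI
  and 70 cm viewing distance, reproducing the paradigm's printed sizes
  (50 px → 1.3°, 140 px → 3.7°) and agreeing with the small-angle
  approximation to 0.5% over the relevant range.
* **Saccade detection.** A speed-threshold detector (default 30 deg/s,
  minimum 6 ms) replaces the tracker vendor's proprietary algorithm.
  Only magnitudes and blink overlaps matter downstream, and the
  detector is validated by recovery on constructed gaze ramps. The
  magnitude is the fixation-to-fixation amplitude (flanking 20-ms
  windows), not path length. Saccades below roughly 0.6° produce peak
  speeds under the default threshold and are intentionally invisible —
  far below the 1.3° analysis floor.
* **Selection.** Saccades touching invalid (blink) samples are excluded
  outright; the rest are stratified as below / within / above the
  inclusive 1.3°–3.7° displacement range. Only in-range saccades enter
  the contrast; all strata enter the GLM as separate predictor sets.
* **Rejection mask.** Tracking dropouts and out-of-stimulus gaze
  episodes are padded by 50 ms before and 250 ms after, merged, and
  excluded from fits; episodes fully explained by blinks are exempt
  (blink responses are modeled, not discarded). The stimulus border is
  a centered rectangle of the stated 15.8° width; the vertical extent
  defaults to 3/4 of the width — an assumption, since only the width is
  stated.
* **Task filter.** Animal-target trials are carried as an `excluded`
  flag on events and dropped before design construction.

## HFB estimation

The 70–150 Hz envelope is computed by splitting the band into eight
10-Hz sub-bands, band-pass filtering (4th-order zero-phase
Butterworth), taking the analytic-signal amplitude, dividing each
sub-band envelope by its own recording mean — so the 1/f spectrum does
not let low sub-bands dominate — averaging, decimating to 100 Hz by
non-overlapping window means (alignment preserved to within one
analysis sample, verified), and z-scoring against inter-block baseline
samples. Output units are therefore baseline SDs. Electrodes enter the
analysis only if a two-sided paired t-test of per-trial response versus
baseline means survives Bonferroni correction across the subject's
electrodes *and* the effect is at least 2 baseline SDs — a conjunctive
rule tested in both directions.

## The synthetic generator: what it emulates and what it does not

The generator realizes the paradigm's event structure — blocks of ten
1-s image trials separated by 3-s gray baselines; 12/44 of blocks are
fixation blocks whose trials each carry one horizontal displacement of
1.3° or 3.7° at 300, 500 or 700 ms; free-viewing blocks carry Poisson
saccades (2/s, log-normal magnitudes truncated to 0.2°–8° so all three
strata are populated), blinks (0.15/s) and brief blank-frame gaps — and
a signal model of gamma-shaped transient kernels superposed linearly on
AR(1) noise with unit marginal variance. A per-ROI suppression factor
$s$ scales the saccade kernel to $(1-s)$ times the displacement kernel
(and the blink kernel relative to the gap kernel — the generator
couples the two, emulating a shared oculomotor gating pathway), so the
true suppression index is $s/(2-s)$ by construction. A per-electrode
latency offset (SD 20 ms) shared by the displacement and saccade
kernels gives electrodes heterogeneous but condition-correlated peak
latencies, which is what makes the latency-correlation analysis
meaningful. Gaze traces are piecewise-constant fixations joined by
raised-cosine ramps of exactly the scheduled magnitudes, with blink
intervals marked invalid.

Free-viewing saccade rate and magnitude distribution are generator
choices, not fitted values — the underlying study does not report them —
and the defaults above are ordinary values for free viewing of large
still images.

What the generator does *not* emulate: realistic raw-voltage spectra
(only a band-limited sinusoid fixture exercises the envelope
estimator), saccade direction selectivity, refractoriness beyond a
minimum inter-saccade gap, non-stationary noise, drifts, or any retinal
content difference between face and non-face images (the two stimulus
kernels differ only in amplitude). Passing tests therefore certify the
*estimators and tests* — unbiasedness, calibration, power, exactness of
the algebra — under the stated model, not the robustness of the method
to real-data pathologies such as epileptic artifacts or montage
effects.

## Aggregation and reporting

Grand averages are computed within subject first (per ROI × condition),
then across subjects, with the error band the SD of subject means over
$\sqrt{n_\text{subjects}}$ — the only order consistent with an error
bar described as between-subject variability; a constructed test checks
that a 9-vs-1 electrode imbalance leaves both subjects equally
weighted. With one subject the SE is undefined. The pipeline pools the
two displacement magnitudes into a single predictor set (as the
electrode-level map does); magnitude- and face-split estimation are
available through `design_spec()`.

## Problem sizes used in validation

The validation experiments run at desk scale, chosen to finish in a few
minutes on one CPU while keeping every Monte-Carlo margin meaningful:
200 null electrodes × 500 shuffles for calibration; 100 simulations for
power; 18 electrodes (3 ROIs × 6) over 3 subjects and 20 blocks for
index recovery; 21 electrodes (7 ROIs × 3) over 3 subjects, 16 blocks
and 300 shuffles for the end-to-end gradient; 300 simulations for CI
coverage. The headline electrophysiological numbers of the motivating
study (36/115 significant electrodes, a 0.5763 Dice coefficient, an
r = 0.66 latency correlation) depend on the actual patient recordings
and are not reproduction targets; the package's claims are about the
correctness and calibration of the machinery.

## Known limitations

* OLS standard errors ignore residual autocorrelation; coverage is
  verified by simulation under the default AR(1), not guaranteed for
  arbitrarily slow noise.
* The permutation contrast assumes the pooled displacement/saccade
  events are exchangeable under the null given the rest of the design;
  strongly magnitude-dependent responses would violate the pooled-label
  null (the study's magnitude strata exist precisely to mitigate this).
* The suppression-index denominators can approach zero for weakly
  responsive electrodes; such electrodes are excluded from ROI means
  rather than imputed.
* `estimate_hfb()` requires the raw sampling rate to be an integer
  multiple of the analysis rate.
* Electrode localization and ROI assignment are inputs, not computed.

## Reproducing the numbers

```{r, eval = FALSE}
# module-level and end-to-end validation
testthat::test_dir("tests/testthat")

# the headline quantities, recomputed from scratch
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json

# narrative drivers
# Rscript analysis/01_simulate_cohort.R
# Rscript analysis/02_deconvolution_oracle.R
# Rscript analysis/03_permutation_validation.R
# Rscript analysis/04_full_pipeline.R
```
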