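# saccsupp

Deconvolution and permutation statistics for saccade-related
suppression of visual cortical transients in intracranial EEG.

## What problem this solves

A small saccade and an equally small jump of the stimulus on the screen
produce nearly identical retinal motion, yet only the external jump is
perceived as movement. For electrophysiologists asking *where* in the
visual hierarchy this distinction arises, the analytical obstacles are
concrete: cortical high-frequency broadband (HFB, 70–150 Hz) transients
to stimuli, displacements, saccades, blinks and blank frames overlap in
time; saccades are self-paced and must be magnitude-matched to the
displacements post hoc; and electrode-level effects must be tested and
aggregated over regions of interest (ROIs) without distributional
assumptions. `saccsupp` implements that full analysis chain for
continuous per-electrode recordings, plus a synthetic-data generator
that realizes the same paradigm with known ground truth so every stage
is testable without patient data.

## The methods at its core

* **FIR-GLM deconvolution.** The envelope is modeled as
  `y(t) = β₀ + Σ_c Σ_i h_c(t − t_i) + ε(t)`; each condition's kernel
  `h_c` is estimated as one least-squares coefficient per 10-ms lag
  over a −300…+500 ms window around the event offset, separating
  overlapping responses that event-locked averaging confounds.
* **Cluster-area label-shuffle test.** Per electrode, the statistic is
  the area of the largest strictly-positive run of the displacement
  trace minus that of the saccade trace; the null reassigns the pooled
  event labels and refits (an exact Frisch–Waugh–Lovell fast path makes
  10,000 refits per electrode cheap). Both one-sided p-value families
  are FDR-corrected across electrodes.
* **Suppression indices** `(ext − self)/(ext + self)` from
  cross-validated response scalars, for saccades (vs. displacements)
  and blinks (vs. gaps); ROI means with between-electrode SEs.
* **Map-overlap and association tests.** Sørensen–Dice coefficient
  `2|A∩B|/(|A|+|B|)` with a label-permutation null, and a
  bias-corrected randomization test for a correlation reported after
  removing a designated outlier (each shuffle also takes the maximum
  correlation over all single-point removals, so the null carries the
  same optimism as the observed statistic).
* **Eye-event processing.** Pixel→degree conversion
  (`2·atan(px·2.54/(DPI·2d))`), speed-threshold saccade detection,
  blink-overlap exclusion, magnitude stratification around the
  inclusive 1.3°–3.7° range, and padded gaze-validity rejection masks.
* **HFB estimation.** Eight 10-Hz sub-bands, zero-phase Butterworth,
  analytic-signal amplitude, per-sub-band mean normalization,
  averaging, decimation to 100 Hz, z-scoring against inter-block
  baselines; conjunctive responsiveness screening (Bonferroni p < 0.05
  AND effect ≥ 2 baseline SDs).

## Worked example

```r
library(saccsupp)

cfg <- sim_config(n_subjects = 2, electrodes_per_roi = c(V1 = 2, Face = 2),
                  n_blocks = 8, fixation_fraction = 0.5, seed = 1)
run <- run_pipeline(cfg, n_perm = 500, n_rand = 2000, n_perm_dice = 5000,
                    n_shuffle_corr = 720)
print(run)
#> <saccsupp_run>
#>   4 electrodes analyzed, 2 ROIs
#>   displacement > saccade: 2/4 electrodes significant (q < 0.05)
#>   Dice overlap with gap > blink map: 1.000 (p = 0.168)

run$roi_counts
#> # A tibble: 2 × 3
#>   roi       n n_significant
#>   <chr> <int>         <int>
#> 1 Face      2             2
#> 2 V1        2             0

run$suppression$roi[, c("roi", "saccade_mean", "saccade_se", "n")]
#> # A tibble: 2 × 4
#>   roi   saccade_mean saccade_se     n
#> 1 Face        0.996      0.0305     2
#> 2 V1         -0.0155     0.0111     2
```

The configuration places complete saccadic suppression in the
face-selective ROI and none in V1 (the defaults). The pipeline finds
exactly that: both Face electrodes — and neither V1 electrode — show a
significantly larger HFB cluster after displacements than after
saccades, and the recovered saccade suppression indices sit at ≈1
(complete suppression, Face) and ≈0 (none, V1). The Dice line reports
the overlap between this map and the analogous gap-vs-blink map; with
only four electrodes its permutation p is unremarkable, as it should
be.

The numbered scripts under `analysis/` run the same machinery as
narrative analyses (cohort simulation, deconvolution oracle,
permutation-test calibration and power, full hierarchy-gradient
pipeline) and write their tables under `results/`.

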