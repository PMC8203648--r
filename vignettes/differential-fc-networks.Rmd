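---
title: "Stimulus-driven BOLD analysis and differential FC networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-driven BOLD analysis and differential FC networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ofmrinet` implements a complete stimulus-driven optogenetic-fMRI analysis
chain for block-design rodent experiments: paradigm construction and
two-gamma-HRF design matrices, preprocessing of 4D BOLD series, voxel-wise
GLM with subject-level FDR control, atlas-based regionalization with
event-related averaging, and a differential functional-connectivity (FC)
network procedure that summarizes group differences as signed connection
counts between composite anatomical nodes. Because the kind of raw data the
pipeline targets is not publicly deposited, the package ships a seeded
synthetic-cohort generator whose planted ground truth makes every stage
testable end to end.

## The stimulation paradigms

The co-stimulation protocol applies `n_heat = 16` heat-class stimuli (50 °C,
20 s each: a 5 s linear ramp followed by a 15 s plateau), with every second
heat stimulus combined with simultaneous laser application ("costim"), and
one laser-only stimulus interspersed after each heat-class stimulus.
Consecutive stimuli of any kind are separated by the stimulus interval of
100 s, so 32 stimuli span roughly 52 minutes of the 65-minute acquisition
(1950 volumes at TR 2000 ms). The wild-type protocol applies three ascending
sets of 40/45/50/55 °C after a 2-minute rest at an interval of 3 min 40 s.

Stimulus regressors are trapezoids rather than boxcars because the ramp is
part of the protocol; each event kind gets its own predictor, in the fixed
order heat, laser, costim. The laser pulse train (10 Hz) is modelled as a
constant-amplitude block: pulse structure is invisible at an effective TR
of 4 s.

## The haemodynamic model

The HRF is the canonical difference of two gamma-shaped lobes,

$$h(t) \propto \left(\tfrac{t}{p_1}\right)^{p_1/d_1}
  e^{-(t - p_1)/d_1} \;-\;
  \tfrac{1}{c}\left(\tfrac{t}{p_2}\right)^{p_2/d_2} e^{-(t - p_2)/d_2},
  \qquad t > 0,$$

parameterized so each lobe's mode sits exactly at its stated latency:
response peak $p_1 = 5$ s, undershoot peak $p_2 = 15$ s,
response/undershoot ratio $c = 6$, unit dispersions — the defaults of the
analysis suites commonly used with this class of data; all are
overridable through `hrf_params()`. The function is normalized to unit
peak, and stimulus predictors are normalized to unit peak after
convolution, so a planted response amplitude expressed in percent signal
change is recovered directly as a GLM beta (in units of the baseline).
Note the distant undershoot shifts the true maximum of the difference a
few milliseconds before $p_1$; tests therefore locate the peak on a 10-ms
grid.

## Preprocessing contracts

Synthetic data are generated motion-free and pre-registered, so motion
correction and affine registration are identity placeholders
(`register_identity()`); slice-timing correction is likewise out of scope.
The implemented contracts are:

* `discard_initial()` — drop the first two volumes (MR saturation);
  `shift_paradigm()` re-references event onsets.
* `pairwise_average()` — average consecutive volume pairs, TR 2000 ms →
  TR\_eff 4000 ms. An odd trailing volume is dropped (the choice is
  logged here because the underlying description is silent about it).
* `spatial_smooth()` — per-slice 2D Gaussian, FWHM 2 voxels by default,
  implemented as a separable symmetric convolution with half-sample
  reflection, which makes the operator doubly stochastic: constants and
  in-plane mass are preserved exactly. At desk-scale grids, where parcels
  are only a few voxels across, a 1-voxel kernel is appropriate — the
  kernel should stay below the parcel diameter, which the 2-pixel kernel
  does at acquisition scale (64 × 64, 196 regions) but not on a 12³ grid.
* `temporal_filter()` — "linear and nonlinear high-pass, 12 s FWHM,
  FFT 9 cycles" is an ambiguous description of the original toolchain; we
  interpret it as a least-squares projection removing the linear trend and
  the 9 lowest integer-cycle Fourier pairs, followed by 12-s-FWHM temporal
  Gaussian smoothing, followed by re-projection (smoothing leaks slightly
  into the removed span, and re-projecting restores exact orthogonality to
  the removed basis). One consequence of the joint projection worth knowing:
  the trend regressor, orthogonalized against the low sines, acquires
  high-frequency content, so passband sinusoids lose a further
  $\mathcal{O}(1/k^2)$ of amplitude; at the study's record length
  (975 volumes, TR 4 s) a cycle-24 component is preserved to within 5 %.

The pipeline restores each voxel's temporal mean after filtering. The
high-pass necessarily removes the mean; adding it back keeps
percent-signal-change baselines well defined while leaving correlations
and stimulus betas untouched.

## GLM and subject-level FDR

`fit_glm()` is ordinary least squares per voxel against the stimulus
predictors plus constant and linear drift; no prewhitening is applied (the
original suite's treatment of serial correlation is unstated, and the
synthetic noise model is white). Tests are two-sided; the sign of the beta
is retained for reporting. `fdr_threshold()` is Benjamini–Hochberg step-up
applied per subject and per predictor, the natural reading of
subject-level FDR control at q = 0.05; an exhaustive-oracle test pins the
implementation on thousands of random p-vectors, including ties and
p = 0.

## Regionalization, event-related averages, group comparison

Region time courses average the significantly activated voxels of each
atlas region (unweighted); regions with no active voxel are omitted and
listed, never zero-filled. A region counts as active in a subject ×
condition entry when it has at least one suprathreshold voxel, and regions
active in at least 50 % of entries enter the network analysis.

Event-related averages align windows of 10 timepoints before onset, the
5-volume stimulation period, and 15 timepoints after it (30 timepoints at
TR\_eff 4 s) over the 8 co-stimulation events, expressing each window as
percent change from its own pre-window mean. Because the pre-window mean
is the denominator, adding a constant to a signal rescales the profile by
`base / (base + c)` — the shape and zero level are invariant, the scale is
not exactly so; this is inherent to the percent convention.

The group comparison is a repeated-measures ANOVA per region with
timepoint as the within-subject factor and group as the between-subject
factor (subjects as repeated units), Tukey HSD on the group factor
(computed on subject-mean responses; with two groups it coincides with the
group contrast), and Bonferroni correction across regions. "One-factor
repeated-measures ANOVA with Tukey HSD" admits other factor structures;
this one is isolated behind `compare_era_groups()` so alternatives can be
swapped. The reported effect is the difference of subject-mean window
responses (treated − control) with its SEM, labelled `reduced` or
`enhanced`.

## The differential FC procedure

Per subject, the global mean (mean across regions at each timepoint) is
removed — this exactly absorbs any brain-wide shared component such as the
stimulus-evoked response — and full-length Pearson correlations are
computed between all region time courses. Correlations are pooled within
groups on the Fisher-z scale (`tanh(mean(atanh r))`, clipping |r| at
1 − 10⁻⁷), and the group-mean matrix is thresholded to a fixed edge count
per channel: the `n_pos` strongest positive (pCorrs) and `n_neg` lowest
negative correlations (nCorrs). With 100 selected regions and 500 edges
per channel the mean node degree is the commonly used k = 10. Ties at the
boundary break by (|r| descending, region-index pair ascending) so the
edge set is reproducible.

Per-edge group differences are two-tailed Student t tests (homoscedastic,
or paired where a pairing exists) on the subject-level Fisher-z values —
the z scale is used because it is the scale on which the procedure already
assumes normality for pooling; the raw-r alternative is a one-line change.
The tested universe is the union of both groups' thresholded channels.
Significant edges (P ≤ 0.05, uncorrected, by default) receive a signed
indicator: −1 control-greater, +1 treated-greater.

`aggregate_composite()` sums these indicators over all constituent region
pairs (both channels) between two composite nodes: a net FC of −6 means
six more significant connections were greater in control than in treated —
for example seven control-greater and one treated-greater. Edges with
|net| at or below the display threshold (4 for laser-only contrasts, 6 for
nociception contrasts) are suppressed from the displayed network but kept
in the matrix; within-composite sums sit on the diagonal and are never
displayed as edges. `pseudo_direct()` orients displayed edges with a
directed structural prior ("synapses" forming on the target region):
A → B where only A projects to B, bidirectional where both do, undirected
and flagged where the prior is silent. The shipped prior
(`inst/extdata/synthetic_structural_prior.tsv`) is a synthetic
illustrative matrix, not tracing data. `compare_conditions()` counts
edge-set overlaps between displayed networks and, given group-mean FC
matrices, compares mean |z| strength over shared edges.

## The synthetic cohort generator

Each subject's region signal is

$$s_r(t) = B\,\bigl(1 + \textstyle\sum_c a_{rc}\, m_g\, g_r\, x_c(t)/100\bigr)
  + \sigma\, f_r(t),$$

with baseline $B$ (100 units), planted amplitudes $a_{rc}$ in percent
signal change at regressor peak, group multipliers $m_g$, Bernoulli
activation gates $g_r$ (exercising the ≥50 % region-selection rule),
unit-peak HRF-convolved regressors $x_c$, and region-level fluctuations
$f_r$ of standard deviation $\sigma = B \times \mathrm{noise\_sd}/100$.
Coupled region pairs share a latent white process (negated on the second
region for the negative channel) with loading `strength`; the remaining
variance is filled independently, so the planted correlation between two
coupled regions is approximately `strength²`. Voxels add independent white
noise of the same σ to their region's signal. Subject seeds derive
deterministically from the cohort seed; identical spec + seed reproduce a
cohort bit for bit.

Default group sizes are 5 controls vs 9 activated subjects, the analyzed
sizes of the reference study arm. The default geometry is desk-scale
(16 × 16 × 8 grid, 20 regions, 975 effective volumes at TR 4 s);
full 64 × 64 × 22 acquisition geometry and raw timing (1950 volumes at
TR 2 s, with discard and pairwise averaging in the pipeline) are supported
but not default, because every tested property is geometry-independent.

What the generator does **not** emulate: scanner drift beyond what the
high-pass removes, physiological noise spectra, motion, spike artifacts,
susceptibility dropout near the implanted fiber, and spatial
autocorrelation of noise. Passing tests therefore demonstrate the
correctness and calibration of the analysis machinery on data satisfying
its assumptions, not robustness to real-scanner artifacts.

## Why the recovery and null scenarios plant a connectivity backbone

A subtlety that shapes the property tests: if the null FC matrix is pure
noise, thresholding to a fixed edge count retains exactly the edges where
one group's mean is most extreme — a winner's curse that guarantees
"significant" group differences on selected edges (we observed p ~ 10⁻⁶ on
truly null edges this way). Real FC matrices are dominated by stable,
group-shared structure, so the retained edges are true correlations whose
group difference is genuinely null. The simulated scenarios therefore
plant a group-shared backbone (`backbone_coupling()`: disjoint positive
and negative pairs at strength 0.6 in both groups) and match the channel
thresholds to the backbone density — the same logic by which a 500-edge
threshold tracks the density of real networks. With the universe composed
of structured edges, the per-edge t test runs at its nominal level, which
the null-calibration suite verifies (fraction of nonzero indicators within
±0.02 of α over 100 seeds).

The exact-recovery scenario additionally plants one group-specific
coupling (strength 0.8, noise 0.2 % signal change, 975 volumes, 5 vs 9
subjects) and demands that the final composite network contain exactly the
planted edge. Exactness over a ~25-edge universe requires family-wise
error control, so that scenario tests each edge at α = 0.002
(≈ 0.05/universe); the planted edge is detected with p ~ 10⁻¹⁰, so power
is unaffected. A second caveat quantified during design: global-mean
removal leaks a group-specific latent into every other region's time
course (order 1/n\_regions in z), so at very small region counts the
procedure itself creates secondary group differences involving the coupled
regions; the scenario uses 30 regions and a universe that excludes the
planted regions' other edges, keeping the leakage outside the tested set.

## Problem sizes used by the test suite

Unit tests run on grids between 6³ and 12³ voxels with 2–30 regions and
60–975 volumes. The heavy property suites use: 50 pipeline executions
(12 × 12 × 5 grid, 30 regions, 975 volumes, 14 subjects) for exact
recovery; 100 region-level cohorts (20 regions, 975 volumes) for null
calibration; 1000 random p-vectors for the FDR oracle; 50 random matrices
for the thresholding oracle. These sizes were chosen so the full suite
completes in a few minutes while every statistical property is assessed at
the study's record length and group sizes.

## Known limitations

* No prewhitening: GLM p-values assume temporally white noise, valid for
  the generator, optimistic for real data.
* The atlas is a synthetic parcellation; anatomical plausibility of
  parcel shapes is not attempted.
* `compare_era_groups()` assumes sphericity within the window
  (no Greenhouse–Geisser correction); the group effect it reports lives in
  the between-subject stratum and is insensitive to this.
* Negative-channel correlations depend strongly on global-mean removal;
  with few regions the removal itself induces negative correlations of
  order −1/(n−1).
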