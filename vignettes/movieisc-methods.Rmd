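---
title: "Methods: ISC/IRC analysis of movie-viewing fMRI with movieisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISC/IRC analysis of movie-viewing fMRI with movieisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`movieisc` analyses naturalistic movie-viewing fMRI at the region-of-interest
(ROI) level, for two-group studies of the social brain: a Theory of Mind (ToM)
network (dMPFC, mMPFC, vMPFC, precuneus, bilateral TPJ) and a Pain network
(AMCC, bilateral insula, MFG, S2). Its dependent variables are:

* **IRC (inter-region correlation)** — per subject, the Pearson correlation of
  each ROI pair over the subject's uncensored timepoints, Fisher-transformed
  (`z = atanh(r)`) per pair and then averaged over within-ToM pairs (15 under
  the default atlas), within-Pain pairs (21), and cross-network pairs (42).
  Summaries are always means of z values, never the z of a mean r.
* **Similarity to the reference-group average (ISC)** — each subject's network
  timecourse (unweighted ROI mean) correlated with the reference group's
  average network timecourse. Members of the reference group are compared
  leave-one-out; other subjects use the full reference average. The reference
  average at each timepoint is taken over the reference subjects with valid
  (uncensored) data there, rather than requiring complete series, which keeps
  the maximum amount of data in play.
* **Within/across-group pairwise similarity** — the full pairwise Fisher-z
  matrix of network timecourses; per subject, the mean z to own-group others
  and to all other-group subjects. Reduced within-group similarity indicates
  idiosyncratic ("heterogeneous") responses.
* **Event response magnitude** — the mean of the z-scored network timecourse
  over the uncensored TRs of an event window (3 TRs by default at TR 0.72 s,
  since a single slow-sampled "peak timepoint" spans several fast TRs).

Between-subject correlations exclude the union of the two subjects' censored
timepoints. Published pipelines typically state censoring subject-wise without
fixing the pairwise rule; union exclusion is the stricter choice and is
applied uniformly. Any correlation with fewer than 10 jointly valid timepoints
(configurable `min_points`) is treated as unusable rather than silently noisy.

# Motion quantification and censoring

Head motion is summarized by filtered framewise displacement over four
timepoints (FDfilt4). Each column of the 6-parameter realignment trace
(translations in mm, rotations in radians) is band-stop filtered to remove
pseudo-respiratory frequencies — at fast multiband sampling, respiration
aliases into the realignment estimates and inflates conventional FD. Then

\[
\mathrm{FD}(t) = \sum_{j=1}^{6} \lvert p_j(t) - p_j(t-4) \rvert ,
\]

with rotations converted to arc displacement on a 50 mm sphere (the standard
convention). The first four entries are defined as zero, so the subject-level
mean (`mean_fd`) is taken over all timepoints.

Design choices, all configurable:

* "Backward differences over four timepoints" is read as a *lag-4* difference
  `p[t] - p[t-4]` — the convention of the filtered-FD multiband literature —
  not as a sum of four lag-1 differences; the `lag` argument exposes the
  alternative.
* The respiratory stop-band defaults to 0.31–0.43 Hz, Butterworth order 10,
  applied forward–backward for zero phase. `signal::filtfilt` performs no
  initial-condition handling, so the package demeans and reflection-pads each
  series before filtering; without that, edge transients of the order of the
  series mean leak into the FD of even a constant trace.
* Timepoints with FD > 0.5 mm are censored together with ±2 padding TRs;
  overlapping pads merge.

Subject-level gates: exclusion when `mean_fd` exceeds the per-site median plus
1.5×IQR (thresholds may be supplied verbatim when computed on a larger
reference sample, e.g. 0.4808/0.5625 mm for the two sites of the motivating
dataset), and when more than one third of the scan is censored. Remaining
group differences in `mean_fd` or censored-TR counts are equalized by
iteratively removing the extreme subject (maximum of the higher-mean group or
minimum of the lower-mean group) whose removal most increases the minimum
Welch-test p-value across the motion metrics, until no metric differs at
p < .05 — retaining as many subjects as possible.

# Temporal preparation

The fixed order is: interpolate censored samples (linearly, edges held at the
nearest uncensored value) → zero-phase Butterworth high-pass (100 s cutoff,
order 5) → z-score each ROI column. Interpolation before filtering prevents
artifact spikes from ringing through the filter; the censor mask is retained
and re-applied inside every correlational analysis, so interpolated values
never contribute to a statistic. Z-scoring uses all timepoints (censoring is
applied *subsequently*, inside analyses); z-scoring precedes network
averaging. Voxel-level nuisance steps (spatial smoothing, aCompCor component
regression) are upstream of this package's scope; the synthetic generator
correspondingly does not inject structured physiological noise — an explicit
fidelity gap documented below.

# The synthetic cohort generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline's statistical behavior is verified. Each ROI `r` in
network `N` of subject `i` in group `g` is

\[
y_r(t) = c_{g,N}\, f_N(t) + \lambda f_{N'}(t) + a\, s(t)
  + \sigma_u u_i(t) + \sigma_e \varepsilon_r(t),
\]

with `f_N` a unit-variance evoked template per network, `s` a shared
audiovisual component, `u_i` **one** idiosyncratic series per subject shared
across all of that subject's ROIs, and ROI-specific white noise. Templates
are smoothed Gaussian noise (kernel FWHM 10 s), orthogonalized and
standardized — this preserves the correlation structure the analyses rely on
without pretending to model the actual film. The event table marks a
"T04"-style final mental-state event at the ToM template's largest excursion.

Defaults (chosen once, as plausible study conditions, and then left alone):

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | ASD 38, NT 78 | two-site cohort before motion QC |
| `n_timepoints`, `tr_seconds` | 548, 0.72 s | ≈6.6 min scan; the scan length is a configurable guess, not a printed quantity |
| loadings `c` | NT: ToM 0.60, Pain 0.65; ASD: ToM 0.40, Pain 0.50 | NT > ASD on both networks, so within-NT > across-group > within-ASD similarity holds in expectation |
| `cross_network_leak`, `shared_scale` | 0.1, 0.3 | cross-network bleed and shared audiovisual response |
| `idio_sd`, `noise_sd` | 1.0, 1.5 | idiosyncratic and white-noise scales; chosen so network-level pairwise ISC lands near the 0.1–0.3 z range typical of movie cohorts |
| `artifact_rate`, `artifact_fd_mm`, `artifact_bold` | 0.005/TR, 2 mm, 5 | ~2.7 spikes per subject corrupting realignment traces *and* BOLD at the same TRs, so censoring is consequential |
| motion walk / respiration | 0.015 mm, 3e-4 rad steps; 0.33 Hz, 0.15 mm | yields mean FD ≈ 0.15–0.2 mm, matching adult movie cohorts |

Behavioral scores use group means/SDs typical of adult autism cohort tables
(higher AQ, lower MASC/EQ in the ASD group; matched age/FSIQ/sex), with
missingness rates mimicking incomplete batteries. The MASC is coupled to the
subject's *latent* (artifact-free) within-ToM IRC in the NT group only, slope
2.0 points per SD with residual SD 2.87 (total NT MASC SD ≈ 3.5, within-NT
brain–behavior correlation ≈ 0.55). The slope is part of the configured
study conditions: it makes the group-by-MASC interaction detectable at ≥80%
power at n = 34/73, the regime the calibration suite checks. The pipeline
then re-measures IRC from corrupted, censored data, so the observed
association includes realistic attenuation.

Determinism: all randomness derives from one seed through fixed substreams
(`subject i` always receives the same stream for a given seed, independent of
cohort composition), so exclusion-sensitive reruns are reproducible, and the
same configuration yields byte-identical outputs.

What the generator does **not** emulate: hemodynamic convolution,
physiological structured noise (aCompCor territory), voxel-level spatial
structure, site-specific scanner effects beyond a site label, and
non-stationary motion. Passing tests therefore demonstrate the pipeline's
statistical correctness under the assumed factor structure, not robustness to
every property of real BOLD data.

# Group inference

Group analyses are ordinary least squares with listwise deletion, controlling
for head motion (`mean_fd`), age, sex, FSIQ, and site, with a group-by-site
interaction candidate. Interactions are fitted first and each is dropped iff
its type-II F-test p ≥ 0.05 (`prune_alpha`), then the model is refitted; a
covariate that is constant in the analysed rows is dropped rather than
allowed to break the design. Per-term Cohen's d is computed from the t
statistic as `d = 2t/√df` — a stated convention, since model-based d has no
single standard — and both raw and standardized (z-scored continuous
variables) coefficient tables are reported, because published
standardized-looking β values are otherwise hard to compare against.

Heterogeneity is tested with paired t-tests (within- vs across-group
similarity, per network per group; `d = mean(diff)/sd(diff)`) and Welch
two-sample t-tests (within-group similarity, NT vs ASD per network; pooled-SD
d with n−1 weights, sign convention group2 − group1). `welch_t()` accepts
printed summary statistics directly, so published results can be recomputed
exactly: NT m = 0.18, sd = 0.07, n = 73 against ASD m = 0.12, sd = 0.07,
n = 34 gives t = −4.13, d = −0.86 on the package's output.

For hypotheses predicting a *null* group effect (the Pain-network models),
evidence for the null is quantified by the BIC approximation
`BF01 = exp((BIC_alt − BIC_null)/2)` against the covariates-only model
whenever the group p exceeds 0.05. This is a unit-information-prior
approximation, deliberately chosen over default-prior Bayesian regression to
avoid a heavyweight dependency; it preserves the direction and rough
magnitude of null evidence but is not numerically identical to
software-specific defaults. For the two brain-behavior tests sharing a neural
measure (MASC and AQ against within-ToM IRC), the Bonferroni-adjusted
threshold α = 0.025 is reported.

The assembled battery is a fixed list of 17 analyses (11 pruned linear
models, 4 paired tests, 2 Welch tests), mirroring a preregistration-style
analysis plan; its composition is asserted by the test suite.

# Numerical choices and degenerate inputs

* Correlations are clipped to |r| ≤ 1 − 1e−7 before `atanh`, so perfect
  correlations map to a large finite z instead of overflowing.
* Paired differences with zero variance are an error, except the all-zero
  (no-difference) case, which returns t = 0, d = 0, p = 1.
* A zero-variance ROI, an all-censored ROI, fewer than 2 uncensored points,
  or a rank-deficient design all fail loudly rather than propagate NaN.
* Ties in motion matching break by subject-identifier order, making removal
  lists reproducible.
* All TR indices are 1-based (R convention); event windows are inclusive.

# Problem sizes used by the verification suite

The test and acceptance suites run entirely on generated data: oracle checks
on 13-ROI fixtures of 80–120 TRs; factor-model recovery on 100 cohorts of 30
subjects per group (435 within-NT pairs per cohort for the closed-form check,
10 cohorts); censoring efficacy on 100 single-subject cohorts at the default
spike regime; calibration on 1000 null model fits at n = 100 and 100 power
cohorts at n = 34/73. These sizes give stable Monte-Carlo estimates for the
stated tolerances (e.g. ±0.05 on a mean correlation from >4000 pairs) while
keeping a full run in the low minutes on one core.

# Known limitations

* ROI-level only: no voxelwise ISC maps, no NIfTI input (a voxel front-end
  would sit upstream and reduce to this package's containers).
* The BIC Bayes factor approximates, rather than reproduces, default-prior
  Bayesian regression output.
* The motion matcher's candidate set (group extremes) follows the published
  procedure; it is greedy and need not find the globally smallest removal
  set.
* The synthetic world's cross-network IRC is higher than typically observed
  in real data, because the single shared idiosyncratic series per subject —
  needed to produce idiosyncratic-but-internally-coherent responses — also
  correlates ROIs across networks. Group *contrasts* are unaffected.
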