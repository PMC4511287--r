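---
title: "Detecting unidirectional BOLD deactivation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting unidirectional BOLD deactivation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldgate)
```

`boldgate` implements a complete analysis chain for a block-design fMRI
question: does a task *only deactivate* cortex relative to rest (a
"gating" profile), or does it trade activation in some regions against
deactivation in others (an "antagonistic", push-pull profile)? The
package covers the protocol, a forward simulator with known ground
truth, preprocessing, single-subject and group GLMs, Monte-Carlo
cluster-extent calibration, the voxelwise t-distribution and antagonism
statistics, ROI time-course analysis, and the accompanying questionnaire
and respiration analyses. This vignette documents the models, the
defaults and why they were chosen, and what the synthetic validation
does and does not establish.

## The experimental protocol

A run alternates 21-s task blocks with 12-s rest epochs at TR 3 s, five
blocks per condition. The repetitive-speech experiment
(`timeline_rs()`) has three conditions (covert repetitive speech, a tone
discrimination motor task, thought control): 15 task blocks + 15 rests =
495 s (8.25 min, 165 volumes). The verbal-fluency experiment
(`timeline_vf()`) has four conditions and lasts 11 min with 20 rest
epochs. The block order was pseudorandom in the original protocol and is
unpublished, so `build_timeline()` draws a seeded permutation; an
explicit order can be supplied. Block onsets snap to the volume grid by
rounding `onset / TR`, which is exact for the 21/12/3-s geometry. The
short (< 1.1 s) auditory cues at block onsets are absorbed into the
baseline by default, since nothing indicates they were modelled; a cue
regressor can be added by treating the cue as its own condition.

## Regressors and the GLM

Each condition is a unit boxcar over its blocks, shifted by the
haemodynamic lag, convolved with a canonical double-gamma HRF (peak 5 s,
undershoot 15 s, peak:undershoot 6), sampled at the volume times, and
peak-normalised so a coefficient reads in signal units at plateau. The
original analysis assumed a per-participant haemodynamic lag of 3-6 s;
we expose the lag as a configurable onset shift with the midpoint 4.5 s
as default rather than inventing a fitting scheme. (Analyses that want a
per-subject lag can refit at lags {3, 4.5, 6} s and keep the one
maximising mean |t| over task columns; because the simulator and the
analysis share the regressor, the validation below is insensitive to
this choice.)

Rest is never a regressor. The intercept absorbs the pooled mean of
*all* rest epochs, so the unit contrast on a task column is exactly
"task versus the average of all rest periods". Six motion parameters (3
translations, 3 rotations), mean-centred, enter as nuisance columns;
volumes whose translation deviates more than 1 mm from the run median
are excluded before fitting (`motion_exclusions()`). The per-voxel fit
is ordinary least squares with `df = n_used - rank(X)`. Serial
correlation is deliberately *not* modelled: the analysed pipeline
describes none, and we document this as a fidelity limit — with mildly
autocorrelated noise, single-subject voxel p-values are slightly
anticonservative, which is why group inference is always the
random-effects one-sample t across subjects (exactly valid as long as
subjects are independent).

## Preprocessing

- **High-pass**: projection onto a sine/cosine basis at 1..2 whole
  cycles per run is removed per voxel. A regression formulation (rather
  than spectral zeroing) handles any volume count, preserves the
  temporal mean exactly, and is idempotent.
- **Smoothing**: separable Gaussian, FWHM 6 mm (SD = FWHM/2.355 per
  axis, in voxels), reflection padding so constants are preserved and a
  desk-scale grid loses no rim mass. Order is high-pass then smoothing,
  following the order the original methods list them in; both stages
  commute per voxel with the GLM's linearity, so the order matters
  little in practice and is configurable.
- **Concatenation control**: `center_and_concatenate()` subtracts each
  run's per-voxel mean before appending runs in time (removing DC
  offsets between scans) and concatenates motion traces to match.

## The synthetic cohort

`make_ground_truth()` labels voxels `task_positive`, `task_negative` or
`null` with signed amplitudes in percent signal change. The two regimes
encode the competing hypotheses: *antagonistic* has equal positive and
negative fractions (ideal antagonism index 0), *gating* forces the
positive fraction to zero (ideal index -1). Responders are placed as
compact spherical blobs around seeded centres in opposite corners of the
grid ("language-like" for positive, "DMN-like" for negative) because
real (de)activation foci are spatially contiguous; counts are exact
(fraction x grid size) so ideal indices are known.

`generate_subject_bold()` applies the forward model

    signal = baseline * (1 + amplitude/100 * regressor) + drift + AR(1) noise + motion-coupled term

with defaults chosen once for realism at desk scale: baseline 100, 10%
responders per sign, |amplitude| 1% signal change, innovation SD 1
(per-volume SNR ~ 1), AR(1) coefficient 0.2 (mild serial correlation at
TR 3 s), sinusoidal drift at 1-2 cycles/run with amplitude 2/k and
random per-voxel phase (exactly the band the high-pass targets), and a
motion-coupled component of amplitude 0.1 driven by the first emitted
translation trace. The emitted motion trace is identical to the one
mixed in, so the nuisance regression is well-posed. Every generator is a
pure function of its parameters and seed.

The default validation grid is 20x20x20 voxels of 3 mm. This preserves
the voxel geometry while keeping a 23-subject, 165-volume cohort pair
(gating + antagonistic, 8000 voxels each) at roughly ten seconds of
computation, so the acceptance analyses can afford 30-50 full cohort
replicates; validation problem sizes are stated with each reported
quantity.

What the simulator does *not* emulate: cardiac/respiratory coupling
into BOLD, EPI distortion, spatial heterogeneity of noise, and
between-subject variation in response amplitude (truth amplitudes are
shared across subjects; between-subject variance in the group test comes
from estimation noise only). Passing recovery tests therefore shows the
chain is *correct*, not that its power estimates transfer to real data.

## Cluster-extent calibration

`estimate_min_cluster_size()` estimates the minimum cluster size whose
family-wise false-positive probability at a given two-tailed voxel
threshold is at most alpha: per iteration, fill the mask with white
noise, smooth to the nominal FWHM, standardise within the mask,
threshold |z|, and record the maximum cluster size; the returned size is
the smallest k whose exceedance fraction is <= alpha. Choices: the
*nominal* preprocessing FWHM (6 mm) stands in for data-estimated
smoothness (none is described in the source analysis; this is logged and
configurable — it also explains why two experiments with identical
nominal smoothing can print different minima, 98 vs 116 voxels, when
smoothness is estimated from data); face connectivity (6) by default as
the conservative choice; two-tailed thresholding because maps carry both
signs. The estimator refuses alpha below 1/iterations, where the null
tail cannot be resolved. Reproducing the printed 98/116-voxel thresholds
is explicitly out of scope — they depend on the real data's mask and
smoothness.

## The voxel-distribution statistic

For each subject and task, the t map over the cortical mask is binned
from -6 to 6 in unit bins (`tvalue_histogram()`); out-of-range values go
to the outermost bins by default ("clip"), so counts always sum to the
mask size — this conservation is what makes the within-subject error
machinery well-defined, and the source analysis is silent on the point.
Histograms are averaged with Cousineau-Morey within-subject SEMs:
recentre each subject's counts per bin across conditions, take the SEM,
inflate by sqrt(C/(C-1)).

Significant voxels are counted two-tailed at |t| > 2.819. The printed
criterion 2.819 equals the two-tailed Student quantile at df 22, alpha
0.01, although the source text pairs it with "P < 0.05"; we ship 2.819
as the default and expose both the df and alpha knobs
(`critical_t()`). The antagonism index A = (P - N)/(P + N) is computed
per subject; subjects with no significant voxels of either sign have
undefined A and are dropped pairwise from tests, with a warning. Within
each task, positive vs negative percentages are compared by paired t;
across tasks, A is compared by paired t (`distribution_summary()`).

## ROI analysis

ROIs come from an independent localizer map: the peak |t| voxel above
the defining threshold (p < 0.02 two-tailed), grown by repeatedly adding
the adjacent (26-neighbourhood) suprathreshold voxel closest to the peak
(ties broken by lexicographic index) until the next voxel would exceed
the 1000 mm^3 cap — at 3-mm voxels, at most 37 voxels. The "within 10^3
mm of the activity centre" phrasing is read as a 1000 mm^3 volume cap
(consistent with the reported ~890 one-mm^3-voxel ROIs; a 1000-mm radius
is physically meaningless), and "activity centre" as the peak rather
than the centre of mass. Time courses are ROI means converted to percent
signal change against the mean of all rest volumes, cut per block from
the pre-onset rest to the post-offset rest, re-baselined on the
pre-onset window, and averaged; the sustained response is the mean over
a plateau window of 6-21 s after onset (skipping the haemodynamic
rise; exact-recovery tests use 6-18 s so the window ends strictly
inside the block). Sustained responses are tested against zero with a
Bonferroni family of 4 (two ROIs x two conditions) by default.

## Questionnaire and respiration

The behavioural form keeps the analysed structure without inventing
item text: 17 items q01..q17, of which seven are "Thoughts" and three
"Sensations". Scores are unweighted category means; conditions are
compared by paired t with Bonferroni family equal to the number of units
tested (17 items, or 2 categories). Cross-category Pearson correlations
are computed across subjects — the only unit consistent with one rating
per subject per item.

The generator draws per-condition category factors from a bivariate
normal and discretises item scores at fixed latent cut-points
{-1.5, -0.5, 0.5, 1.5} SD. Because discretisation attenuates
correlations, the latent factor correlation is inflated by the
analytically computed attenuation factor so the *observed* item-pair
correlation targets the requested value; defaults target r = -0.24 at
Rest and -0.04 during repetitive speech with Thoughts/Sensations shifts
of -0.8/-0.6 latent SD during the task. Conditions are generated
independently within subject (no shared trait term), which leaves null
calibration of the paired tests intact but understates real
between-condition correlation.

Respiration traces are one sine cycle per breath (positive lobe =
inhale) with lognormal per-breath period jitter, avoiding degenerate
strict periodicity. `extract_breath_params()` segments inhales by a
hysteresis detector (enter above +5% of trace SD, leave below -5%, on a
0.2-s moving average used for detection only), interpolates the flow
zero crossings for boundaries, and reports the five standard measures:
pace, inhale duration, peak, mean and trapezoidal integral. On a
noiseless half-sine of amplitude A and period T these equal 60/ (T),
T/2, A, 2A/pi and AT/pi, which anchors the closed-form tests.
Conditions are compared measure-wise by paired t with Bonferroni
family 5.

## Numerical choices and degenerate inputs

- OLS via Cholesky of X'X after a rank check by QR; rank-deficient
  designs fail naming the collinear columns.
- Voxels whose residual variance is numerically zero at the data's
  scale (constant or perfectly fitted) keep their coefficients but carry
  an undefined (NaN) t.
- Group voxels with zero between-subject variance and non-zero mean
  report a signed infinite sentinel with a warning; zero mean gives t=0.
- Paired tests with zero-variance differences: t=0, p=1 when the
  differences are all zero, otherwise an undefined sentinel.
- All random placement, orderings and noise derive from explicit seeds;
  identical configurations are byte-identical end to end
  (`run_pipeline()` stamps outputs with a config hash and the seeds).

## Known limitations

Plain OLS at the subject level (no prewhitening); nominal rather than
estimated smoothness in the cluster null; no motion correction (motion
parameters are taken as given); no atlas space or cortical surface —
masks are arbitrary 3D arrays; generator amplitudes are chosen for
testability, since the source reports no deactivation effect sizes in
percent signal change; and the questionnaire generator's independence
across conditions is a simplification. None of these affect the
correctness claims the tests make, but all of them matter when carrying
conclusions to real data.
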