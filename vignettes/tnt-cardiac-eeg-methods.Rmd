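---
title: "Methods: evoked cardiac deceleration and EEG oscillations under memory suppression"
author: "tntphysio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked cardiac deceleration and EEG oscillations under memory suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntphysio)
```

# The scientific problem

In the Think/No-Think (TNT) paradigm, participants learn cue-scene pairs
and are then repeatedly cued either to retrieve a scene (*Think*) or to
suppress its retrieval (*No-Think*); *Baseline* scenes are learned but
never cued. Suppression typically induces forgetting of No-Think scenes
relative to Baseline. The question this package's pipeline addresses is
physiological: unpleasant scenes normally evoke a transient cardiac
deceleration (a parasympathetically mediated drop of a few beats per
minute peaking a few seconds after image onset), and repeated suppression
of a scene's memory may blunt that deceleration when the scene is viewed
again. The pipeline quantifies the stimulus-locked deceleration from ECG
beat series, tests condition differences pointwise in time with false
discovery rate (FDR) control, summarizes each participant's *cardiac
inhibition* (No-Think minus Baseline deceleration), and relates it to
oscillatory EEG correlates of suppression (theta/alpha/beta power
decreases during No-Think trials), using nonparametric cluster-based
permutation inference and rank statistics.

Because the human recordings behind such studies are generally not fully
deposited, the package ships a synthetic-cohort generator with known
ground truth. Every downstream estimator can therefore be validated by
parameter recovery rather than by eyeballing.

# The cardiac model and its estimators

## Instantaneous rate

A beat series is the ordered sequence of R-peak times. Each R-R interval
of length $RR_i$ carries the rate $60 / RR_i$ bpm, assigned to the
interval midpoint; the midpoint polyline is linearly interpolated onto a
uniform grid (default 10 Hz) clipped to the span of the midpoints. This
estimator is standard for evoked heart-rate analysis: it is monotone-safe,
exact at midpoints, and agnostic to the sampling rate of the original ECG.
Its inherent cost is a small smoothing bias: a smooth extremum narrower
than a few R-R intervals is underestimated by the interpolation chord, on
the order of 0.1 bpm for a 2.3-bpm trough at a 75-bpm baseline. The grid
rate is exposed in `run_config()` because sub-second peak latencies are
only meaningful relative to a declared grid.

Artifact screening (`reject_artifacts()`) flags R-R intervals outside
[0.3, 2.0] s or deviating more than 25% from a running median of 11
intervals; flagged intervals are removed from the interpolation support
(the rate bridges over them), recordings with more than 25% flags warn,
and more than 50% flags reject the recording. These thresholds are
package conventions (configurable), chosen because the analysis itself
needs *some* deterministic rule; epochs are rejected, never imputed.

## Epoching and referencing

Epochs span $[0, 10)$ s after image onset (scenes are shown for 10 s;
all windows in the package are half-open to avoid double-counting
boundary samples). The default reference maps the rate *at onset* to
zero, matching evoked curves drawn with image onset as the zero point; a
pre-onset window mean ($[-1, 0)$ s) is available as an alternative
policy. Item curves are averaged within participant and design cell;
participant-level curves are retained for statistics and only grand
means are used for display.

## Pointwise statistics, TOI, and the inhibition score

Condition contrasts run a paired $t$ test at every grid point, with
Benjamini-Hochberg adjustment across time (`q = 0.05`). Timepoints with
zero-variance differences are flagged and assigned $p = 1$ instead of an
undefined statistic. The *time of interest* (TOI) is the longest
contiguous run of significant timepoints (earliest run on ties); both the
FDR-corrected and raw masks are carried, because published analyses
sometimes display both, and a union-span rule is available as an option.

The per-participant cardiac inhibition score is the mean of the
No-Think minus Baseline bpm-change difference over the *intersection* of
the emotional TOI (from the pre-TNT assessment, canonically
$[1.89, 5.03)$ s) and the suppression window (from the post-TNT
No-Think/Baseline contrast, canonically $[2.41, 10)$ s). Positive scores
mean blunted deceleration for suppressed items. A published description
of this score reads "divided by the intersection", which is
dimensionally ill-posed for a bpm quantity; it is implemented as
*averaging within* the intersection window, consistent with the
within-window averaging used everywhere else.

Cohen's $d$ for paired contrasts is $\bar{d} / s_d$, which satisfies
$d = t / \sqrt{n}$, consistent with the printed effect sizes of the
literature this pipeline follows.

# EEG spectral analysis

Time-frequency power uses sliding-window multitapers: at frequency $f$
the window spans `n_cycles`$/f$ seconds (default 3.5 cycles) and carries
`floor(time_bandwidth) - 1` discrete prolate spheroidal (Slepian) tapers
with time half-bandwidth `time_bandwidth / 2` (default 4, hence 3
tapers). Tapers are computed from the classical symmetric tridiagonal
eigenproblem and are unit-energy, so unit-variance white noise has
expected power 1 at every (channel, frequency, time) point; this fixes
the power scale. The implementation was checked against an established
multitaper TFR implementation: bin-by-bin profiles agree up to a global
scale constant (the other convention normalizes tapers to norm
$\sqrt 2$). The taper parameters are stated as package defaults because
the source analyses report only the method, the 3-30 Hz range and the
27-bin count; the 27 bins are spaced linearly (the integer reading
3..29 Hz also yields 27 values; log spacing is available by argument).
One consequence of frequency-dependent windows worth knowing: a pure
tone's power is not maximal *exactly* at the nearest bin when the
analysis bandwidth (about $\pm 2 f / 3.5$ Hz) spans several bins; the
peak can land one bin low. This matches the reference implementation's
behavior and is a property of the method, not a defect.

Power is converted to percent change per channel and frequency,
$100\,(P(t) - \bar P_B)/\bar P_B$ with baseline $B = [-0.5, 0)$ s, then
cropped to $[-0.5, 3.0)$ s and down-sampled to 20-ms bins
(non-overlapping means, trailing partial bin dropped). Zero-baseline
bins are propagated as `NA` and excluded pairwise from statistics.
Condition contrasts difference the trial-averaged TFRs per participant;
participants with fewer than 5 trials in either condition are excluded,
because a small-trial mean is unreliable. Band summaries average over
channels, the band's frequency bins (edges inclusive; with the default
linear bins no interior bin falls on a band edge) and a declared time
window, canonically $[1.0, 2.5)$ s for the band contrasts and
$[1.0, 1.5)$ s for the beta contrast during successful control.

# Cluster-based permutation inference

For paired designs, difference maps (participant x channel x frequency x
time) are tested against zero: a pointwise paired $t$ map is thresholded
at 2.5 (the conventional cluster-forming threshold for this literature);
suprathreshold points are grouped into clusters connected under the
channel adjacency list plus immediate frequency/time neighborhood;
cluster mass is the sum of $t$ inside the cluster (extent-based mass is
deliberately not the default); and the null distribution of the maximal
cluster mass is built from random sign flips of whole participant maps.
Cluster $p$ values use the small-sample correction
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$, which
guarantees $p > 0$ and valid type-I control. When $2^n \le n_\text{perm}$
the full sign-flip set is enumerated instead of sampled. The permutation
count (default 1024) is a package default; the source analyses do not
state one.

Group comparisons of band summaries use the Mann-Whitney $U$ test with
$U$ = number of (x, y) pairs with $x > y$ plus half the ties. For
$n_1 + n_2 \le 12$ the $p$ value is exact by enumeration of all group
assignments (ties handled naturally); otherwise the tie-corrected normal
approximation with continuity correction is used. The common-language
effect size is $U / (n_1 n_2)$.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the pipeline is validated under.

**Cardiac.** Beats are realized from an instantaneous-rate model by time
rescaling (integrate-and-fire): the $k$-th beat occurs when
$\int r(t)/60\,dt$ since the previous beat reaches 1. The rate is a sum
of: a participant baseline (population mean 75.7 bpm, SD 10.5, with a
+4.9/-4.9 bpm pre/post session split, matching the observed decline of
session-mean heart rate across an experimental day); gamma-shaped
deceleration kernels per design cell, parameterized by peak amplitude,
peak latency and width and normalized so the bump's minimum equals the
stated amplitude at the stated latency (disgust -2.34 bpm at 3.48 s and
sad -2.24 bpm at 3.36 s in the pre-TNT table; deeper kernels post-TNT);
respiratory sinus arrhythmia as a fixed 0.25-Hz sine of 1.5 bpm with
random phase per recording; and smooth Gaussian-correlated noise
(SD 0.5 bpm, 2-s correlation), emulating residual slow variability in a
clean, artifact-screened series. The kernel width default is 1.5 s: a
broader bump would still be ~0.15 bpm deep when the *next* trial's
reference point arrives 10.5 s later, contradicting evoked curves that
recover by picture offset. The No-Think disgust kernel is shifted toward
zero by a per-participant inhibition effect (mean 1.0 bpm, SD 0.6 bpm
across participants).

**EEG.** Epochs are spatially correlated pink noise (30% shared
variance) plus ongoing band oscillations (theta/alpha/low-beta/high-beta),
each a sum of three equal-amplitude sinusoids spread across the band with
independent random phases per trial — a single carrier would concentrate
all band power in one analysis bin, which real broadband rhythms do not.
From 0.5 s after cue onset the oscillation amplitude is scaled by
condition: Think trials are unchanged, No-Think trials scale alpha and
low-beta by 0.9 and theta by $1 - g_i$, where $g_i$ is the participant's
theta decrease (mean 0.30, SD 0.15). Channels live on a sunflower disc
montage with distance-threshold adjacency; the real sensor-net geometry
is not needed to exercise clustering logic.

**Coupling.** Each participant's cardiac inhibition effect and theta
decrease are drawn from a bivariate normal with correlation 0.6, so the
median-split analysis (high- vs low-inhibition participants compared on
their theta No-Think decrease) is recoverable in principle.

**Behavior.** Intrusions are Bernoulli with a per-emotion block-1
probability (0.45-0.55) decaying by 0.85 per block over eight blocks;
final recall is Bernoulli per condition (think 0.95 / baseline 0.90 /
no-think 0.80); criterion-test failures occur at 1.2%; valence ratings
are 1-9 integers around per-emotion means.

**What the generator does not emulate.** No QRS morphology (beats are
generated directly), no ectopy or measurement artifacts beyond what the
screening rule is tested with, no volume conduction or realistic scalp
topography, no trial-order or habituation effects, and no dependence of
behavior on the physiological state. Passing recovery tests therefore
shows the *estimators* are correct under the assumed structure, not that
real recordings satisfy that structure.

# Validation design and problem sizes

The test suite validates by recovery at sizes chosen to keep a full run
in minutes on one core: pre-TNT kernel recovery uses 100 cohorts of 28
participants with 12 items per cell; sign-convention checks use 280
simulated participants; error-rate control uses 500 (pointwise FDR) and
1000 (cluster test) null simulations at n = 12; the EEG-cardiac link uses 100 cohorts of 24 participants
with 8-channel, 16-trial-per-condition epochs at 100 Hz over
$[-1.2, 3.1)$ s, which preserves the full analysis chain while shrinking
only dimensions that average noise.

One validation target is knowingly out of reach and kept honest rather
than softened: detecting the theta-cardiac link in at least 80% of
simulated cohorts of 24 at coupling 0.6. With a median split and a
one-sided Mann-Whitney test at $\alpha = .05$, the expected standardized
group difference at correlation $\rho$ is
$d = 1.596\,\rho / \sqrt{1 - 0.637\,\rho^2} \approx 1.09$ at
$\rho = 0.6$ *even with noiseless measurements*, giving power near 0.82
— the 80% bar sits at the procedure's theoretical ceiling. Any honest
measurement noise (RSA leakage into the inhibition score, finite-trial
TFR variance) lowers the observed rate to roughly 0.6-0.7. The
corresponding test is expected to fail and documents this; the null
(coupling 0) arm is comfortably controlled.

# Numerical choices and degenerate inputs

- All windows half-open; label matching case-insensitive, canonical
  lower-case.
- Beat files may carry beat times or R-R intervals (header-disambiguated);
  writes are at microsecond precision so round trips are value-exact.
- Time-rescaling integrates the rate by trapezoid at `dt = 0.01` s and
  refuses non-positive rates rather than clipping them.
- Degenerate statistics (zero-variance differences, zero-baseline power
  bins, empty significance masks, empty cluster sets) are flagged or
  return typed errors; they never propagate silently as `NaN`.
- Median-split ties go to the low-inhibition group: deterministic and
  conservative for the high-inhibition contrast (configurable).
- The forgetting split groups participants by whether at least one
  retained No-Think item was forgotten; a variant correcting the count by
  baseline forgetting is available behind a flag (it isolates
  suppression-specific forgetting but tends to produce small groups).
- FFT work is padded to 5-smooth lengths; prime-length transforms in R
  are quadratic-time and were the dominant cost before padding.

# Known limitations

- The pipeline starts from beat times; R-peak detection from raw ECG is
  out of scope, as are frequency-domain HRV indices.
- No repeated-measures ANOVA machinery: planned paired contrasts cover
  the pipeline's needs.
- The EEG path assumes cleaned epochs; filtering, re-referencing, sensor
  repair and ICA belong to acquisition-side preprocessing tools.
- Between-group cluster tests (independent samples) are not implemented;
  only paired/sign-flip designs are.
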