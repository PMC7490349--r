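# tntphysio

Analysis pipeline for the cardiac and EEG after-effects of memory
suppression in Think/No-Think (TNT) experiments, for psychophysiologists
working with ECG beat series and dense-array EEG epochs.

Unpleasant scenes evoke a transient cardiac deceleration — a drop of a
few beats per minute (bpm) peaking ~3-4 s after image onset. Repeatedly
suppressing a scene's memory (the *No-Think* condition of the TNT task)
can blunt that deceleration when the scene is seen again, and the size
of this blunting relates to oscillatory EEG signatures of suppression.
`tntphysio` implements the full analysis chain:

- **Cardiac**: R-R intervals → instantaneous rate (60/RR at interval
  midpoints, linearly interpolated to a uniform grid) → artifact
  screening → baseline-referenced epochs over [0, 10) s → per-participant
  evoked curves.
- **Evoked statistics**: paired *t* tests at every timepoint with
  Benjamini–Hochberg FDR control; time-of-interest (TOI) extraction
  (longest significant run); neutral-deceleration correction; window-mean
  contrasts with Cohen's *d* = *t*/√n; and the **cardiac inhibition
  score** — the mean No-Think − Baseline bpm change over the intersection
  of the emotional and suppression windows.
- **EEG spectra**: multitaper time–frequency power (frequency-dependent
  windows, 3.5 cycles, time-bandwidth 4, DPSS tapers; 27 linear bins over
  3–30 Hz), percent-change baselining over [−0.5, 0) s, 20-ms
  down-sampling, condition contrasts with a 5-trial floor, and band
  summaries (theta 3–8, alpha 8–12, low-beta 13–20, high-beta 20–30 Hz).
- **Cluster statistics**: nonparametric cluster-based permutation tests
  over channel × frequency × time (cluster-forming threshold *t* = 2.5,
  mass = Σt, max-mass sign-flip null, p = (1+#{perm ≥ obs})/(1+n));
  Mann–Whitney U with exact enumeration for small samples and the
  common-language effect size CLES = U/(n₁n₂).
- **Behavior**: criterion-test exclusion, intrusion timecourses across
  the eight TNT blocks, recall and suppression-induced-forgetting scores,
  valence-change scores, forgetting and median splits.
- **Synthetic cohorts**: an integrate-and-fire (time-rescaling) heartbeat
  generator driven by an explicit rate model (baseline + gamma-shaped
  deceleration kernels + respiratory sinus arrhythmia + smooth noise),
  oscillatory EEG epochs with condition-scaled band amplitudes, and TNT
  behavioral contingencies — all with a ground-truth manifest, so every
  estimator is validated by parameter recovery.

## Worked example

Simulate a 12-participant pre-TNT assessment (disgust vs neutral scenes,
12 items per cell), recover the evoked deceleration, then score cardiac
inhibition from a simulated post-TNT session:

```r
library(tntphysio)

cardiac <- cardiac_sim_params(n_participants = 12)
sim <- simulate_cohort_epochs(cardiac, phase = "pre",
                              emotions = c("disgust", "neutral"),
                              conditions = "baseline", seed = 42)
res <- pre_assessment_contrast(sim$epochs)
res$test
#> <pointwise_test> 100 timepoints, n = 12, tail = two: 70 significant after FDR (q = 0.05)
sprintf("peak deflection: %.2f bpm at %.2f s", res$peak$amplitude, res$peak$latency)
#> "peak deflection: -2.14 bpm at 3.50 s"
sprintf("emotional TOI: [%.2f, %.2f) s", res$toi[1], res$toi[2])
#> "emotional TOI: [0.60, 7.50) s"
```

The recovered peak matches the generator's disgust kernel (−2.34 bpm at
3.48 s) up to the ~0.1–0.2 bpm smoothing bias inherent in midpoint
interpolation of ~0.8-s R-R intervals, and the significant window covers
the injected deceleration.

```r
inh <- cohort_inhibition_scores(cardiac, seed = 42, emotions = "disgust",
                                conditions = c("nothink", "baseline"))
head(inh$scores, 4)
#> # A tibble: 4 x 4
#>   participant score true_inhibition true_theta_decrease
#> 1 P01         1.50            1.82                0.257
#> 2 P02         0.603           0.661               0.216
#> 3 P03         0.687           1.22                0.317
#> 4 P04         1.09            1.38                0.433

table(median_split(inh$scores)$label)
#> high_inhibition  low_inhibition
#>               6               6

mann_whitney(c(3, 4), c(1, 2), tail = "greater")
#> <rank_test> U = 4 (n1 = 2, n2 = 2), p = 0.1667 (exact, tail greater), CLES = 1.00
```

Positive scores mean the deceleration to suppressed scenes was blunted
relative to baseline scenes; the `score` column tracks each participant's
`true_inhibition` injected by the generator. `cohort_theta_split()` runs
the full EEG–cardiac chain: inhibition scores → median split →
per-participant theta No-Think power decrease → one-sided Mann–Whitney.

See the methods vignette (`vignettes/tnt-cardiac-eeg-methods.Rmd`) for
the models, defaults, and validation design.

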