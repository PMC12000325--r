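---
title: "Pre-movement phase, behaviour and phase-gated connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-movement phase, behaviour and phase-gated connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasegate)
```

## The scientific question

In trial-based motor experiments, the instantaneous phase of slow
sensorimotor oscillations (theta/alpha, 4–13 Hz) just *before* a movement
can carry information about how the upcoming movement will be experienced —
for example, whether the participant will report a high or low sense of
agency over it. `phasegate` implements the full analysis chain for this kind
of question: does the pre-movement phase separate behavioural outcomes
(phase opposition), is the statistical evidence sound under multiple
comparisons (cluster permutation), is the oscillation physiologically
grounded in spiking (spike–field coupling), and does the phase *gate*
downstream communication (phase-conditioned connectivity and its
directionality)?

## The phase opposition product

For trial-wise complex analytic values $\omega_i$ at a fixed (frequency,
time) point, the inter-trial coherence over a trial set $S$ is

$$\mathrm{ITC}_S = \Bigl|\sum_{i \in S} \omega_i / |\omega_i|\Bigr| / |S|,$$

the resultant length of the amplitude-normalised phase vectors: 1 when all
phases coincide, near 0 when they are dispersed. With two behavioural
conditions $A$ and $B$, the phase opposition product is

$$\mathrm{POP} = \mathrm{ITC}_A \cdot \mathrm{ITC}_B - \mathrm{ITC}_{ALL}^2 .$$

If each condition clusters at its own phase and those phases oppose each
other, the within-condition ITCs are high while the pooled ITC collapses,
so POP is large. POP is 0 for identical phase multisets, 1 for perfect
opposition, and invariant to a global rotation of all phases and to
swapping the condition labels. Amplitude never enters the statistic
(`pop_stat()`, `pop()`).

Because the analytic null distribution of POP is not known, inference is by
label permutation: condition labels are shuffled (condition sizes
preserved), POP is recomputed, and the one-sided p-value is the add-one
smoothed fraction of permutations reaching the observed value
(`permutation_pvalues()`). Smoothing bounds p away from zero at
$1/(n_{perm}+1)$ and makes degenerate (all-tied) statistics report p = 1.

### Cluster correction

p-values across the (frequency × time) map are converted to T-values by the
one-sided standard-normal quantile of $1-p$; points with $T \ge 2$
(approximately p ≈ 0.05, the default threshold) form 4-connected clusters
scored by their T-sum within the declared pre-movement window (default
[−0.5, 0) s). Each permutation's statistic map is ranked inside the same
pooled ensemble as the observed map, converted to T the same way, and the
corrected p of an observed cluster is the fraction of permutations whose
*maximal* cluster score reaches it. Keeping the observed map inside the
ranking ensemble matters: ranking permutations only against each other
(with their self-count) systematically deflates the null cluster scores and
we measured the family-wise error rate at ~0.11 instead of the nominal
0.05; the pooled construction measures 0.02–0.03 on pure-noise maps.

Whether the point-level threshold should be one- or two-sided is not
determined by the construct itself; the package uses the one-sided
transform, consistent with the one-sided POP permutation comparison.

### Group level and ratings

With several subjects, the group statistic is the subject-mean POP averaged
over a declared window, permuted *within* subject (`group_pop_test()`).
Graded agency ratings are first linearly detrended against the go-cue to
movement delay (`detrend_ratings_by_delay()`) — delay is an exogenous
confound of rating — and the highest and lowest thirds form the "high" and
"low" conditions (`split_rating_extremes()`).

## Analytic signal extraction

`morlet_analytic()` convolves each trial with complex Morlet wavelets. The
wavelet width is expressed in cycles; the default is $2\pi \approx 6.28$
cycles (EEG analyses conventionally use $4\pi$ to trade time resolution for
SNR). The Gaussian envelope SD at frequency $f$ is
$\sigma_t = n_{cyc}/(2\pi f)$; samples within $3.5\sigma_t$ of an epoch
edge are flagged invalid rather than silently zero-filled, and the wavelet's
DC gain is removed exactly so constant offsets cannot leak into phase.
Amplitude is normalised so a unit sinusoid yields unit modulus at its own
frequency; phase is unaffected by any such normalisation choice, and power
is reported on this amplitude scale throughout.

Because the wavelet is non-causal, a pre-movement effect could in principle
be smeared backwards from post-movement data. The control extractor
`causal_analytic()` therefore band-passes with a one-pass (strictly causal)
linear-phase FIR — a Hamming-windowed low-pass prototype modulated to the
band centre, applied as a causal complex demodulation. Output at time $t$
depends only on samples at or before $t$; the phase tracks the band-centre
phase with a fixed, reported group delay of `order/(2 fs)` seconds, and the
filter startup region is flagged invalid. On stationary test oscillations
the two extractors agree in phase within 0.3 rad once the group delay is
accounted for.

## Optimal-phase partitioning

The "optimal" phase for an outcome is the circular mean of the
high-condition mean angle and the antiphase of the low-condition mean angle,
averaging the two unit direction vectors without weighting by trial count
or resultant length (`optimal_phase_angle()`). Trials whose phase lies
strictly within π/3 of the optimal angle are "optimal"; strictly within π/3
of its antiphase, "non-optimal"; the boundary case (distance exactly π/3)
and everything else is excluded. With uniform phases each group captures
one third of trials. When the per-trial phase is summarised over a time
window, phases are first de-rotated at the analysis frequency to the window
midpoint — a circular average of a rotating phasor would otherwise cancel.

## Spike–field coupling

The spike–field phase-locking value is the ITC of oscillation phases
sampled at spike times, pooled over units (`spike_field_plv()`); spikes map
to the nearest sample with ties resolved toward the earlier sample. For
von Mises distributed spike phases with concentration $\kappa$ the PLV
converges to the Bessel ratio $I_1(\kappa)/I_0(\kappa)$, which the tests
use as a closed-form oracle. The 5-bin spike-phase histogram is aligned so
the first bin is centred on the global preferred phase; under uniformity
each bin holds 1/5 of spikes, and for a rate density proportional to
$1+\cos$ the bin masses equal the analytic integrals. Firing-rate contrasts
between outcomes use the same cluster-permutation machinery over time bins.

## Phase-conditioned connectivity and directionality

Connectivity between the seed region and targets is the debiased weighted
phase-lag index — an estimator built on the imaginary part of the
cross-spectrum, insensitive to instantaneous (zero-lag, volume-conduction
like) mixing, with small-sample bias correction — computed over all
(trial × window-sample) observations in the post-movement window
(default 0.2–1.2 s) per frequency (`debiased_wpli()`). The exact zero-lag
copy yields a 0/0 expression; it is reported as 0 with a degeneracy flag
because zero-lag mixing is precisely what the estimator is designed to
discount. The optimal/non-optimal contrast is a paired comparison across
subjects per frequency with a sign-flip cluster permutation over the
frequency axis, followed by macro-group aggregation (unweighted mean over
member targets) under Bonferroni correction
(`phase_split_connectivity_contrast()`).

Directionality uses lagged phase coherence: the ITC over window samples of
$\varphi_{seed}(t)-\varphi_{target}(t+\ell)$, per trial and frequency, then
averaged over trials and frequencies so only the lag dependence remains
(`lag_phase_coherence()`). The peak lag's sign indicates the leading
signal (positive = seed leads). The default grid is ±100 ms in 5 ms steps,
snapped to whole samples; peak ties break toward lag 0, preferring the
non-negative lag. Averaging over frequencies *before* locating the peak is
the implemented reading of the aggregation order (the alternative — peak
first, average after — is a one-line change in user code since curves are
returned per call). Per-subject peak lags in optimal vs non-optimal trials
are compared with a paired t statistic computed from its definition;
flat-curve subjects are flagged and excluded with a warning.

## The synthetic-data generator

Every analysis stage has a generator that plants exactly the structure the
stage assumes, so estimators can be validated against known truth:

* `make_phase_coded_trials()` — two balanced conditions; a sinusoid at
  `f0` rides on 1/f background noise (spectral shaping of white noise,
  exponent default 1, matching broadband field-potential spectra) and its
  phase at the pre-movement lock time `t_lock` is von Mises with centre
  `mu_high` ("high") or `mu_high + π` ("low"). The oscillation is
  continuous with the phase pinned at `t_lock`, so the planted effect lives
  at a known (frequency, time) point. Defaults mirror the implanted-cohort
  conditions the package targets: `fs` 250 Hz, epoch [−1.5, 1] s (the 4 Hz
  wavelet needs 1.76 s of support), `f0` 8 Hz, `t_lock` −256 ms,
  `mu_high = 3π/4`, κ = 5, 100 trials per condition.
* `make_agency_labels_from_phase()` — Bernoulli outcomes through the cosine
  link $p_0+\beta\cos(\varphi-\varphi_{opt})$. The strength of the
  phase→behaviour link is a free simulation knob: the source studies report
  the shape of this dependency but not a quantitative effect size.
* `make_spike_trains()` — inhomogeneous Poisson spiking (thinning) with
  rate $r_0(1+m\cos(\varphi(t)-\varphi_{pref}))$; default preferred phase
  4π/3, where unit preferences cluster in the recordings this emulates.
* `make_coupled_source_pair()` — a seed/target pair whose lagged coupling
  direction depends on the seed's phase at `t_lock`: gated trials couple
  seed→target at `+coupling_lag` (default 30 ms), all others target→seed.
  Two additions beyond the minimal construct matter. First, the oscillation
  carries a phase random walk (`phase_diffusion`, default 15 rad²/s, a
  coherence time of a few hundred ms as for cortical alpha): a perfectly
  stationary sinusoid is indistinguishable from its own lagged copy, so
  without phase diffusion the lag-coherence curve is flat and directionality
  has no recoverable truth. Second, `ungated_gain` optionally weakens the
  reverse coupling: with perfectly symmetric gains the WPLI *strength*
  contrast is null by construction (WPLI is direction-insensitive, and
  pooling opposite-lag trials cancels imaginary parts), so cohorts meant to
  show a connectivity increase plant `ungated_gain` < `coupling_gain`
  (the validation cohorts use 0.25 vs 0.9 at noise amplitude 1).
* `make_subject_cohort()` — subjects with individual planted frequencies
  drawn from the alpha band, for the alpha-peak/POP-frequency alignment.

What the generator does *not* emulate: volume conduction and leadfields,
realistic electrode montages, artefacts, non-sinusoidal waveform shape, or
amplitude dynamics correlated with behaviour. Passing tests therefore
demonstrate correctness of the estimators and inference under the stated
generative assumptions — not robustness to every property of real
recordings.

## Individual alpha peak

`fit_background_one_over_f()` fits a straight line to log-power vs
log-frequency over 5–30 Hz and subtracts the back-transformed power law.
`individual_alpha_peak()` then looks for the sharpest local peak — the most
negative discrete second difference after a 3-bin moving average — strictly
inside the 8–13 Hz band; band-edge maxima are rejected. A candidate must
additionally be *prominent*: its relative residual (power/background − 1,
whose estimation noise is homoscedastic across frequency, unlike the
absolute residual) must exceed 4 robust SDs of the out-of-band relative
residual. Otherwise the result is "no peak" (`NA`) — without the prominence
rule, periodogram noise alone produces interior local maxima. The
per-subject frequency of strongest phase opposition
(`peak_pop_frequency()`) averages POP over the pre-movement window per
frequency and takes the frequency of minimal permutation p; saturated ties
break by the larger observed statistic, then the lower frequency.

## Numerical conventions

* Time is in seconds relative to movement onset; windows are closed–open
  [a, b); pre-movement means negative time.
* Angles live in (−π, π]; wrapping is exact (identity) for in-range values
  so strict window boundaries behave deterministically.
* Circular means are undefined (error) below resultant length 1e−12.
* All random draws derive from one seeded generator per call; seeds are
  recorded in outputs, and fixed seeds give bit-identical results.
* Permutation defaults: 10000 for full analyses, reduced counts
  (200–1000) in the validation suite, which analyses maps decimated in
  time; the suite's problem sizes (up to 200 trials, 10–13 frequencies,
  ~150 time points, 20-seed repetitions, cohorts of 10–20 subjects) were
  chosen so the entire validation runs in a few minutes on one CPU.

## Known limitations

* The container format is a plain-text directory (TSV signals + JSON
  sidecar); it is lossless and auditable but not suited to very large
  arrays.
* The causal extractor estimates phase at a single band-centre frequency;
  multi-frequency causal maps require one call per band.
* ROI-level cluster correction over arbitrary adjacency graphs is limited
  to the 1-D frequency axis and 2-D time-frequency grids; anatomical
  neighbourhood graphs are out of scope.
* The alpha-peak estimator models a single bump over a single power-law
  background; multi-peak spectral parameterisation is intentionally not
  implemented.
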