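---
title: "Pre-stimulus EEG microstates, sources and alpha phase: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-stimulus EEG microstates, sources and alpha phase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prestim` implements a single-trial analysis of the EEG immediately
preceding a stimulus: which quasi-stable scalp topography ("microstate")
the brain is in at stimulus onset, which intracranial sources distinguish
experimental conditions in that pre-stimulus window, and what the
alpha-band (10 Hz) power and phase look like under different reference
choices. The two conditions throughout are CA (correct and aware) and CU
(correct but unaware), the classic contrast of metacontrast masking
experiments where physically identical, correctly discriminated stimuli
differ only in reported awareness.

This vignette documents the models, the estimators, the tunable
parameters, the synthetic-data generator that backs every test, and the
numerical choices the implementation makes where the field's conventions
leave room.

## The microstate model

The scalp potential topography is quasi-stable for stretches of roughly
80–120 ms and switches abruptly between a small set of template maps.
During a state only the field *strength* varies; the normalized topography
is fixed up to polarity. Field strength at one time point is the global
field power,

$$GFP(t) = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}\big(u_i(t) - \bar u(t)\big)^2},$$

the population spatial standard deviation over the $N$ channels
(`gfp()`). Local GFP maxima are the cleanest snapshots of the momentary
topography, so each trial is represented by a single map: the one at the
GFP local maximum closest to stimulus onset inside a 50 ms pre-stimulus
search window (`find_prestim_peak_map()`).

**Numerical choices.** A "peak" is a strict window-interior local maximum
of the GFP series; when the window contains none (e.g. monotone GFP), the
sample of maximal GFP is used, boundary allowed, latest sample on ties.
Time offsets are reported with the last pre-stimulus sample at −1 ms.

## Polarity-invariant spatial k-means and model selection

Single-trial peak maps from all subjects and both conditions are pooled
and clustered with a modified spatial k-means (`cluster_microstates()`):

* **Assignment.** Map $x_i$ (mean-removed across channels) joins the
  template $t_k$ (unit norm) maximizing the squared projection
  $(x_i^\top t_k)^2$ — a map and its polarity reversal are treated
  identically, as is standard for spontaneous EEG.
* **Update.** Each template becomes the dominant eigenvector of
  $\sum_{i \in k} x_i x_i^\top$ over its assigned maps (computed by
  warm-started power iteration in compiled code).
* **Restarts.** Each of `restarts` (default 100) initializations seeds the
  templates with $k$ distinct maps drawn from the data; the best final
  explained variance wins. Convergence is a relative explained-variance
  change below `tol` (default 1e-6). Empty clusters are re-seeded with the
  currently worst-fitted map.

The number of classes is chosen by the cross-validation criterion

$$CV(k) = \hat\sigma^2_k \left(\frac{N-1}{N-1-k}\right)^2,
\qquad
\hat\sigma^2_k = \frac{\sum_i \big(x_i^\top x_i - (x_i^\top t_{L_i})^2\big)}
                      {n\,(N-1)},$$

a predictive-residual-variance proxy whose minimum over $k$ (default scan
1..20) selects the model (`cv_criterion()`, `select_k()`). Note the
penalty is mild when $N$ is large: with 204 channels it grows by roughly
1% per additional cluster, so on data whose maps are blends of several
topographies the criterion legitimately picks large $k$. In our synthetic
recovery experiments the selected $k$ matches the planted count when peak
maps are extracted from unfiltered epochs; after 1–30 Hz filtering the
filter's temporal smearing creates genuine between-template mixtures and
CV drifts upward — the same behavior that produces double-digit cluster
counts on real recordings.

## Back-fitting and GEV contrasts

Each trial's peak map is labeled with the template of maximal absolute
spatial correlation

$$C(u, v) = \frac{u'^\top v'}{\lVert u'\rVert\,\lVert v'\rVert}$$

on mean-removed vectors (`spatial_correlation()`, `label_trials()`; ties
go to the lowest template index). The global explained variance of
template $k$ within subject and condition is

$$GEV(k, cond) = \frac{\sum_{t \in cond,\; L_t = k} GFP_t^2\, C_t^2}
                     {\sum_{t \in cond} GFP_t^2},$$

so $\sum_k GEV(k, cond) \le 1$ with equality exactly when every map is a
scaled template. The denominator is per subject × condition, which makes
GEV comparable across subjects with unequal trial counts. Condition
differences are tested per template with a paired two-tailed t test across
subjects (`compare_gev()`; df = subjects − 1); templates with p below the
configured level are the *dissociating* maps.

## Distributed source analysis

**Forward model.** An analytic three-shell spherical head (scalp/skull/
brain radii 1.0/0.92/0.87, relative conductivities 1/0.0125/1). For each
harmonic degree the boundary system of the concentric conductor model is
solved directly, giving surface factors that reduce to the homogeneous
sphere's $(2n+1)/n$ when conductivities are equal; dipole fields are the
truncated Legendre series (default 60 terms) evaluated at the electrodes
and average-referenced (`compute_leadfield()`, `dipole_field()`). The
source space is a quasi-regular cubic grid (default spacing 0.13, about
1000 free-orientation points) clipped to 92% of the brain radius; the
posterior region with $y < -0.5$ in source-space-normalized coordinates is
flagged "occipital" (`source_space()`). A realistic head geometry and
atlas-based gray-matter sampling are out of scope; all localization claims
are therefore statements about planted effects in the spherical model.

**Inverse.** A LAURA-style regularized linear inverse
$M = R A^\top (A R A^\top + \lambda I)^{-1}$ (`build_laura_operator()`).
The prior covariance $R$ combines (a) a local autoregressive smoothness
term — each point's moment is driven toward the inverse-squared-distance
weighted average of its neighbors within 1.6 grid spacings — realized as
$(I-B)^\top(I-B)$ plus a small ridge (2% of its mean diagonal) so the
prior is proper, and (b) depth weighting by the inverse squared per-point
gain norm. $\lambda$ defaults to 0.1 times the mean eigenvalue of
$A R A^\top$. Because depth-weighted minimum-norm magnitudes still
mislocalize deep and tangential sources by a few grid spacings, the
operator by default folds in a resolution-based standardization: each
point's three rows of $M$ are whitened by the inverse square root of its
3×3 posterior-covariance block, after which noiseless single-dipole fields
peak within two grid spacings of the truth across the whole source space.
The exact internal weights of the original method are not recoverable from
the literature values we target, so the operator is deliberately
pluggable; `standardize = FALSE` gives the raw smoothed minimum norm (on
which the classical $\lambda$-shrinkage monotonicity holds).

Per-trial current magnitudes are Euclidean norms of the 3-D moments
(`estimate_source_magnitudes()`). Condition contrasts are paired t tests
across subjects at every solution point on per-subject mean magnitudes
with Benjamini–Hochberg control at q = 0.05 (`spm_contrast()`), reporting
the maximal-|t| point. Following the microstate logic, the pipeline feeds
only trials labeled with the dissociating templates into this contrast
(an `all_trials` switch reproduces the control analysis with every trial).

## Alpha power and phase

The spectral path works on *unfiltered* (only re-referenced) epochs: the
1–30 Hz zero-phase filter is for the microstate path, and band-passing
before phase estimation would distort the analysis window's mainlobe. Each
trial/channel gets a Blackman window
$w[n] = 0.42 - 0.5\cos\frac{2\pi n}{N-1} + 0.08\cos\frac{4\pi n}{N-1}$
over the final 200 ms before onset and a plain DFT: bin spacing
$1/0.2\,\mathrm{s} = 5$ Hz, so 10 Hz is exactly bin 2; off-bin frequencies
are refused rather than interpolated (`spectral_estimate()`). Because the
200 ms window holds an integer number of 10 Hz cycles, the extracted phase
of an on-bin cosine equals its phase at stimulus onset (up to ~1e-4 of
leakage through the window's negative-frequency image). Each channel is
demeaned over the window first: the Blackman DC lobe otherwise leaks a
static electrode offset into bin 2 at about 9% amplitude, which would
masquerade as alpha power; demeaning makes power exactly invariant to
constant offsets and is a no-op for on-bin oscillations.

Phase statistics are circular: per-subject mean phase angles per condition
and electrode (`circular_mean()`), then a Watson–Williams test per
electrode across subjects,

$$F = K\,\frac{(N-2)(R_1 + R_2 - R)}{N - (R_1 + R_2)},
\qquad K = 1 + \frac{3}{8\hat\kappa},$$

with $\hat\kappa$ estimated from the weighted within-sample resultant (the
standard toolbox approximations) and p from $F(1, N-2)$; a warning flags
mean resultants below 0.45 where the test's assumptions are doubtful
(`watson_williams()`). The lag map is the circular difference of group
mean phases (CA − CU) in degrees; electrodes that are significant with
|lag| > 170° are flagged "near-inversion". The analysis runs under five
references — average, linked mastoids, Fpz, Cz, Oz — because phase at a
channel is algebraically the phase of the difference signal against the
reference, so lag topographies are reference-dependent by construction
(`phase_lag_analysis()`). Electrode-wise phase tests are reported on raw p
values by default (matching electrode-count reporting conventions); a
flag enables FDR. Power contrasts (`alpha_power_contrast()`) use paired t
tests per channel with FDR across channels.

## The synthetic-data generator

`simulate_epochs()` builds 204-channel, 1000 Hz epochs (defaults: 300 ms
epochs with 250 ms pre-stimulus) as the sum of

1. a piecewise-constant sequence of planted template maps — themselves
   average-referenced forward fields of random intracranial dipoles, with
   pairwise |spatial correlation| capped at 0.7 — with uniform 80–120 ms
   state durations and no back-to-back repeats. The sequence is built
   *backward* from the epoch end so that the state covering stimulus onset
   follows the configured per-condition occurrence probabilities
   (`state_prob`) exactly; with forward construction the no-repeat rule
   made a strongly favored state systematically *avoid* the pre-stimulus
   window in short epochs. Only the epoch-initial segment is truncated.
2. a strength envelope: a rectified sinusoid at `envelope_freq` (default
   10 Hz, giving in-band ripple at 20 Hz and a GFP local maximum every
   50 ms). A rectified ~20 Hz envelope was considered and rejected: its
   spectrum sits at DC and ≥40 Hz, so the 1–30 Hz analysis filter removes
   the state signal almost entirely. `state_amplitude` (default 5 µV) is
   the planted *peak GFP* of this component.
3. a 10 Hz alpha component projected through a spatial profile (default: a
   Gaussian centred on the occipital pole), whose phase at onset is von
   Mises across trials (`phase_concentration`, default 2) with a
   condition-dependent mean direction (`condition_phase_offset`, default
   π); the amplitude may differ by condition.
4. the forward field of a designated differential source (default placed
   near the posterior pole of the occipital region) scaled per condition
   (`amplitude_CA`/`amplitude_CU`) with a 6 Hz carrier and random trial
   phase, and
5. white Gaussian sensor noise (`noise_sd`, default 1.5 µV ≈ 0.3 × the
   state amplitude).

`simulate_cohort()` adds subject structure: per-subject baseline alpha
phase von Mises around zero (concentration 8) and independent derived
seeds. Everything is recorded in a ground-truth object (state sequence,
onset phases, planted maps, source point, artifact trials), and the whole
output is bit-reproducible for a fixed seed.

**What the generator does not emulate:** 1/f background spectra (noise is
white), ocular/muscle artifacts beyond simple amplitude excursions,
between-channel noise correlations, volume-conducted interactions between
the alpha profile and the state templates, and realistic head geometry.
Passing recovery tests therefore demonstrate the estimators' correctness
and calibration under the stated model, not performance on real
recordings.

## Study conditions used by the validation suite

The recovery experiments run at the sizes the analyses are designed for:
5 planted templates, 204 channels, 150 trials per condition and noise at
0.3 × state amplitude for template recovery (CV scan 1..10 with 20
restarts — restarts beyond ~20 did not change the attained optima on this
data); cohorts of 9–11 subjects with 30 trials per condition for the
phase, power and source contrasts; a ~1000-point grid for the inverse;
4000 null replicates for the Watson–Williams size check and 200 for FDR
calibration of the source contrast. The acceptance script scales some
replicate counts down (10 cohorts for model selection, 8 for the
phase/source recovery rates, 100 null FDR replicates) and reports the
measured rates.

## Known limitations

* The CV criterion's penalty is weak at high channel counts; on mixed or
  temporally smeared maps it selects more clusters than planted. This is a
  property of the criterion, reproduced faithfully.
* The "occipital" region is a coordinate half-space flag in a spherical
  model; no anatomical labels are attempted.
* The spherical-spline interpolation, head model and inverse assume unit-
  sphere electrode positions; digitized montages must be normalized first.
* Watson–Williams assumes comparable, reasonably concentrated von Mises
  samples; the implementation warns, but does not refuse, below the
  customary resultant threshold.
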