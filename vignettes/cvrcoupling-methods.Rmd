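---
title: "Methods: cerebrovascular reactivity mapping and task-BOLD coupling"
author: "cvrcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cerebrovascular reactivity mapping and task-BOLD coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrcoupling)
```

## Scope and model

`cvrcoupling` estimates cerebrovascular reactivity (CVR) from breath-hold
and CO2-inhalation BOLD runs, quantifies the linear coupling between
regional CVR and regional task response magnitude, and corrects group-level
task maps for vascular variance. The computational core is a
mass-univariate ordinary-least-squares GLM per voxel, solved through a QR
factorization; contrast t statistics use
$t = w'\hat\beta / \sqrt{\hat\sigma^2\, w'(X'X)^{-1}w}$ with one-sided
upper-tail p-values by default, because the contrasts of interest are
activation-greater-than-baseline. Percent signal change is
$\mathrm{PSC} = 100\, \hat\beta_w h / \hat\beta_0$, where $h$ is the peak
height of the weighted task regressor measured on the high-resolution
convolved series (before sampling at volume times) and $\hat\beta_0$ the
constant-column baseline. The PSC convention is a genuinely open choice —
peak-height scaling versus raw beta ratios — and both are reachable
(`percentSignalChange(..., scaling =)`); peak-height scaling is the default
because it makes PSC independent of arbitrary regressor scaling and lets
the simulator's injected amplitudes round-trip exactly.

All analyses assume preprocessed, grid-aligned data: slice timing, motion
correction and registration are out of scope, and the synthetic phantoms
are generated already aligned. Residuals are treated as white (no
prewhitening); the default nuisance set is a constant plus a linear trend,
with an optional cosine high-pass basis (128 s cutoff).

## Response kernels

Two impulse responses drive every regressor:

* the canonical double-gamma HRF (response gamma with shape 6, undershoot
  gamma with shape 16, unit scales, undershoot ratio 1/6, 32 s support,
  peak-normalized), peaking near 5 s; and
* the respiratory response function
  $0.6\,t^{2.1}e^{-t/1.6} - 0.0023\,t^{3.54}e^{-t/4.25}$, peaking near 3 s
  with a much deeper relative undershoot that carries non-negligible mass
  out to about a minute — hence its 60 s support (truncation at 30 s still
  leaves ~10% of the peak amplitude in the tail).

A subtlety worth recording: although the respiratory undershoot is deeper
(|min|/|max| ≈ 1.1 versus ≈ 0.09) and much longer than the HRF's, its
*minimum* occurs marginally earlier (≈ 15.4 s versus ≈ 15.8 s). Shape
contrasts are therefore asserted on undershoot depth and duration, not on
the position of the minimum. The respiratory kernel also integrates to a
negative value over its support; only the HRF is required to have positive
integral.

Breath-hold epochs are modelled as a ramp rising linearly 0→1 across each
hold — CO2 accumulates over the hold — and 0 during paced breathing. The
ramp resets at epoch end by default: washout dynamics are carried by the
kernel's long undershoot rather than by the input. Whether the ramp should
instead hold its plateau into recovery is not decidable from first
principles, so `rampRegressor(..., extendIntoRest = TRUE)` provides the
alternative.

Regressors are built by convolution at an internal resolution of TR/16 and
sampled at volume onsets (slice-timing reference 0, since preprocessing is
out of scope). Onset shifts are applied to the input before convolution.

## Breath-hold CVR: staggered-onset selection with kernel fallback

Hypercapnic BOLD responses lag the hold by a subject-specific delay. One
GLM is fitted per onset lag on the grid 0, TR, …, 12 s (the grid includes
lag 0: a subject may have no measurable delay, and a grid starting at one
TR could only hurt; the start is configurable). The model with the most
voxels significant at the one-sided p < 0.001 criterion — the same
uncorrected voxel criterion used everywhere else, for a single consistent
significance notion — is selected. Count ties are broken by the mean t over
significant voxels and only then by the smallest lag: on noise-free data
every lag saturates the count (all in-mask voxels pass the threshold at
every lag of a periodic design), and the goodness-of-fit tie-break is what
makes the selected lag identifiable there; with realistic noise the counts
differ and the smallest-lag rule is effectively what operates.

If the respiratory kernel's best model has fewer than 100 significant
voxels (a proxy for "too few voxels to support the region analysis";
configurable), the search reruns with the canonical HRF and the kernel
with more significant voxels wins. On the synthetic phantoms this fallback
engages, at the noise level used for the cohort simulations, for exactly
the subjects whose data were generated under the HRF forward model.

## Gas-challenge CVR

End-tidal CO2 is extracted from the capnograph trace as per-breath local
maxima with a minimum separation of 2 s and a prominence of at least
2 mmHg (no algorithm is canonical here; these rules reject within-breath
ripple while keeping every true end-tidal peak of a 4 s breath cycle), then
linearly interpolated onto volume times. The baseline is the mean end-tidal
value over a pre-challenge window, and the challenge magnitude is
max(resampled) − baseline.

The end-tidal series is shifted forward in TR steps — CO2 leads the BOLD
response — over 0–18 s, and the shift maximizing the Pearson correlation
with the mean in-mask BOLD series wins (smallest shift on ties; shifts with
fewer than 10 overlapping samples are skipped). Negative shifts are not
searched by default; the range is configurable. The shifted,
baseline-subtracted series enters the GLM in mmHg, so the contrast estimate
is directly interpretable per mmHg; the CVR map is still computed by the
PSC ÷ max ΔPetCO2 route for fidelity to the protocol, and the two agree by
construction since the regressor's peak height equals the end-tidal
excursion.

## Region coupling regressions

Per subject, task PSC and vascular value are averaged over the voxels
significant (p < 0.001, uncorrected) in *both* thresholded maps within each
atlas region. Outlier handling follows the two-stage protocol: first a
single-pass filter on the vascular values removing points more than 3 mean
absolute deviations from the centre, then a single-pass 3-SD rule on both
coordinates immediately before regression. The MAD centring is ambiguous in
the underlying protocol description; the literal reading — deviation about
the sample mean — is the default, with a median-centred switch, and the
convention used is recorded on the output. The two differ materially: for
{1, 1, 1, 1, 100} at k = 3, mean-centring retains the 100 (3·MAD = 95.04 >
79.2) while median-centring removes it.

Regions with fewer than 10 subjects after filtering are dropped. Task PSC
is regressed on the vascular value across subjects; two-sided slope
p-values are Benjamini–Hochberg corrected at q = 0.05 within each task's
region family (each analysis is corrected for the number of regressions it
performs; cross-task pooling would mix families with different region
sets). Summaries report counts, the percentage significant to one decimal,
and an inverse-variance-weighted pooled slope.

Restricting regions to jointly significant voxels is a selection step that
can inflate R²; the property suite asserts the weaker guarantee that
selection never flips the sign of a strong true coupling.

## Group-level vascular correction

Uncorrected group maps are one-sample t-tests per voxel (dof n − 1;
zero-variance voxels are masked with a logged count). Voxel-wise correction
fits, at each voxel, the subject contrast values on an intercept plus the
mean-centred subject covariate values at that voxel, reporting the
intercept t with dof n − 2 — centring keeps the intercept equal to the
adjusted group mean, which is the quantity the correction is meant to
sharpen. Voxels with a degenerate covariate fall back to the uncorrected
model and are flagged. ROI-level correction is the same model with one
scalar covariate per subject, restricted to the region mask.

Cluster-extent correction is provided as a sign-flip permutation null
(default 1000 permutations, cluster-forming p = 0.005, familywise 0.05,
6-connectivity), replacing external cluster-simulation tooling; a plain
voxel-p mode mirrors uncorrected reporting.

## The synthetic cohort: what it emulates, and what it does not

`generatePhantom` carves the grid into connected rectangular blocks
(default 68 parcels on 24×24×18 voxels of 3 mm — fast, unambiguous, and
trivially aligned), not anatomy. `drawGroundTruth` draws per-parcel
population CVR from a lognormal distribution (reactivity is positive and
right-skewed in real maps; default median 0.2 %BOLD/mmHg, sdlog 0.25),
multiplies it by a per-subject lognormal factor (sdlog 0.3 — the
between-subject reactivity variation that the coupling regressions measure;
without it the per-region regression across subjects would be degenerate),
and generates task amplitudes from
task = 0.2 + 0.5·(CVR·ΔPetCO2) + N(0, 0.3), with ΔPetCO2 defaulting to the
9.81 mmHg hypercapnic rise of a 5% CO2 challenge (baseline plateau
35.38 mmHg, hypercapnic plateau 45.19 mmHg).

The forward model per voxel is baseline·(1 + response) + Gaussian noise
(optionally AR(1) with coefficient 0.3; the white default reflects that no
noise structure is prescribed). Breath-hold responses are ramp ⊗
respiratory kernel scaled so the run's peak PSC equals CVR·ΔPetCO2; 13% of
cohort subjects can be generated under the HRF forward model to exercise
the fallback path. Gas responses are the end-tidal envelope excursion times
CVR/100, dispersed through a positive unit-area gamma kernel (the width of
the HRF's positive lobe). A unit-area positive kernel conserves plateau
amplitudes; using the full double-gamma here would overshoot a slow block
input by ~20% (its positive lobe exceeds its net integral), making injected
plateau PSC unrecoverable by construction. Event responses are correct-trial
delta sticks ⊗ HRF scaled to the subject's task amplitude, with 10% of
trials flagged incorrect and modelled as a separate regressor with an
independent amplitude.

The per-subject delay (drawn from {0, 2, 4, 6} s by default) is applied as a
pure shift to the vascular runs only: it models CO2 transit and
accumulation lag, which is what the staggered-onset search and the
cross-correlation shift estimate. Event-task responses use canonical
latency — task GLMs do not lag-optimize, and several seconds of neural-
hemodynamic latency variation would be physiologically unmotivated and
would confound the coupling the generator is defined to embody.

Within-subject noise defaults to 0.5% of baseline for recovery properties
and 4% for the fallback-cohort simulation; the latter is the regime where a
mismatched respiratory kernel drops below the 100-voxel criterion on the
800-voxel test phantom while the matched kernel stays well above, i.e.
where kernel misfit manifests the way the fallback rule expects. These are
design choices of the package (no within-subject noise level is prescribed
by the protocol), chosen once for plausible single-subject t statistics.

What the phantoms do *not* emulate: anatomy and tissue boundaries, spatial
noise correlation and scanner drift structure, head motion coupling into
the signal (motion parameter files are emitted as nuisance bookkeeping
only), susceptibility distortion, and any nonlinearity of the CVR response
(sigmoidal saturation at high CO2 is out of scope). Passing recoveries
therefore validate the estimators' correctness and calibration under the
stated generative model, not their robustness to artefacts of real scans.

## Numerical choices and degenerate inputs

* Convolution at dt = TR/16; kernels peak-normalized exactly (max = 1).
* Exactly constant voxel series (synthetic background) are dropped from
  the mask with a logged count, not errors; voxels fitted exactly
  (zero residual variance) get infinite |t| and p ∈ {0, 1} by the sign of
  the contrast rather than NaN.
* Non-positive baselines mask the voxel out of PSC maps.
* Ties: smallest lag / smallest shift, after the count and correlation
  criteria respectively.
* Atlas resampling is nearest-neighbour with ≥ 0.5 partial-volume
  binarization when grids differ; the synthetic atlas is generated on the
  functional grid so the default path needs none.
* Filters are single-pass; identical values are never removed (the
  deviation scale is 0 and the rule uses a strict inequality).

## Problem sizes

The test and acceptance suites run, per invocation: 200 random small
least-squares problems against a brute-force normal-equation oracle;
noiseless lag recovery over the full 0–12 s grid plus 50 noisy replicates;
one 68-parcel gas-challenge run at 0.5% noise for CVR recovery; 200
replicates of 68-region coupling regressions at n = 100 subjects for
interval coverage; 500 null-coupling replicates for the FDR rate; 100
replicates of the covariate-correction contrast; and a 114-subject
breath-hold cohort (15 HRF-generated) for the fallback fraction. These
sizes make the full suite run in a few minutes while keeping Monte-Carlo
standard errors well inside the asserted tolerances.

## Known limitations

Lag and shift optimization are subject-wise, not voxel-wise; respiratory
kernel coefficients are fixed (no subject-specific estimation); no
F-tests, HRF derivative expansions, prewhitening, or random-field
corrections; two-sample group designs are out of scope. The coupling
regressions inherit the selection effects of joint voxel thresholding
discussed above.
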