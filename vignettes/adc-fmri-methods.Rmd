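---
title: "ADC-fMRI analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ADC-fMRI analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcfmri)
```

## The problem

Blood-oxygen-level-dependent (BOLD) fMRI reads out brain activity through the
vascular response, which confounds the interpretation of activation maps
wherever vascularization differs across regions, and which is nearly blind to
white matter. Diffusion fMRI with apparent-diffusion-coefficient (ADC)
readout targets neuromorphological coupling instead: activity-linked
microstructural change (for example cell swelling) lowers the tissue's
effective water diffusivity during excitation. `adcfmri` implements the
analysis chain for such experiments — rodent visual stimulation in a block
design, with a gradient-echo BOLD series and a spin-echo diffusion-weighted
series acquired with two alternating b-values — together with a synthetic
phantom that makes the whole chain verifiable against known ground truth
without any acquired data.

## The ADC time course

The diffusion-weighted series alternates two weightings every second,
b1 = 200 and b2 = 1000 s/mm². Splitting per b-value gives two series at 2-s
sampling (252 volumes each under the default 504-s paradigm), from which the
ADC time course is computed per voxel and pair:

$$\mathrm{ADC}(t) \;=\; \frac{\ln\!\big(S_{200}(t)/S_{1000}(t)\big)}{b_2 - b_1}.$$

Both weightings share every b-independent signal factor — T2 relaxation and
therefore the BOLD effect — so those cancel in the ratio. The lower b-value
sits above the intravoxel-incoherent-motion (IVIM) pseudo-diffusion regime,
suppressing (though not eliminating) direct perfusion contributions. Voxels
with any nonpositive sample, which Rician magnitude noise can produce at low
SNR, are flagged invalid and excluded from all inference rather than clipped.

A cosmetic 1-s ADC series is available through pairwise interpolation (each
measured b-value paired with the other weighting linearly interpolated to
the same time point; 2n − 1 samples, nearest-measurement at the leading
endpoint). It is used only for plotting and epoch averages; GLM and FIR
inference always run at the native 2-s resolution.

## The phantom's signal model

Each region of the synthetic label map carries tissue parameters for the
IVIM biexponential with three activity-locked mechanisms:

$$S(b,t) = s_0\,\big(1 + a_v\,r_v(t)\big)\Big[(1 - f(t))\,e^{-b\,D(t)} +
f(t)\,e^{-b D^\*}\Big],$$

with diffusivity $D(t) = D_0(1 + a_d\,r_d(t))$, perfusion fraction
$f(t) = f_0(1 + a_f\,r_f(t))$ (clipped to $[0,1)$; reaching 1 is an error),
and unit-peak response waveforms $r(\cdot)$. The three mechanisms are kept
separable on purpose:

* $a_v$ — multiplicative (T2/BOLD) modulation; visible in the BOLD series,
  cancels exactly in the ADC.
* $a_d$ — diffusivity modulation; negative values encode the excitatory,
  neuromorphological ADC decrease.
* $a_f$ — perfusion-fraction modulation; the switchable "residual vascular
  contamination" route that produces positive, BOLD-shaped ADC responses.

Response shapes are either `block` (first-order exponential relaxation
toward the stimulus boxcar, time constant `rise_tau_s`, default 2.5 s for
vascular and 2 s for diffusivity responses) or `double_peak` (transient
onset and offset peaks over an intermediate plateau, the superior-colliculus
signature under high-frequency stimulation). The double-peak
parameterization — causal Gaussians of FWHM `peak_width_s` starting at the
block edges, centered 2 s after them, over the relaxed plateau — is this
package's own concrete choice for a shape that the source observations
describe only qualitatively. Waveforms are normalized to unit peak on the
simulation grid, so a shape's `amplitude_pct` is exactly the peak fractional
change it produces.

### Calibrated presets

`preset()` returns tissue parameters whose noise-free pipeline output
reproduces the reported region amplitudes (medial/lateral superior
colliculus and corpus callosum, at 1-Hz and 25-Hz flicker): BOLD +2.2 % with
ADC −0.5 % via $a_d$ in mSC, BOLD +1.5 % with ADC +0.7 % via $a_f$ only in
lSC, ADC −0.3 % with no BOLD in CC at 1 Hz; −0.2 %, +0.6 % (BOLD +1.2 %) and
−0.2 % at 25 Hz, where the SC BOLD shapes are double-peaked. Because the ADC
of a biexponential is not linear in $D$ or $f$, the amplitudes $a_d$ and
$a_f$ are calibrated by root finding against the biexponential so that the
peak fractional ADC change equals the target exactly at waveform peak;
grey-matter baselines are $D_0 = 0.7\times10^{-3}$ mm²/s, $f_0 = 0.05$,
white matter $D_0 = 0.8\times10^{-3}$, $f_0 = 0.02$, and
$D^* = 10^{-2}$ mm²/s throughout.

### Sampling, noise and drift

Both series are generated at TR = 1 s over the default paradigm: 24 s rest,
then 12 epochs of 16 s stimulation + 24 s rest (504 volumes; flash frequency
and flash duration are metadata — the regressors model whole blocks). For
the interleaved series the physiological waveforms are sampled once per
b-value pair, both members sharing the waveform value at the pair's start
time. This makes the multiplicative-BOLD cancellation in the ADC exact by
construction. Real acquisitions violate this slightly — T2 changes between
the two successive 1-s volumes of a pair — and that imperfect cancellation
is deliberately **not** emulated; it is the main generator limitation to
keep in mind when extrapolating test results to acquired data.

Noise is Rician by default (two independent Gaussian draws per voxel and
volume; Gaussian available for analytic tests), with width set through an
SNR knob, `snr = s0 / noise_sigma`, default 450. This default represents the
residual noise level after the denoising that real pipelines apply upstream
(the preprocessing chain of acquired data — MP-PCA denoising, unringing,
distortion and motion correction — is out of scope here and substantially
raises effective tSNR). It was chosen by a power analysis so that the
subject-level FIR chain detects the smallest planted sub-percent ADC
amplitudes with useful power (≈ 0.6 per voxel) on the default 32 × 32 × 4
grid with ~74-voxel regions: the phantom's role is to verify the detection
chain, not to emulate raw scanner SNR. A slow multiplicative sinusoidal
drift (1 % amplitude, 300-s period, random phase per voxel) stands in for
scanner instabilities and is removed by the high-pass filter.

## Temporal filtering

High-pass filtering regresses out a discrete-cosine basis spanning periods
longer than the 100-s cutoff and keeps the temporal mean (the basis is
mean-free). Compared to an IIR filter this has no phase distortion and exact
behaviour on short series. With 504 samples the basis holds 10 regressors; a
200-s drift is attenuated to below 10 % while the 40-s epoch fundamental
passes at better than 99 %. Series shorter than the cutoff are returned
unchanged with a warning.

## Detection: GLMs and cluster-extent inference

BOLD series are tested with an ordinary least-squares GLM on an intercept
plus the raw stimulus boxcar — the rodent hemodynamic response is fast
enough that the unconvolved boxcar outperforms a canonical HRF — and the
boxcar t statistic is mapped to z through the exact quantile transform
(log-tail evaluation; |z| capped at 38). ADC series are tested without shape
assumptions: the boxcar is convolved with a finite-impulse-response basis
(4 lag bins over a 16-s window by default) and all FIR coefficients are
tested jointly with an F statistic mapped to a one-sided z. The omnibus z
carries no sign; polarity is assigned later from the response time course.
Temporal autocorrelation is not modeled (the phantom's noise is white); with
acquired, denoised data this is an acknowledged approximation.

Cluster correction thresholds the z map at |z| > 2.3 (positive and negative
tails separately), groups supra-threshold voxels by 26-connectivity (the
most inclusive 3-D neighbourhood; the choice matters little at these blob
sizes), and keeps clusters whose extent exceeds the permutation null of the
maximum cluster extent at α = 0.05.

The permutation null deserves a note. Shifting the raw series circularly in
time is the textbook recipe, but with a *periodic* block design a fraction
of the shifts realigns the stimulus with the response (any multiple of the
40-s cycle, and partially for shifts within the FIR window of one), so
strong true responses leak into the null and suppress weaker true clusters
elsewhere in the volume. The package therefore permutes **residuals under
the full model**: the fitted stimulus-locked component is removed, the
residuals are circularly shifted (preserving their autocorrelation), the
intercept is re-added, and the GLM is refit on the surrogate. This is exact
under the global null, signal-free otherwise, and costs the same (the
surrogate fit reduces to shifted cross-products plus a rank-one update).
With 100–1000 permutations the attainable p floor is 1/(n+1); empirical
family-wise error over 200 null simulations sits inside [0.01, 0.10].

Group maps are one-sample t statistics across subjects per voxel (synthetic
subjects share the grid, standing in for template registration), mapped to
z, with zero-variance voxels capped at |z| = 8. Group-level cluster
correction uses sign-flip permutations across subjects — the package's own
choice for a level the analysis chain otherwise leaves open.

## Response classification and epoch averages

Voxels significant in the FIR analysis are pooled across subjects. Each
voxel contributes its epoch-averaged response: every 40-s epoch window
(starting 6 samples before onset) is normalized to the mean of its first 6
samples, converted to fractional change, and averaged over the 12 epochs.
Clustering operates on these epoch-averaged responses rather than full time
courses: epoch averaging is what makes rows comparable across subjects with
different noise realizations, and it is the response shape, not the noise
realization, that the classification should see. K-means (Euclidean, k = 10,
k-means++ seeding, 10 restarts, fixed seed; responses are onset-locked by
the trigger, so no time warping is needed) partitions the rows; each
cluster's polarity is the sign of its centroid's mean over the stimulation
window, voxels inherit their cluster's polarity, and exactly-zero centroids
join neither pool. Surplus clusters beyond the phantom's two archetypes are
harmless — polarity pooling merges them.

Two conventions are deliberate choices where the procedure is
underdetermined: the epoch window includes a pre-onset baseline (6 samples,
exposed as a parameter) because plotted responses conventionally show one,
and "first six volumes" is interpreted at each stream's native sampling —
6 s of baseline for BOLD at 1 s, 12 s for native ADC at 2 s.

## Numerical choices and degenerate inputs

* t→z and F→z transforms run through log tail probabilities, staying exact
  far beyond |z| = 8; subject-level |z| caps at 38 (noise-free fits map to
  the cap instead of infinity).
* Equal signals give ADC 0 exactly; monoexponential signals with
  ΔB = 800 s/mm² recover the planted diffusivity to machine precision.
* Baseline means ≤ 0 drop the voxel from response extraction with a log
  message; empty masks and all-zero z maps yield empty cluster tables, not
  errors.
* K-means reduces k with a warning when there are fewer distinct rows than
  clusters; identical rows collapse to one effective cluster.
* All randomness (phantom noise, drift phases, permutations, k-means
  restarts) flows through explicit seeds; package functions restore the
  caller's RNG state.

## Problem sizes

The shipped validation uses the 32 × 32 × 4 default grid (seven ~74-voxel
regions), 504-volume series, 6 synthetic subjects for chain-level checks,
12 runs for amplitude recovery, 100–200 permutations per cluster
correction, and 200 simulations for the family-wise-error calibration —
sizes chosen so the full suite runs on a desk machine in minutes while
keeping every statistical check adequately powered.

## What passing tests do and do not show

The phantom emulates the signal mechanisms (multiplicative BOLD,
diffusivity modulation, IVIM contamination), magnitude noise, and slow
drift on a simplified geometry. It does not emulate imperfect T2
cancellation between successive volumes, EPI distortion, motion, spatial
correlation of noise, temporal autocorrelation, realistic anatomy, or the
preprocessing that acquired data require upstream. Passing tests therefore
demonstrate that the estimator, inference and classification chain is
correct and calibrated under the stated model — not that acquired data meet
that model's assumptions.
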