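---
title: "Single-channel removal of facial EMG artifacts from EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel removal of facial EMG artifacts from EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgclean)
```

## The problem

Contraction of facial muscles (Frontalis, Masseter, Orbicularis Oculi,
Orbicularis Oris, Zygomatic) produces electromyographic (EMG) activity that
reaches scalp EEG electrodes by volume conduction. Facial EMG is broadband —
its energy overlaps every EEG rhythm from delta to gamma — and during a
contraction the EEG can sit 10 dB or more *below* the artifact. Frequency-
selective filtering therefore cannot separate the two, and with a single
channel the usual spatial decompositions (ICA, CCA, multichannel Wiener)
are unavailable.

`emgclean` implements a single-channel alternative built from three ideas:

1. **Decompose** the contaminated record into components (EMD, EEMD, SSA,
   CiSSA, a coif5 wavelet multiresolution, or EMD followed by a
   principal-axis reduction).
2. **Shrink** each component by soft-thresholding against statistics of the
   noise-only (EMG-free) portions of the record, and sum the shrunk
   components. Because baseline EEG rarely exceeds its own noise-region
   threshold while bursts greatly do, the reconstruction is an estimate of
   the artifact: the **EMG reference**. Its complement (contaminated minus
   EMG reference) is the **EEG reference**.
3. **Cancel adaptively**: the reference drives an adaptive filter (LMS,
   NLMS, RLS, or a batch Wiener FIR) with the contaminated record as the
   desired signal. With an EMG-like reference the cleaned signal is the
   cancellation error `d - y`; with an EEG-like reference it is the filter
   output `y`. This selection rule is the only reading under which both
   reference types remove the artifact, so it is stated explicitly in
   `adaptive_filter()` rather than left implicit.

## Processing stages and their parameters

### Detrending and outliers

Electrode-impedance drift and cable motion produce slow trends. The linear
trend is the least-squares line; the non-linear trend is the sequence of
medians of non-overlapping 20 ms windows (100 samples at 5 kHz),
re-expanded to every sample by monotone piecewise-cubic (pchip)
interpolation. A trailing partial window is kept as its own window so no
samples are discarded, and the first/last medians are held constant to the
record edges so no extrapolation occurs. The same pchip interpolant builds
the EMD envelopes, keeping the package's interpolation behaviour uniform.

Note a side effect worth planning around: median anchors spaced 20 ms apart
can represent oscillations up to roughly 25 Hz, so subtracting this trend
also high-passes the record near that frequency. For EMG (20-450 Hz) this
only removes baseline wander, but on EEG it attenuates the delta-to-beta
rhythms along with the drift. `run_pipeline()` exposes
`detrend_window_ms`, and widening it (e.g. to 200-500 ms) confines the
detrend to sub-rhythm drift when the slow bands must survive the cleaning
chain.

Amplitude outliers are defined from the EMG-contaminated region only: mean
± 10 SD of the mask-high samples. Violating samples anywhere in the record
are replaced by *standard normal* draws — deliberately not rescaled to
microvolt units, which is worth knowing when the channel's scale is far
from unity; everything else is returned bit-identically.

### Decomposition

* **EMD** — sifting with pchip envelopes of the local extrema, Huang's
  normalized squared-change criterion at 0.2 per sift, at most 100 sifts
  per mode and at most 10 intrinsic mode functions; the final residue is
  stored separately, so IMFs + residue reconstruct the input exactly. The
  cap of 10 counts IMFs only, not the residue.
* **EEMD** — 5 ensemble members with added white noise at 0.2 × signal SD,
  seeded, component-wise averaged (members with fewer modes are
  zero-padded). The ensemble average does not reconstruct exactly; that is
  inherent to the method.
* **SSA** — window length 100, eigendecomposition of the trajectory
  covariance, one component per eigentriple in descending eigenvalue order
  until 80% cumulative variance, then the remainder as a final component so
  the set always sums to the input. Diagonal averaging is computed via
  convolution (O(n log n) per component).
* **CiSSA** — the circulant variant: Fourier eigenvectors tie every
  elementary component to a frequency j/L; conjugate pairs are merged, the
  largest-share bins kept individually (at most 9) and the rest aggregated
  into one closing component, keeping the 10-component cap *and* exact
  reconstruction.
* **Wavelet** — periodized orthogonal DWT with the 30-tap coif5 filter, one
  reconstructed component per detail level plus the final approximation
  (perfect reconstruction by orthogonality). The depth is capped at
  min(10, feasible depth), where feasibility requires each stage to halve
  an even number of samples that still exceeds the filter length; for
  typical record lengths this yields 3–8 levels rather than the nominal 10.
* **EMD-PCA** — EMD components (plus residue) stacked as a matrix and
  rotated to uncentered principal axes (SVD); axes are kept until 80% of
  the component-matrix energy. The reference built from this method skips
  soft-thresholding entirely: the rank reduction itself is the denoiser.

### Soft-thresholding

For component m the threshold is `t_m = k · SD` of that component over the
mask-low (noise-only) samples, pooled by default across all low samples; a
`noise_window` argument restricts them to one interval when only a single
calibrated noise stretch is trusted. Shrinkage is
`sign(c) · max(|c| − t_m, 0)`. The multiplier `k` defaults to 1.5, its
typical operating value; sweeping k from 0.1 to 2.0 in steps of 0.1
produces the GL(k)/GH(k) feature curves used to quantify contamination.

### Burst detection

The contamination mask can be supplied, or detected: detrend → EMD →
soft-threshold with thresholds from a declared noise window → sum →
centered moving-RMS envelope (100 ms) → binarize at envelope mean + 3 SD
over the noise window → drop high runs shorter than 250 ms → merge gaps
shorter than 200 ms. Detection is preferably run on a simultaneously
recorded EMG channel, but works directly on the corrupted EEG.

Two cleanup values deserve justification. The minimum duration must exceed
the envelope window: a single above-threshold instant is smeared to
roughly the window length (~100–130 ms observed at 0 dB in-burst SNR), so a
100 ms minimum admits false bursts; 250 ms is 2.5 × the envelope window and
still half the shortest contraction the protocol produces (500 ms). The
merge gap (200 ms) is an order of magnitude below the 2 s inter-contraction
gaps, so distinct contractions are never fused.

### Adaptive cancellation

Defaults follow the study configuration: order 10 (NLMS: 4), LMS step
µ = 1e-7 on microvolt-scale inputs. A literal step size has no meaning for
the normalized or recursive filters, so the stated 1e-7 maps onto the NLMS
power regularizer and the RLS inverse-correlation initialization
(P(0) = I/1e-7), with a normalized NLMS step of 0.1 and an RLS forgetting
factor λ = 0.999 (nowhere stated; exposed in `filter_config()`). The batch
Wiener filter solves the order-10 Toeplitz normal equations from the
biased sample autocorrelations; its tap estimates carry an O(1/n) edge
bias, visible only below ~1e-5 at 2·10^5 samples. Weights start at zero
with zero-padded history, making LMS/NLMS/RLS fully deterministic. RLS
re-symmetrizes its inverse-correlation matrix each step; without this,
accumulated floating-point asymmetry destroys positive definiteness within
a few tens of thousands of samples on realistic records.

One practical caveat: when the reference is nearly silent between bursts
(an EMG channel with a −40 dB floor), NLMS weights random-walk during the
silence and produce onset transients at the next burst; on records of a few
minutes the median-based features absorb this, but on very short records
NLMS can transiently amplify. RLS is far less susceptible because its gain
collapses when excitation is weak.

### Evaluation features

All four time-domain features are medians of 1 s windowed RMS values,
windows tiled over the *concatenated* samples of a mask region. Tiling the
concatenation (rather than per-interval) lets 0.5 s bursts — a third of the
protocol — contribute; the alternative discards them. `GL` (noise-region
output/input, dB; 0 is ideal) and `GH` (EMG-region output/input; negative
is attenuation) evaluate a filter; `GXin`/`GXout` compare the in/out
contrast before and after. Logarithms are base 10 (dB convention).

Spectral features use the Yule–Walker AR(10) spectrum on the grid
0 : Δf : fs/2 with Δf = 0.01 Hz by default (coarser grids are accepted and
grid-converged for the quantities reported); the median frequency is the
smallest grid point at which cumulative mass reaches half the total, and
its "power" is the PSD value at that point (the natural reading of the
associated energy at the median frequency). Band analysis splits the
signal with a zero-phase brick-wall FFT band-pass at Delta 0.5–4, Theta
4–7, Alpha 7–13, Beta 13–30, Gamma 30–70 Hz (left-closed bands; gamma
capped at 70 Hz). The brick wall is used instead of an IIR design because
at 5 kHz sampling the delta band occupies 1e-4 of the Nyquist range, where
high-order IIR band-passes are numerically fragile; zero-phase FFT masking
is stable at any band/rate combination.

The contamination index between the GL(k) and GH(k) curves is the
normalized Euclidean distance `d(u,v) = ‖u−v‖ / (‖u‖+‖v‖)` — bounded in
[0, 1], symmetric, zero iff the curves coincide. The literature the
measure descends from admits several normalizations; this bounded form was
chosen and is stated explicitly so results are comparable.

## The synthetic generator

No public dataset reproduces the acquisition: five facial muscles, each
contracted 15 times per eye condition (five each of 3 s, 1 s, 0.5 s in
seeded random order), a 2 s neutral period after every contraction, the
whole protocol run once with eyes open and once closed — 150 contractions
and 225 s of contaminated signal per participant, 2,250 s for ten. The
generator reproduces this schedule exactly (duration-class order is
randomized within each muscle block, which is also the only randomization
the protocol description supports; muscle order is kept fixed), and each
muscle block is preceded by a 2 s neutral lead-in that doubles as the
burst detector's noise window.

The EEG is a superposition of FFT-band-limited Gaussian noise in the five
rhythm bands with open-eyes variances (µV²) Delta 40, Theta 15, Alpha 20,
Beta 10, Gamma 2 — a ~9.3 µV RMS channel with the usual low-frequency
dominance. During the closed-eyes half the alpha variance is multiplied by
4, a pronounced posterior alpha enhancement. The EMG channel is 20–450 Hz
Gaussian noise gated by a trapezoidal envelope (50 ms ramps inside the
contraction, so the mask equals the envelope support exactly) over a
−40 dB baseline floor. `mix()` scales the EMG so the requested in-burst
SNR holds exactly over the mask (−10 dB by default, the heavy-contamination
regime).

What the generator does *not* emulate: volume-conducted spatial structure
across a montage (a single channel is synthesized), muscle-specific
spectral signatures, eye blinks, ECG, line noise, non-Gaussian EEG
microstructure, or non-stationarity within a block. Passing tests on this
material therefore demonstrate the pipeline's signal-processing
correctness and its behaviour under protocol-faithful timing and SNR — not
robustness to every artifact class of real recordings.

## Numerical choices and degenerate inputs

* Component sets always reconstruct through `reconstruct()`; completeness
  is asserted at 1e-8 relative error for EMD, SSA, CiSSA and Wavelet.
* `mix()` errors on an all-low mask (gain undefined); thresholds error
  without at least two noise samples; `region_rms_median()` errors when a
  region is shorter than one window; the Wiener solve reports singularity
  (e.g. an all-zero reference) rather than returning garbage.
* A monotone input yields a single-component EMD set (the trend itself) so
  downstream stages always receive at least one component.
* Ties in the median-frequency search resolve to the smallest grid
  frequency; band edges are left-closed.
* Seeds: every stochastic stage (protocol permutation, EEG/EMG noise,
  EEMD ensemble, outlier replacement) draws from a named substream derived
  from one root seed, and restores the caller's RNG state afterwards.

## Scale of the shipped validation

The test-suite and acceptance runs synthesize at 1 kHz (and 200–500 Hz for
purely spectral checks) with records of 10–300 s — sizes chosen so the full
validation executes in minutes while every property being checked
(completeness, SNR calibration, detection accuracy, cancellation gains,
curve monotonicity) is scale-free or already asymptotic at those lengths.
The contamination-monotonicity check uses in-burst SNRs of +5, −5 and
−15 dB: the distance metric is bounded by 1 and saturates under extreme
contamination, so levels are placed inside its sensitive range — the
ordering, not the spacing, is the property under test.

## Known limitations

* EEMD is approximate by construction (no exact reconstruction), and its
  computational cost is 5 × EMD.
* The wavelet depth cap depends on the 2-adic structure of the record
  length; prime-ish lengths get shallow decompositions.
* Burst detection assumes a declared noise-only window and ≥ 2 s gaps; it
  is an offline procedure, not a streaming detector.
* File I/O is delimited text (plus JSON sidecars); EDF is not read or
  written.
* Inferential statistics over feature distributions (ANOVA and friends)
  are out of scope; the package emits tidy feature tables for whatever
  downstream framework the user prefers.
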