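# emgclean

Single-channel attenuation of facial EMG artifacts in EEG.

Contractions of facial muscles (Frontalis, Masseter, Orbicularis Oculi,
Orbicularis Oris, Zygomatic) contaminate scalp EEG through volume
conduction. The artifact is broadband — it overlaps every EEG rhythm — and
in contaminated stretches the EEG can lie 10 dB or more below the EMG, so
neither band-pass filtering nor (with one channel) spatial decomposition
can remove it. `emgclean` implements a decomposition-based single-channel
pipeline for exactly this situation, together with the evaluation features
needed to quantify how well it worked.

## Method

For a contaminated record `x` with a binary contamination mask (high =
EMG active, low = noise-only EEG):

1. **Detrend**: subtract the least-squares line, then the non-linear trend
   (medians of non-overlapping 20 ms windows, pchip-interpolated back to
   all samples). Outliers beyond mean ± 10 SD of the contaminated region
   are replaced.
2. **Decompose** `x` into components `c_1 … c_M` by EMD, EEMD, SSA, CiSSA,
   a coif5 wavelet multiresolution, or EMD-PCA.
3. **Soft-threshold** each component with `t_m = k · SD(c_m | mask low)`
   (default `k = 1.5`):
   `tc_m = sign(c_m) · max(|c_m| − t_m, 0)`.
   Summing the shrunk components yields the **EMG reference**;
   `x − EMG_ref` is the **EEG reference**. (EMD-PCA skips thresholding:
   its reduced-rank reconstruction is used directly.)
4. **Adaptive cancellation**: LMS, NLMS, RLS (order 10, NLMS order 4) or a
   batch Wiener FIR driven by the reference, desired signal `x`. The
   cleaned EEG is the cancellation error for an EMG-like reference, the
   filter output for an EEG-like reference.
5. **Evaluate** with windowed-RMS median features (1 s windows):
   `GL = 20 log10(Xout0'/Xin0')` (noise region; 0 dB is ideal),
   `GH = 20 log10(Xout1'/Xin1')` (EMG region; negative = attenuation),
   plus `GXin`/`GXout`, Yule-Walker AR(10) spectra with median frequency
   per EEG band, and the normalized Euclidean distance
   `‖u−v‖/(‖u‖+‖v‖)` between the `GL(k)` and `GH(k)` curves swept over
   `k = 0.1 … 2.0` — a bounded [0, 1] index of contamination severity.

An EMG burst detector (detrend → EMD → soft-threshold → moving-RMS
envelope → threshold at noise mean + 3 SD → morphological cleanup)
produces the mask automatically when none is recorded.

Because no public recording of the underlying acquisition protocol exists,
the package ships a protocol-faithful generator: per participant, 5
muscles × 15 contractions per eye condition (5 each of 3 s / 1 s / 0.5 s,
seeded random order, 2 s neutral gaps; open- and closed-eyes halves with
elevated alpha when closed), band-limited EEG and 20–450 Hz EMG bursts
mixed at an exact in-burst SNR. Every downstream stage is validated
against it.

## Worked example

```r
library(emgclean)

p   <- synth_params(fs = 1000, seed = 42, snr_db = -10)
rec <- synthesize_recording(1, p, duration_s = 120)
mx  <- mix(rec$eeg, rec$emg, rec$mask, snr_db = -10)
mx
#> <ts_uv> 120000 samples @ 1000 Hz (120.000 s)
#>   range [-133.8, 151.1] uV, RMS 21.43 uV
rec$mask
#> <emg_mask> 120000 samples @ 1000 Hz: 33 high runs, 49.000 s high time

emg_ref <- make_emg_reference(mx, "SSA", rec$mask, k = 1.5)
eeg_ref <- make_eeg_reference(mx, emg_ref)
cleaned <- clean_eeg(mx, eeg_ref,
                     filter_config("RLS", reference_kind = "EEG_ref"))
time_features(mx, cleaned, rec$mask)
#> <time_features> GL 1.58 dB, GH -2.75 dB, GXin 10.84 dB, GXout 6.51 dB
```

Reading the numbers: the 120 s record contains 33 contractions (49 s of
contamination) mixed at −10 dB in-burst SNR, i.e. ten times more EMG than
EEG power inside bursts. After SSA-based referencing and RLS cancellation,
contaminated regions are attenuated by 2.75 dB (`GH < 0`) while noise-only
EEG is altered by only 1.58 dB (`GL` near 0) — the artifact shrinks, the
brain signal survives. The in/out contrast drops from 10.84 dB (`GXin`) to
6.51 dB (`GXout`). Sweeping the threshold multiplier quantifies the
contamination itself:

```r
fc <- feature_curve(mx, "SSA", rec$mask)
normalized_distance(fc)
#> [1] 0.8587035
```

0.86 on the [0, 1] scale marks this channel as heavily contaminated (an
EMG-free copy of the same EEG scores below 0.12).

A thin command-line front end with verbs `synth`, `detect-bursts`, `run`,
`sweep-k` and `evaluate` lives at `inst/cli/emgclean.R`; signals travel as
2-column delimited text, masks as interval files, run reports as JSON.

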