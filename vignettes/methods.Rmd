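---
title: "Methods: visual complexity of interictal iEEG time-frequency images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual complexity of interictal iEEG time-frequency images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Epilepsy surgery removes the epileptogenic zone (EZ), the brain region
indispensable for seizure generation. Clinically the EZ is estimated from the
seizure onset zone (SOZ) — the intracranial electrode contacts showing the
earliest ictal change — which requires capturing seizures during days of
monitoring. This package implements an interictal alternative: it scores each
contact's *resting* activity by the visual complexity of its time-frequency
(TF) image, on the premise that epileptiform interictal discharges produce TF
images whose complexity statistics differ systematically from the chaotic
1/f background of healthy tissue.

The pipeline is:

1. **Preprocessing** — Kaiser-window FIR bandpass 1–70 Hz (60 dB stopband,
   zero-phase application), then segmentation into non-overlapping 3 s epochs.
2. **TF imaging** — a Morlet wavelet amplitude spectrogram
   $S_w(f,t) = |s(t) * w_f(t)|$ with $w_f$ a complex sinusoid under a Gaussian
   envelope of width $\sigma = n_c / (2\pi f)$, $n_c = 7$ cycles, sampled on a
   fixed 224 × 224 grid: frequencies $1.0, 1.3, \dots, 67.9$ Hz (0.30 Hz
   steps) by times in 8.9 ms steps centered in the epoch. The grid is
   min–max normalized to $[0,1]$ and rendered with a piecewise-linear jet
   colormap into a 224 × 224 × 3 RGB image.
3. **Complexity features** — the image is passed through the 13 convolutional
   layers of a VGG16-topology network; for each layer the *unsupervised
   activation energy* (UAE) is the mean of the post-ReLU activation tensor
   over height × width × depth. Per contact, UAE vectors are averaged over
   epochs, giving 13 numbers per contact.
4. **Point-of-interest (POI) detection** — two routes: (a) per patient and
   per layer, a minimum-type Gumbel (extreme-value) distribution
   $p(x) = \sigma^{-1} e^{z} e^{-e^{z}}$, $z = (x-\mu)/\sigma$, is fitted by
   maximum likelihood to the contact UAE values, and contacts with UAE
   strictly below the location parameter $\mu$ (cumulative probability
   $1 - e^{-1} \approx 0.632$) are flagged; (b) a linear SVM (cost 1) on all
   13 layers with patient-distinct three-fold cross-validation, so every
   contact is predicted by a model that never saw its patient.
5. **Geometry and statistics** — each contact's Euclidean distance to the
   margin of the resection mask (the EZ ground truth in seizure-free
   patients) is computed in patient-MRI millimeter space; contacts closer
   than 5 mm count as inside the EZ. Per layer, inside-SOZ versus outside-SOZ
   mean UAE is compared across patients with the paired Wilcoxon signed-rank
   test, paired Cohen's *d* (noncentral-*t* 95% interval) and Bonferroni
   correction over the 13 layers.

## The synthetic cohort generator

No public accession exists for a clinical cohort of this design, so the
package ships a generator that emulates its *structure*:

- **Background**: pink (1/f) noise by spectral synthesis — a white complex
  Gaussian spectrum scaled by $f^{-\beta/2}$ and inverse-transformed — the
  stand-in for chaotic interictal background.
- **Discharges**: biphasic sharp transients (Gaussian-windowed 20 Hz sine,
  envelope SD 15 ms, followed by a 25%-amplitude opposite-polarity slow wave
  150 ms later) at Poisson event times with a 300 ms refractory rule, peak
  scaled to a multiple (default 5×) of the channel RMS. Their energy is
  concentrated above 10 Hz, the broadband signature of epileptiform spikes.
- **Geometry**: per patient, a random centroid in a 100 mm box; the
  epileptogenic contacts are placed uniformly inside a sphere (default
  radius 15 mm) around it, the background contacts at least 5 mm outside,
  so ground-truth discharge flags and the distance-based EZ labels coincide.
  The resection mask is the sphere voxelized at 1 mm.

What it does **not** emulate: spatial correlation between channels, realistic
electrode trajectories, non-stationary background, artifacts, propagation of
discharges across contacts, or partial overlap between SOZ and resection.
Conclusions from synthetic runs are software-validation claims, not clinical
ones.

## Numerical choices

- **Zero-phase filtering** is performed in the frequency domain by
  multiplying the signal spectrum with the squared magnitude response
  $|H(\omega)|^2$ of the designed FIR filter — the exact frequency-domain
  equivalent of forward–backward filtering, with no group delay.
- **Morlet kernels** are L1-normalized and truncated at ±4σ; the transform is
  computed by FFT convolution and agrees with a direct convolution oracle to
  1e−6 (see the test suite). Grid times falling between samples are linearly
  interpolated.
- **Network weights**: no pretrained-weight file can be downloaded in an
  offline environment, so the default backbone uses He-initialized random
  weights under a fixed seed (`weightsSource` records this). Random-weight
  VGG features are a recognized baseline for texture statistics; the
  discharge-versus-background UAE separation direction is reproduced under
  random weights. A weights file trained elsewhere can be supplied via
  `vggBackbone("file", path = ...)`.
- **Forward pass** is a single-precision im2col + GEMM implementation in
  RcppArmadillo (~1–2 s per image on one CPU core).
- **EVD fitting** optimizes $(\mu, \log\sigma)$ by BFGS from
  method-of-moments starts; recovery was verified on simulated Gumbel-min
  samples (±0.1 on $\mu$, ±3% on $\sigma$ at n = 10,000).

## Problem sizes

The analysis this package targets — tens of patients with ~96 contacts and
2 min recordings — needs roughly 10⁵ network forward passes, hours of CPU
time. The bundled tests and the `scripts/acceptance.R` runner therefore use a
deliberately scaled-down cohort (12 patients × 12 contacts, 6 s at 256 Hz,
two epochs per contact) chosen so that the full pipeline runs in minutes on
one core while keeping every qualitative property intact: each patient
retains both contact classes, the paired tests across 12 patients can reach
Bonferroni-corrected significance, and each patient has enough contacts for
the extreme-value fits. The discharge rate is raised to 40/min so that the
two available epochs express the discharge phenotype that 40 epochs would
average over at the default rate. These are runtime choices of this package,
configurable through `syntheticConfig()`.

## Limitations

- Random-weight features are a proxy; absolute UAE values differ from a
  pretrained network even though the separation direction is preserved here.
- The extreme-value threshold flags ~63% of each patient's contacts per
  layer by construction; it is a screening rule, not a specificity-oriented
  detector.
- The 5 mm EZ rule and the resection sphere are idealizations; clinical
  masks are irregular and registration error is not modeled.
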