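---
title: "Quantifying macrovascular contributions to resting-state functional connectivity"
author: "vasconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macrovascular contributions to resting-state functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasconn)
```

## The problem

Resting-state functional connectivity (rs-fcMRI) is usually read as a map of
neuronal co-activation. Large cerebral arteries and veins, however, carry a
*systemic low-frequency oscillation* (sLFO): a non-neuronal, vasculature-borne
BOLD fluctuation in the same 0.01–0.1 Hz band that connectivity analyses
retain. Because the oscillation travels with the blood, voxels containing (or
adjacent to) major vessels correlate with each other and with gray matter for
reasons that have nothing to do with neural activity — and arterial and venous
signals tend to be anti-correlated, since the oscillation arrives in arteries
and veins in different phases of the vascular transit.

`vasconn` provides the machinery to measure that contribution:

1. **Vessel-mask engineering** — fuse binary vessel segmentations from
   multi-orientation angiographic acquisitions, resample them to the fMRI
   grid, split artery from vein with a label map, restrict to gray matter,
   and build perivascular shells by dilation and subtraction.
2. **Minimal preprocessing** — regression of mean WM/CSF signals, 0.01–0.1 Hz
   bandpass, 6 mm FWHM spatial smoothing, in that order (motion correction,
   slice timing and coregistration are assumed done upstream).
3. **Connectivity metrics** — for each seed voxel and a target set, the
   degree of connectivity $D$ (number of suprathreshold correlations, default
   $|r| > 0.15$), the signed strength $S^{+}, S^{-}$ (mean of positive-only /
   negative-only correlations) and the signed spatial variance
   $\sigma^{2+}, \sigma^{2-}$, for the seed–target categories
   venous–venous, arterial–arterial, arterial–venous, venous–arterial,
   vessel-to-GM and whole-GM.
4. **Ratio maps** — macrovascular-to-GM ratios such as
   $D_{V,V} : D_{V,GM}$, quantifying what fraction of a vessel voxel's
   whole-GM connectivity is attributable to the vascular network itself.
5. **Perivascular profiles** — the same ratios with shell seeds at 1–3 voxels
   from the vasculature, resolving how far the vascular signal reaches.
6. **RSN occupancy** — the percentage of a resting-state network (thresholded
   at $z > 3$) occupied by high-probability macrovasculature (frequency map
   thresholded at its 90th percentile).
7. **A ground-truthed phantom** — a seeded synthetic 4D dataset carrying the
   statistical structure the analysis assumes, so the entire pipeline is
   testable end to end without any imaging data.

## The phantom signal model

Every voxel time series in the phantom is

$$ y(v, t) \;=\; g_{\mathrm{type}(v)} \; c\!\left(d(v)\right) \,
   s\!\left(t - \tau_{\mathrm{type}(v)}\right) \;+\; b(v, t) \;+\;
   \varepsilon(v, t), $$

where

* $s(t)$ is the sLFO: white Gaussian noise hard band-limited to
  0.01–0.1 Hz in the frequency domain and standardized to zero mean and unit
  variance. Hard bin selection makes the spectral confinement exact, and the
  generator is fully seeded.
* $g_{\mathrm{vein}} = +1$ and $g_{\mathrm{artery}} = -0.5$ are the
  intravascular gains. The opposite signs build in the arterial–venous
  anti-correlation; the smaller arterial magnitude reflects the generally
  weaker arterial BOLD contrast. Both remain configurable because the true
  arterial-to-venous amplitude ratio is not well established.
* $d(v)$ is the Chebyshev distance to the nearest vessel voxel, and
  $c(0) = 1$ inside vessels while
  $c(d) = c_0 \, e^{-d/\lambda}$ for perivascular voxels, truncated to zero
  beyond $4\lambda$. Chebyshev distance matches the 26-connected dilation
  used to build shells, so shell $k$ is exactly the set of voxels at
  $d = k$.
* $b(v, t)$ is the compartment background: GM voxels carry
  $g_{GM}\, s(t)$ plus spatially smooth noise; WM and CSF carry half the
  global gain (so nuisance regression has a real but partial effect) plus
  the same smooth noise. Vessel voxels carry *no* background, which makes
  noise-free intravascular correlations exactly $\pm 1$ and gives
  parameter-recovery tests sharp expectations.
* $\varepsilon$ is white measurement noise.

Geometry: a straight arterial tube and an L-shaped venous tube, both
1 voxel thick, embedded in a brain box with a 1-voxel CSF rim and a central
WM core. The desk-scale default is a $24 \times 24 \times 16$ grid at 4 mm
isotropic resolution, TR 2.2 s, 200 volumes; an `"msc-like"` preset provides
the 36-slice, 818-volume profile of a 30-minute run. Ties between arterial
and venous distance resolve to the vein, reflecting the venous dominance of
BOLD.

### Default parameter choices

The spec-level acquisition parameters (TR, band, voxel size, gains, lags)
are fixed by the emulated acquisition. The free parameters of the signal
model were chosen once, by forward simulation of the model itself, so that
the phantom actually exhibits the qualitative structure the analysis is
designed to detect:

* `coupling_c0 = 0.6`, `coupling_lambda_vox = 1.0` — perivascular coupling
  truncates at 4 voxels, leaving a genuinely uncoupled GM far field on the
  desk grid. With a longer coupling length nearly every GM voxel on a small
  grid is vessel-coupled and the whole-GM reference loses its meaning.
* `gm_global_gain = 0.1` — a modest global sLFO share in GM. A large value
  is unrealistic and, combined with 6 mm smoothing (which dilutes a
  1-voxel tube roughly 5:1 with surrounding tissue), would drown the
  arterial anti-correlation entirely.
* `bg_noise_sd = 0.3`, `noise_sd = 0.5` — background spatially-smooth
  physiological noise and white measurement noise at amplitudes that leave
  vascular correlations strong but not degenerate.

## Analysis conventions

* **Degree counting** uses $|r| > 0.15$ by default (`mode = "absolute"`).
  The headline phenomenon includes arterial–venous *anti*-correlations,
  which a signed count would discard; `mode = "positive"` is available for
  the strict reading of "correlation greater than threshold".
* **Variance** is the population (divide-by-$N$) spatial variance of the
  enumerated correlation set, not a sample estimate, and is computed within
  each sign class.
* **Self-pairs are excluded everywhere**: a voxel's $r = 1$ with itself is
  uninformative and would bias $D$ and $S^{+}$.
* **Zero-variance voxels** are removed from target sets before
  `n_targets_valid` is fixed (so degree upper bounds are honest) and yield
  undefined seed rows rather than zeros.
* **No Fisher transform** before averaging: raw correlations are averaged,
  matching common practice for these metrics; undefined cells are excluded
  from means with counts reported.
* **No lag search**: plain Pearson correlation at lag zero.
* **Blocked streaming**: correlations are computed in seed blocks of
  `block_size`, so the working set is bounded by
  `block_size × n_targets` and never by the full seed–target matrix. The
  central oracle test verifies the blocked result equals a dense
  recomputation to $10^{-10}$.

### Preprocessing choices

The bandpass is implemented as an orthogonal projection onto the in-band
Fourier basis (DFT bins with $f_{lo} \le f \le f_{hi}$, DC excluded),
orthogonalized against a linear trend. Compared with cascaded
detrend-then-ideal-filter steps, the projection has an exactly bounded
passband, no phase distortion, removes constants and drift completely, and
is idempotent — applying it twice is applying it once. Smoothing converts
FWHM to $\sigma = \mathrm{FWHM} / \sqrt{8 \ln 2}$ per axis in voxel units,
truncates the kernel at $4\sigma$, and uses zero-padded borders without mask
renormalization, mirroring plain-Gaussian tool behavior; kernels narrower
than about half a voxel reduce to the identity. Nuisance regressors are the
raw region means (regression happens before filtering, in pipeline order);
collinear regressors are dropped with a warning rather than failing.

### Shells and perivascular profiles

"Dilated by 1 voxel in 3D" is read as the 26-connected (full cube)
structuring element, which includes diagonal neighbors; 6- and 18-connected
elements are offered for sensitivity analysis. Shells are clipped to the
brain mask when one is supplied and always exclude the union of arterial and
venous voxels, so an artery's shell never contains vein voxels. The two
vessel classes are dilated independently; a voxel lying in both an arterial
and a venous shell contributes to both profiles, and the overlap fraction is
reported. Whether shells should further be restricted to GM is left as an
option (default: brain mask only), since either choice is defensible.

### Occupancy conventions

The percentile threshold of the macrovascular frequency map is computed over
its *nonzero* voxels — the natural support of a probabilistic vessel map —
and ties at the percentile value are kept ($\ge$). Both choices are recorded
in the output. Empty RSNs after thresholding raise an error naming the RSN.

## What the tests demonstrate (and what they do not)

The test suite exercises, on seeded phantoms:

* **Sign-structure recovery**: across 20 default phantoms, group-mean
  venous–venous strength is positive and group-mean arterial–venous strength
  is negative in at least 19.
* **Perivascular decay**: on the *decaying-coupling condition*
  (`noise_sd = 0`, `gm_global_gain = 0`, `bg_noise_sd = 2.4`), the mean
  degree-ratio profile is non-increasing over distances 0–3 for both vessel
  types in 10 of 10 seeded runs, and with coupling switched off
  (`coupling_c0 = 0`, 818 volumes) the shell degree ratios collapse to a
  null floor below 0.05.
* **Venous dominance**: venous shell profiles exceed arterial ones at every
  distance in at least 9 of 10 of those runs.

The decay condition uses stronger background noise than the default phantom.
That is deliberate: with a hard degree threshold, shell-to-vessel
correlations must traverse the threshold's partial-detection window across
$d = 1..3$ for a *profile* to be visible at all. If the coupling is strong
relative to noise, every shell's correlation with the vessel saturates above
threshold and the measured ratio profile flattens or even peaks at $d = 1$ —
a real property of degree thresholding worth remembering when interpreting
degree-ratio profiles on real data. At the null-floor end, the two profiles
converge, so the venous-dominance margin at $d = 3$ is the least robust of
the recovered effects.

What passing these tests does **not** show: the phantom has no hemodynamic
response, no realistic vascular tree, no cardiac/respiratory aliasing, no
motion, and no field-strength-dependent susceptibility physics; its
background is stationary Gaussian. Results on real data depend on
segmentation quality, registration accuracy and physiological confounds that
the phantom deliberately omits. The phantom establishes that the *pipeline
measures what it claims to measure*, not that real-data values will match
any particular magnitude.

## Problem sizes

The desk-scale phantom ($24 \times 24 \times 16$, 200 volumes, ~4700 GM
voxels) keeps a full pipeline run — including the whole-GM reference, which
is quadratic in GM size — in the order of seconds, and the complete
Monte-Carlo test suite in a couple of minutes. The same code paths scale to
full-resolution data by raising `block_size`-bounded streaming over larger
masks; the `"msc-like"` preset exists to exercise the 818-volume temporal
profile.

## A worked example

```{r example, eval = FALSE}
library(vasconn)

ph <- make_phantom(phantom_spec(rng_seed = 1))
art <- restrict_to_gm(label_mask(ph$labels, "artery"), ph$masks$gm)
ven <- restrict_to_gm(label_mask(ph$labels, "vein"), ph$masks$gm)

pre <- preprocess_bold(ph$bold, ph$masks$wm, ph$masks$csf,
                       f_lo = 0.01, f_hi = 0.1, fwhm_mm = 6)

cats <- category_metrics(pre, art, ven, ph$masks$gm, threshold = 0.15)
ratio_maps(cats$VV, cats$V_GM)

perivascular_profiles(pre, art, ven, ph$masks$gm, brain = ph$masks$brain)$vein
```

Or as one configured, provenance-tracked run:

```{r pipeline, eval = FALSE}
cfg <- run_config(phantom = phantom_spec(rng_seed = 1), n_sessions = 3)
man <- run_pipeline(cfg, "out/")
make_report(man, out_dir = "out/")
```

## Known limitations

* Mask resampling assumes the fine grid tiles the coarse one by integer
  factors after upstream registration; arbitrary affine resampling is out of
  scope.
* The phantom's vessels are axis-aligned tubes; curvature and caliber
  variation are not modeled.
* Degree ratios are undefined where the GM-reference degree is zero; such
  voxels are excluded from means (with counts reported), which can bias
  shell means when almost all voxels are undefined — the profile reports
  `n_defined` so this is visible.
* The paper-scale analysis (full-brain masks over 818 volumes across many
  sessions) is compute-bound in R; the blocked engine keeps memory flat but
  wall-clock time grows with `n_seeds × n_targets`.
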