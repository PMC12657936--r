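---
title: "Quantifying plasma-membrane tension gradients from Flipper-TR FLIM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasma-membrane tension gradients from Flipper-TR FLIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiongrad)
```

## The measurement problem

Flipper-TR is a mechanosensitive membrane probe whose fluorescence lifetime
increases with lipid packing, and therefore with membrane tension. Imaging
its lifetime across a cell turns a FLIM microscope into a spatial tension
probe: a lifetime difference between the front and the rear of a migrating
cell, or between positions on a spreading supported lipid bilayer (SLB), is
read as a tension gradient. The difficulty is statistical: live-cell
acquisitions are photon-starved (10–50 photons per pixel, because stronger
illumination arrests actin dynamics), so every downstream quantity —
gradients, region averages, velocity couplings — must be built from
estimators that behave well at very low counts, and every stage needs to be
verifiable against ground truth. This package implements the full analysis
chain together with a seeded synthetic-data generator so that each stage can
be tested end to end without any experimental download.

## Lifetime estimation

Flipper-TR decays bi-exponentially,
$I(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$, and the quantity of interest
is the intensity-weighted mean lifetime
$\bar\tau = \sum_i \alpha_i \tau_i$ with
$\alpha_i = A_i\tau_i / \sum_j A_j\tau_j$. Two estimators are provided:

* **Barycenter ("fast") lifetime** (`barycenter_lifetime()`): the
  count-weighted mean arrival time of the decay histogram minus the
  barycenter of the instrument response function (IRF). It is unbiased at
  arbitrarily low counts (it is a sample mean), needs no optimization, and
  equals $\bar\tau$ up to the small truncation term
  $W/(e^{W/\tau}-1)$ from the finite excitation window $W$
  (0.012 ns for $\tau = 6$ ns at $W = 50$ ns). It is the default and the
  estimator used for all per-pixel maps.
* **Bi-exponential reconvolution fit** (`fit_biexponential()`): a Poisson
  maximum-likelihood fit of the two-component decay convolved with the IRF
  and folded into the periodic window. The IRF is summarized by its first
  two moments (a Gaussian approximation), which makes the convolved model an
  exponentially modified Gaussian with analytic bin integrals — there is no
  grid-sampled convolution and hence no half-bin alignment error, a
  systematic that otherwise dominates at the coarse 0.195 ns bins of a
  256-bin, 50 ns window. Used on bright pixels and pooled ROIs (default
  threshold 100 photons).

Region averages always use the photon-count-weighted mean
$\bar\tau = \sum_i n_i\tau_i / N$ (`weighted_mean_tau()`). This is exactly
the barycenter of the pooled ROI histogram, i.e. the minimum-variance
estimator of a common ROI lifetime; for that reason region statistics are
computed on the count-masked but *unfiltered* image. The 3-pixel median
filter (`median_filter_tau()`) exists for maps and profiles, where
robustness against single-pixel outliers matters; applied before large-ROI
averaging it would only inflate the variance of the mean (by a factor
approaching $\pi/2$ for near-Gaussian pixel noise) without adding
information.

Numerical conventions, where the acquisition convention leaves freedom:

* "Under a threshold of 20 photons" is read strictly: 19 photons is masked,
  20 is kept (`mask_low_counts()`, configurable).
* The median filter ignores invalid neighbors, reflects at image borders,
  and never revalidates an invalid pixel.
* Negative barycenter lifetimes (decay apparently preceding the IRF) are
  marked invalid rather than clipped to zero.
* The barycenter uses all bins with no background subtraction by default;
  a constant-background subtraction from the pre-rise bins is available as
  a flag.
* The bi-exponential fit is initialized at $\tau_1 = \bar\tau/2$,
  $\tau_2 = 1.5\,\bar\tau$, equal photon fractions, with
  $\tau \in [0.1, 20]$ ns bounds — a scale-aware start that converges for
  every decay the generator produces.

The conversion to tension is deliberately minimal: a user-supplied linear
map (`tension_calibration()`, `tension_from_lifetime()`). The calibration
coefficients come from independent experiments and are not shipped as
truth; the example configuration (1.25 mN/m per ns) simply pairs a 0.20 ns
gradient with a 0.25 mN/m tension drop.

## Spatial statistics

All spatial quantities are built on exact Euclidean distance transforms of
binary masks (`signed_distance()`, negative inside the mask, zero exactly on
boundary pixels; verified against a brute-force nearest-boundary search).
Two sign conventions coexist on purpose: pattern-boundary analyses use the
signed field (negative inside the micropattern), while cell-edge decay
profiles use the unsigned inward distance (`edge_distance()`), matching how
such profiles are plotted.

`decay_profile()` averages lifetimes per 1 µm distance bin
(photon-weighted, consistent with `weighted_mean_tau()`; the unweighted mode
is available since the choice is a convention, not physics) and
`fit_slope()` fits a pixel-count-weighted line, reporting slope, standard
error and $R^2$. `hist2d_mean()` generalizes this to joint binning over two
distance fields; marginalizing it over one axis reproduces the 1D profile
exactly, which is enforced by a test.

Region systems:

* `front_rear_angular()`: 60° sectors (±30° about a supplied polarity axis)
  within 10 µm of the cell edge — the migrating-cell convention. The
  polarity angle is an *input*, determined from morphology, never from
  lifetimes.
* `front_rear_by_fraction()`: closest/most-distant 20% of the area by
  distance rank — the SLB convention.
* `decile_regions()`: top and bottom two lifetime deciles of a control
  average map, applied unchanged to other conditions. Ties are broken by
  stable pixel order, so region sizes are exact to rounding; a constant map
  has no deciles and errors.

`align_and_average()` registers cells by their micropattern: translation to
the template centroid plus the discrete symmetry rotation (multiples of
90°; fold 1, 2 or 4) maximizing mask overlap. Free rotation/scaling is
deliberately excluded — patterns are manufactured at fixed size and
orientation, and free registration could smear genuine gradients. Cells
below a 50% Jaccard overlap (configurable) are dropped with a message.
`difference_map()` subtracts a reference average per cell on the common
support, the convention used for drug-treatment comparisons against an
actin-frozen baseline.

## Edge kinematics and SLB spreading

`edge_velocity()` implements the distance-map difference: the signed
distance-to-exterior of frame $i{+}1$ minus that of frame $i$, evaluated at
the contour pixels of frame $i$ and divided by the frame interval, so
outward motion is positive. Contour integration (`edge_flux()`) uses the
Vossepoel–Smeulders chain-length estimate (0.980 per axial, 1.406 per
diagonal step) and the mean of the two frames' contour lengths — the
trapezoidal length of the moving interface — which balances the area change
within 5% on smooth synthetic movies.

Edges are classified protruding/retracting by a symmetric ±0.2 µm/min
threshold; the band in between stays unclassified rather than being merged
into either class, keeping the two populations distinct. Classified contour
seeds are extended 0–10 µm inward by nearest-seed assignment.

SLB spreading speed is the area increase per time per crop width
(`slb_speed()`), and `speed_slope_curve()` pairs each frame's speed with a
linear gradient fit over the 100 µm closest to the advancing front (taken
as the rightmost occupied column; direction configurable). Note that the
measured speed is an interval average while the generator couples the
gradient to the instantaneous front speed; recovery tests therefore compare
fitted slopes against the instantaneous truth and use the measured pairs
only for the monotone (Spearman) association.

## Fluctuation spectroscopy and FRAP

Line-scan kymographs (64 pixels × 0.16 µm at 960 µs per line) are detrended
column-wise by moving-average division (`detrend()`), preserving column
means. The window default is 10000 lines (~10 s): the 2D-diffusion ACF has
a heavy $1/\tau$ tail, and a ~1 s window measurably high-passes it (a +45%
bias on $D$ at 2 µm²/s in our recovery tests), while ~10 s leaves the
millisecond-to-100 ms correlations intact and still removes
bleaching-scale drifts.

`kymo_acf()` computes per-column autocorrelations (FFT-based, unbiased
normalization) averaged over a pixel section — the acquisition convention
splits the line into pixels 1–21, 22–42 and 43–63 (1-based inclusive,
converted internally to 0-based half-open ranges) — on a quasi-logarithmic
lag grid starting at one line time. `fit_acf()` fits the two-component 2D
diffusion model
$G(\tau) = G_0\left[\frac{f}{1+\tau/\tau_{D,1}} +
\frac{1-f}{1+\tau/\tau_{D,2}}\right] + G_\infty$, with
$\tau_{D,i} = w^2/4D_i$ for a Gaussian waist $w$ (default 0.25 µm). The 2D
form is the natural choice for a dye confined to the membrane plane; the
functional form is recorded in the fit object. $D_0$ is reported as the
amplitude-weighted mean of the two components (both are also returned,
since the definition is a convention). The fit uses raw Levenberg–Marquardt
over a small ladder of starting points, keeping the best by deviance — a
single-component dataset legitimately collapses one fraction to 0 or 1, and
the raw interface tolerates that degeneracy.

`kymo_pcf()` cross-correlates columns δr = 5 pixels apart, forward
(pixels 1–59) and reverse (5–64). `fit_pcf()` fits a Gaussian in
$\log_{10}$ lag around the positive peak — transport peaks span decades, so
the log axis is the right support — giving the arrival time and, against
the paired ACF amplitude, the transport efficiency $G_\tau/G_0$; a curve
with no positive peak is a no-transport result, not an error. Directed flow
is *called* from the forward/reverse peak asymmetry
$(G_f - G_r)/(G_f + G_r) > 0.35$: pure diffusion is symmetric
(asymmetry ≈ 0.1 at our noise levels) while modest flows reach 0.7+, so the
threshold sits well between the two populations.

FRAP traces are normalized to 0 at the first post-bleach sample and 1 at
the 5 s pre-bleach mean, with optional background subtraction and
reference-trace bleaching correction (`frap_normalize()`), then fitted to
$M(1-e^{-kt})$ (`frap_fit()`; $t_{1/2} = \ln 2/k$). Because the zero anchor
is a single sample, its noise propagates into the parameters; the
experimental convention — normalize each recovery, average aligned curves,
fit the average — is what the recovery tests reproduce. A fully immobile
trace is flagged rather than fitted ($k$ is unidentifiable at $M = 0$).
`line_frap_flow()` integrates a bleached-line movie parallel to the line,
tracks the profile minimum with a three-point parabola vertex, and reports
the drift of the minimum as the flow velocity, truncating with a warning
once the dip contrast falls below detection.

## MALDI-MSI lipid fractions

`lipid_fractions()` converts a channel stack plus a peak-assignment table
into per-species fraction maps: species intensity over the summed intensity
of *known* peaks only, with multi-peak species summed. Pixels with zero
known intensity are invalid, not zero — off-cell background must not dilute
statistics. `zscore_fractions()` pools all valid pixels of all cells per
species ("all cells, all pixels" is read as all in-cell pixels) and
standardizes to pooled mean 0, SD 1. `msi_average_map()` reuses the
micropattern alignment, computing one transform per cell from the pattern
and applying it to every species, averaging unweighted (z-scores carry no
photon weights). The 0.5 µm MSI pixel size is carried in the container so
the distance-based tools apply unchanged.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions:

* **TCSPC** (`simulate_tcspc_image()`): 20 MHz repetition (50 ns window),
  256 bins, Gaussian IRF with σ = 0.2 ns centered at 2 ns (the acquisition
  system specifies neither, so plausible values are fixed and configurable).
  A target mean lifetime is realized by fixing the component pair
  (τ₁, τ₂) = (1.5, 6.0) ns — matching the probe's two-state photochemistry —
  and varying the photon fraction per pixel; photon counts are
  Poisson(30)/pixel by default, the middle of the 10–50 photon acquisition
  range. Photons are drawn individually, jittered, folded into the window
  and binned, so histogram sums equal drawn counts by construction.
* **Geometry** (`make_scene()`): keratocyte = half-annulus crescent;
  polarized cell = 76 × 52 µm ellipse plus a protruding lobe (a large,
  well-spread fibroblast, chosen so 60°/10 µm edge sectors contain enough
  pixels for meaningful region statistics); cross/crossbow/ring/disc
  micropatterns from simple geometry at the published pattern scale. The
  default pixel size is 0.25 µm (a 3-pixel median kernel then spans
  0.75 µm, matching the acquisition note). Lifetime fields combine a
  baseline, a linear gradient along the polarity axis, an
  exponential-or-linear edge term in the inward edge distance, and a plane
  offset.
* **SLB movies** (`simulate_slb_movie()`): front advancing with
  $v(t) = v_0((t+t_1)/t_1)^{-\beta}$ (power-law slowdown) and per-frame
  gradient slope equal to a coupling constant times the instantaneous
  speed, so speed → 0 forces slope → 0.
* **Line scans** (`simulate_linescan()`): emitters diffuse in 2D (per-axis
  step variance $2D\,\Delta t$) on a periodic domain 3× the scan length
  (and 8 waists tall), with optional drift; intensities are Poisson counts
  of Gaussian-PSF sums plus background. MSD slope and FCS amplitude laws
  are verified against their closed forms.
* **FRAP** (`simulate_frap()`): plateau, step bleach, single-exponential
  recovery with configurable mobile fraction, rate and noise.

All randomness flows through one seeded generator per call, and identical
spec + seed reproduce outputs bit for bit; the caller's RNG state is left
untouched.

What the generator does **not** emulate: detector afterpulsing and
dead-time, non-Gaussian IRFs, autofluorescent background with its own decay,
segmentation errors (masks are exact), out-of-focus light, probe
internalization, and anomalous (non-Brownian) lipid diffusion. Passing the
recovery tests therefore demonstrates that the *estimators* are correct and
unbiased under ideal photophysics, not that real images are free of these
systematics.

## Problem sizes and a known statistical limitation

The test-suite simulations use 384² px scenes at 30 photons/pixel (50
seeds for the gradient-recovery study), 50 000-line kymographs (10 seeds
per diffusion coefficient, 20 for the flow false-positive rate), and
10-trace FRAP averages — sizes chosen so the whole suite runs on a single
CPU in well under half an hour while keeping Monte-Carlo error far below
every tolerance being tested.

One recovery target is genuinely photon-limited: a front-minus-rear
difference of sector means at 30 photons/pixel. The per-photon arrival-time
SD of the (1.5, 6.0) ns mixture at $\bar\tau \approx 4.6$ ns is ≈5.5 ns, so
a sector holding $N_{px}$ pixels has
$\mathrm{SE}(\Delta) = \sqrt{2}\,\sigma_T/\sqrt{30\,N_{px}}$ ≈ 0.019 ns for
the ~6×10³-pixel sectors of even a large cell. An absolute 0.03 ns
tolerance is then a ~1.6 σ band, met by roughly 85–90% of seeds rather than
95%+; reaching 95% requires ~1.6× more photons per sector. The estimator is
unbiased (mean error ≈ 0.002 ns across seeds) — the limit is information,
not implementation, and the corresponding recovery test reports it
honestly.

## Limitations

Segmentation, polarity angles, and peak assignments are inputs, as in the
experimental workflow (pixel classification and manual annotation live
outside this package). Phasor-plot lifetime analysis, >2-component decay
models, per-photon time-tag formats, PIV of actin flows, and MSI peak
picking upstream of the channel stack are out of scope.
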