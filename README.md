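# tensiongrad

Quantification of plasma-membrane tension gradients from fluorescence
lifetime images of the mechanosensitive probe Flipper-TR.

Flipper-TR's fluorescence lifetime rises with lipid packing and hence with
membrane tension, so a FLIM image of a labeled cell is a spatial tension
map. This package implements the complete quantitative chain from photon
arrival statistics to biology-facing numbers, for researchers analyzing
TCSPC FLIM of membrane probes, spreading supported lipid bilayers (SLBs),
line-scan fluctuation spectroscopy, FRAP, or MALDI mass-spectrometry-imaging
lipid maps:

* **Lifetime estimation** — the barycenter "fast lifetime"
  (count-weighted mean arrival time minus the IRF barycenter), reliable at
  the 10–50 photons/pixel of live-cell imaging, and a Poisson
  maximum-likelihood bi-exponential reconvolution fit
  (`I(t) = A1 e^(-t/τ1) + A2 e^(-t/τ2)`, reported as the intensity-weighted
  mean `τ̄ = Σ αᵢτᵢ`). Masking (photons < 20 → invalid), NA-aware 3-pixel
  median filtering, photon-weighted ROI means `τ̄ = Σ nᵢτᵢ / N`, and a
  user-supplied linear lifetime→tension map.
* **Spatial gradients** — exact signed Euclidean distance fields from
  masks, per-micron lifetime decay profiles and weighted slope fits
  (ns/µm), front/rear regions (60°/0–10 µm sectors or 20% area fractions),
  2D distance histograms, micropattern alignment and pixel-wise average
  maps, extreme-decile high/low regions, and condition-difference maps.
* **Dynamics** — edge velocities from distance-map differences of mask
  movies, protruding/retracting classification (±0.2 µm/min), SLB spreading
  speed (ΔA per time per crop width) and its coupling to gradient slopes,
  directionality ratios and ellipse aspect ratios.
* **Fluctuation spectroscopy & FRAP** — kymograph detrending, section ACFs
  with two-component 2D diffusion fits (`G(τ) = G0 Σ fᵢ/(1+τ/τ_{D,i})`,
  `τ_D = w²/4D`), forward/reverse pair-correlation (δr = 5 px) with
  Gaussian peak fits for arrival times and transport efficiency `G_τ/G0`,
  FRAP normalization and single-exponential recovery
  (`M(1-e^{-kt})`, `t½ = ln2/k`), and line-FRAP minima tracking for flow
  velocities.
* **MSI** — per-species lipid fractions over known peaks, pooled z-score
  normalization, and aligned cross-cell average maps.
* **Synthetic data** — a seeded generator for every input modality
  (TCSPC photon stacks over realistic cell/pattern geometries, SLB
  spreading movies with power-law slowdown, diffusing/flowing line-scan
  kymographs, FRAP traces) with exact ground truth, so the whole pipeline
  is testable end to end.

## Worked example

Simulate a polarized migrating cell carrying a 0.02 ns/µm lifetime gradient
plus a 0.3 ns edge elevation (2 µm decay length) at 30 photons/pixel, then
run the standard pipeline: count masking, median filtering, an edge-distance
decay profile with slope fit, and 60° front/rear sector averages.

```r
library(tensiongrad)

cfg <- tcspc_config()                     # 20 MHz, 256 bins, (1.5, 6.0) ns pair
irf <- make_irf(cfg)

spec <- scene_spec("polarized", linear_slope = 0.02, edge_amplitude = 0.3,
                   edge_decay_length = 2, mean_photons = 30, seed = 7)
truth <- make_scene(spec)
#> <scene_truth> polarized 384x384 px, 51210 cell px, tau range 3.839-5.654 ns

stack <- simulate_tcspc_image(truth, cfg)
img <- mask_low_counts(lifetime_image(stack, irf), threshold = 20)
#> <lifetime_image> 384x384 px (0.25 um/px), 50047 valid, tau 1.299-10.65 ns [barycenter]

d <- edge_distance(truth$cell_mask, spec$pixel_size)
fit_slope(decay_profile(median_filter_tau(img, 3), d, bin = 1, range = c(0, 10)))
#> <slope_fit> -0.0260 ns/um (se 0.0046), r2 0.801 over 0.5-9.5 um

sectors <- front_rear_angular(truth$cell_mask, polarity_angle = 0,
                              half_angle = 30, dmax = 10,
                              pixel_size = spec$pixel_size)
front <- weighted_mean_tau(img, sectors$front)
rear  <- weighted_mean_tau(img, sectors$rear)
sprintf("front %.3f ns, rear %.3f ns, delta %.3f ns", front, rear, front - rear)
#> "front 5.167 ns, rear 3.944 ns, delta 1.223 ns"

cal <- tension_calibration(slope = 1.25, source = "example linear map")
tension_from_lifetime(front - rear, cal)
#> 1.529  # mN/m
```

The fitted profile slope is negative because lifetime *decays* with distance
from the edge (the edge term dominates the 0–10 µm window), and the
front–rear difference is positive because the constructed gradient runs
toward the front. The lifetime-to-tension conversion is a user-supplied
linear calibration; the example slope pairs a 0.20 ns difference with
0.25 mN/m.

The methods vignette (`vignettes/tension-gradients.Rmd`) documents the
models, estimator choices, conventions and known statistical limits.

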