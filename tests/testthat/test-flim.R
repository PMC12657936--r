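test_that("barycenter lifetime handles point decays, empty pixels and closed forms", {
  cfg <- tcspc_config(irf_sigma = 0, irf_center = 10.5 * 50 / 256)
  irf <- make_irf(cfg)
  # all photons in the bin holding the IRF barycenter -> 0 ns
  h0 <- decay_histogram(irf$counts, cfg$bin_width)
  expect_equal(barycenter_lifetime(h0, irf), 0)
  # empty histogram -> invalid, not an error
  expect_true(is.na(barycenter_lifetime(
    decay_histogram(rep(0, 256), cfg$bin_width), irf)))
  # negative lifetimes are invalid unless explicitly allowed
  hneg <- decay_histogram(replace(rep(0, 256), 1, 100), cfg$bin_width)
  expect_true(is.na(barycenter_lifetime(hneg, irf)))
  expect_lt(barycenter_lifetime(hneg, irf, allow_negative = TRUE), 0)

  # noiseless mono-exponential tau = 4 over a 50 ns window (fine bins)
  cfgf <- tcspc_config(n_bins = 4096, irf_sigma = 0,
                       irf_center = 168.5 * 50 / 4096)
  irff <- make_irf(cfgf)
  edges <- (0:4096) * cfgf$bin_width
  shift <- cfgf$irf_center  # delta IRF sits on a bin center
  p4 <- diff(-exp(-pmax(0, edges - shift) / 4))
  hf <- decay_histogram(1e6 * p4 / sum(p4), cfgf$bin_width)
  expect_equal(barycenter_lifetime(hf, irff), 4 - 50 / (exp(50 / 4) - 1),
               tolerance = 5e-4)
  # equal-amplitude (1, 5) ns mixture: infinite-window barycenter 26/6
  # equal amplitudes A1 = A2 give photon fractions (1/6, 5/6)
  pm <- diff(-(1 / 6) * exp(-pmax(0, edges - shift))) +
    diff(-(5 / 6) * exp(-pmax(0, edges - shift) / 5))
  hm <- decay_histogram(1e6 * pm / sum(pm), cfgf$bin_width)
  expect_equal(barycenter_lifetime(hm, irff), 26 / 6, tolerance = 2e-3)
})

test_that("bi-exponential reconvolution fit recovers known decays", {
  cfg <- tcspc_config()
  irf <- make_irf(cfg)
  # noiseless synthetic decay with known parameters
  p <- tensiongrad:::.biexp_bin_probs(c(1.5, 6), c(0.3, 0.7), cfg$irf_center,
                                      cfg$irf_sigma, cfg$bin_width, cfg$n_bins)
  h <- decay_histogram(1e6 * p, cfg$bin_width)
  f <- fit_biexponential(h, irf)
  expect_true(f$converged)
  expect_equal(f$tau1, 1.5, tolerance = 0.01)
  expect_equal(f$tau2, 6, tolerance = 0.01)
  expect_equal(f$alpha1, 0.3, tolerance = 0.01)
  expect_equal(f$tau_bar, 0.3 * 1.5 + 0.7 * 6, tolerance = 0.01)

  # mono-exponential input: component split arbitrary, mean lifetime not
  pmono <- tensiongrad:::.biexp_bin_probs(c(4, 4), c(0.5, 0.5), cfg$irf_center,
                                          cfg$irf_sigma, cfg$bin_width, cfg$n_bins)
  fm <- fit_biexponential(decay_histogram(1e6 * pmono, cfg$bin_width), irf)
  expect_equal(fm$tau_bar, 4, tolerance = 0.01)

  expect_error(fit_biexponential(
    decay_histogram(rep(0, 256), cfg$bin_width), irf), "photons")
})

test_that("barycenter and fitted mean lifetime agree on high-count pixels", {
  cfg <- tcspc_config()
  irf <- make_irf(cfg)
  tr <- make_scene(scene_spec("slb", image_size = c(2, 4),
                              baseline_tau = 4.7, mean_photons = 12500))
  stk <- simulate_tcspc_image(tr, cfg, seed = 21)
  h <- decay_histogram(rowSums(matrix(stk$counts, 256)), cfg$bin_width)
  f <- fit_biexponential(h, irf)
  b <- barycenter_lifetime(h, irf)
  expect_lt(abs(f$tau_bar - b) / b, 0.01)
})

test_that("estimator equivalence holds in the median even at 50 photons", {
  cfg <- tcspc_config()
  irf <- make_irf(cfg)
  tr <- ramp_scene(5, 24, 4.3, 5.0, mean_photons = 50, seed = 31)
  stk <- simulate_tcspc_image(tr, cfg, seed = 31)
  H <- matrix(stk$counts, cfg$n_bins)
  idx <- which(tr$cell_mask & matrix(colSums(H) >= 30, nrow(tr$cell_mask)))
  rel <- vapply(idx, function(i) {
    h <- decay_histogram(H[, i], cfg$bin_width)
    b <- barycenter_lifetime(h, irf)
    f <- fit_biexponential(h, irf, min_photons = 30)
    abs(f$tau_bar - b) / b
  }, numeric(1))
  expect_lt(median(rel), 0.05)
})

test_that("low-count masking is strict and photon counts stay untouched", {
  tau <- matrix(4.5, 3, 3)
  ph <- matrix(c(0, 5, 19, 20, 21, 50, 19, 20, 300), 3, 3)
  img <- new_lifetime_image(tau, ph, 0.25)
  m <- mask_low_counts(img, 20)
  expect_identical(is.na(m$tau), ph < 20)
  expect_identical(m$photons, ph)
  expect_identical(mask_low_counts(img, 0)$tau, tau)
})

test_that("NA-aware median filter matches a brute-force sliding window", {
  img <- uniform_img(matrix(5, 8, 8))
  expect_identical(median_filter_tau(img, 3)$tau, img$tau)
  # single outlier in a constant field is replaced
  out <- matrix(4, 9, 9); out[5, 5] <- 40
  expect_identical(median_filter_tau(uniform_img(out), 3)$tau, matrix(4, 9, 9))
  # brute-force oracle on a random 16x16 image with invalid pixels
  set.seed(42)
  x <- matrix(rnorm(256, 4.5), 16)
  x[sample(256, 40)] <- NA
  got <- median_filter_tau(uniform_img(x), 3)$tau
  xp <- x[c(2, 1:16, 15), c(2, 1:16, 15)]
  want <- matrix(NA_real_, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    if (is.finite(x[i, j]))
      want[i, j] <- median(xp[i:(i + 2), j:(j + 2)], na.rm = TRUE)
  }
  expect_equal(got, want)
  # idempotent on a constant-by-region image
  reg <- matrix(4, 12, 12); reg[, 7:12] <- 5
  once <- median_filter_tau(uniform_img(reg), 3)
  expect_identical(median_filter_tau(once, 3)$tau, once$tau)
})

test_that("photon-weighted ROI mean follows the count-weighting rule", {
  img <- new_lifetime_image(matrix(c(4, 5), 1, 2), matrix(c(2, 2), 1, 2), 1)
  expect_equal(weighted_mean_tau(img), 4.5)
  img2 <- new_lifetime_image(matrix(c(4.8, 4.4), 1, 2),
                             matrix(c(30, 10), 1, 2), 1)
  expect_equal(weighted_mean_tau(img2), 4.7)
  # invariance: constant lifetimes for any counts; count rescaling
  set.seed(1)
  ph <- matrix(rpois(25, 30), 5)
  imgc <- new_lifetime_image(matrix(3.3, 5, 5), ph, 1)
  expect_equal(weighted_mean_tau(imgc), 3.3)
  tau <- matrix(runif(25, 4, 5), 5)
  a <- weighted_mean_tau(new_lifetime_image(tau, ph, 1))
  b <- weighted_mean_tau(new_lifetime_image(tau, 7 * ph, 1))
  expect_equal(a, b)
  # empty ROI: NA with a warning
  imgn <- new_lifetime_image(matrix(NA_real_, 2, 2), matrix(0, 2, 2), 1)
  expect_warning(r <- weighted_mean_tau(imgn), "no valid")
  expect_true(is.na(r))
})

test_that("lifetime-to-tension conversion is linear in the lifetime difference", {
  cal <- tension_calibration(slope = 1.25, source = "example config")
  expect_equal(tension_from_lifetime(0.20, cal), 0.25)
  expect_equal(tension_from_lifetime(0, cal), 0)
  expect_equal(tension_from_lifetime(0.4, cal), 2 * tension_from_lifetime(0.2, cal))
})

test_that("barycenter and fit estimators produce matching lifetime maps at high counts", {
  cfg <- tcspc_config()
  irf <- make_irf(cfg)
  tr <- make_scene(scene_spec("slb", image_size = c(2, 6), baseline_tau = 4.5,
                              mean_photons = 5000))
  stk <- simulate_tcspc_image(tr, cfg, seed = 8)
  b <- lifetime_image(stk, irf, "barycenter")
  f <- lifetime_image(stk, irf, "biexp")
  ok <- is.finite(b$tau) & is.finite(f$tau)
  expect_true(any(ok))
  expect_lt(max(abs(b$tau[ok] - f$tau[ok]) / b$tau[ok]), 0.01)
  # empty pixels are invalid with zero photons
  expect_true(all(is.na(b$tau[!tr$cell_mask])))
  expect_true(all(b$photons[!tr$cell_mask] == 0))
})
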