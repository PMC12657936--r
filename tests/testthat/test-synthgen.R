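test_that("intensity fraction solves the mean-lifetime mixing relation", {
  cfg <- tcspc_config(tau_pair = c(1, 5))
  expect_equal(target_tau_to_amplitudes(1, cfg), 1)
  expect_equal(target_tau_to_amplitudes(3, cfg), 0.5)
  # oracle: with equal amplitudes A1 = A2 the barycenter of the mixture is
  # (A1 tau1^2 + A2 tau2^2) / (A1 tau1 + A2 tau2) = 26/6; solving the linear
  # relation for that mean must give alpha1 = tau1*A1/(sum Ai tau_i) = 1/6
  tau_bar <- (1 + 25) / (1 + 5)
  expect_equal(target_tau_to_amplitudes(tau_bar, cfg), 1 / 6)
  expect_error(target_tau_to_amplitudes(0.5, cfg), "outside")
  expect_error(target_tau_to_amplitudes(6, cfg), "outside")
})

test_that("scene fields follow baseline, linear slope and edge terms", {
  flat <- make_scene(scene_spec("disc", baseline_tau = 4.5))
  expect_true(all(flat$true_tau[flat$cell_mask] == 4.5))
  expect_true(all(is.na(flat$true_tau[!flat$cell_mask])))

  sp <- scene_spec("polarized", linear_slope = 0.02)
  tr <- make_scene(sp)
  mid <- round(nrow(tr$true_tau) / 2)
  cols <- which(is.finite(tr$true_tau[mid, ]))
  j <- cols[10]
  dpx <- round(10 / sp$pixel_size)  # 10 um along the polarity axis
  expect_equal(tr$true_tau[mid, j + dpx] - tr$true_tau[mid, j], 0.2,
               tolerance = 1e-10)

  spe <- scene_spec("disc", edge_amplitude = 0.3, edge_decay_length = 2)
  tre <- make_scene(spe)
  d <- -signed_distance(tre$cell_mask, spe$pixel_size)$d
  pick <- which(tre$cell_mask & abs(d - 2) < 1e-9)
  expect_true(length(pick) > 0)
  expect_equal(unique(round(tre$true_tau[pick] - 4.5, 10)),
               round(0.3 * exp(-1), 10))

  expect_error(scene_spec("banana"))
})

test_that("TCSPC simulation conserves photons, reproduces under a seed, and matches Poisson totals", {
  cfg <- tcspc_config()
  tr <- make_scene(scene_spec("slb", image_size = c(50, 40), mean_photons = 30))
  s1 <- simulate_tcspc_image(tr, cfg, seed = 5)
  s2 <- simulate_tcspc_image(tr, cfg, seed = 5)
  expect_identical(s1$counts, s2$counts)
  npix <- sum(tr$cell_mask)
  total <- sum(s1$counts)
  expect_lt(abs(total - 30 * npix), 4 * sqrt(30 * npix))
  # photon counts channel equals per-pixel histogram sums
  img <- lifetime_image(s1, make_irf(cfg))
  expect_equal(sum(img$photons), total)
  expect_true(all(img$photons[!tr$cell_mask] == 0))
})

test_that("empirical arrival-time mean matches the truncated-exponential barycenter", {
  # effectively mono-exponential tau = 4 ns, delta IRF, 50 ns window
  cfg <- tcspc_config(irf_sigma = 0, irf_center = 2, tau_pair = c(4, 4.1))
  tr <- make_scene(scene_spec("slb", image_size = c(4, 4),
                              baseline_tau = 4, mean_photons = 2e4))
  stk <- simulate_tcspc_image(tr, cfg, seed = 2)
  centers <- (seq_len(cfg$n_bins) - 0.5) * cfg$bin_width
  h <- rowSums(matrix(stk$counts, cfg$n_bins))
  emp <- sum(h * centers) / sum(h)
  expect_equal(emp, 2 + 4 - 50 / (exp(50 / 4) - 1), tolerance = 0.005)
})

test_that("pixel barycenters converge to the analytic mixture barycenter", {
  cfg <- tcspc_config()
  irf <- make_irf(cfg)
  tau_bar <- 4.6
  tr <- make_scene(scene_spec("slb", image_size = c(2, 4),
                              baseline_tau = tau_bar, mean_photons = 25000))
  stk <- simulate_tcspc_image(tr, cfg, seed = 11)  # 1e5 photons pooled
  h <- decay_histogram(rowSums(matrix(stk$counts, cfg$n_bins)), cfg$bin_width)
  a1 <- target_tau_to_amplitudes(tau_bar, cfg)
  wrap <- function(tau) tau - 50 / (exp(50 / tau) - 1)
  analytic <- a1 * wrap(1.5) + (1 - a1) * wrap(6)
  expect_equal(barycenter_lifetime(h, irf), analytic, tolerance = 0.005)
})

test_that("SLB movies slow down as a power law and couple slope to speed", {
  sl <- simulate_slb_movie(slope_coupling = 0, frames = 5, seed = 3)
  for (k in seq_along(sl$tau)) {
    v <- sl$tau[[k]][sl$masks[[k]]]
    expect_lt(diff(range(v)), 1e-12)
  }
  sl2 <- simulate_slb_movie(beta = 2, frames = 8, seed = 3)
  expect_lt(sl2$truth$speed[8], sl2$truth$speed[1])
  # area oracle: pixel-counted area matches crop_width * front position
  # within one pixel column of discretization
  px <- sl2$pixel_size
  for (k in c(1, 4, 8)) {
    area <- sum(sl2$masks[[k]]) * px^2
    expect_lt(abs(area - sl2$truth$front_x[k] * 40), 40 * px)
  }
})

test_that("line-scan particles are static without diffusion and drift as prescribed", {
  k0 <- simulate_linescan(n_lines = 1500, D = 0, drift_v = 0, n_particles = 10,
                          seed = 4, keep_tracks = TRUE)
  expect_true(all(apply(k0$tracks_x, 1, function(r) diff(range(r))) == 0))
  cm <- colMeans(k0$intensity)
  half1 <- colMeans(k0$intensity[1:750, ])
  half2 <- colMeans(k0$intensity[751:1500, ])
  expect_lt(max(abs(half1 - half2) / pmax(cm, 1)), 0.35)  # shot noise only

  kd <- simulate_linescan(n_lines = 2084, D = 0, drift_v = 0.8,
                          n_particles = 10, seed = 4, keep_tracks = TRUE)
  # 1042 lines = 1 s: mean advance 0.8 um (track increments, no wrap issues)
  adv <- kd$tracks_x[, 1043] - kd$tracks_x[, 1]
  adv <- ((adv + kd$truth$domain[1] / 2) %% kd$truth$domain[1]) -
    kd$truth$domain[1] / 2
  expect_equal(mean(adv), 0.8 * 1042 * 960e-6, tolerance = 1e-9)
})

test_that("line-scan Brownian steps reproduce the configured diffusion coefficient", {
  k <- simulate_linescan(n_lines = 4000, D = 2, n_particles = 30, seed = 6,
                         keep_tracks = TRUE)
  X <- k$tracks_x
  dx <- X[, -1] - X[, -ncol(X)]
  L <- k$truth$domain[1]
  dx <- ((dx + L / 2) %% L) - L / 2
  msd_slope <- var(as.numeric(dx)) / k$line_time
  expect_equal(msd_slope, 2 * 2, tolerance = 0.1)
})

test_that("FRAP traces honor the recovery model", {
  tr1 <- simulate_frap(mobile = 1, k = 0.5, bleach_depth = 0.7, n_post = 200,
                       dt = 0.5)
  expect_equal(tail(tr1$intensity, 1), 1, tolerance = 1e-3)
  tr0 <- simulate_frap(mobile = 0, k = 0.5, bleach_depth = 0.7)
  post <- tr0$intensity[tr0$time >= 0]
  expect_true(all(abs(post - 0.3) < 1e-12))
  # half-life identity: at t = ln2/k half the recoverable signal is back
  tr <- simulate_frap(mobile = 0.8, k = 0.2, bleach_depth = 0.6, dt = log(2) / 0.2)
  at_half <- tr$intensity[which(tr$time >= 0)[2]]
  expect_equal((at_half - 0.4) / (0.6 * 0.8), 0.5, tolerance = 1e-9)
})
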