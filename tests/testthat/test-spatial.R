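test_that("signed distance is zero on the boundary, signed inside, exact vs brute force", {
  m <- disc_mask(21, 7)
  f <- signed_distance(m, pixel_size = 0.5)
  b <- tensiongrad:::.mask_boundary(m)
  expect_true(all(f$d[b] == 0))
  expect_true(all(f$d[m & !b] < 0))
  out <- which(!m, arr.ind = TRUE)
  expect_true(all(f$d[!m] > 0))
  # monotone outside along a ray
  expect_true(all(diff(f$d[11, 18:21]) > 0))
  expect_error(signed_distance(matrix(FALSE, 4, 4)), "mask")
  expect_error(signed_distance(matrix(TRUE, 4, 4)), "mask")
  # brute-force oracle on random 12x12 masks
  set.seed(7)
  for (i in 1:25) {
    mm <- matrix(runif(144) > 0.6, 12, 12)
    if (!any(mm) || all(mm)) next
    expect_equal(signed_distance(mm, 1)$d, brute_signed_distance(mm, 1))
  }
})

test_that("decay profiles average per distance bin and report gaps as invalid", {
  m <- disc_mask(41, 15)
  d <- edge_distance(m, 1)
  img <- uniform_img(ifelse(m, 4.5, NA), photons = 30, pixel_size = 1)
  p <- decay_profile(img, d, bin = 1)
  valid <- is.finite(p$mean_tau)
  expect_true(all(p$mean_tau[valid] == 4.5))
  expect_true(all(p$sd_tau[p$n_pixels > 1] < 1e-12))
  # linear field tau = a + b*d reproduces the line at bin centers
  tau <- 4 + 0.05 * d$d
  tau[!m] <- NA
  pl <- decay_profile(uniform_img(tau, 30, 1), d, bin = 1)
  ok <- is.finite(pl$mean_tau) & pl$n_pixels > 30
  # annulus geometry skews the within-bin mean distance by up to ~half a bin
  expect_true(all(abs(pl$mean_tau[ok] - (4 + 0.05 * pl$bin_center[ok])) < 0.03))
  # a distance range with no pixels yields invalid bins
  pr <- decay_profile(img, d, bin = 1, range = c(0, 40))
  expect_true(any(!is.finite(pr$mean_tau)))
})

test_that("slope fits are exact on exact lines and error with too few bins", {
  prof <- data.frame(bin_center = 0:9, mean_tau = 4 + 0.02 * (0:9),
                     sd_tau = 0, n_pixels = 50, photon_sum = 1500)
  class(prof) <- c("gradient_profile", "data.frame")
  f <- fit_slope(prof)
  expect_equal(f$slope, 0.02)
  expect_equal(f$r2, 1)
  prof$mean_tau <- rep(4.4, 10)
  expect_equal(fit_slope(prof)$slope, 0)
  prof$mean_tau[3:10] <- NA
  expect_error(fit_slope(prof), "3 valid bins")
})

test_that("area-fraction front/rear regions have the right size and ordering", {
  m <- matrix(FALSE, 10, 12)
  m[3:7, 2:11] <- TRUE  # 50-px strip is awkward; use 100-px block
  m <- matrix(FALSE, 10, 12); m[1:10, 2:11] <- TRUE
  d <- matrix(rep(1:12, each = 10), 10, 12)  # distance to the left edge
  rs <- front_rear_by_fraction(m, d, 0.2)
  expect_equal(sum(rs$front), 20)
  expect_equal(sum(rs$rear), 20)
  expect_false(any(rs$front & rs$rear))
  rs5 <- front_rear_by_fraction(m, d, 0.5)
  expect_equal(sum(rs5$front) + sum(rs5$rear), sum(m))
  # on a linear field the front mean exceeds the rear mean iff slope is
  # positive toward the edge (small distance = front)
  tau <- 5 - 0.05 * d; tau[!m] <- NA
  img <- uniform_img(tau, 30, 1)
  expect_gt(weighted_mean_tau(img, rs$front), weighted_mean_tau(img, rs$rear))
})

test_that("angular front/rear sectors are symmetric and swap under 180 degrees", {
  m <- disc_mask(81, 35)
  rs <- front_rear_angular(m, 0, half_angle = 30, dmax = 5, pixel_size = 1)
  expect_lt(abs(sum(rs$front) - sum(rs$rear)) / sum(rs$front), 0.02)
  expect_false(any(rs$front & rs$rear))
  # dmax covering the whole disc: each sector is ~60/360 of the area
  rs2 <- front_rear_angular(m, 0, 30, dmax = 100, pixel_size = 1)
  expect_equal(sum(rs2$front) / sum(m), 1 / 6, tolerance = 0.03)
  # rotating the polarity by 180 swaps the masks
  rs3 <- front_rear_angular(m, 180, 30, dmax = 5, pixel_size = 1)
  expect_identical(rs3$front, rs$rear)
  expect_identical(rs3$rear, rs$front)
})

test_that("2D histograms are consistent with 1D profiles and conserve pixels", {
  m <- disc_mask(41, 16)
  set.seed(3)
  tau <- matrix(NA_real_, 41, 41)
  tau[m] <- runif(sum(m), 4, 5)
  ph <- matrix(0, 41, 41); ph[m] <- rpois(sum(m), 30)
  img <- new_lifetime_image(tau, ph, 1)
  dA <- edge_distance(m, 1)$d
  dB <- (col(m) - 21) * 1
  h <- hist2d_mean(img, dA, dB, binA = 1, binB = 2)
  expect_equal(sum(h$n_pixels), sum(is.finite(tau) & ph > 0 & is.finite(dA)))
  # constant tau: every occupied cell equals the constant
  imgc <- new_lifetime_image(ifelse(m, 4.2, NA), ph, 1)
  hc <- hist2d_mean(imgc, dA, dB)
  expect_true(all(abs(hc$mean_tau[hc$n_pixels > 0] - 4.2) < 1e-12))
  # tau depending only on field A: map constant along B
  imga <- new_lifetime_image(4 + 0.1 * floor(dA) + 0 * dB, ph, 1)
  ha <- hist2d_mean(imga, dA, dB, binA = 1, binB = 2)
  for (i in seq_along(ha$centersA)) {
    v <- ha$mean_tau[i, ha$n_pixels[i, ] > 0]
    if (length(v) > 1) expect_lt(diff(range(v)), 1e-9)
  }
  # marginalizing the 2D histogram over B equals the 1D profile exactly
  prof <- decay_profile(img, dA, bin = 1, range = range(h$edgesA))
  marg <- rowSums(h$mean_tau * h$photon_sum, na.rm = TRUE) /
    rowSums(h$photon_sum, na.rm = TRUE)
  cmp <- is.finite(prof$mean_tau)
  expect_equal(marg[cmp], prof$mean_tau[cmp], tolerance = 1e-12)
})

test_that("pattern alignment recovers shifts and respects template symmetry", {
  tmpl <- make_scene(scene_spec("cross"))
  pm <- tmpl$pattern_mask
  img <- uniform_img(ifelse(tmpl$cell_mask, 4.5, NA))
  # single image, identity placement
  a1 <- align_and_average(list(img), list(pm), pm, fold = 4)
  expect_equal(a1$mean[is.finite(a1$mean)],
               img$tau[is.finite(a1$mean)])
  # two copies shifted by (5, -3): average equals the value on common support
  sh <- tensiongrad:::.shift_mat
  img2 <- new_lifetime_image(sh(img$tau, 5, -3), sh(img$photons, 5, -3, fill = 0), 0.25)
  pm2 <- sh(pm, 5, -3, fill = FALSE)
  a2 <- align_and_average(list(img, img2), list(pm, pm2), pm, fold = 4)
  expect_true(all(a2$kept))
  expect_true(all(abs(a2$mean[is.finite(a2$mean)] - 4.5) < 1e-12))
  # rotating an input by 90 degrees leaves the average unchanged (4-fold)
  rot <- tensiongrad:::.rot90
  img3 <- new_lifetime_image(rot(img$tau, 1), rot(img$photons, 1), 0.25)
  a3 <- align_and_average(list(img3), list(rot(pm, 1)), pm, fold = 4)
  expect_equal(a3$mean, a1$mean)
  # misaligned image below the overlap floor is dropped
  blob <- matrix(FALSE, 256, 256); blob[1:40, 1:40] <- TRUE
  expect_message(
    a4 <- align_and_average(list(img, uniform_img(matrix(1, 256, 256))),
                            list(pm, blob), pm, fold = 1),
    "dropping")
  expect_identical(a4$kept, c(TRUE, FALSE))
})

test_that("decile regions cover two deciles each, stay disjoint, sit at the extremes", {
  set.seed(9)
  mp <- matrix(runif(100), 10)
  r <- decile_regions(mp, 2)
  expect_equal(sum(r$high), 20)
  expect_equal(sum(r$low), 20)
  expect_false(any(r$high & r$low))
  grad <- matrix(rep(1:20, each = 10) + 0.001 * (1:200), 10, 20)
  rg <- decile_regions(grad, 2)
  expect_true(all(which(rg$high, arr.ind = TRUE)[, 2] >= 17))
  expect_true(all(which(rg$low, arr.ind = TRUE)[, 2] <= 4))
  expect_error(decile_regions(matrix(1, 10, 10)), "constant")
})

test_that("difference maps subtract the reference and obey the algebra", {
  ref <- matrix(4.5, 8, 8)
  same <- difference_map(list(ref), ref)
  expect_true(all(same$average == 0))
  plus <- difference_map(list(ref + 0.3), ref)
  expect_true(all(abs(plus$average - 0.3) < 1e-12))
  A <- ref + 0.2; B <- ref - 0.1
  dA <- difference_map(list(A), ref)$average
  dB <- difference_map(list(B), ref)$average
  expect_equal(dA - dB, A - B)
  expect_error(difference_map(list(matrix(NA_real_, 8, 8)), ref), "support")
})

test_that("contour profiles are flat for constant fields and measure the perimeter", {
  m <- disc_mask(121, 45)
  img <- uniform_img(ifelse(m, 4.5, NA), 30, 0.25)
  cp <- contour_profile(img, m, band = 1)
  expect_true(all(abs(cp$mean_tau[cp$n_pixels > 0] - 4.5) < 1e-12))
  expect_equal(attr(cp, "arc_length"), 2 * pi * 45 * 0.25, tolerance = 0.05)
  # periodic: occupied bins at both ends of the arc
  occ <- which(cp$n_pixels > 0)
  expect_equal(min(occ), 1)
  expect_gt(max(occ), nrow(cp) - 2)
  # multiple components: largest used with a warning
  m2 <- m; m2[1:6, 1:6] <- TRUE
  expect_warning(contour_profile(img, m2), "largest")
})
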