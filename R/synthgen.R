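# Synthetic data generation: scenes with known lifetime ground truth, TCSPC
# photon statistics, SLB spreading movies, FCS line scans and FRAP traces.

#' TCSPC acquisition configuration
#'
#' Describes the time base of a pulsed time-correlated single photon counting
#' acquisition and the fixed bi-exponential component pair used to realize a
#' target mean lifetime. The histogram window is `1000 / rep_rate` ns
#' (50 ns at the default 20 MHz repetition rate).
#'
#' @param rep_rate laser repetition rate, MHz.
#' @param n_bins number of arrival-time histogram bins across the window.
#' @param irf_center instrument-response delay, ns.
#' @param irf_sigma Gaussian IRF width, ns (0 gives a delta IRF).
#' @param tau_pair fixed component lifetimes `c(tau1, tau2)` in ns; target mean
#'   lifetimes are realized by varying the photon fraction on `tau1`.
#' @return an object of class `tcspc_config`.
#' @export
tcspc_config <- function(rep_rate = 20, n_bins = 256, irf_center = 2,
                         irf_sigma = 0.2, tau_pair = c(1.5, 6.0)) {
  window <- 1000 / rep_rate
  stopifnot(rep_rate > 0, n_bins >= 8, irf_sigma >= 0,
            length(tau_pair) == 2, tau_pair[1] > 0,
            tau_pair[1] < tau_pair[2], tau_pair[2] < window)
  structure(list(rep_rate = rep_rate, window = window, n_bins = n_bins,
                 bin_width = window / n_bins, irf_center = irf_center,
                 irf_sigma = irf_sigma, tau_pair = tau_pair),
            class = "tcspc_config")
}

#' Scene specification for synthetic lifetime images
#'
#' Describes the geometry and true-lifetime field of a synthetic cell or
#' supported lipid bilayer (SLB) scene. The lifetime field is
#' `baseline_tau + linear_slope * x + edge_amplitude * g(d) + plane_offset`
#' where `x` is the coordinate along the polarity axis (relative to the mask
#' centroid) and `g(d)` decays with the inward distance `d` from the cell edge
#' either linearly (`max(0, 1 - d/L)`) or exponentially (`exp(-d/L)`).
#'
#' @param shape one of `"keratocyte"`, `"polarized"`, `"cross"`, `"crossbow"`,
#'   `"ring"`, `"disc"`, `"slb"`.
#' @param image_size image dimensions in pixels (rows, cols); defaults depend
#'   on the shape.
#' @param pixel_size µm per pixel.
#' @param baseline_tau baseline mean lifetime, ns.
#' @param linear_slope lifetime slope along the polarity axis (+x), ns/µm.
#' @param edge_amplitude lifetime elevation at the cell edge, ns.
#' @param edge_decay_length decay length of the edge term, µm.
#' @param edge_decay_form `"exponential"` or `"linear"`.
#' @param plane_offset additive offset, ns (e.g. to emulate the upper plane of
#'   the plasma membrane relative to the bottom plane).
#' @param mean_photons expected photons per pixel inside the mask.
#' @param seed integer seed used by downstream photon simulation.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c("polarized", "keratocyte", "cross", "crossbow",
                                 "ring", "disc", "slb"),
                       image_size = NULL, pixel_size = 0.25,
                       baseline_tau = 4.5, linear_slope = 0,
                       edge_amplitude = 0, edge_decay_length = 2,
                       edge_decay_form = c("exponential", "linear"),
                       plane_offset = 0, mean_photons = 30, seed = 1L) {
  shape <- match.arg(shape)
  edge_decay_form <- match.arg(edge_decay_form)
  if (is.null(image_size))
    image_size <- if (shape == "polarized") c(384L, 384L) else c(256L, 256L)
  stopifnot(baseline_tau > 0, mean_photons > 0, edge_decay_length > 0,
            pixel_size > 0, length(image_size) == 2)
  structure(list(shape = shape, image_size = as.integer(image_size),
                 pixel_size = pixel_size, baseline_tau = baseline_tau,
                 linear_slope = linear_slope, edge_amplitude = edge_amplitude,
                 edge_decay_length = edge_decay_length,
                 edge_decay_form = edge_decay_form,
                 plane_offset = plane_offset, mean_photons = mean_photons,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# pixel-center coordinate grids (µm) relative to the image center;
# x runs along columns (polarity axis), y along rows (up = +y)
.scene_grid <- function(image_size, pixel_size) {
  nr <- image_size[1]; nc <- image_size[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * pixel_size
  y <- -(seq_len(nr) - (nr + 1) / 2) * pixel_size
  list(x = matrix(rep(x, each = nr), nr, nc),
       y = matrix(rep(y, nc), nr, nc))
}

.shape_masks <- function(shape, g) {
  x <- g$x; y <- g$y
  r <- sqrt(x^2 + y^2)
  pattern <- NULL
  mask <- switch(shape,
    disc = r <= 20,
    ring = r >= 14 & r <= 20,
    cross = (abs(x) <= 4 & abs(y) <= 20) | (abs(y) <= 4 & abs(x) <= 20),
    crossbow = (r >= 17 & r <= 23 & y >= -5) |
               (abs(x) <= 3 & y <= 0 & y >= -20),
    keratocyte = r >= 10 & r <= 22 & x >= 0,
    polarized = (x / 38)^2 + (y / 26)^2 <= 1 |
                (x - 34)^2 + y^2 <= 10^2,
    slb = x <= 0,
    stop("unknown shape: ", shape)
  )
  if (shape %in% c("cross", "crossbow", "ring", "disc")) {
    pattern <- mask
    # cell spreads over and slightly beyond the adhesive pattern
    rmax <- max(r[pattern]) + 2
    mask <- r <= rmax
  }
  list(cell = mask, pattern = pattern)
}

#' Build a synthetic scene with known per-pixel true lifetime
#'
#' Deterministic given the scene specification: rasterizes the cell (and, for micropatterns,
#' the pattern) mask and evaluates the true mean-lifetime field inside it.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `scene_truth` with elements `cell_mask`,
#'   `pattern_mask` (or `NULL`), `true_tau` (ns, `NA` outside the cell) and
#'   `spec`.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  g <- .scene_grid(spec$image_size, spec$pixel_size)
  m <- .shape_masks(spec$shape, g)
  mask <- m$cell
  if (!any(mask)) stop("empty scene mask")
  xc <- mean(g$x[mask])
  tau <- spec$baseline_tau + spec$linear_slope * (g$x - xc) + spec$plane_offset
  if (spec$edge_amplitude != 0) {
    d <- -signed_distance(mask, spec$pixel_size)$d  # inward distance, µm
    d[!mask] <- NA
    gterm <- if (spec$edge_decay_form == "exponential")
      exp(-d / spec$edge_decay_length)
    else pmax(0, 1 - d / spec$edge_decay_length)
    tau <- tau + spec$edge_amplitude * gterm
  }
  tau[!mask] <- NA_real_
  if (any(tau[mask] <= 0)) stop("true lifetime field non-positive inside mask")
  structure(list(cell_mask = mask, pattern_mask = m$pattern,
                 true_tau = tau, spec = spec),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth>", x$spec$shape, paste(dim(x$cell_mask), collapse = "x"),
      "px,", sum(x$cell_mask), "cell px, tau range",
      paste(signif(range(x$true_tau, na.rm = TRUE), 4), collapse = "-"), "ns\n")
  invisible(x)
}

#' Photon fraction on the fast component realizing a target mean lifetime
#'
#' For a bi-exponential decay with fixed component lifetimes `(tau1, tau2)`,
#' the intensity-weighted mean lifetime is `alpha1*tau1 + alpha2*tau2`, so the
#' intensity (photon) fraction on the fast component that realizes `tau_bar`
#' is `alpha1 = (tau2 - tau_bar) / (tau2 - tau1)`.
#'
#' @param tau_bar target intensity-weighted mean lifetime, ns.
#' @param cfg a [tcspc_config()] supplying `tau_pair`.
#' @return intensity fraction on `tau1`, in `[0, 1]` (vectorized).
#' @export
target_tau_to_amplitudes <- function(tau_bar, cfg) {
  t1 <- cfg$tau_pair[1]; t2 <- cfg$tau_pair[2]
  if (any(tau_bar < t1 - 1e-12 | tau_bar > t2 + 1e-12, na.rm = TRUE))
    stop("tau_bar outside the component interval [", t1, ", ", t2, "] ns")
  pmin(1, pmax(0, (t2 - tau_bar) / (t2 - t1)))
}

# run code with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Expected (noise-free) instrument response curve
#'
#' Gaussian IRF integrated over the histogram bins (wrapped at the window).
#' With `irf_sigma = 0` the IRF is a delta; its mass is placed in the bin
#' containing `irf_center`.
#'
#' @param cfg a [tcspc_config()].
#' @param total total counts the curve is scaled to.
#' @return an object of class `irf_curve` (fields `counts`, `bin_width`,
#'   `t0`, `n_bins`).
#' @export
make_irf <- function(cfg, total = 1e6) {
  nb <- cfg$n_bins; bw <- cfg$bin_width
  edges <- seq(0, cfg$window, length.out = nb + 1)
  p <- numeric(nb)
  if (cfg$irf_sigma == 0) {
    p[pmin(nb, floor((cfg$irf_center %% cfg$window) / bw) + 1)] <- 1
  } else {
    for (s in -1:1) {  # wrap Gaussian tails across the periodic window
      p <- p + diff(stats::pnorm(edges, cfg$irf_center - s * cfg$window,
                                 cfg$irf_sigma))
    }
  }
  structure(list(counts = p / sum(p) * total, bin_width = bw, t0 = 0,
                 n_bins = nb), class = "irf_curve")
}

#' Simulate a TCSPC image stack from a scene truth
#'
#' Each in-mask pixel receives `Poisson(mean_photons)` photons; every photon's
#' arrival time is drawn from the bi-exponential realizing the pixel's true
#' mean lifetime (components fixed by `cfg$tau_pair`), shifted by the IRF
#' center, jittered by the Gaussian IRF, folded into the periodic excitation
#' window and binned.
#'
#' @param truth a [make_scene()] result.
#' @param cfg a [tcspc_config()].
#' @param seed integer seed (defaults to the scene spec's seed).
#' @return an object of class `decay_stack`: `counts` array of dimension
#'   `(n_bins, rows, cols)` plus the configuration.
#' @export
simulate_tcspc_image <- function(truth, cfg, seed = truth$spec$seed) {
  stopifnot(inherits(truth, "scene_truth"), inherits(cfg, "tcspc_config"))
  mask <- truth$cell_mask
  nb <- cfg$n_bins; bw <- cfg$bin_width; W <- cfg$window
  idx <- which(mask)
  a1 <- target_tau_to_amplitudes(truth$true_tau[idx], cfg)
  counts <- .with_seed(seed, {
    n <- rpois(length(idx), truth$spec$mean_photons)
    pid <- rep.int(seq_along(idx), n)
    m <- length(pid)
    comp1 <- runif(m) < a1[pid]
    t <- rexp(m) * ifelse(comp1, cfg$tau_pair[1], cfg$tau_pair[2]) +
      cfg$irf_center
    if (cfg$irf_sigma > 0) t <- t + rnorm(m, 0, cfg$irf_sigma)
    t <- t %% W
    bin <- pmin(nb, floor(t / bw) + 1)
    tabulate(bin + nb * (pid - 1L), nbins = nb * length(idx))
  })
  out <- matrix(0L, nb, length(mask))
  out[, idx] <- matrix(counts, nb)
  dim(out) <- c(nb, dim(mask))
  structure(list(counts = out, cfg = cfg, pixel_size = truth$spec$pixel_size),
            class = "decay_stack")
}

#' Simulate a spreading supported lipid bilayer movie
#'
#' The bilayer front advances along +x with speed `v(t) = v0 ((t+t1)/t1)^-beta`
#' (power-law slowdown); each frame carries a linear lifetime gradient of slope
#' `slope_coupling * v(t)` oriented so the advancing front has the highest
#' lifetime (`front_high = FALSE` flips the sign).
#'
#' @param r0 initial front position from the left crop edge, µm.
#' @param beta power-law exponent of the slowdown (> 0).
#' @param slope_coupling gradient slope per unit speed, ns·min/µm².
#' @param frames number of frames (>= 2).
#' @param dt frame interval, min.
#' @param v0 initial spreading speed, µm/min.
#' @param t1 power-law reference time, min.
#' @param crop_length,crop_width crop dimensions, µm (length along +x).
#' @param pixel_size µm/pixel.
#' @param baseline_tau baseline lifetime at the front, ns.
#' @param mean_photons expected photons per pixel (photon-count channel).
#' @param noise_sd per-pixel Gaussian lifetime noise, ns.
#' @param front_high logical; if `TRUE` lifetime decreases away from the front.
#' @param seed integer seed.
#' @return list with `masks` and `tau` (lists of matrices), `photons`,
#'   `times` (min) and a `truth` list (`front_x`, `speed`, `slope` per frame).
#' @export
simulate_slb_movie <- function(r0 = 20, beta = 1, slope_coupling = 0.004,
                               frames = 10, dt = 1, v0 = 8, t1 = 1,
                               crop_length = 200, crop_width = 40,
                               pixel_size = 0.5, baseline_tau = 4.4,
                               mean_photons = 50, noise_sd = 0,
                               front_high = TRUE, seed = 1L) {
  stopifnot(beta > 0, frames >= 2, crop_width > 0)
  nr <- round(crop_width / pixel_size); nc <- round(crop_length / pixel_size)
  xs <- (seq_len(nc) - 0.5) * pixel_size
  times <- (seq_len(frames) - 1) * dt
  pos <- function(t) {
    if (abs(beta - 1) < 1e-9) r0 + v0 * t1 * log((t + t1) / t1)
    else r0 + v0 * t1 / (1 - beta) * (((t + t1) / t1)^(1 - beta) - 1)
  }
  front_x <- pos(times)
  speed <- v0 * ((times + t1) / t1)^(-beta)
  slope <- slope_coupling * speed
  sgn <- if (front_high) 1 else -1
  .with_seed(seed, {
    masks <- tau <- photons <- vector("list", frames)
    for (k in seq_len(frames)) {
      inside <- xs <= front_x[k]
      m <- matrix(rep(inside, each = nr), nr, nc)
      tk <- matrix(NA_real_, nr, nc)
      tk[, inside] <- rep(baseline_tau - sgn * slope[k] * (front_x[k] - xs[inside]),
                          each = nr)
      if (noise_sd > 0) tk[m] <- tk[m] + rnorm(sum(m), 0, noise_sd)
      ph <- matrix(0L, nr, nc)
      ph[m] <- rpois(sum(m), mean_photons)
      masks[[k]] <- m; tau[[k]] <- tk; photons[[k]] <- ph
    }
    list(masks = masks, tau = tau, photons = photons, times = times,
         dt = dt, pixel_size = pixel_size, crop_width = crop_width,
         truth = list(front_x = front_x, speed = speed, slope = slope,
                      slope_coupling = slope_coupling, beta = beta))
  })
}

#' Simulate a line-scan FCS kymograph
#'
#' Point emitters diffuse in two dimensions (per-axis step variance
#' `2 D line_time`) on a periodic domain at least 3x the scan length, with an
#' optional drift along the scan axis. Per line, each scan pixel records
#' `Poisson(background + sum brightness * exp(-2((x-xp)^2+yp^2)/waist^2))`
#' counts.
#'
#' @param n_pixels pixels per line.
#' @param pixel_size µm/pixel.
#' @param line_time s per line.
#' @param n_lines number of lines (>= 1000).
#' @param D diffusion coefficient, µm²/s.
#' @param n_particles number of emitters in the periodic domain.
#' @param brightness peak counts per emitter per line.
#' @param background background counts per pixel per line.
#' @param drift_v drift speed along the scan axis, µm/s.
#' @param psf_waist 1/e² Gaussian beam waist, µm.
#' @param dwell pixel dwell time, s (metadata only).
#' @param seed integer seed.
#' @param keep_tracks if `TRUE`, attach the particle x-trajectories (µm).
#' @return an object of class `kymograph` (see [kymograph()]).
#' @export
simulate_linescan <- function(n_pixels = 64, pixel_size = 0.16,
                              line_time = 960e-6, n_lines = 50000,
                              D = 2, n_particles = 50, brightness = 5,
                              background = 1, drift_v = 0, psf_waist = 0.25,
                              dwell = 5.2e-6, seed = 1L, keep_tracks = FALSE) {
  stopifnot(n_lines >= 1000, D >= 0, psf_waist > 0)
  Lx <- 3 * n_pixels * pixel_size
  Ly <- 8 * psf_waist
  w2 <- psf_waist^2
  xpix <- (seq_len(n_pixels) - 0.5) * pixel_size
  .with_seed(seed, {
    sdstep <- sqrt(2 * D * line_time)
    x0 <- runif(n_particles, 0, Lx)
    y0 <- runif(n_particles, -Ly / 2, Ly / 2)
    stepx <- matrix(rnorm(n_particles * (n_lines - 1), drift_v * line_time,
                          sdstep), n_particles)
    stepy <- matrix(rnorm(n_particles * (n_lines - 1), 0, sdstep), n_particles)
    X <- cbind(x0, x0 + t(apply(stepx, 1, cumsum))) %% Lx
    Y <- (cbind(y0, y0 + t(apply(stepy, 1, cumsum))) + Ly / 2) %% Ly - Ly / 2
    inten <- matrix(0, n_lines, n_pixels)
    chunk <- 2000L
    for (s in seq(1L, n_lines, by = chunk)) {
      e <- min(n_lines, s + chunk - 1L)
      Xc <- X[, s:e, drop = FALSE]
      Ey <- brightness * exp(-2 * Y[, s:e, drop = FALSE]^2 / w2)
      for (j in seq_len(n_pixels)) {
        dx <- (Xc - xpix[j] + Lx / 2) %% Lx - Lx / 2
        inten[s:e, j] <- colSums(Ey * exp(-2 * dx^2 / w2))
      }
    }
    counts <- matrix(rpois(length(inten), inten + background),
                     n_lines, n_pixels)
    k <- kymograph(counts, pixel_size = pixel_size, line_time = line_time,
                   dwell = dwell)
    k$truth <- list(D = D, drift_v = drift_v, psf_waist = psf_waist,
                    n_particles = n_particles, domain = c(Lx, Ly),
                    brightness = brightness, background = background)
    if (keep_tracks) k$tracks_x <- X
    k
  })
}

#' Simulate a FRAP intensity trace
#'
#' Pre-bleach plateau at 1, then
#' `f(t) = (1 - bleach_depth) + bleach_depth * mobile * (1 - exp(-k t))`
#' with additive Gaussian noise.
#'
#' @param mobile mobile fraction in `[0, 1]`.
#' @param k recovery rate, 1/s.
#' @param bleach_depth fraction of signal removed by the bleach.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param n_pre,n_post number of pre-/post-bleach samples.
#' @param dt sampling interval, s.
#' @param seed integer seed.
#' @return data.frame with `time` (s; bleach at 0) and `intensity`; ground
#'   truth in `attr(, "truth")`.
#' @export
simulate_frap <- function(mobile = 0.8, k = 0.1, bleach_depth = 0.6,
                          noise_sd = 0, n_pre = 25, n_post = 150, dt = 0.5,
                          seed = 1L) {
  stopifnot(mobile >= 0, mobile <= 1, k > 0, bleach_depth > 0,
            bleach_depth <= 1)
  tpre <- -rev(seq_len(n_pre)) * dt
  tpost <- (seq_len(n_post) - 1) * dt
  f <- c(rep(1, n_pre),
         (1 - bleach_depth) + bleach_depth * mobile * (1 - exp(-k * tpost)))
  if (noise_sd > 0) f <- .with_seed(seed, f + rnorm(length(f), 0, noise_sd))
  out <- data.frame(time = c(tpre, tpost), intensity = f)
  attr(out, "truth") <- list(mobile = mobile, k = k, t_half = log(2) / k,
                             bleach_depth = bleach_depth)
  out
}
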