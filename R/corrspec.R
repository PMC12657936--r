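# Line-scan fluctuation spectroscopy (ACF/pCF) and FRAP analysis.

#' Line-scan kymograph container
#'
#' @param intensity matrix, lines (time) x pixels (space).
#' @param pixel_size µm/pixel (default 0.16).
#' @param line_time s per line (default 960 µs).
#' @param dwell pixel dwell time, s (metadata).
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(intensity, pixel_size = 0.16, line_time = 960e-6,
                      dwell = 5.2e-6) {
  stopifnot(is.matrix(intensity), all(intensity >= 0, na.rm = TRUE),
            pixel_size > 0, line_time > 0)
  structure(list(intensity = intensity, n_lines = nrow(intensity),
                 n_pixels = ncol(intensity), pixel_size = pixel_size,
                 line_time = line_time, dwell = dwell), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d lines x %d px, %.0f nm px, %.0f us lines\n",
              x$n_lines, x$n_pixels, x$pixel_size * 1e3, x$line_time * 1e6))
  invisible(x)
}

#' Detrend a kymograph column-wise
#'
#' Divides each column by its centered moving-average trend (truncated at the
#' ends) and rescales by the column mean, removing slow artefacts such as
#' photobleaching while preserving each column's mean intensity. The window
#' must stay much longer than the diffusion correlation time: the default of
#' 10000 lines (~10 s at 960 µs lines) suppresses bleaching on the
#' tens-of-seconds scale while leaving the heavy 1/lag tail of membrane
#' diffusion ACFs (correlation times of milliseconds to ~100 ms) intact.
#'
#' @param k a [kymograph()].
#' @param window moving-average window, lines (>= 100).
#' @return the detrended `kymograph`.
#' @export
detrend <- function(k, window = 10000) {
  stopifnot(inherits(k, "kymograph"), window >= 100)
  x <- k$intensity
  n <- nrow(x)
  h <- floor(window / 2)
  cs <- rbind(0, apply(x, 2, cumsum))
  lo <- pmax(0, seq_len(n) - h - 1)
  hi <- pmin(n, seq_len(n) + h)
  trend <- (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / (hi - lo)
  trend[trend <= 0] <- NA
  mu <- matrix(colMeans(x), n, ncol(x), byrow = TRUE)
  out <- x / trend * mu
  out[!is.finite(out)] <- 0
  k$intensity <- out
  k
}

# quasi-logarithmic binning of integer lags: every lag up to `keep`, then
# geometrically growing bins
.log_lag_bins <- function(max_lag, keep = 16, factor = 1.12) {
  b <- seq_len(min(keep, max_lag))
  v <- keep
  while (v < max_lag) {
    v <- max(v + 1, round(v * factor))
    b <- c(b, min(v, max_lag))
  }
  unique(b)
}

.bin_curve <- function(G_lin, line_time, kind, delta_r, n_avg) {
  max_lag <- length(G_lin)
  ub <- .log_lag_bins(max_lag)
  lb <- c(1, head(ub, -1) + 1)
  G <- lag <- numeric(length(ub))
  for (i in seq_along(ub)) {
    r <- lb[i]:ub[i]
    G[i] <- mean(G_lin[r])
    lag[i] <- mean(r) * line_time
  }
  structure(data.frame(lag = lag, G = G),
            kind = kind, delta_r = delta_r, n_avg = n_avg,
            class = c("correlation_curve", "data.frame"))
}

# positive-lag auto/cross-correlations for all requested column pairs via
# zero-padded FFT; unbiased normalization by (n - lag) and the column means
.corr_pairs <- function(x, ia, ib, max_lag) {
  n <- nrow(x)
  nfft <- stats::nextn(2 * n, 2)
  mu <- colMeans(x)
  dx <- sweep(x, 2, mu)
  pad <- rbind(dx, matrix(0, nfft - n, ncol(x)))
  Fa <- stats::mvfft(pad)
  acc <- numeric(max_lag)
  for (j in seq_along(ia)) {
    cc <- Re(stats::fft(Conj(Fa[, ia[j]]) * Fa[, ib[j]], inverse = TRUE)) / nfft
    acc <- acc + cc[2:(max_lag + 1)] / ((n - seq_len(max_lag)) *
                                          mu[ia[j]] * mu[ib[j]])
  }
  acc / length(ia)
}

#' Temporal autocorrelation of a kymograph section
#'
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` per column, averaged over the
#' section's columns and reported on a quasi-logarithmic lag grid. The
#' acquisition convention splits the 64-pixel line into three sections
#' (pixels 1-21, 22-42, 43-63, 1-based inclusive).
#'
#' @param k a detrended [kymograph()].
#' @param columns integer vector of columns (1-based); default all.
#' @param max_lag_frac largest lag as a fraction of the record length.
#' @return a `correlation_curve` data.frame with `lag` (s) and `G`.
#' @export
kymo_acf <- function(k, columns = NULL, max_lag_frac = 0.25) {
  stopifnot(inherits(k, "kymograph"))
  columns <- columns %||% seq_len(k$n_pixels)
  if (any(columns < 1 | columns > k$n_pixels))
    stop("section outside the kymograph")
  max_lag <- floor(k$n_lines * max_lag_frac)
  G <- .corr_pairs(k$intensity, columns, columns, max_lag)
  .bin_curve(G, k$line_time, "acf", 0, length(columns))
}

#' Pair correlation between columns a fixed pixel shift apart
#'
#' Cross-correlates each column `i` with column `i + delta_r` (forward,
#' left to right) or `i - delta_r` (reverse), averaged over all admissible
#' columns. Directed transport produces a forward/reverse peak asymmetry;
#' pure diffusion gives symmetric curves.
#'
#' @param k a detrended [kymograph()].
#' @param delta_r column shift, pixels (default 5).
#' @param direction `"forward"` or `"reverse"`.
#' @param max_lag_frac largest lag as a fraction of the record length.
#' @return a `correlation_curve` data.frame.
#' @export
kymo_pcf <- function(k, delta_r = 5, direction = c("forward", "reverse"),
                     max_lag_frac = 0.25) {
  stopifnot(inherits(k, "kymograph"), delta_r >= 1, delta_r < k$n_pixels)
  direction <- match.arg(direction)
  np <- k$n_pixels
  if (direction == "forward") {
    ia <- seq_len(np - delta_r); ib <- ia + delta_r
  } else {
    ia <- (delta_r + 1):np; ib <- ia - delta_r
  }
  max_lag <- floor(k$n_lines * max_lag_frac)
  G <- .corr_pairs(k$intensity, ia, ib, max_lag)
  .bin_curve(G, k$line_time, paste0("pcf_", direction), delta_r, length(ia))
}

#' Two-component diffusion fit of an autocorrelation curve
#'
#' Least-squares fit of
#' `G(tau) = G0 (f / (1 + tau/tauD1) + (1-f) / (1 + tau/tauD2)) + offset`
#' with `tauD_i = waist^2 / (4 D_i)`, the standard two-dimensional membrane
#' diffusion model for a Gaussian detection area. `D0` is the
#' amplitude-weighted mean of the two coefficients.
#'
#' @param curve a [kymo_acf()] result (>= 10 lag points).
#' @param psf_waist Gaussian beam waist, µm (default 0.25).
#' @return an object of class `acf_fit` with `G0`, `f1`, `f2`, `D1 <= D2`,
#'   `D0`, `offset`, `converged`.
#' @export
fit_acf <- function(curve, psf_waist = 0.25) {
  ok <- is.finite(curve$G)
  if (sum(ok) < 10) stop("need at least 10 lag points")
  d <- as.data.frame(curve[ok, ])
  g0 <- mean(d$G[1:3])
  td0 <- d$lag[which.min(abs(d$G - g0 / 2))]
  model <- function(p)
    p[1] * (p[2] / (1 + d$lag / p[3]) + (1 - p[2]) / (1 + d$lag / p[4])) + p[5]
  starts <- list(
    list(f = 0.45, s1 = 1 / 5, s2 = 5), list(f = 0.5, s1 = 1 / 2, s2 = 2),
    list(f = 0.3, s1 = 1, s2 = 10), list(f = 0.7, s1 = 1 / 10, s2 = 1))
  best <- NULL
  for (st in starts) {
    # raw Levenberg-Marquardt: robust to components collapsing at a bound
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(G0 = max(g0, 1e-4), f = st$f, td1 = td0 * st$s1,
                td2 = td0 * st$s2, off = 0),
        lower = c(0, 0, 1e-7, 1e-7, -abs(g0)),
        upper = c(10 * abs(g0) + 1, 1, 1e4, 1e4, abs(g0)),
        fn = function(p) d$G - model(p),
        control = nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(G0 = NA, f1 = NA, f2 = NA, D1 = NA, D2 = NA,
                          D0 = NA, offset = NA, converged = FALSE),
                     class = "acf_fit"))
  }
  p <- best$par
  D <- psf_waist^2 / (4 * c(p[["td1"]], p[["td2"]]))
  f <- c(p[["f"]], 1 - p[["f"]])
  if (D[1] > D[2]) { D <- rev(D); f <- rev(f) }
  structure(list(G0 = p[["G0"]], f1 = f[1], f2 = f[2], D1 = D[1], D2 = D[2],
                 D0 = sum(f * D), offset = p[["off"]], converged = TRUE,
                 psf_waist = psf_waist),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("<acf_fit> G0 %.4g, D0 %.3g um2/s (D1 %.3g f %.2f, D2 %.3g f %.2f)\n",
              x$G0, x$D0, x$D1, x$f1, x$D2, x$f2))
  invisible(x)
}

#' Gaussian fit of a pair-correlation peak
#'
#' Fits a Gaussian in `log10(lag)` around the positive peak of a pCF curve;
#' the peak position is the direction-dependent arrival time and, when an
#' ACF fit is supplied, the peak amplitude over `G0` is the transport
#' efficiency. A curve with no positive peak yields a no-transport result
#' rather than an error.
#'
#' @param curve a [kymo_pcf()] result.
#' @param acf_fit optional paired [fit_acf()] result.
#' @param min_lag ignore lags below this, s (default 2 line times).
#' @return an object of class `pcf_fit`: `tau_arrival` (s), `G_tau`,
#'   `transport_efficiency`, `has_peak`.
#' @export
fit_pcf <- function(curve, acf_fit = NULL, min_lag = NULL) {
  min_lag <- min_lag %||% (2 * min(curve$lag))
  d <- curve[is.finite(curve$G) & curve$lag >= min_lag, ]
  if (!nrow(d) || max(d$G) <= 0) {
    return(structure(list(tau_arrival = NA_real_, G_tau = NA_real_,
                          transport_efficiency = NA_real_, has_peak = FALSE),
                     class = "pcf_fit"))
  }
  pk <- which.max(d$G)
  d$l <- log10(d$lag)
  sel <- d$G > 0.2 * d$G[pk]
  # keep the contiguous run around the peak
  runs <- rle(sel)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  ri <- which(runs$values & starts <= pk & ends >= pk)
  sel <- seq(starts[ri], ends[ri])
  dd <- d[sel, ]
  fit <- tryCatch(
    nlsLM(G ~ A * exp(-(l - mu)^2 / (2 * s^2)), data = dd,
          start = list(A = d$G[pk], mu = d$l[pk], s = 0.4),
          lower = c(0, min(d$l) - 1, 0.05), upper = c(Inf, max(d$l) + 1, 3),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- d$lag[pk]; A <- d$G[pk]
  } else {
    p <- coef(fit); tau <- 10^p[["mu"]]; A <- p[["A"]]
  }
  structure(list(tau_arrival = unname(tau), G_tau = unname(A),
                 transport_efficiency =
                   if (!is.null(acf_fit)) unname(A / acf_fit$G0) else NA_real_,
                 has_peak = TRUE),
            class = "pcf_fit")
}

#' Forward/reverse pCF asymmetry and flow decision
#'
#' Compares the peak amplitudes of the forward and reverse pair-correlation
#' curves. Directed flow transports correlation preferentially in one
#' direction, so the normalized asymmetry
#' `(peak_fwd - peak_rev) / (peak_fwd + peak_rev)` is near 0 for pure
#' diffusion and approaches 1 for strong flow.
#'
#' @param fwd,rev forward and reverse [kymo_pcf()] curves.
#' @param threshold asymmetry above which flow is called (default 0.35).
#' @param lag_range optional `c(lo, hi)` lag window, s.
#' @return list with `asymmetry`, `flow` (logical), `peak_fwd`, `peak_rev`.
#' @export
transport_asymmetry <- function(fwd, rev, threshold = 0.35, lag_range = NULL) {
  win <- function(cv) {
    d <- cv[is.finite(cv$G), ]
    if (!is.null(lag_range))
      d <- d[d$lag >= lag_range[1] & d$lag <= lag_range[2], ]
    max(d$G)
  }
  pf <- win(fwd); pr <- win(rev)
  a <- if (pf + pr <= 0) 0 else (pf - pr) / (abs(pf) + abs(pr))
  list(asymmetry = a, flow = is.finite(a) && a > threshold && pf > 0,
       peak_fwd = pf, peak_rev = pr)
}

#' Normalize a FRAP trace
#'
#' Background-subtracts, optionally corrects for acquisition photobleaching
#' with a reference trace, and rescales so the mean of the `pre_window`
#' seconds before the bleach is 1 and the first post-bleach sample is 0.
#'
#' @param trace data.frame with `time` (s) and `intensity`.
#' @param background scalar background intensity (or vector along the trace).
#' @param reference optional reference intensity vector (same length) used to
#'   divide out acquisition bleaching.
#' @param bleach_time time of the bleach, s (default 0).
#' @param pre_window pre-bleach averaging window, s (default 5).
#' @return data.frame with `time` (s, bleach at 0) and `value`.
#' @export
frap_normalize <- function(trace, background = 0, reference = NULL,
                           bleach_time = 0, pre_window = 5) {
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  x <- trace$intensity - background
  pre <- trace$time < bleach_time &
    trace$time >= bleach_time - pre_window
  if (!any(pre)) stop("no pre-bleach samples before the bleach time")
  if (!is.null(reference)) {
    ref <- reference - background
    x <- x / (ref / mean(ref[pre]))
  }
  post1 <- which(trace$time >= bleach_time)[1]
  if (is.na(post1)) stop("no post-bleach samples")
  f0 <- x[post1]
  fpre <- mean(x[pre])
  data.frame(time = trace$time - bleach_time,
             value = (x - f0) / (fpre - f0))
}

#' Single-exponential fit of a normalized FRAP recovery
#'
#' Fits `M (1 - exp(-k t))` to the post-bleach samples; the mobile fraction
#' is `M` and the recovery half-time `ln 2 / k`.
#'
#' @param norm a [frap_normalize()] result (or data.frame `time`, `value`).
#' @return an object of class `frap_result`: `mobile_fraction`, `k` (1/s),
#'   `t_half` (s), `residual_sd`, `converged`, `flagged` (degenerate
#'   recovery, e.g. fully immobile).
#' @export
frap_fit <- function(norm) {
  d <- norm[norm$time >= 0 & is.finite(norm$value), ]
  stopifnot(nrow(d) >= 5)
  plateau <- mean(tail(d$value, max(3, floor(nrow(d) / 10))))
  if (plateau < 0.02 || stats::sd(d$value) < 1e-12) {
    return(structure(list(mobile_fraction = max(0, plateau), k = NA_real_,
                          t_half = NA_real_, residual_sd = stats::sd(d$value),
                          converged = FALSE, flagged = TRUE),
                     class = "frap_result"))
  }
  khalf <- {
    i <- which(d$value >= plateau / 2)[1]
    if (is.na(i) || d$time[i] <= 0) 0.1 else log(2) / d$time[i]
  }
  fit <- tryCatch(
    nlsLM(value ~ M * (1 - exp(-k * time)), data = d,
          start = list(M = plateau, k = khalf),
          lower = c(0, 1e-6), upper = c(2, 1e3),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(mobile_fraction = NA_real_, k = NA_real_,
                          t_half = NA_real_, residual_sd = NA_real_,
                          converged = FALSE, flagged = TRUE),
                     class = "frap_result"))
  }
  p <- coef(fit)
  structure(list(mobile_fraction = unname(p[["M"]]), k = unname(p[["k"]]),
                 t_half = log(2) / unname(p[["k"]]),
                 residual_sd = stats::sd(residuals(fit)),
                 converged = TRUE, flagged = FALSE),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("<frap_result> mobile %.3f, t_half %.3g s%s\n",
              x$mobile_fraction, x$t_half, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Lipid flow velocity from a line-FRAP movie
#'
#' Integrates the fluorescence parallel to the bleached line (rows), tracks
#' the profile minimum across frames by fitting a parabola around the
#' discrete minimum, and reports the drift velocity of the minimum as the
#' slope of position versus time. Tracking stops with a warning once the dip
#' has recovered below the detection contrast.
#'
#' @param frames 3D array `(rows, cols, frames)` or list of matrices; the
#'   bleached line runs along rows, so profiles are taken along columns.
#' @param pixel_size µm/pixel along the profile (default 0.11, i.e. 11 µm
#'   per 100 pixels).
#' @param frame_dt s per frame (default 0.5).
#' @param search_halfwidth px around the previous minimum to search.
#' @param min_contrast dip depth (fraction of the profile median) below which
#'   tracking stops.
#' @return list with `positions` (µm per frame, `NA` after truncation),
#'   `velocity` (µm/s), `n_tracked`.
#' @export
line_frap_flow <- function(frames, pixel_size = 0.11, frame_dt = 0.5,
                           search_halfwidth = 10, min_contrast = 0.03) {
  if (is.list(frames)) frames <- simplify2array(frames)
  stopifnot(length(dim(frames)) == 3)
  nt <- dim(frames)[3]
  pos <- rep(NA_real_, nt)
  prev <- NULL
  for (t in seq_len(nt)) {
    prof <- colMeans(frames[, , t])
    nc <- length(prof)
    cand <- if (is.null(prev)) seq_len(nc)
            else max(1, prev - search_halfwidth):min(nc, prev + search_halfwidth)
    i <- cand[which.min(prof[cand])]
    depth <- (median(prof) - prof[i]) / median(prof)
    if (depth < min_contrast) {
      warning("dip recovered at frame ", t, "; track truncated")
      break
    }
    if (i <= 1 || i >= nc) { pos[t] <- (i - 1) * pixel_size; prev <- i; next }
    # parabola vertex through the three points around the discrete minimum
    y <- prof[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    frac <- if (abs(denom) < 1e-12) 0 else 0.5 * (y[1] - y[3]) / denom
    pos[t] <- (i - 1 + frac) * pixel_size
    prev <- i
  }
  ok <- which(is.finite(pos))
  vel <- if (length(ok) >= 2) {
    tt <- (ok - 1) * frame_dt
    unname(coef(lm(pos[ok] ~ tt))[2])
  } else NA_real_
  list(positions = pos, velocity = vel, n_tracked = length(ok))
}
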