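# Edge kinematics from mask time series, lifetime-velocity coupling, SLB
# expansion analysis, and track/shape descriptors.

#' Mask movie container
#'
#' @param masks list of congruent logical matrices, one per frame.
#' @param dt frame interval, min.
#' @param pixel_size µm/pixel.
#' @return an object of class `mask_movie`.
#' @export
mask_movie <- function(masks, dt, pixel_size) {
  stopifnot(length(masks) >= 1, dt > 0, pixel_size > 0)
  d <- dim(masks[[1]])
  stopifnot(all(vapply(masks, function(m) all(dim(m) == d), logical(1))))
  structure(list(masks = lapply(masks, function(m) m > 0), dt = dt,
                 pixel_size = pixel_size, n_frames = length(masks)),
            class = "mask_movie")
}

# distance to the cell exterior: positive inside (Euclidean distance to the
# nearest background pixel), negative outside (to the nearest mask pixel)
.dist_to_exterior <- function(mask) {
  din <- as.matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
  dout <- as.matrix(EBImage::distmap(matrix(as.numeric(!mask), nrow(mask))))
  din - dout
}

#' Edge velocity between consecutive frames
#'
#' The normal edge displacement is the difference between the
#' distance-to-exterior maps of frames `i+1` and `i`, evaluated at the
#' contour pixels of frame `i` and divided by the frame interval: positive
#' velocities point outward (protrusion), negative inward (retraction).
#'
#' @param movie a [mask_movie()].
#' @param i frame index (frames `i` and `i+1` must exist).
#' @return an object of class `edge_velocity_field`: `v` (µm/min; `NA` off
#'   the contour), `contour_idx` (linear indices of contour pixels), `frame`.
#' @export
edge_velocity <- function(movie, i = 1) {
  stopifnot(inherits(movie, "mask_movie"), i >= 1, i + 1 <= movie$n_frames)
  m0 <- movie$masks[[i]]; m1 <- movie$masks[[i + 1]]
  if (!any(m0) || !any(m1)) stop("empty mask")
  contour <- .mask_boundary(m0)
  dv <- (.dist_to_exterior(m1) - .dist_to_exterior(m0)) *
    movie$pixel_size / movie$dt
  v <- matrix(NA_real_, nrow(m0), ncol(m0))
  v[contour] <- dv[contour]
  structure(list(v = v, contour_idx = which(contour), frame = i,
                 pixel_size = movie$pixel_size, dt = movie$dt,
                 mask = m0, mask_next = m1), class = "edge_velocity_field")
}

# Vossepoel-Smeulders contour length (µm) of a mask
.contour_length <- function(mask, pixel_size) {
  tr <- .trace_contour(mask)
  sum(tr$step_len) * pixel_size
}

#' Kinematic consistency of an edge-velocity field
#'
#' Integrates the edge velocity over the contour (each contour pixel carries
#' an equal share of the contour length, taken as the mean of the two
#' frames' contour lengths -- the trapezoidal length of the moving
#' interface) times the frame interval, which should match the area change
#' between the two frames for smooth motion.
#'
#' @param vf an [edge_velocity()] field.
#' @return list with `integral` and contour `length` (µm², µm).
#' @export
edge_flux <- function(vf) {
  stopifnot(inherits(vf, "edge_velocity_field"))
  len <- (.contour_length(vf$mask, vf$pixel_size) +
            .contour_length(vf$mask_next, vf$pixel_size)) / 2
  vbar <- mean(vf$v[vf$contour_idx])
  list(integral = vbar * len * vf$dt, length = len)
}

#' Classify cell edges into protruding and retracting regions
#'
#' Contour pixels with velocity above `+threshold` seed protruding regions,
#' below `-threshold` retracting regions; contour pixels in between stay
#' unclassified. Each classified seed is extended inward over the pixels
#' within `band` µm of the edge that are nearer (by Euclidean distance) to a
#' seed of that class than to any other classified seed.
#'
#' @param vf an [edge_velocity()] field.
#' @param threshold classification threshold, µm/min (default 0.2).
#' @param band inward extension from the edge, µm (default 10).
#' @return a `region_set` with logical masks `protruding` and `retracting`
#'   (always disjoint).
#' @export
classify_edges <- function(vf, threshold = 0.2, band = 10) {
  stopifnot(inherits(vf, "edge_velocity_field"), threshold > 0)
  v <- vf$v[vf$contour_idx]
  cls <- ifelse(v > threshold, 1L, ifelse(v < -threshold, -1L, 0L))
  mask <- vf$mask
  dedge <- edge_distance(mask, vf$pixel_size)$d
  inband <- mask & is.finite(dedge) & dedge <= band
  prot <- retr <- matrix(FALSE, nrow(mask), ncol(mask))
  seeds <- vf$contour_idx[cls != 0L]
  if (length(seeds) && any(inband)) {
    coords <- cbind((seeds - 1L) %% nrow(mask) + 1L,
                    (seeds - 1L) %/% nrow(mask) + 1L)
    target <- which(inband, arr.ind = TRUE)
    lab <- knn1(coords, target, factor(cls[cls != 0L], levels = c(-1L, 1L)))
    ti <- target[, 1] + (target[, 2] - 1L) * nrow(mask)
    prot[ti[lab == "1"]] <- TRUE
    retr[ti[lab == "-1"]] <- TRUE
  }
  .region_set(list(protruding = prot, retracting = retr))
}

#' Mean lifetime binned by edge distance and edge velocity
#'
#' Every in-mask pixel inherits the velocity of its nearest contour pixel;
#' the photon-weighted mean lifetime is reported per (distance-from-edge,
#' edge-velocity) bin.
#'
#' @param img a [new_lifetime_image()].
#' @param vf an [edge_velocity()] field congruent with the image.
#' @param bin_d distance bin width, µm.
#' @param bin_v velocity bin width, µm/min.
#' @param range_d,range_v optional ranges.
#' @return as [hist2d_mean()]: matrices indexed (distance bin, velocity bin).
#' @export
velocity_binned_lifetime <- function(img, vf, bin_d = 1, bin_v = 0.2,
                                     range_d = NULL, range_v = NULL) {
  stopifnot(inherits(img, "lifetime_image"),
            inherits(vf, "edge_velocity_field"))
  mask <- vf$mask
  nr <- nrow(mask)
  dedge <- edge_distance(mask, vf$pixel_size)$d
  coords <- cbind((vf$contour_idx - 1L) %% nr + 1L,
                  (vf$contour_idx - 1L) %/% nr + 1L)
  target <- which(mask, arr.ind = TRUE)
  nn <- as.integer(knn1(coords, target, factor(seq_along(vf$contour_idx))))
  vmap <- matrix(NA_real_, nr, ncol(mask))
  vmap[mask] <- vf$v[vf$contour_idx][nn]
  hist2d_mean(img, dedge, vmap, binA = bin_d, binB = bin_v,
              rangeA = range_d, rangeB = range_v)
}

#' Spreading speed of a supported lipid bilayer
#'
#' Net area increase between frames `i` and `i+1` divided by the frame
#' interval and the crop width.
#'
#' @param movie a [mask_movie()] of the rectangular SLB crop.
#' @param crop_width crop width perpendicular to the advance, µm.
#' @param i frame index.
#' @return speed, µm/min (negative for a shrinking film).
#' @export
slb_speed <- function(movie, crop_width, i = 1) {
  stopifnot(inherits(movie, "mask_movie"), crop_width > 0,
            i + 1 <= movie$n_frames)
  dA <- (sum(movie$masks[[i + 1]]) - sum(movie$masks[[i]])) *
    movie$pixel_size^2
  dA / (movie$dt * crop_width)
}

#' Per-frame spreading speed and lifetime-gradient slope of an SLB
#'
#' For each frame pair the spreading speed ([slb_speed()]) is paired with a
#' linear fit of the lifetime against the distance from the advancing front
#' (the rightmost occupied column of the crop), restricted to the `window` µm
#' closest to the front.
#'
#' @param movie a [mask_movie()].
#' @param tau_frames list of lifetime matrices (ns) or
#'   [new_lifetime_image()]s, one per frame.
#' @param photon_frames optional list of photon-count matrices (defaults to
#'   uniform weights for bare matrices).
#' @param crop_width crop width, µm.
#' @param window analysis window from the advancing edge, µm (default 100).
#' @param bin profile bin width, µm.
#' @return data.frame with `frame`, `time`, `speed` (µm/min), `slope`
#'   (ns/µm, sign as fitted vs distance-from-front), `slope_se`, `r2`.
#' @export
speed_slope_curve <- function(movie, tau_frames, photon_frames = NULL,
                              crop_width, window = 100, bin = 1) {
  stopifnot(inherits(movie, "mask_movie"),
            length(tau_frames) >= movie$n_frames)
  px <- movie$pixel_size
  out <- data.frame(frame = integer(), time = numeric(), speed = numeric(),
                    slope = numeric(), slope_se = numeric(), r2 = numeric())
  for (i in seq_len(movie$n_frames - 1)) {
    sp <- slb_speed(movie, crop_width, i)
    m <- movie$masks[[i]]
    tf <- tau_frames[[i]]
    if (inherits(tf, "lifetime_image")) {
      tau <- tf$tau; ph <- tf$photons
    } else {
      tau <- tf
      ph <- if (is.null(photon_frames)) matrix(1, nrow(tau), ncol(tau))
            else photon_frames[[i]]
    }
    front_col <- max(which(colSums(m) > 0))
    dfront <- (front_col - col(m)) * px  # distance from the advancing front
    dfront[!m] <- NA_real_
    img <- new_lifetime_image(ifelse(m, tau, NA_real_), ph, px)
    prof <- decay_profile(img, dfront, bin = bin, range = c(0, window))
    fit <- fit_slope(prof)
    out <- rbind(out, data.frame(frame = i, time = (i - 1) * movie$dt,
                                 speed = sp, slope = fit$slope,
                                 slope_se = fit$slope_se, r2 = fit$r2))
  }
  out
}

#' Directionality ratio of a migration track
#'
#' Net displacement divided by total path length; 1 for a straight path,
#' 0 for a closed loop.
#'
#' @param track matrix or data.frame with columns `x`, `y` (µm), time-ordered.
#' @return dimensionless ratio in `[0, 1]`.
#' @export
directionality_ratio <- function(track) {
  xy <- as.matrix(track[, c("x", "y")])
  stopifnot(nrow(xy) >= 2)
  seg <- sqrt(rowSums(diff(xy)^2))
  path <- sum(seg)
  if (path <= 0) stop("zero path length")
  disp <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  disp / path
}

#' Aspect ratio of a binary mask
#'
#' Major/minor axis ratio of the second-moment-equivalent ellipse of the
#' mask pixels (always >= 1).
#'
#' @param mask logical matrix.
#' @return dimensionless aspect ratio.
#' @export
aspect_ratio <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("mask too small")
  cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  if (eigen(cv, symmetric = TRUE, only.values = TRUE)$values[2] <= 1e-9)
    stop("degenerate (collinear) mask")
  # + 1/12: second moment of the unit pixel footprint
  ev <- eigen(cv + diag(2) / 12, symmetric = TRUE, only.values = TRUE)$values
  sqrt(ev[1] / ev[2])
}
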