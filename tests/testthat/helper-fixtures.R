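# Shared fixtures: small synthetic inputs built in code.

# flat rectangular scene spanning a lifetime ramp across the occupied half
# (uses the "slb" half-plane shape so tiny images stay non-empty)
ramp_scene <- function(nr, nc, tau_lo, tau_hi, mean_photons, seed = 1) {
  spec <- scene_spec("slb", image_size = c(nr, nc), baseline_tau = (tau_lo + tau_hi) / 2,
                     mean_photons = mean_photons, seed = seed)
  inside_cols <- floor(nc / 2)
  width_um <- inside_cols * spec$pixel_size
  spec$linear_slope <- if (tau_hi > tau_lo)
    (tau_hi - tau_lo) / max(width_um - spec$pixel_size, spec$pixel_size) else 0
  make_scene(spec)
}

disc_mask <- function(n, r, center = (n + 1) / 2) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - center)^2 + (col(m) - center)^2 <= r^2] <- TRUE
  m
}

# lifetime image with given tau field and uniform photon counts
uniform_img <- function(tau, photons = 30, pixel_size = 0.25) {
  new_lifetime_image(tau, matrix(photons, nrow(tau), ncol(tau)), pixel_size)
}

# brute-force signed distance to the 4-connected boundary pixel set
brute_signed_distance <- function(mask, pixel_size = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  b <- which(mask & !inner, arr.ind = TRUE)
  d <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d[i, j] <- sqrt(min((b[, 1] - i)^2 + (b[, 2] - j)^2))
    if (mask[i, j]) d[i, j] <- -d[i, j]
  }
  d * pixel_size
}
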