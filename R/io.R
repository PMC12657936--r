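# File I/O: 2-channel lifetime TIFFs, masks, kymographs, traces, peak tables.

#' Write a lifetime image as a 2-channel TIFF plus JSON metadata
#'
#' Channel 1 holds the lifetime in ns (invalid pixels as 0 with a companion
#' validity flag in the metadata convention: photons = 0), channel 2 the
#' photon counts, emulating the confocal FLIM export of one lifetime and one
#' photon-count channel per image.
#'
#' @param img a [new_lifetime_image()].
#' @param path output TIFF path; metadata is written to `<path>.json`.
#' @export
write_lifetime_tiff <- function(img, path) {
  stopifnot(inherits(img, "lifetime_image"))
  tau <- img$tau
  tau[!is.finite(tau)] <- 0
  sc <- max(tau, max(img$photons), 1)
  tiff::writeTIFF(list(tau / sc, img$photons / sc), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = sc, pixel_size = img$pixel_size, plane = img$plane,
         estimator = img$estimator, units = c("ns", "photons")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 2-channel lifetime TIFF written by [write_lifetime_tiff()]
#'
#' @param path TIFF path with a `<path>.json` metadata sidecar.
#' @return a [new_lifetime_image()]; pixels with zero photons are invalid.
#' @export
read_lifetime_tiff <- function(path) {
  ch <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tau <- ch[[1]] * meta$scale
  photons <- round(ch[[2]] * meta$scale)
  tau[photons <= 0] <- NA_real_
  new_lifetime_image(tau, photons, meta$pixel_size, plane = meta$plane,
                     estimator = meta$estimator)
}

#' Write a binary mask as a TIFF
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask > 0), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask TIFF (any nonzero pixel is inside)
#' @param path TIFF path.
#' @return logical matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0
}

#' Write a kymograph as CSV (lines as rows)
#' @param k a [kymograph()].
#' @param path output CSV path.
#' @export
write_kymograph_csv <- function(k, path) {
  stopifnot(inherits(k, "kymograph"))
  write.csv(k$intensity, path, row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size = k$pixel_size, line_time = k$line_time, dwell = k$dwell),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph CSV written by [write_kymograph_csv()]
#' @param path CSV path with a `<path>.json` metadata sidecar.
#' @return a [kymograph()].
#' @export
read_kymograph_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  kymograph(as.matrix(read.csv(path, check.names = FALSE)),
            pixel_size = meta$pixel_size, line_time = meta$line_time,
            dwell = meta$dwell)
}

#' Read a peak-to-species table from CSV
#'
#' Expects columns `channel`, `mz`, `species`.
#'
#' @param path CSV path.
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  peak_table(d$channel, d$mz, d$species)
}
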