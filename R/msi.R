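# MALDI mass-spectrometry-imaging channel stacks to lipid-fraction maps.

#' Peak-to-species assignment table
#'
#' @param channel integer channel indices into the MSI stack (unique).
#' @param mz m/z value per channel.
#' @param species species label per channel; `"unknown"` marks unassigned
#'   peaks, which are excluded from all fraction calculations.
#' @return an object of class `peak_table` (a data.frame).
#' @export
peak_table <- function(channel, mz, species) {
  stopifnot(!anyDuplicated(channel), length(mz) == length(channel),
            length(species) == length(channel))
  if (!any(species != "unknown")) stop("need at least one known species")
  structure(data.frame(channel = as.integer(channel), mz = mz,
                       species = as.character(species)),
            class = c("peak_table", "data.frame"))
}

#' Per-species lipid fraction maps from an MSI channel stack
#'
#' Per pixel, each species' fraction is the summed intensity of its assigned
#' peaks over the total intensity of all known peaks; unknown channels are
#' excluded entirely, and species assigned several peaks have their relative
#' abundances added. Pixels with zero total known intensity are invalid (not
#' zero) so that off-cell background cannot dilute pooled statistics.
#'
#' @param stack array `(rows, cols, channels)`.
#' @param peaks a [peak_table()] whose channel count matches the stack.
#' @param pixel_size µm/pixel (default 0.5), carried as metadata.
#' @return an object of class `fraction_map`: named list `fractions` of
#'   per-species matrices (fractions in `[0,1]`, `NA` on invalid pixels),
#'   logical `valid`, and `pixel_size`.
#' @export
lipid_fractions <- function(stack, peaks, pixel_size = 0.5) {
  stopifnot(length(dim(stack)) == 3, inherits(peaks, "peak_table"))
  if (max(peaks$channel) > dim(stack)[3])
    stop("peak table channel exceeds stack channel count")
  known <- peaks[peaks$species != "unknown", ]
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  chan <- function(ch) matrix(stack[, , ch], nr, nc)
  tot <- Reduce(`+`, lapply(known$channel, chan))
  valid <- tot > 0
  sp <- split(known$channel, known$species)
  fractions <- lapply(sp, function(chs) {
    f <- Reduce(`+`, lapply(chs, chan)) / tot
    f[!valid] <- NA_real_
    f
  })
  structure(list(fractions = fractions, valid = valid,
                 pixel_size = pixel_size), class = "fraction_map")
}

#' Pooled z-score normalization of lipid fractions across cells
#'
#' For each species, the fractions of all valid pixels of all cells are
#' pooled; each pixel is then expressed in standard deviations from the
#' pooled mean, making spatial heterogeneity comparable across species of
#' very different absolute abundance.
#'
#' @param maps list of [lipid_fractions()] results (one per cell).
#' @param species character vector of species to normalize (default: all
#'   species of the first map).
#' @return list of cells, each a named list of z-score matrices; pooled
#'   means/SDs in `attr(, "pooled")`.
#' @export
zscore_fractions <- function(maps, species = NULL) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, logical(1), "fraction_map")))
  species <- species %||% names(maps[[1]]$fractions)
  pooled <- lapply(setNames(species, species), function(s) {
    v <- unlist(lapply(maps, function(m) {
      f <- m$fractions[[s]]
      f[is.finite(f)]
    }))
    mu <- mean(v); sdv <- sd(v)
    if (!is.finite(sdv) || sdv == 0)
      stop("species '", s, "' has zero pooled SD (uninformative)")
    list(mean = mu, sd = sdv, n = length(v))
  })
  out <- lapply(maps, function(m) {
    lapply(setNames(species, species), function(s) {
      (m$fractions[[s]] - pooled[[s]]$mean) / pooled[[s]]$sd
    })
  })
  attr(out, "pooled") <- pooled
  out
}

#' Cross-cell average map of z-scored lipid fractions
#'
#' Aligns cells by their micropattern masks (same transform for every species
#' of a cell, found once from the pattern) and averages the z-score maps
#' pixel-wise (unweighted), per species.
#'
#' @param zmaps a [zscore_fractions()] result.
#' @param pattern_masks list of logical pattern masks, one per cell.
#' @param template_mask logical template pattern mask.
#' @param fold discrete rotational symmetry of the template (1, 2 or 4).
#' @param overlap_floor minimum Jaccard overlap to keep a cell.
#' @return named list per species, each as [align_and_average()]'s result.
#' @export
msi_average_map <- function(zmaps, pattern_masks, template_mask, fold = 4,
                            overlap_floor = 0.5) {
  species <- names(zmaps[[1]])
  lapply(setNames(species, species), function(s) {
    align_and_average(lapply(zmaps, `[[`, s), pattern_masks, template_mask,
                      fold = fold, overlap_floor = overlap_floor)
  })
}
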