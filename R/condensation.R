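# Sister-chromatid condensation assay.
#
# Condensation concentrates a fixed amount of histone fluorescence into a
# smaller area, reshaping the pixel intensity distribution. After per-cell
# rescaling to the full 16-bit range, the fraction of pixels below 35% of
# the maximum (the condensation parameter) tracks how condensed a channel
# is, and the ratio of new-histone-occupied to old-histone-occupied area
# (the compaction factor) compares the two channels.

#' Rescale an image to the full 16-bit range
#'
#' Per-cell min/max normalization: the minimum maps to 0 and the maximum to
#' 65535, making downstream thresholds invariant to illumination, sample
#' and photobleaching differences. Values are rounded half away from zero.
#' A constant image maps to all zeros and is flagged degenerate.
#'
#' @param image Numeric matrix.
#' @return An object of class `scaled_image`: fields `values` (integer matrix
#'   on `[0, 65535]`), `original_min`, `original_max`, `degenerate`.
#' @export
rescale_16bit <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    return(structure(list(values = matrix(0L, nrow(image), ncol(image)),
                          original_min = lo, original_max = hi,
                          degenerate = TRUE),
                     class = "scaled_image"))
  }
  v <- (image - lo) / (hi - lo) * 65535
  v <- sign(v) * floor(abs(v) + 0.5) # round half away from zero
  structure(list(values = matrix(as.integer(v), nrow(image), ncol(image)),
                 original_min = lo, original_max = hi, degenerate = FALSE),
            class = "scaled_image")
}

#' Condensation threshold as a fraction of the maximum scaled intensity
#'
#' `floor(fraction * image_max)`; with the defaults (35% of the 16-bit
#' ceiling) this gives the scaled-intensity threshold 22937.
#'
#' @param fraction Fraction of the maximum, in (0, 1). Default 0.35.
#' @param image_max Maximum of the intensity scale. Default 65535.
#' @return Integer threshold in scaled counts.
#' @export
condensation_threshold <- function(fraction = 0.35, image_max = 65535L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  as.integer(floor(fraction * image_max))
}

#' Condensation parameter: percentage of pixels below threshold
#'
#' @param scaled A [rescale_16bit()] result (or an integer matrix already on
#'   the scaled range).
#' @param mask Logical matrix restricting the analysis region; `NULL` uses
#'   all pixels.
#' @param threshold Scaled-intensity threshold (strictly-below counting).
#' @return Percentage in `[0, 100]`.
#' @export
condensation_parameter <- function(scaled, mask = NULL,
                                   threshold = condensation_threshold()) {
  v <- if (inherits(scaled, "scaled_image")) scaled$values else scaled
  if (any(v < 0 | v > 65535)) stop("scaled image outside the 16-bit range")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(v), ncol(v))
  if (!any(mask)) stop("mask is empty")
  px <- v[mask]
  100 * sum(px < threshold) / length(px)
}

#' Compaction factor between old- and new-histone channels
#'
#' Each channel is rescaled independently; "occupied" pixels are those at or
#' above the threshold (the exact complement of the below-threshold set that
#' defines the condensation parameter). The compaction factor is
#' `occupied_new / occupied_old`: values above 1 mean the old-histone signal
#' is concentrated into a smaller area, i.e. more condensed.
#'
#' @param old_image,new_image Numeric matrices of the old- and new-histone
#'   channels over the same analysis window.
#' @param mask Optional logical matrix restricting the region.
#' @param threshold_frac Threshold fraction of the maximum (default 0.35).
#' @return An object of class `condensation_result` with per-channel
#'   condensation parameters and occupied areas, the threshold used,
#'   `compaction_factor` and `log2_compaction_factor`.
#' @export
compaction_factor <- function(old_image, new_image, mask = NULL,
                              threshold_frac = 0.35) {
  stopifnot(identical(dim(old_image), dim(new_image)))
  thr <- condensation_threshold(threshold_frac, 65535L)
  old_s <- rescale_16bit(old_image)
  new_s <- rescale_16bit(new_image)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(old_image), ncol(old_image))
  if (!any(mask)) stop("mask is empty")
  occ <- function(s) sum(s$values[mask] >= thr)
  occupied_old <- occ(old_s); occupied_new <- occ(new_s)
  if (occupied_old == 0L)
    stop("undefined compaction factor: no old-channel pixels at/above threshold")
  cf <- occupied_new / occupied_old
  structure(list(
    threshold = thr,
    condensation_old = condensation_parameter(old_s, mask, thr),
    condensation_new = condensation_parameter(new_s, mask, thr),
    occupied_old = occupied_old, occupied_new = occupied_new,
    n_pixels = sum(mask),
    compaction_factor = cf, log2_compaction_factor = log2(cf),
    degenerate = old_s$degenerate || new_s$degenerate),
    class = "condensation_result")
}

#' @export
print.condensation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "condensation: threshold %d; parameter old %.2f%% / new %.2f%%; ",
    "occupied old %d / new %d px; compaction factor %.3f (log2 %.3f)\n"),
    x$threshold, x$condensation_old, x$condensation_new,
    x$occupied_old, x$occupied_new, x$compaction_factor,
    x$log2_compaction_factor))
  invisible(x)
}

#' Full per-cell condensation pipeline
#'
#' Maximum-intensity projects the old and new channels, crops the largest
#' axis-aligned square inscribed in the nucleus mask, rescales each channel
#' to the 16-bit range, thresholds at `threshold_frac` of the maximum, and
#' returns the condensation parameters plus the compaction factor.
#'
#' @param stack An [image_stack()] with both histone channels.
#' @param nucleus_mask Logical matrix (projection-plane nucleus region).
#' @param channels Length-2 character vector `(old, new)` naming the
#'   channels.
#' @param threshold_frac Threshold fraction of the maximum (default 0.35).
#' @return A `condensation_result` with the crop window attached as
#'   attribute `window`.
#' @export
analyze_condensation <- function(stack, nucleus_mask, channels = c("old", "new"),
                                 threshold_frac = 0.35) {
  stopifnot(length(channels) == 2L)
  proj_old <- max_projection(stack, channels[1])
  proj_new <- max_projection(stack, channels[2])
  if (!identical(dim(nucleus_mask), dim(proj_old)))
    stop("nucleus mask shape does not match the projection plane")
  sq <- largest_inscribed_square(nucleus_mask)
  rows <- sq$top:(sq$top + sq$side - 1L)
  cols <- sq$left:(sq$left + sq$side - 1L)
  res <- compaction_factor(proj_old[rows, cols], proj_new[rows, cols],
                           threshold_frac = threshold_frac)
  attr(res, "window") <- sq
  res
}
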