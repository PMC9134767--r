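# Chromatin-bound fraction, colocalization, nuclear-size proxies and
# replication-timing ratios.

#' Chromatin-bound versus chromatin-excluded signal ratio
#'
#' For a licensing factor such as Cdc6 on a single slice: the amount bound to
#' chromatin is the chromatin area times the mean intensity in the chromatin
#' region; the excluded amount is the whole-cell area-times-mean minus the
#' bound amount; the bound ratio divides the two. When a 3D array is given,
#' the slice with the largest chromatin cross-section is selected (ties ->
#' lowest z), following the "largest volume of the chromatin region" rule.
#'
#' @param image 2D matrix or 3D `(z, y, x)` array of the factor's channel.
#' @param chromatin_mask,cell_mask Logical matrices; chromatin must be a
#'   strict subset of the cell. For 3D input, `chromatin_mask` may be a
#'   logical `(z, y, x)` array used for slice selection.
#' @param background Scalar background level subtracted from every pixel
#'   before the area-times-mean products; 0 (the default) gives the raw
#'   variant.
#' @return An object of class `chromatin_association` with areas, means,
#'   `amount_bound`, `amount_excluded`, `bound_ratio`, and the `slice` used.
#' @export
chromatin_bound_fraction <- function(image, chromatin_mask, cell_mask,
                                     background = 0) {
  slice_used <- NA_integer_
  if (!is.matrix(image)) {
    stopifnot(length(dim(image)) == 3L)
    if (is.array(chromatin_mask) && length(dim(chromatin_mask)) == 3L) {
      areas <- apply(chromatin_mask, 1, sum)
      slice_used <- which.max(areas) # which.max takes the lowest index on ties
      chromatin_mask <- chromatin_mask[slice_used, , ]
    } else {
      slice_used <- 1L
    }
    image <- image[slice_used, , ]
  }
  image <- image - background
  stopifnot(identical(dim(chromatin_mask), dim(image)),
            identical(dim(cell_mask), dim(image)))
  if (any(chromatin_mask & !cell_mask))
    stop("chromatin mask must lie inside the cell mask")
  a_chr <- sum(chromatin_mask); a_cell <- sum(cell_mask)
  if (a_chr == 0L) stop("empty chromatin mask")
  if (a_cell <= a_chr) stop("cell mask must be strictly larger than chromatin mask")
  m_chr <- mean(image[chromatin_mask])
  m_cell <- mean(image[cell_mask])
  bound <- a_chr * m_chr
  excluded <- a_cell * m_cell - bound
  if (excluded <= 0)
    stop("undefined bound ratio: non-positive chromatin-excluded amount (",
         format(excluded), ")")
  structure(list(chromatin_area = a_chr, chromatin_mean = m_chr,
                 cell_area = a_cell, cell_mean = m_cell,
                 amount_bound = bound, amount_excluded = excluded,
                 bound_ratio = bound / excluded, slice = slice_used),
            class = "chromatin_association")
}

#' @export
print.chromatin_association <- function(x, ...) {
  cat(sprintf(paste0("chromatin association: bound %g (area %d x mean %.3f), ",
                     "excluded %g, ratio %.4f\n"),
              x$amount_bound, x$chromatin_area, x$chromatin_mean,
              x$amount_excluded, x$bound_ratio))
  invisible(x)
}

#' Pixel-level Spearman colocalization over a bounding box
#'
#' Spearman rank correlation of two channels' pixel intensities within a
#' mask, with average ranks for ties. +1 is perfect correlation, 0 no
#' correlation, -1 perfect anti-correlation. A constant channel has no
#' defined ranks: rho is `NA` and the result is flagged.
#'
#' @param channel_a,channel_b 2D matrices of identical shape.
#' @param box_mask Logical matrix selecting the analysis box (>= 3 pixels);
#'   `NULL` uses the full frame.
#' @return An object of class `coloc_result` with `rho`, `n`, `degenerate`.
#' @export
spearman_coloc <- function(channel_a, channel_b, box_mask = NULL) {
  stopifnot(identical(dim(channel_a), dim(channel_b)))
  if (is.null(box_mask)) box_mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  a <- channel_a[box_mask]; b <- channel_b[box_mask]
  if (length(a) < 3L) stop("need at least 3 pixels for colocalization")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(rho = NA_real_, n = length(a), degenerate = TRUE),
                     class = "coloc_result"))
  }
  ra <- rank(a); rb <- rank(b) # average ranks on ties
  rho <- stats::cor(ra, rb)
  structure(list(rho = rho, n = length(a), degenerate = FALSE),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Spearman colocalization: rho = %s over %d px%s\n",
              format(x$rho, digits = 4), x$n,
              if (x$degenerate) " (degenerate: constant channel)" else ""))
  invisible(x)
}

#' Nuclear size: maximum single-slice area
#'
#' @param stack An [image_stack()] (used for the plane shape and slice count).
#' @param nucleus_rois List of per-slice nucleus `roi` objects (each with an
#'   explicit slice) or one roi applied to all slices.
#' @return Maximum rasterized per-slice area in pixels.
#' @export
nuclear_size_single_slice <- function(stack, nucleus_rois) {
  areas <- .roi_slice_areas(stack, nucleus_rois)
  max(areas)
}

#' Nuclear size: summed-slice volume proxy
#'
#' Sum of the per-slice areas multiplied by the z step.
#'
#' @param stack An [image_stack()].
#' @param nucleus_rois As in [nuclear_size_single_slice()].
#' @param z_step z spacing in micrometres; defaults to the stack voxel size.
#' @return Volume proxy (pixel-area times micrometres).
#' @export
nuclear_size_volume <- function(stack, nucleus_rois, z_step = NULL) {
  if (is.null(z_step)) z_step <- stack$voxel_size[1]
  areas <- .roi_slice_areas(stack, nucleus_rois)
  sum(areas) * z_step
}

.roi_slice_areas <- function(stack, nucleus_rois) {
  if (inherits(nucleus_rois, "roi")) nucleus_rois <- list(nucleus_rois)
  if (length(nucleus_rois) == 0L) stop("no nucleus ROI given")
  d <- dim(stack$channels[[1]])
  areas <- numeric(0)
  for (r in nucleus_rois) {
    m <- rasterize_roi(r, d[2:3])
    areas <- c(areas, rep(sum(m), length(.roi_slices(r, d[1]))))
  }
  areas
}

#' Replication-timing log2 ratio between post-mitotic siblings
#'
#' log2 of the stem-cell total over the differentiating-cell total of a
#' replication marker (PCNA or EdU). Reported in log2 so that a negative
#' value means the differentiating daughter carries more marker, i.e. enters
#' S phase first.
#'
#' @param ts_gsc,ts_gb [total_signal()] objects for the GSC and GB nuclei.
#' @param nuclear_size Optional nuclear-size proxy used as the time axis.
#' @param pair_id Optional pair identifier.
#' @return A one-row data.frame with `pair_id`, `nuclear_size`, `channel`,
#'   `log2_ratio`.
#' @export
replication_ratio <- function(ts_gsc, ts_gb, nuclear_size = NA_real_,
                              pair_id = NA_character_) {
  if (ts_gsc$Fs <= 0 || ts_gb$Fs <= 0)
    stop("undefined replication ratio: non-positive total signal; flag the pair")
  data.frame(pair_id = pair_id, nuclear_size = nuclear_size,
             channel = ts_gsc$channel,
             log2_ratio = log2(ts_gsc$Fs / ts_gb$Fs),
             stringsAsFactors = FALSE)
}

#' Order replication-timing entries by nuclear size
#'
#' Nuclear size approximates time after mitosis, so sorting by it yields the
#' S-phase entry time course. Stable on ties; no smoothing.
#'
#' @param entries data.frame of [replication_ratio()] rows.
#' @return The same data.frame sorted ascending by `nuclear_size`.
#' @export
timing_curve <- function(entries) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1L)
  entries[order(entries$nuclear_size), , drop = FALSE]
}
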