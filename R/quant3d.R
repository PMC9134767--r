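# Sum-of-slices total fluorescence quantification.
#
# The total amount of fluorescence in a cell or chromatid mass is measured by
# summing, slice by slice, the raw integrated density of a signal circle and
# subtracting the integrated density of an identically sized background
# circle drawn in a signal-free region:
#
#   Fs = sum_z (Rs_z - Bs_z)
#
# Per-slice differences may be negative (no clamping); a warning is emitted
# if the resulting Fs is non-positive.

#' Raw integrated density of a masked region
#'
#' The plain sum of pixel grey values under a mask ("RawIntDen").
#'
#' @param image A 2D matrix or 3D `(z, y, x)` array.
#' @param mask Logical matrix matching the image plane shape. For 3D input
#'   the same mask is applied to every slice.
#' @return The scalar sum of masked pixel values.
#' @export
raw_sum <- function(image, mask) {
  d <- dim(image)
  if (is.matrix(image)) {
    if (!identical(dim(mask), d)) stop("mask shape does not match image plane")
    if (!any(mask)) stop("mask is empty")
    return(sum(image[mask]))
  }
  if (length(d) != 3L) stop("image must be 2D or 3D")
  if (!identical(dim(mask), d[2:3])) stop("mask shape does not match image plane")
  if (!any(mask)) stop("mask is empty")
  sum(apply(image, 1, function(pl) sum(pl[mask])))
}

#' Background-subtracted total fluorescence over a z-stack
#'
#' Computes the sum-of-slices total signal of `signal_roi` with per-slice
#' subtraction of an identically sized `background_roi`. Both regions must
#' rasterize to the same pixel area per slice within `area_tol` (default 1%),
#' mirroring the "identical circle" background convention; a larger mismatch
#' is an error, never a silent rescale.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param signal_roi,background_roi [roi_circle()]/[roi_polygon()] objects.
#' @param area_tol Maximum relative area mismatch between the two ROIs.
#' @return An object of class `total_signal` with fields `Rs` (per-slice raw
#'   sums), `Bs` (per-slice background sums), `Fs` (total), `slices`, `area`,
#'   `label`, `channel`.
#' @export
total_signal <- function(stack, channel, signal_roi, background_roi,
                         area_tol = 0.01) {
  a <- .stack_channel(stack, channel)
  d <- dim(a)
  m_sig <- rasterize_roi(signal_roi, d[2:3])
  m_bg <- rasterize_roi(background_roi, d[2:3])
  area_sig <- sum(m_sig); area_bg <- sum(m_bg)
  if (abs(area_sig - area_bg) / area_sig > area_tol)
    stop("background ROI area (", area_bg, " px) does not match signal ROI area (",
         area_sig, " px) within ", area_tol * 100, "%")
  z_sig <- .roi_slices(signal_roi, d[1])
  z_bg <- .roi_slices(background_roi, d[1])
  if (!identical(z_sig, z_bg))
    stop("signal and background ROIs must cover the same slices")
  Rs <- vapply(z_sig, function(z) sum(a[z, , ][m_sig]), numeric(1))
  Bs <- vapply(z_sig, function(z) sum(a[z, , ][m_bg]), numeric(1))
  Fs <- sum(Rs - Bs)
  if (Fs <= 0)
    warning("non-positive total signal Fs = ", Fs, " for roi '",
            signal_roi$label, "' (channel ", channel, ")")
  structure(list(Rs = Rs, Bs = Bs, Fs = Fs, slices = z_sig,
                 area = area_sig, label = signal_roi$label, channel = channel),
            class = "total_signal")
}

#' @export
print.total_signal <- function(x, ...) {
  cat(sprintf("total_signal '%s' (%s): Fs = %g over %d slice(s), area %d px\n",
              x$label, x$channel, x$Fs, length(x$slices), x$area))
  invisible(x)
}

#' Directed intensity ratio between two sibling regions
#'
#' The stem-side total divided by the differentiating-side total
#' (GSC/GB, or SG1/SG2 for the symmetric control).
#'
#' @param ts_stem,ts_diff [total_signal()] objects (or anything with an `Fs`
#'   field) for the stem-side and differentiating-side masses.
#' @param stage Optional cell-cycle stage annotation.
#' @return An object of class `sister_ratio` with `ratio`, `log2_ratio`,
#'   `numerator`, `denominator`, `channel`, `stage`.
#' @export
sister_ratio <- function(ts_stem, ts_diff, stage = NA_character_) {
  if (ts_stem$Fs <= 0 || ts_diff$Fs <= 0)
    stop("undefined sister ratio: non-positive total signal (stem Fs = ",
         ts_stem$Fs, ", diff Fs = ", ts_diff$Fs, "); flag the pair, do not drop it")
  ratio <- ts_stem$Fs / ts_diff$Fs
  structure(list(ratio = ratio, log2_ratio = log2(ratio),
                 numerator = ts_stem$label, denominator = ts_diff$label,
                 channel = ts_stem$channel, stage = stage),
            class = "sister_ratio")
}

#' @export
print.sister_ratio <- function(x, ...) {
  cat(sprintf("sister_ratio %s/%s (%s): %.4f (log2 = %.4f)\n",
              x$numerator, x$denominator, x$channel, x$ratio, x$log2_ratio))
  invisible(x)
}

#' Nucleosome density ratio between sibling chromatid masses
#'
#' Nucleosome density is half the total core-histone amount per unit DNA.
#' Between sister chromatid masses the halving factor and the DNA length
#' cancel, so the density ratio equals the total-histone sister ratio; this
#' function records the derivation explicitly.
#'
#' @param sr A [sister_ratio()] measured on a core-histone channel.
#' @return The dimensionless density ratio, with a `derivation` attribute.
#' @export
nucleosome_density_ratio <- function(sr) {
  stopifnot(inherits(sr, "sister_ratio"))
  structure(sr$ratio,
            derivation = paste0(
              "(0.5 * histone_stem / DNA) / (0.5 * histone_diff / DNA) = ",
              "histone_stem / histone_diff; 0.5 and DNA length cancel"))
}

#' Classify a sister ratio as asymmetric or symmetric
#'
#' The symmetric range is derived from ratios measured in symmetrically
#' dividing control cells: a ratio strictly above (control mean + control SE)
#' is called "asymmetric", otherwise "symmetric". SE is the sample (n-1)
#' standard deviation divided by sqrt(n).
#'
#' @param ratio The dimensionless ratio to classify (raw, not log2).
#' @param control_ratios Numeric vector of >= 2 control ratios. Either this
#'   or `control_summary` must be given.
#' @param control_summary Optional `c(mean, SE)` overriding `control_ratios`.
#' @return An object of class `asymmetry_call` with `threshold`,
#'   `control_mean`, `control_se`, `ratio`, `call`.
#' @export
classify_asymmetry <- function(ratio, control_ratios = NULL, control_summary = NULL) {
  if (is.null(control_summary)) {
    if (is.null(control_ratios) || length(control_ratios) < 2L)
      stop("need >= 2 control ratios (SE requires n >= 2), or an explicit ",
           "control_summary = c(mean, SE)")
    m <- mean(control_ratios)
    se <- stats::sd(control_ratios) / sqrt(length(control_ratios))
  } else {
    stopifnot(length(control_summary) == 2L)
    m <- control_summary[[1]]; se <- control_summary[[2]]
  }
  threshold <- m + se
  structure(list(threshold = threshold, control_mean = m, control_se = se,
                 ratio = ratio,
                 call = if (ratio > threshold) "asymmetric" else "symmetric"),
            class = "asymmetry_call")
}

#' @export
print.asymmetry_call <- function(x, ...) {
  cat(sprintf("ratio %.4f vs threshold %.4f (mean %.4f + SE %.4f): %s\n",
              x$ratio, x$threshold, x$control_mean, x$control_se, x$call))
  invisible(x)
}
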