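# Chromatin-fiber sister-strand quantification.
#
# Replicated chromatin fibers show two parallel sister strands; the lagging
# strand is identified by enriched PCNA. Fibers are measured in consecutive
# 2 um segments; each segment's statistic is
#   log2( (leading mean - background mean) / (lagging mean - background mean) )

#' Partition a fiber axis into fixed-length arc segments
#'
#' The axis is a polyline in pixel coordinates; consecutive non-overlapping
#' spans of exactly `segment_length` micrometres are laid out along its arc
#' length and the trailing remainder is dropped.
#'
#' @param fiber_axis Two-column matrix of `(y, x)` polyline vertices (pixels).
#' @param pixel_size Micrometres per pixel.
#' @param segment_length Segment length in micrometres (default 2).
#' @return A data.frame with one row per segment: `segment`, `s_start`,
#'   `s_end` (arc positions, um) and interpolated endpoint coordinates
#'   `y_start, x_start, y_end, x_end` (pixels).
#' @export
segment_fiber <- function(fiber_axis, pixel_size, segment_length = 2.0) {
  stopifnot(is.matrix(fiber_axis), ncol(fiber_axis) == 2L,
            nrow(fiber_axis) >= 2L, pixel_size > 0, segment_length > 0)
  seg_d <- sqrt(diff(fiber_axis[, 1])^2 + diff(fiber_axis[, 2])^2) * pixel_size
  cum <- c(0, cumsum(seg_d))
  total <- cum[length(cum)]
  n_seg <- floor(total / segment_length + 1e-12)
  if (n_seg < 1L)
    stop("fiber is shorter (", format(total), " um) than one segment (",
         segment_length, " um)")
  point_at <- function(s) {
    # arc-length parameterized point on the polyline
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(seg_d))
    t <- if (seg_d[i] == 0) 0 else (s - cum[i]) / seg_d[i]
    fiber_axis[i, ] + t * (fiber_axis[i + 1L, ] - fiber_axis[i, ])
  }
  out <- lapply(seq_len(n_seg), function(k) {
    s0 <- (k - 1) * segment_length; s1 <- k * segment_length
    p0 <- point_at(s0); p1 <- point_at(min(s1, total))
    data.frame(segment = k, s_start = s0, s_end = s1,
               y_start = p0[1], x_start = p0[2], y_end = p1[1], x_end = p1[2])
  })
  do.call(rbind, out)
}

#' Assign leading and lagging strands by PCNA enrichment
#'
#' The lagging strand is the one with the higher background-subtracted mean
#' PCNA intensity. Exactly equal PCNA means are ambiguous: the segment is
#' flagged and must be excluded, never guessed.
#'
#' @param strand_mask_a,strand_mask_b Disjoint logical masks for the two
#'   strands within the segment.
#' @param pcna_image 2D PCNA-channel matrix.
#' @param background_mask Logical mask of an off-fiber background region;
#'   `NULL` for zero background.
#' @return A list with `leading` and `lagging` masks, the two PCNA means,
#'   and `ambiguous` (logical).
#' @export
assign_strands <- function(strand_mask_a, strand_mask_b, pcna_image,
                           background_mask = NULL) {
  if (any(strand_mask_a & strand_mask_b))
    stop("strand masks must be disjoint")
  if (!any(strand_mask_a) || !any(strand_mask_b)) stop("empty strand mask")
  bg <- if (is.null(background_mask)) 0 else mean(pcna_image[background_mask])
  pa <- mean(pcna_image[strand_mask_a]) - bg
  pb <- mean(pcna_image[strand_mask_b]) - bg
  if (pa == pb) {
    return(list(leading = NULL, lagging = NULL, pcna_leading = pa,
                pcna_lagging = pb, ambiguous = TRUE))
  }
  if (pb > pa)
    list(leading = strand_mask_a, lagging = strand_mask_b,
         pcna_leading = pa, pcna_lagging = pb, ambiguous = FALSE)
  else
    list(leading = strand_mask_b, lagging = strand_mask_a,
         pcna_leading = pb, pcna_lagging = pa, ambiguous = FALSE)
}

#' Background-subtracted log2 leading/lagging intensity ratio
#'
#' @param assignment Result of [assign_strands()].
#' @param histone_image 2D histone-channel matrix.
#' @param background_mask Logical mask of an off-fiber background region.
#' @return A list with `log2_ratio`, the strand and background means, and
#'   `valid` (FALSE when the assignment was ambiguous or a subtracted mean is
#'   non-positive, in which case `log2_ratio` is `NA`).
#' @export
fiber_log2_ratio <- function(assignment, histone_image, background_mask) {
  bg <- mean(histone_image[background_mask])
  if (isTRUE(assignment$ambiguous))
    return(list(log2_ratio = NA_real_, leading_mean = NA_real_,
                lagging_mean = NA_real_, background_mean = bg,
                valid = FALSE, reason = "ambiguous PCNA assignment"))
  lead <- mean(histone_image[assignment$leading])
  lag <- mean(histone_image[assignment$lagging])
  if (lead - bg <= 0 || lag - bg <= 0)
    return(list(log2_ratio = NA_real_, leading_mean = lead, lagging_mean = lag,
                background_mean = bg, valid = FALSE,
                reason = "non-positive background-subtracted intensity"))
  list(log2_ratio = log2((lead - bg) / (lag - bg)),
       leading_mean = lead, lagging_mean = lag, background_mean = bg,
       valid = TRUE, reason = NA_character_)
}

#' Summarize fiber-segment log2 ratios
#'
#' Mean +/- SE of the valid per-segment log2 ratios, with a one-sample t test
#' against the symmetric null log2 = 0. Invalid segments are counted in a QC
#' field, not imputed.
#'
#' @param log2_ratios Numeric vector of per-segment log2 ratios (`NA` =
#'   excluded segment).
#' @return A list with `n`, `mean`, `se` (`NA` and flagged at n = 1), the t
#'   statistic, `df`, `p_value`, and `n_excluded`.
#' @export
summarize_fibers <- function(log2_ratios) {
  valid <- log2_ratios[!is.na(log2_ratios)]
  n <- length(valid)
  if (n == 0L) stop("no valid fiber segments to summarize")
  m <- mean(valid)
  if (n == 1L) {
    return(list(n = 1L, mean = m, se = NA_real_, t = NA_real_, df = 0L,
                p_value = NA_real_, n_excluded = sum(is.na(log2_ratios)),
                note = "SE undefined at n = 1"))
  }
  se <- stats::sd(valid) / sqrt(n)
  if (se == 0) {
    return(list(n = n, mean = m, se = 0, t = NA_real_, df = n - 1L,
                p_value = NA_real_, n_excluded = sum(is.na(log2_ratios)),
                note = "degenerate: zero variance, t test undefined"))
  }
  tt <- one_sample_t(valid, null_value = 0)
  list(n = n, mean = m, se = se, t = tt$t, df = tt$df, p_value = tt$p_value,
       n_excluded = sum(is.na(log2_ratios)), note = NA_character_)
}
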