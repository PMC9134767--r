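# Synthetic microscopy generators with known ground truth.
#
# Every generator draws images whose *expected* (noiseless) downstream
# statistic equals a closed-form function of the generative parameters, so
# the whole quantification pipeline can be exercised by parameter recovery
# with no external data. Noise model: counts ~ Poisson(expected) plus
# Gaussian read noise, rounded and clipped to the bit-depth range. With
# noise disabled the images carry the real-valued expectations themselves,
# making noiseless checks exact to floating tolerance.

# run code with a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# counter-based substream: adding a channel never perturbs the others
.substream <- function(seed, k) {
  # modulo in double precision first: the intermediate product can exceed
  # .Machine$integer.max but stays well below 2^53
  as.integer(((as.numeric(seed) %% 2147483647) * 31 + k * 1000003) %% 2147483647)
}

.apply_noise <- function(expected, poisson, read_sd, seed, ceiling_v = 65535) {
  if (!poisson && read_sd == 0) return(expected)
  .with_seed(seed, {
    v <- if (poisson) stats::rpois(length(expected), lambda = expected)
         else as.numeric(expected)
    if (read_sd > 0) v <- v + stats::rnorm(length(v), 0, read_sd)
    v <- round(pmin(pmax(v, 0), ceiling_v))
    array(v, dim = dim(expected))
  })
}

.circle_dist2 <- function(nr, nc, cy, cx) {
  yy <- matrix(seq_len(nr) - 0.5, nr, nc)
  xx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  (yy - cy)^2 + (xx - cx)^2
}

#' Specification of a synthetic telophase sister-chromatid pair
#'
#' Two ellipsoidal Gaussian-profile chromatid masses in a z-stack whose
#' background-subtracted totals stand in a controllable ratio (stem side /
#' differentiating side, ~1.3-1.5 at the scale seen in germline stem cells),
#' over a uniform per-slice background with Poisson photon noise and
#' Gaussian read noise.
#'
#' @param true_ratio Stem-side total / differentiating-side total, > 0.
#' @param base_intensity Peak in-focus signal of the stem mass (counts).
#' @param shape Stack shape `(z, y, x)`.
#' @param mass_radius In-plane mass/ROI radius (pixels); signal is truncated
#'   at this radius so the ROI captures the mass total exactly.
#' @param centers 2x2 matrix of `(y, x)` mass centers (rows: stem, diff).
#' @param background_center Background-patch circle center `(y, x)`.
#' @param background Uniform background level (counts).
#' @param read_noise_sd Gaussian read noise SD (counts); 0 disables.
#' @param poisson Apply Poisson noise to the expected counts?
#' @param channel Channel name.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(true_ratio = 1.5, base_intensity = 400,
                      shape = c(8L, 96L, 96L), mass_radius = 12,
                      centers = rbind(stem = c(48, 30), diff = c(48, 66)),
                      background_center = c(14, 48),
                      background = 100, read_noise_sd = 3,
                      poisson = TRUE, channel = "histone") {
  if (true_ratio <= 0) stop("true_ratio must be > 0")
  if (background < 0) stop("background must be >= 0")
  if (read_noise_sd < 0) stop("read noise SD must be >= 0")
  d_bg <- sqrt(rowSums((centers - matrix(background_center, 2, 2, byrow = TRUE))^2))
  if (any(d_bg < 2 * mass_radius))
    stop("background patch overlaps a chromatid mass; move background_center")
  structure(list(true_ratio = true_ratio, base_intensity = base_intensity,
                 shape = as.integer(shape), mass_radius = mass_radius,
                 centers = centers, background_center = background_center,
                 background = background, read_noise_sd = read_noise_sd,
                 poisson = poisson, channel = channel),
            class = "pair_spec")
}

#' Generate a synthetic GSC-GB telophase pair
#'
#' @param spec A [pair_spec()].
#' @param seed Integer seed; identical (spec, seed) give identical output.
#' @return A list with `stack` ([image_stack()]), `rois` (stem, diff and
#'   background circles), `annotations` (two [cell_annotation()]s), and
#'   `ground_truth` (all generative parameters plus the expected mass totals
#'   and expected ratio).
#' @export
generate_pair <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pair_spec"))
  nz <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  sigma <- spec$mass_radius / 2
  z_prof <- exp(-((seq_len(nz) - (nz + 1) / 2)^2) / (2 * (nz / 4)^2))
  profile_of <- function(center) {
    d2 <- .circle_dist2(nr, nc, center[1], center[2])
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > spec$mass_radius^2] <- 0 # truncate at the ROI radius
    g
  }
  p_stem <- profile_of(spec$centers[1, ])
  p_diff <- profile_of(spec$centers[2, ])
  unit_stem <- sum(p_stem) * sum(z_prof)
  unit_diff <- sum(p_diff) * sum(z_prof)
  amp_stem <- spec$base_intensity
  amp_diff <- amp_stem * unit_stem / (unit_diff * spec$true_ratio)
  expected <- array(0, dim = c(nz, nr, nc))
  for (z in seq_len(nz))
    expected[z, , ] <- spec$background +
      z_prof[z] * (amp_stem * p_stem + amp_diff * p_diff)
  values <- .apply_noise(expected, spec$poisson, spec$read_noise_sd,
                         .substream(seed, 1L))
  stack <- image_stack(stats::setNames(list(values), spec$channel),
                       voxel_size = c(0.5, 0.1, 0.1), bit_depth = 16L,
                       metadata = list(generator = "generate_pair", seed = seed))
  rois <- list(
    stem = roi_circle("GSC", spec$centers[1, 1], spec$centers[1, 2],
                      spec$mass_radius, pair_id = "pair1"),
    diff = roi_circle("GB", spec$centers[2, 1], spec$centers[2, 2],
                      spec$mass_radius, pair_id = "pair1"),
    background = roi_circle("background", spec$background_center[1],
                            spec$background_center[2], spec$mass_radius))
  annotations <- list(
    cell_annotation("GSC", "telophase", "pair1", "stem"),
    cell_annotation("GB", "telophase", "pair1", "diff"))
  gt <- list(spec = unclass(spec), seed = seed,
             expected_total_stem = amp_stem * unit_stem,
             expected_total_diff = amp_diff * unit_diff,
             expected_ratio = spec$true_ratio)
  list(stack = stack, rois = rois, annotations = annotations, ground_truth = gt)
}

#' Specification of a synthetic dual-channel condensation cell
#'
#' A nucleus containing a chromatin disc whose old- and new-histone channels
#' each split a fixed photon budget between a diffuse uniform component and
#' compact Gaussian foci; `cluster_fraction` (0 diffuse, 1 fully clustered)
#' controls how condensed a channel looks. Foci are placed deterministically
#' on a ring (the new channel's ring is rotated half a step) so that the
#' expected condensation statistics are smooth functions of the fractions.
#'
#' @param cluster_fraction_old,cluster_fraction_new Fractions in `[0, 1]`.
#' @param n_foci Number of foci per channel.
#' @param focus_sigma Gaussian focus radius (pixels).
#' @param nucleus_radius Nucleus circle radius (pixels).
#' @param chromatin_radius Chromatin disc radius (< nucleus radius).
#' @param shape Stack shape `(z, y, x)`.
#' @param total_signal Photon budget per channel (counts).
#' @param background Uniform background (counts).
#' @param read_noise_sd,poisson Noise controls as in [pair_spec()].
#' @return A `condensation_spec` list.
#' @export
condensation_spec <- function(cluster_fraction_old = 0.8,
                              cluster_fraction_new = 0.2,
                              n_foci = 6L, focus_sigma = 2,
                              nucleus_radius = 24, chromatin_radius = 16,
                              shape = c(3L, 72L, 72L),
                              total_signal = 2e5, background = 10,
                              read_noise_sd = 2, poisson = TRUE) {
  for (f in c(cluster_fraction_old, cluster_fraction_new))
    if (f < 0 || f > 1) stop("cluster_fraction must lie in [0, 1]")
  if (chromatin_radius >= nucleus_radius)
    stop("chromatin disc must fit inside the nucleus")
  structure(list(cluster_fraction_old = cluster_fraction_old,
                 cluster_fraction_new = cluster_fraction_new,
                 n_foci = as.integer(n_foci), focus_sigma = focus_sigma,
                 nucleus_radius = nucleus_radius,
                 chromatin_radius = chromatin_radius,
                 shape = as.integer(shape), total_signal = total_signal,
                 background = background, read_noise_sd = read_noise_sd,
                 poisson = poisson),
            class = "condensation_spec")
}

.condensation_channel_expected <- function(spec, cluster_fraction, phase) {
  nz <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  cy <- nr / 2; cx <- nc / 2
  d2 <- .circle_dist2(nr, nc, cy, cx)
  chrom <- d2 <= spec$chromatin_radius^2
  # diffuse component: broad Gaussian over the chromatin disc rather than a
  # flat plateau, so threshold statistics vary continuously with the
  # cluster fraction (real decondensed chromatin is not uniformly bright)
  unif <- exp(-d2 / (2 * (0.6 * spec$chromatin_radius)^2))
  unif[!chrom] <- 0
  unif <- unif / sum(unif)
  # one focus at the disc center (keeps the image maximum there for every
  # cluster fraction, so threshold statistics vary monotonically) plus a
  # deterministic ring of n_foci - 1 peripheral foci
  angles <- 2 * pi * (seq_len(max(spec$n_foci - 1L, 0L)) - 1) /
    max(spec$n_foci - 1L, 1L) + phase
  ring_r <- 0.55 * spec$chromatin_radius
  centers_y <- c(cy, cy + ring_r * sin(angles))
  centers_x <- c(cx, cx + ring_r * cos(angles))
  foci <- matrix(0, nr, nc)
  for (k in seq_along(centers_y)) {
    g <- exp(-.circle_dist2(nr, nc, centers_y[k], centers_x[k]) /
               (2 * spec$focus_sigma^2))
    g[!chrom] <- 0
    foci <- foci + g
  }
  foci <- foci / sum(foci)
  plane <- spec$total_signal *
    ((1 - cluster_fraction) * unif + cluster_fraction * foci)
  z_prof <- exp(-((seq_len(nz) - (nz + 1) / 2)^2) / (2 * (max(nz, 2) / 4)^2))
  z_prof <- z_prof / max(z_prof) # in-focus slice carries the full plane
  expected <- array(0, dim = c(nz, nr, nc))
  for (z in seq_len(nz)) expected[z, , ] <- spec$background + z_prof[z] * plane
  expected
}

#' Generate a synthetic dual-channel (old/new histone) nucleus
#'
#' @param spec A [condensation_spec()].
#' @param seed Integer seed.
#' @return A list with `stack` (channels "old" and "new"), `nucleus_mask`
#'   (logical matrix), and `ground_truth` including the noiseless expected
#'   condensation parameters and compaction factor computed by running the
#'   condensation pipeline on the expected images.
#' @export
generate_condensation_cell <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "condensation_spec"))
  nr <- spec$shape[2]; nc <- spec$shape[3]
  exp_old <- .condensation_channel_expected(spec, spec$cluster_fraction_old, 0)
  exp_new <- .condensation_channel_expected(spec, spec$cluster_fraction_new,
                                            pi / spec$n_foci)
  old_v <- .apply_noise(exp_old, spec$poisson, spec$read_noise_sd,
                        .substream(seed, 1L))
  new_v <- .apply_noise(exp_new, spec$poisson, spec$read_noise_sd,
                        .substream(seed, 2L))
  stack <- image_stack(list(old = old_v, new = new_v),
                       voxel_size = c(0.5, 0.1, 0.1), bit_depth = 16L,
                       metadata = list(generator = "generate_condensation_cell",
                                       seed = seed))
  nucleus_mask <- .circle_dist2(nr, nc, nr / 2, nc / 2) <= spec$nucleus_radius^2
  noiseless <- image_stack(list(old = exp_old, new = exp_new),
                           bit_depth = 16L)
  expected_result <- analyze_condensation(noiseless, nucleus_mask)
  gt <- list(spec = unclass(spec), seed = seed,
             expected_condensation_old = expected_result$condensation_old,
             expected_condensation_new = expected_result$condensation_new,
             expected_compaction_factor = expected_result$compaction_factor)
  list(stack = stack, nucleus_mask = nucleus_mask, ground_truth = gt)
}

#' Specification of a synthetic replicating chromatin fiber
#'
#' Two parallel horizontal strands of controllable background-subtracted
#' histone intensity, with PCNA confined to one strand (the lagging strand).
#'
#' @param leading_intensity,lagging_intensity Histone intensity above
#'   background on each strand (counts), > 0.
#' @param pcna_intensity PCNA intensity above background on the lagging
#'   strand (counts).
#' @param pcna_on Which strand carries PCNA (and is therefore lagging):
#'   `"a"` (upper) or `"b"` (lower).
#' @param strand_width Strand thickness (pixels).
#' @param strand_separation Gap between strand top edges (pixels).
#' @param fiber_length_um Fiber length in micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param background Background level (counts).
#' @param read_noise_sd,poisson Noise controls.
#' @return A `fiber_spec` list.
#' @export
fiber_spec <- function(leading_intensity = 200, lagging_intensity = 100,
                       pcna_intensity = 150, pcna_on = c("b", "a"),
                       strand_width = 3L, strand_separation = 8L,
                       fiber_length_um = 12, pixel_size = 0.04,
                       background = 50, read_noise_sd = 2, poisson = TRUE) {
  pcna_on <- match.arg(pcna_on)
  if (leading_intensity <= 0 || lagging_intensity <= 0)
    stop("strand intensities (above background) must be > 0")
  if (background < 0) stop("background must be >= 0")
  structure(list(leading_intensity = leading_intensity,
                 lagging_intensity = lagging_intensity,
                 pcna_intensity = pcna_intensity, pcna_on = pcna_on,
                 strand_width = as.integer(strand_width),
                 strand_separation = as.integer(strand_separation),
                 fiber_length_um = fiber_length_um, pixel_size = pixel_size,
                 background = background, read_noise_sd = read_noise_sd,
                 poisson = poisson),
            class = "fiber_spec")
}

#' Generate a synthetic chromatin fiber image
#'
#' Strand "a" is the upper strand. The strand carrying PCNA (`spec$pcna_on`)
#' is the lagging strand and receives `lagging_intensity`; the other strand
#' receives `leading_intensity`.
#'
#' @param spec A [fiber_spec()].
#' @param seed Integer seed.
#' @return A list with `stack` (one-slice channels "histone" and "pcna"),
#'   `masks` (`strand_a`, `strand_b`, `background`), `axis` (fiber midline
#'   polyline, pixels), `pixel_size`, and `ground_truth` with the expected
#'   log2 leading/lagging ratio.
#' @export
generate_fiber <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fiber_spec"))
  len_px <- ceiling(spec$fiber_length_um / spec$pixel_size)
  margin <- 6L
  nr <- 2L * margin + spec$strand_separation + spec$strand_width + 10L
  nc <- len_px + 2L * margin
  cols <- (margin + 1L):(margin + len_px)
  rows_a <- (margin + 1L):(margin + spec$strand_width)
  rows_b <- rows_a + spec$strand_separation
  m_a <- matrix(FALSE, nr, nc); m_a[rows_a, cols] <- TRUE
  m_b <- matrix(FALSE, nr, nc); m_b[rows_b, cols] <- TRUE
  m_bg <- matrix(FALSE, nr, nc); m_bg[(nr - 4L):nr, ] <- TRUE
  int_a <- if (spec$pcna_on == "a") spec$lagging_intensity else spec$leading_intensity
  int_b <- if (spec$pcna_on == "b") spec$lagging_intensity else spec$leading_intensity
  hist_exp <- matrix(spec$background, nr, nc)
  hist_exp[m_a] <- hist_exp[m_a] + int_a
  hist_exp[m_b] <- hist_exp[m_b] + int_b
  pcna_exp <- matrix(spec$background, nr, nc)
  pcna_mask <- if (spec$pcna_on == "a") m_a else m_b
  pcna_exp[pcna_mask] <- pcna_exp[pcna_mask] + spec$pcna_intensity
  to3 <- function(m) array(m, dim = c(1L, nr, nc))
  hist_v <- .apply_noise(to3(hist_exp), spec$poisson, spec$read_noise_sd,
                         .substream(seed, 1L))
  pcna_v <- .apply_noise(to3(pcna_exp), spec$poisson, spec$read_noise_sd,
                         .substream(seed, 2L))
  stack <- image_stack(list(histone = hist_v, pcna = pcna_v),
                       voxel_size = c(1, spec$pixel_size, spec$pixel_size),
                       bit_depth = 16L,
                       metadata = list(generator = "generate_fiber", seed = seed))
  mid_row <- (min(rows_a) + max(rows_b)) / 2
  axis <- rbind(c(mid_row, margin + 0.5), c(mid_row, margin + len_px - 0.5))
  gt <- list(spec = unclass(spec), seed = seed,
             lagging_strand = spec$pcna_on,
             expected_log2_ratio = log2(spec$leading_intensity /
                                        spec$lagging_intensity))
  list(stack = stack,
       masks = list(strand_a = m_a, strand_b = m_b, background = m_bg),
       axis = axis, pixel_size = spec$pixel_size, ground_truth = gt)
}

#' Specification of a synthetic chromatin-association cell
#'
#' A single-slice cell with a chromatin disc occupying a controllable area
#' fraction; a licensing-factor-like channel distributes a fixed total
#' signal with `bound_fraction` inside the chromatin mask and the remainder
#' uniformly over the rest of the cell.
#'
#' @param bound_fraction Share of total signal on chromatin, in `[0, 1]`.
#' @param chromatin_area_fraction Chromatin area / cell area, in (0, 1).
#' @param cell_radius Cell circle radius (pixels).
#' @param shape Image shape `(y, x)`.
#' @param total_signal Photon budget (counts).
#' @param read_noise_sd,poisson Noise controls.
#' @return An `association_spec` list.
#' @export
association_spec <- function(bound_fraction = 0.75,
                             chromatin_area_fraction = 0.25,
                             cell_radius = 30, shape = c(80L, 80L),
                             total_signal = 1e5,
                             read_noise_sd = 2, poisson = TRUE) {
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("bound_fraction must lie in [0, 1]")
  if (chromatin_area_fraction <= 0 || chromatin_area_fraction >= 1)
    stop("chromatin_area_fraction must lie in (0, 1)")
  structure(list(bound_fraction = bound_fraction,
                 chromatin_area_fraction = chromatin_area_fraction,
                 cell_radius = cell_radius, shape = as.integer(shape),
                 total_signal = total_signal,
                 read_noise_sd = read_noise_sd, poisson = poisson),
            class = "association_spec")
}

#' Generate a synthetic chromatin-association cell
#'
#' Noiseless images give `bound_ratio = bound_fraction / (1 - bound_fraction)`
#' exactly (areas enter through the rasterized masks, which are returned).
#'
#' @param spec An [association_spec()].
#' @param seed Integer seed.
#' @return A list with `image` (2D matrix), `chromatin_mask`, `cell_mask`,
#'   and `ground_truth` with the expected bound ratio.
#' @export
generate_association_cell <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "association_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cy <- nr / 2; cx <- nc / 2
  d2 <- .circle_dist2(nr, nc, cy, cx)
  cell_mask <- d2 <= spec$cell_radius^2
  chrom_radius <- spec$cell_radius * sqrt(spec$chromatin_area_fraction)
  chromatin_mask <- d2 <= chrom_radius^2
  a_cell <- sum(cell_mask); a_chr <- sum(chromatin_mask)
  f <- spec$bound_fraction
  expected <- matrix(0, nr, nc)
  expected[cell_mask] <- (1 - f) * spec$total_signal / (a_cell - a_chr)
  expected[chromatin_mask] <- f * spec$total_signal / a_chr
  values <- .apply_noise(array(expected, c(1L, nr, nc)), spec$poisson,
                         spec$read_noise_sd, .substream(seed, 1L))[1, , ]
  gt <- list(spec = unclass(spec), seed = seed,
             expected_bound_ratio = if (f < 1) f / (1 - f) else Inf,
             chromatin_area = a_chr, cell_area = a_cell)
  list(image = values, chromatin_mask = chromatin_mask,
       cell_mask = cell_mask, ground_truth = gt)
}
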