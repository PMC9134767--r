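test_that("chromatin_bound_fraction implements area-times-mean accounting", {
  img <- matrix(0, 10, 10)
  chrom <- matrix(FALSE, 10, 10); chrom[1:2, 1:5] <- TRUE  # 10 px
  cell <- matrix(FALSE, 10, 10); cell[1:5, 1:8] <- TRUE    # 40 px
  img[chrom] <- 5                       # chromatin mean 5 -> bound 50
  img[cell & !chrom] <- 1               # 30 px of 1 -> cell sum 80, mean 2
  res <- chromatin_bound_fraction(img, chrom, cell)
  expect_equal(res$amount_bound, 50)
  expect_equal(res$amount_excluded, 30)
  expect_equal(res$bound_ratio, 50 / 30)
  # uniform intensity: the ratio reduces to the area ratio
  uni <- chromatin_bound_fraction(matrix(7, 10, 10), chrom, cell)
  expect_equal(uni$bound_ratio, 10 / (40 - 10))
  # gain invariance
  res3 <- chromatin_bound_fraction(3 * img, chrom, cell)
  expect_equal(res3$bound_ratio, res$bound_ratio)
  # background-subtracted variant: subtracting a constant offset first
  res_bg <- chromatin_bound_fraction(img + 2, chrom, cell, background = 2)
  expect_equal(res_bg$bound_ratio, res$bound_ratio)
  expect_error(chromatin_bound_fraction(img, cell, chrom), "inside")
  expect_error(chromatin_bound_fraction(img, chrom, chrom), "strictly larger")
})

test_that("3D input selects the largest-chromatin slice, lowest z on ties", {
  a <- array(1, dim = c(3, 6, 6))
  a[2, , ] <- 9 # distinguishable slice
  chrom3 <- array(FALSE, dim = c(3, 6, 6))
  chrom3[1, 1:2, 1:2] <- TRUE  # area 4
  chrom3[2, 1:3, 1:3] <- TRUE  # area 9 <- selected
  chrom3[3, 1:3, 1:3] <- TRUE  # area 9, higher z loses the tie
  cell <- matrix(TRUE, 6, 6)
  res <- chromatin_bound_fraction(a, chrom3, cell)
  expect_equal(res$slice, 2L)
  expect_equal(res$chromatin_mean, 9)
})

test_that("noiseless synthetic cells give bound_ratio = f / (1 - f)", {
  for (f in c(0.5, 0.75)) {
    g <- generate_association_cell(association_spec(bound_fraction = f,
                                                    poisson = FALSE,
                                                    read_noise_sd = 0), seed = 3)
    res <- chromatin_bound_fraction(g$image, g$chromatin_mask, g$cell_mask)
    expect_equal(res$bound_ratio, f / (1 - f), tolerance = 1e-9)
  }
})

test_that("spearman_coloc reproduces the reference correlations", {
  set.seed(61)
  a <- matrix(stats::runif(400), 20, 20)
  expect_equal(spearman_coloc(a, a)$rho, 1)
  expect_equal(spearman_coloc(a, -a + 2)$rho, -1)
  # rank-formula oracle
  a4 <- matrix(c(1, 2, 3, 4), 1, 4); b4 <- matrix(c(1, 3, 2, 4), 1, 4)
  expect_equal(spearman_coloc(a4, b4)$rho, 0.8)
  expect_equal(spearman_coloc(a4, b4)$rho, oracle_spearman_noties(a4, b4))
  # invariance under strictly monotone transforms
  b <- matrix(stats::runif(400), 20, 20)
  r0 <- spearman_coloc(a, b)$rho
  expect_equal(spearman_coloc(exp(a), b)$rho, r0)
  expect_equal(spearman_coloc(a, b^3)$rho, r0)
  # constant channel is degenerate
  dg <- spearman_coloc(matrix(5, 3, 3), matrix(stats::runif(9), 3, 3))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
  expect_error(spearman_coloc(a[1, 1:2, drop = FALSE], b[1, 1:2, drop = FALSE]),
               "3 pixels")
  # independent channels: near-zero rho at 10^4 pixels
  big_a <- matrix(stats::rnorm(1e4), 100, 100)
  big_b <- matrix(stats::rnorm(1e4), 100, 100)
  expect_lt(abs(spearman_coloc(big_a, big_b)$rho), 0.05)
})

test_that("nuclear size proxies follow max-slice-area and summed-volume rules", {
  s <- stack_from_slices(lapply(1:3, function(z) matrix(0, 30, 30)))
  rois <- list(rect_roi("nuc", 1, 1, 5, 10, slices = 1L),   # 50 px
               rect_roi("nuc", 1, 1, 8, 10, slices = 2L),   # 80 px
               rect_roi("nuc", 1, 1, 6, 10, slices = 3L))   # 60 px
  expect_equal(nuclear_size_single_slice(s, rois), 80)
  expect_equal(nuclear_size_volume(s, rois, z_step = 1), 190)
  expect_equal(nuclear_size_volume(s, rois, z_step = 0.5), 95)
  expect_equal(nuclear_size_single_slice(s, rois[2]), 80)
  expect_error(nuclear_size_single_slice(s, list()), "no nucleus ROI")
})

test_that("ellipsoid nuclei match the geometric area and volume formulas", {
  # ellipsoid with equatorial radius a and z semi-axis c, sampled per slice
  a_r <- 10; c_z <- 8; z_step <- 0.25
  z_centers <- seq(-c_z + z_step / 2, c_z - z_step / 2, by = z_step)
  radii <- a_r * sqrt(pmax(1 - (z_centers / c_z)^2, 0))
  keep <- radii > 0.5
  rois <- lapply(which(keep), function(k)
    roi_circle("nuc", 32, 32, radii[k], slices = k))
  s <- stack_from_slices(lapply(seq_along(z_centers), function(z)
    matrix(0, 64, 64)))
  eq_area <- nuclear_size_single_slice(s, rois)
  expect_lt(abs(eq_area - pi * a_r^2) / (pi * a_r^2), 0.05)
  vol <- nuclear_size_volume(s, rois, z_step = z_step)
  true_vol <- 4 / 3 * pi * a_r^2 * c_z
  expect_lt(abs(vol - true_vol) / true_vol, 0.10)
})

test_that("replication_ratio uses log2 with the GB-leading sign convention", {
  ts <- function(fs, label) structure(list(Fs = fs, label = label,
                                           channel = "PCNA"),
                                      class = "total_signal")
  expect_equal(replication_ratio(ts(50, "GSC"), ts(100, "GB"))$log2_ratio, -1)
  expect_equal(replication_ratio(ts(80, "GSC"), ts(80, "GB"))$log2_ratio, 0)
  # a brighter GB (earlier replication in the differentiating daughter)
  # always yields a negative value
  expect_lt(replication_ratio(ts(90, "GSC"), ts(130, "GB"))$log2_ratio, 0)
  # antisymmetry
  expect_equal(replication_ratio(ts(50, "GSC"), ts(100, "GB"))$log2_ratio,
               -replication_ratio(ts(100, "GSC"), ts(50, "GB"))$log2_ratio)
  expect_error(replication_ratio(ts(0, "GSC"), ts(100, "GB")), "non-positive")
})

test_that("timing_curve sorts by nuclear size, stable on ties", {
  df <- data.frame(pair_id = c("a", "b", "c", "d"),
                   nuclear_size = c(120, 80, 120, 50),
                   channel = "PCNA",
                   log2_ratio = c(0.1, -0.8, 0.2, -1.2))
  out <- timing_curve(df)
  expect_equal(out$pair_id, c("d", "b", "a", "c")) # ties keep input order
  expect_equal(timing_curve(df[2, ])$pair_id, "b")
  # synthetic construction: early (small) pairs carry the negative ratios
  early <- out$log2_ratio[out$nuclear_size <= 80]
  expect_true(all(early < 0))
})
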