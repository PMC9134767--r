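# One-pixel signal and background circles keep the per-slice sums readable:
# a circle of radius 0.6 centered on a pixel center covers exactly that pixel.
one_px_stack <- function(signal_values, background_values, nr = 5, nc = 9) {
  slices <- lapply(seq_along(signal_values), function(z) {
    m <- matrix(0, nr, nc)
    m[3, 3] <- signal_values[z]
    m[3, 7] <- background_values[z]
    m
  })
  stack_from_slices(slices, channel = "H3")
}
sig_roi <- roi_circle("GSC", 2.5, 2.5, 0.6)
bg_roi <- roi_circle("background", 2.5, 6.5, 0.6)

test_that("total_signal implements the per-slice background-subtracted sum", {
  s1 <- one_px_stack(100, 0)
  ts <- total_signal(s1, "H3", sig_roi, bg_roi)
  expect_equal(ts$Fs, 100)
  expect_equal(ts$Rs, 100)
  expect_equal(ts$Bs, 0)

  s3 <- one_px_stack(c(120, 150, 90), c(20, 30, 10))
  ts3 <- total_signal(s3, "H3", sig_roi, bg_roi)
  expect_equal(ts3$Rs, c(120, 150, 90))
  expect_equal(ts3$Bs, c(20, 30, 10))
  expect_equal(ts3$Fs, 300)
})

test_that("negative per-slice differences are kept, not clamped", {
  s <- one_px_stack(c(50, 10), c(20, 30))
  ts <- total_signal(s, "H3", sig_roi, bg_roi)
  expect_equal(ts$Fs, (50 - 20) + (10 - 30))
  # a non-positive total draws a warning but still returns
  s_neg <- one_px_stack(10, 30)
  expect_warning(ts_neg <- total_signal(s_neg, "H3", sig_roi, bg_roi),
                 "non-positive")
  expect_equal(ts_neg$Fs, -20)
})

test_that("mismatched background area is an error, never a silent rescale", {
  s <- one_px_stack(100, 0)
  big_bg <- roi_circle("background", 2.5, 6.5, 1.4)
  expect_error(total_signal(s, "H3", sig_roi, big_bg), "does not match")
})

test_that("Fs is additive over a z-range split", {
  set.seed(31)
  slices <- lapply(1:6, function(z) {
    m <- matrix(sample.int(500, 20 * 20, TRUE), 20, 20)
    m[4:12, 4:12] <- m[4:12, 4:12] + 400 # keep the signal region above background
    m
  })
  s <- stack_from_slices(slices, channel = "H3")
  sig <- roi_circle("GSC", 8, 8, 4)
  bg <- roi_circle("background", 8, 16, 4)
  full <- total_signal(s, "H3", sig, bg)
  lo <- total_signal(s, "H3",
                     roi_circle("GSC", 8, 8, 4, slices = 1:3),
                     roi_circle("background", 8, 16, 4, slices = 1:3))
  hi <- total_signal(s, "H3",
                     roi_circle("GSC", 8, 8, 4, slices = 4:6),
                     roi_circle("background", 8, 16, 4, slices = 4:6))
  expect_equal(lo$Fs + hi$Fs, full$Fs)
})

test_that("raw_sum matches the brute-force loop and ratios are scale-invariant", {
  set.seed(32)
  img <- matrix(sample.int(1000, 64 * 64, TRUE), 64, 64)
  mask <- matrix(stats::runif(64 * 64) < 0.4, 64, 64)
  expect_equal(raw_sum(img, mask), oracle_masked_sum(img, mask))
  expect_error(raw_sum(img, matrix(FALSE, 64, 64)), "empty")
  expect_equal(raw_sum(matrix(0, 3, 3), matrix(TRUE, 3, 3)), 0)
  expect_equal(raw_sum(matrix(1:4, 2, 2), matrix(TRUE, 2, 2)), 10L)

  # multiplying intensities by c scales Fs by c and leaves the ratio unchanged
  slices <- lapply(1:3, function(z) matrix(sample.int(300, 30 * 30, TRUE), 30, 30))
  s <- stack_from_slices(slices, channel = "H3")
  s5 <- stack_from_slices(lapply(slices, function(m) 5 * m), channel = "H3")
  sig1 <- roi_circle("GSC", 10, 8, 4); sig2 <- roi_circle("GB", 10, 22, 4)
  bg <- roi_circle("background", 24, 15, 4)
  r1 <- sister_ratio(total_signal(s, "H3", sig1, bg),
                     total_signal(s, "H3", sig2, bg))
  r5 <- sister_ratio(total_signal(s5, "H3", sig1, bg),
                     total_signal(s5, "H3", sig2, bg))
  expect_equal(total_signal(s5, "H3", sig1, bg)$Fs,
               5 * total_signal(s, "H3", sig1, bg)$Fs)
  expect_equal(r5$ratio, r1$ratio)
})

test_that("sister_ratio computes the directed ratio and its log2", {
  ts <- function(fs, label) structure(list(Fs = fs, label = label, channel = "H3"),
                                      class = "total_signal")
  sr <- sister_ratio(ts(150, "GSC"), ts(100, "GB"))
  expect_equal(sr$ratio, 1.5)
  expect_equal(sr$log2_ratio, log2(1.5))
  expect_equal(round(sr$log2_ratio, 3), 0.585)
  eq <- sister_ratio(ts(70, "SG1"), ts(70, "SG2"))
  expect_equal(eq$ratio, 1)
  expect_equal(eq$log2_ratio, 0)
  expect_error(sister_ratio(ts(-5, "GSC"), ts(100, "GB")), "non-positive")
  # orientation antisymmetry: swapping labels inverts and negates
  swapped <- sister_ratio(ts(100, "GB"), ts(150, "GSC"))
  expect_equal(swapped$ratio, 1 / sr$ratio)
  expect_equal(swapped$log2_ratio, -sr$log2_ratio)
})

test_that("nucleosome density ratio reduces to the total-histone ratio", {
  ts <- function(fs, label) structure(list(Fs = fs, label = label, channel = "H4"),
                                      class = "total_signal")
  sr <- sister_ratio(ts(150, "GSC"), ts(100, "GB"))
  expect_equal(as.numeric(nucleosome_density_ratio(sr)), 1.5)
  # algebraic oracle: carrying the 1/2 and DNA length through explicitly
  dna <- 1.8e8
  expect_equal((0.5 * 150 / dna) / (0.5 * 100 / dna), 1.5)
  unit <- sister_ratio(ts(88, "GSC"), ts(88, "GB"))
  expect_equal(as.numeric(nucleosome_density_ratio(unit)), 1)
})

test_that("classify_asymmetry applies the control mean + SE rule", {
  # worked example: symmetric-division H2A control summary -> threshold 1.095,
  # and the asymmetric-division H2A mean ratio 1.33 is called asymmetric
  call <- classify_asymmetry(1.33, control_summary = c(1.059, 0.036))
  expect_equal(call$threshold, 1.095)
  expect_equal(call$call, "asymmetric")
  # a ratio exactly at the threshold is symmetric (strict inequality)
  expect_equal(classify_asymmetry(1.095,
                                  control_summary = c(1.059, 0.036))$call,
               "symmetric")
  # direct-formula oracle on a small control list
  ctl <- c(1.0, 1.1, 1.2)
  call2 <- classify_asymmetry(1.2, control_ratios = ctl)
  expect_equal(call2$control_mean, 1.1)
  expect_equal(call2$control_se, stats::sd(ctl) / sqrt(3))
  expect_equal(call2$threshold, 1.1 + 0.1 / sqrt(3))
  expect_equal(call2$call, "asymmetric")
  expect_equal(classify_asymmetry(1.15, control_ratios = ctl)$call, "symmetric")
  expect_error(classify_asymmetry(1.2, control_ratios = 1.0), ">= 2")
})

test_that("noiseless synthetic pairs recover the generated ratio exactly", {
  for (tr in c(1.0, 1.5)) {
    g <- generate_pair(pair_spec(true_ratio = tr, poisson = FALSE,
                                 read_noise_sd = 0), seed = 5)
    ts_stem <- total_signal(g$stack, "histone", g$rois$stem, g$rois$background)
    ts_diff <- total_signal(g$stack, "histone", g$rois$diff, g$rois$background)
    expect_equal(ts_stem$Fs, g$ground_truth$expected_total_stem, tolerance = 1e-9)
    expect_equal(sister_ratio(ts_stem, ts_diff)$ratio, tr, tolerance = 1e-9)
  }
})
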