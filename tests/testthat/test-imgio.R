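test_that("read_stack deinterleaves plane-interleaved channels", {
  # 8 planes, two channels interleaved c1 z1, c2 z1, c1 z2, ... with
  # recognizable constant values per (channel, z)
  planes <- lapply(1:8, function(k) matrix(k * 10L, 4, 6))
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(planes, path, bit_depth = 16L) # no metadata: order from caller
  s <- read_stack(path, c("old", "new"))
  expect_equal(dim(s$channels$old), c(4L, 4L, 6L))
  expect_equal(unique(as.vector(s$channels$old[3, , ])), 50L)  # c1, z3 = plane 5
  expect_equal(unique(as.vector(s$channels$new[3, , ])), 60L)  # c2, z3 = plane 6
})

test_that("read_stack rejects plane counts not divisible by channel count", {
  planes <- lapply(1:5, function(k) matrix(0L, 3, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(planes, path)
  expect_error(read_stack(path, c("a", "b")), "not divisible")
})

test_that("image_stack enforces its invariants", {
  expect_error(image_stack(list(a = array(0, c(2, 3, 3)),
                                b = array(0, c(2, 3, 4)))), "share")
  expect_error(image_stack(list(a = array(-1, c(1, 2, 2)))), "outside")
  expect_error(image_stack(list(a = array(300, c(1, 2, 2))), bit_depth = 8L),
               "outside")
  expect_error(image_stack(list(a = array(0, c(1, 2, 2))),
                           voxel_size = c(0, 1, 1)), "positive")
})

test_that("rasterize_roi follows the pixel-center containment rule", {
  # circle of radius 0.6 around the center pixel of a 3x3 image: only that
  # pixel's center (distance 0) is inside; neighbours are at distance 1
  m <- rasterize_roi(roi_circle("c", 1.5, 1.5, 0.6), c(3, 3))
  expect_equal(sum(m), 1L)
  expect_true(m[2, 2])
  # square polygon covering a 2x2 pixel block exactly
  m2 <- rasterize_roi(roi_polygon("p", vy = c(0, 0, 2, 2), vx = c(0, 2, 2, 0)),
                      c(4, 4))
  expect_equal(sum(m2), 4L)
  expect_true(all(m2[1:2, 1:2]))
  # boundary points count as inside: circle through a pixel center
  m3 <- rasterize_roi(roi_circle("c", 1.5, 1.5, 1), c(3, 3))
  expect_equal(sum(m3), 5L) # center + 4-neighbours at distance exactly 1
  expect_error(rasterize_roi(roi_circle("c", -50, -50, 2), c(5, 5)),
               "does not cover")
})

test_that("polygon mask area agrees with a Monte-Carlo winding-number oracle", {
  set.seed(101)
  for (rep in 1:3) {
    # random convex polygon, large enough that pixelation error is < 1%
    n_v <- sample(5:9, 1)
    ang <- sort(stats::runif(n_v, 0, 2 * pi))
    rad <- stats::runif(n_v, 25, 32)
    vy <- 40 + rad * sin(ang); vx <- 40 + rad * cos(ang)
    mask_area <- sum(rasterize_roi(roi_polygon("p", vy, vx), c(80, 80)))
    py <- stats::runif(1e5, 0, 80); px <- stats::runif(1e5, 0, 80)
    inside <- vapply(seq_along(py), function(k)
      oracle_in_polygon(py[k], px[k], vy, vx), logical(1))
    mc_area <- mean(inside) * 80 * 80
    expect_lt(abs(mask_area - mc_area) / mc_area, 0.02)
  }
})

test_that("max_projection matches a per-pixel loop and is idempotent", {
  s1 <- stack_from_slices(list(matrix(c(0, 5, 1, 7), 1, 4)))
  expect_equal(max_projection(s1, "ch"), matrix(c(0, 5, 1, 7), 1, 4))
  s2 <- stack_from_slices(list(matrix(c(0, 5), 1, 2), matrix(c(3, 2), 1, 2)))
  expect_equal(max_projection(s2, "ch"), matrix(c(3, 5), 1, 2))
  set.seed(7)
  a <- array(sample.int(1000, 3 * 6 * 5, TRUE), c(3, 6, 5))
  s <- image_stack(list(ch = a))
  proj <- max_projection(s, "ch")
  loop <- matrix(0, 6, 5)
  for (i in 1:6) for (j in 1:5) loop[i, j] <- max(a[, i, j])
  expect_equal(proj, loop)
  # idempotence: projecting the projection changes nothing
  expect_equal(max_projection(image_stack(list(ch = proj)), "ch"), proj)
  # commutes with cropping
  expect_equal(proj[2:4, 1:3],
               max_projection(image_stack(list(ch = a[, 2:4, 1:3])), "ch"))
  expect_error(max_projection(s, "nope"), "not found")
})

test_that("largest_inscribed_square handles the reference geometries", {
  expect_equal(largest_inscribed_square(matrix(TRUE, 5, 5)),
               list(top = 1L, left = 1L, side = 5L))
  # L-shape made of two 2x4 arms: widest inscribed square has side 2
  L <- matrix(FALSE, 4, 4)
  L[1:2, 1:4] <- TRUE
  L[1:4, 1:2] <- TRUE
  expect_equal(largest_inscribed_square(L)$side, 2L)
  single <- matrix(FALSE, 3, 3); single[2, 3] <- TRUE
  expect_equal(largest_inscribed_square(single),
               list(top = 2L, left = 3L, side = 1L))
  expect_error(largest_inscribed_square(matrix(FALSE, 2, 2)), "empty")
})

test_that("largest_inscribed_square always lies inside the mask", {
  set.seed(21)
  for (rep in 1:20) {
    mask <- matrix(stats::runif(100) < 0.7, 10, 10)
    if (!any(mask)) next
    sq <- largest_inscribed_square(mask)
    expect_true(all(mask[sq$top:(sq$top + sq$side - 1L),
                         sq$left:(sq$left + sq$side - 1L)]))
  }
})

test_that("ROI tables round-trip through CSV and JSON", {
  rois <- list(
    roi_circle("GSC", 10.5, 20, 5, pair_id = "p1"),
    roi_circle("GB", 10.5, 40, 5, slices = c(2L, 3L), pair_id = "p1"),
    roi_polygon("chromatin", vy = c(0, 0, 4), vx = c(0, 4, 2)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_roi_table(rois, csv)
  back <- read_roi_table(csv)
  expect_equal(length(back), 3L)
  expect_equal(back[[1]]$radius, 5)
  expect_equal(back[[2]]$slices, c(2L, 3L))
  expect_equal(back[[3]]$vy, c(0, 4, 2) * 0 + c(0, 0, 4))
  expect_equal(back[[3]]$vx, c(0, 4, 2))
  # identical rasterization after the round-trip
  for (k in 1:3)
    expect_equal(rasterize_roi(back[[k]], c(50, 50)),
                 rasterize_roi(rois[[k]], c(50, 50)))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(label = "GSC", shape = "circle", cy = 10.5, cx = 20, radius = 5),
    list(label = "chromatin", shape = "polygon",
         vy = c(0, 0, 4), vx = c(0, 4, 2))), js, auto_unbox = TRUE)
  back_js <- read_roi_table(js)
  expect_equal(back_js[[1]]$cy, 10.5)
  expect_equal(back_js[[2]]$vy, c(0, 0, 4))
})

test_that("measurement_table validates and writes", {
  df <- data.frame(pair_id = c("p1", "p1"), cell_type = c("GSC", "GB"),
                   stage = "telophase", measure = "Fs", channel = "H3",
                   value = c(150, 100), units = "counts")
  tab <- measurement_table(df, provenance = list(source = "test"))
  expect_s3_class(tab, "measurement_table")
  dup <- rbind(df, df[1, ])
  expect_error(measurement_table(dup), "duplicate")
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(tab, path)
  expect_equal(nrow(utils::read.csv(path)), 2L)
})

test_that("cell annotations validate their type", {
  expect_error(cell_annotation("HUB", "telophase", "p", "stem"))
  a <- cell_annotation("GSC", "telophase", "p1", "stem")
  expect_equal(a$cell_type, "GSC")
})
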