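#' Multi-channel 3D image stack
#'
#' The universal pixel-level container of the package: a z-ordered set of 2D
#' intensity planes per named channel, with voxel dimensions. Arrays are
#' indexed `[z, y, x]`. Intensities are non-negative and bounded by the bit
#' depth ceiling; synthetic noiseless images may carry non-integer expected
#' values (see the methods vignette), real TIFF data are integer counts.
#'
#' @param channels Named list of 3D arrays with dim `(z, y, x)`; a single
#'   matrix is promoted to a one-slice array.
#' @param voxel_size Numeric length-3 `(z, y, x)` in micrometres, all > 0.
#' @param bit_depth 8 or 16.
#' @param metadata Free-form named list.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size = c(1, 1, 1), bit_depth = 16L,
                        metadata = list()) {
  stopifnot(is.list(channels), length(channels) > 0)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("all channels must be named")
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(1L, dim(a)))
    if (length(dim(a)) != 3L) stop("each channel must be a (z, y, x) array")
    a
  })
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("all channels must share one (z, y, x) shape")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  ceiling_v <- 2^bit_depth - 1
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(v < 0) || any(v > ceiling_v))
      stop("channel '", nm, "' has intensities outside [0, ", ceiling_v, "]")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive values (z, y, x)")
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size),
         bit_depth = as.integer(bit_depth), metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d channel(s) [%s], z=%d y=%d x=%d, %d-bit\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$bit_depth))
  cat(sprintf("voxel size (z,y,x): %s um\n",
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

.stack_channel <- function(stack, channel) {
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not found; available: ",
         paste(names(stack$channels), collapse = ", "))
  stack$channels[[channel]]
}

#' Read a TIFF z-stack into an image_stack
#'
#' Planes are assigned to channels from the file's description metadata when
#' present (as written by [write_stack()]); otherwise they are assumed
#' plane-interleaved in the order of `channel_names` (c1 z1, c2 z1, c1 z2, ...).
#'
#' @param path TIFF file path.
#' @param channel_names Character vector of channel names.
#' @param voxel_size Voxel size `(z, y, x)` in micrometres; overridden by file
#'   metadata when present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_names, voxel_size = c(1, 1, 1)) {
  tf <- read_tiff(path)
  n_ch <- length(channel_names)
  meta <- NULL
  if (!is.null(tf$description) && nzchar(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  }
  if (!is.null(meta) && !is.null(meta$channels)) {
    if (!identical(sort(as.character(meta$channels)), sort(channel_names)))
      stop("channel names in file metadata (", paste(meta$channels, collapse = ","),
           ") do not match requested channels")
    file_order <- as.character(meta$channels)
    if (!is.null(meta$voxel_size)) voxel_size <- as.numeric(meta$voxel_size)
  } else {
    file_order <- channel_names
  }
  n_planes <- length(tf$planes)
  if (n_planes %% n_ch != 0L)
    stop("plane count (", n_planes, ") not divisible by channel count (", n_ch, ")")
  nz <- n_planes %/% n_ch
  h <- nrow(tf$planes[[1]]); w <- ncol(tf$planes[[1]])
  channels <- vector("list", n_ch)
  names(channels) <- file_order
  for (c_i in seq_len(n_ch)) {
    a <- array(0L, dim = c(nz, h, w))
    for (z in seq_len(nz)) a[z, , ] <- tf$planes[[(z - 1L) * n_ch + c_i]]
    storage.mode(a) <- "integer"
    channels[[c_i]] <- a
  }
  image_stack(channels[channel_names], voxel_size = voxel_size,
              bit_depth = tf$bit_depth,
              metadata = list(source = path))
}

#' Write an image_stack as a plane-interleaved TIFF
#'
#' Channel names, voxel size and bit depth are persisted in the
#' ImageDescription tag as JSON, so [read_stack()] round-trips exactly.
#' Non-integer (noiseless synthetic) intensities are rounded on write.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1]])
  planes <- vector("list", d[1] * length(stack$channels))
  i <- 1L
  for (z in seq_len(d[1])) {
    for (ch in names(stack$channels)) {
      planes[[i]] <- stack$channels[[ch]][z, , ]
      i <- i + 1L
    }
  }
  desc <- jsonlite::toJSON(list(channels = names(stack$channels),
                                voxel_size = stack$voxel_size,
                                bit_depth = stack$bit_depth),
                           auto_unbox = FALSE, digits = NA)
  write_tiff(planes, path, bit_depth = stack$bit_depth,
             description = as.character(desc))
}

#' Maximum intensity projection of one channel
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @return A 2D matrix; each pixel is the maximum over z.
#' @export
max_projection <- function(stack, channel) {
  a <- .stack_channel(stack, channel)
  apply(a, c(2, 3), max)
}

#' Largest axis-aligned square inscribed in a binary mask
#'
#' Dynamic-programming maximal-square search. Ties are broken by the smallest
#' (top, left) position, compared lexicographically.
#'
#' @param mask Logical matrix (TRUE = inside region).
#' @return A list with `top`, `left` (1-based indices of the square's
#'   top-left pixel) and `side`.
#' @export
largest_inscribed_square <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("mask is empty: no inscribed square exists")
  nr <- nrow(mask); nc <- ncol(mask)
  s <- matrix(0L, nr, nc) # side of largest square with bottom-right at (i,j)
  best_side <- 0L; best_top <- NA_integer_; best_left <- NA_integer_
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      s[i, j] <- if (i == 1L || j == 1L) 1L else
        1L + min(s[i - 1L, j], s[i, j - 1L], s[i - 1L, j - 1L])
      side <- s[i, j]
      top <- i - side + 1L; left <- j - side + 1L
      if (side > best_side ||
          (side == best_side &&
           (top < best_top || (top == best_top && left < best_left)))) {
        best_side <- side; best_top <- top; best_left <- left
      }
    }
  }
  list(top = best_top, left = best_left, side = best_side)
}
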