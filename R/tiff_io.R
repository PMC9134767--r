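# Minimal baseline TIFF codec: uncompressed greyscale, 8- or 16-bit unsigned,
# multi-page. Reads both little- ("II") and big-endian ("MM") files; writes
# little-endian. Enough of the format for un-scaled microscopy z-stacks; no
# compression, tiles, or colour.

.TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, description = 270L, strip_offsets = 273L,
  rows_per_strip = 278L, strip_byte_counts = 279L, sample_format = 339L,
  samples_per_pixel = 277L
)

.read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

.parse_ifd_entries <- function(raw, ifd_offset, endian) {
  n <- .read_uint(raw, ifd_offset, 2L, endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e0 <- ifd_offset + 2L + (i - 1L) * 12L
    tag <- .read_uint(raw, e0, 2L, endian)
    type <- .read_uint(raw, e0 + 2L, 2L, endian)
    count <- .read_uint(raw, e0 + 4L, 4L, endian)
    type_size <- switch(as.character(type),
      "1" = 1L, "2" = 1L, "3" = 2L, "4" = 4L, "5" = 8L, 4L)
    nbytes <- type_size * count
    val_off <- if (nbytes <= 4L) e0 + 8L else .read_uint(raw, e0 + 8L, 4L, endian)
    values <- if (type == 2L) {
      if (count <= 1L) "" else {
        chars <- raw[(val_off + 1):(val_off + count)]
        rawToChar(chars[chars != as.raw(0L)]) # drop NUL terminator(s)
      }
    } else if (type == 5L) { # RATIONAL: return numerator/denominator
      vapply(seq_len(count), function(k) {
        num <- .read_uint(raw, val_off + (k - 1L) * 8L, 4L, endian)
        den <- .read_uint(raw, val_off + (k - 1L) * 8L + 4L, 4L, endian)
        num / max(den, 1)
      }, numeric(1))
    } else {
      vapply(seq_len(count), function(k) {
        .read_uint(raw, val_off + (k - 1L) * type_size, type_size, endian)
      }, numeric(1))
    }
    entries[[i]] <- list(tag = tag, values = values)
  }
  next_ifd <- .read_uint(raw, ifd_offset + 2L + n * 12L, 4L, endian)
  list(entries = entries, next_ifd = next_ifd)
}

.ifd_value <- function(entries, tag, default = NULL) {
  for (e in entries) if (e$tag == tag) return(e$values)
  default
}

#' Read an uncompressed greyscale TIFF as a list of matrices
#'
#' Low-level reader for baseline TIFF: one matrix (rows = y, cols = x) per
#' page/plane, in file order. Supports 8- and 16-bit unsigned samples, single
#' or multiple strips, and either byte order.
#'
#' @param path Path to a TIFF file.
#' @return A list with `planes` (list of integer matrices), `bit_depth`
#'   (8 or 16) and `description` (ImageDescription string of the first page,
#'   or `NULL`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
    stop("not a TIFF file (bad byte-order mark): ", path))
  if (.read_uint(raw, 2L, 2L, endian) != 42)
    stop("not a TIFF file (bad magic number): ", path)
  ifd_offset <- .read_uint(raw, 4L, 4L, endian)
  planes <- list()
  bit_depth <- NULL
  description <- NULL
  while (ifd_offset != 0L) {
    ifd <- .parse_ifd_entries(raw, ifd_offset, endian)
    en <- ifd$entries
    w <- .ifd_value(en, .TIFF_TAGS[["width"]])
    h <- .ifd_value(en, .TIFF_TAGS[["length"]])
    bits <- .ifd_value(en, .TIFF_TAGS[["bits"]], 1)[1]
    comp <- .ifd_value(en, .TIFF_TAGS[["compression"]], 1)
    spp <- .ifd_value(en, .TIFF_TAGS[["samples_per_pixel"]], 1)
    if (is.null(w) || is.null(h)) stop("TIFF page missing width/length tags")
    if (comp != 1) stop("unsupported TIFF compression scheme: ", comp)
    if (spp != 1) stop("unsupported TIFF samples per pixel: ", spp)
    if (!bits %in% c(8, 16)) stop("unsupported TIFF bit depth: ", bits)
    if (is.null(bit_depth)) bit_depth <- as.integer(bits)
    if (bits != bit_depth) stop("mixed bit depths across TIFF pages")
    if (is.null(description))
      description <- .ifd_value(en, .TIFF_TAGS[["description"]])
    offs <- .ifd_value(en, .TIFF_TAGS[["strip_offsets"]])
    counts <- .ifd_value(en, .TIFF_TAGS[["strip_byte_counts"]])
    bytes <- raw(0)
    for (k in seq_along(offs))
      bytes <- c(bytes, raw[(offs[k] + 1):(offs[k] + counts[k])])
    size <- bits / 8L
    vals <- readBin(bytes, "integer", n = w * h, size = size,
                    signed = FALSE, endian = endian)
    # TIFF stores rows sequentially (row-major); R matrices are column-major
    planes[[length(planes) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_offset <- ifd$next_ifd
  }
  if (length(planes) == 0L) stop("TIFF contains no pages: ", path)
  list(planes = planes, bit_depth = bit_depth, description = description)
}

.uint_bytes <- function(x, size) {
  # little-endian raw encoding of unsigned integers (vectorized)
  out <- raw(length(x) * size)
  for (k in seq_len(size)) {
    out[seq(k, length(out), by = size)] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

.ifd_entry <- function(tag, type, count, value) {
  # `value` is either an inline value or a byte offset; SHORT scalars are
  # left-packed into the 4-byte field, everything else written as 4 bytes
  vbytes <- .uint_bytes(value, if (type == 3L && count == 1L) 2L else 4L)
  c(.uint_bytes(tag, 2L), .uint_bytes(type, 2L), .uint_bytes(count, 4L),
    vbytes, raw(4L - length(vbytes)))
}

#' Write a list of matrices as an uncompressed greyscale TIFF
#'
#' Writes baseline little-endian TIFF, one page per matrix, one strip per
#' page. An optional description string is attached to the first page
#' (used by [write_stack()] to persist channel names and voxel sizes).
#'
#' @param planes A list of integer matrices (rows = y, cols = x), all of the
#'   same shape, or a single matrix.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @param description Optional ImageDescription string for the first page.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(planes, path, bit_depth = 16L, description = NULL) {
  if (is.matrix(planes)) planes <- list(planes)
  stopifnot(length(planes) > 0L, bit_depth %in% c(8L, 16L))
  dims <- unique(lapply(planes, dim))
  if (length(dims) != 1L) stop("all TIFF planes must share one shape")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  ceiling_v <- 2^bit_depth - 1
  size <- bit_depth / 8L
  strip_bytes <- w * h * size
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0L)) else raw(0)
  # layout: 8-byte header | description | strip data per page | IFDs
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  n <- length(planes)
  ifd_entry_counts <- c(10L, rep(9L, max(0L, n - 1L)))
  if (is.null(description)) ifd_entry_counts[1] <- 9L
  ifd_sizes <- 2L + ifd_entry_counts * 12L + 4L
  first_ifd <- data_off + n * strip_bytes
  ifd_offsets <- first_ifd + c(0L, cumsum(ifd_sizes))[seq_len(n)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.uint_bytes(42L, 2L), con)
  writeBin(.uint_bytes(first_ifd, 4L), con)
  if (length(desc_raw)) writeBin(desc_raw, con)
  for (p in planes) {
    v <- as.vector(t(p)) # row-major
    if (any(v < 0 | v > ceiling_v))
      stop("pixel values outside [0, ", ceiling_v, "] for ", bit_depth, "-bit TIFF")
    writeBin(.uint_bytes(round(v), size), con)
  }
  for (i in seq_len(n)) {
    entries <- list(
      .ifd_entry(256L, 4L, 1L, w),
      .ifd_entry(257L, 4L, 1L, h),
      .ifd_entry(258L, 3L, 1L, bit_depth),
      .ifd_entry(259L, 3L, 1L, 1L),   # no compression
      .ifd_entry(262L, 3L, 1L, 1L)    # BlackIsZero
    )
    if (i == 1L && length(desc_raw))
      entries <- c(entries, list(.ifd_entry(270L, 2L, length(desc_raw), desc_off)))
    entries <- c(entries, list(
      .ifd_entry(273L, 4L, 1L, data_off + (i - 1L) * strip_bytes),
      .ifd_entry(277L, 3L, 1L, 1L),
      .ifd_entry(278L, 4L, 1L, h),
      .ifd_entry(279L, 4L, 1L, strip_bytes)
    ))
    # tags must be ascending: 256,257,258,259,262,(270),273,277,278,279
    writeBin(.uint_bytes(length(entries), 2L), con)
    for (e in entries) writeBin(e, con)
    next_off <- if (i < n) ifd_offsets[i + 1L] else 0L
    writeBin(.uint_bytes(next_off, 4L), con)
  }
  invisible(path)
}
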