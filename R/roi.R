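# Regions of interest: circles and polygons in continuous pixel coordinates.
#
# Coordinate convention: the image plane spans [0, nrow] x [0, ncol]; the
# pixel at matrix position (i, j) occupies [i-1, i) x [j-1, j) and has its
# center at (i - 0.5, j - 0.5). A pixel belongs to a region iff its center
# lies inside; boundary points count as inside.

#' Circular region of interest
#'
#' @param label Region label (e.g. "GSC", "GB", "background", "chromatin").
#' @param cy,cx Circle center in continuous pixel coordinates (y, x).
#' @param radius Radius in pixels, > 0.
#' @param slices `"all"` or an integer vector of 1-based z indices.
#' @param pair_id Optional identifier grouping sibling regions.
#' @return An object of class `roi`.
#' @export
roi_circle <- function(label, cy, cx, radius, slices = "all", pair_id = NA_character_) {
  if (radius <= 0) stop("circle radius must be > 0")
  structure(list(label = label, shape = "circle", cy = cy, cx = cx,
                 radius = radius, slices = slices, pair_id = pair_id),
            class = "roi")
}

#' Polygonal region of interest
#'
#' @param label Region label.
#' @param vy,vx Numeric vectors of vertex coordinates (>= 3 vertices).
#' @param slices `"all"` or an integer vector of 1-based z indices.
#' @param pair_id Optional identifier grouping sibling regions.
#' @return An object of class `roi`.
#' @export
roi_polygon <- function(label, vy, vx, slices = "all", pair_id = NA_character_) {
  if (length(vy) < 3L || length(vy) != length(vx))
    stop("polygon needs >= 3 vertices with matching y/x coordinates")
  structure(list(label = label, shape = "polygon", vy = as.numeric(vy),
                 vx = as.numeric(vx), slices = slices, pair_id = pair_id),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  geom <- if (x$shape == "circle")
    sprintf("circle c=(%.2f, %.2f) r=%.2f", x$cy, x$cx, x$radius)
  else sprintf("polygon with %d vertices", length(x$vy))
  cat(sprintf("roi '%s': %s, slices: %s, pair: %s\n", x$label, geom,
              paste(x$slices, collapse = ","), x$pair_id))
  invisible(x)
}

# point-in-polygon, even-odd rule, boundary counted inside
.point_in_polygon <- function(py, px, vy, vx, eps = 1e-9) {
  n <- length(vy)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    y1 <- vy[j]; x1 <- vx[j]; y2 <- vy[i]; x2 <- vx[i]
    # on-segment test
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    if (abs(cross) < eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps)
      return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      x_int <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Rasterize a region of interest to a binary mask
#'
#' A pixel is set iff its center `(i - 0.5, j - 0.5)` lies inside the circle
#' or polygon (boundary inclusive).
#'
#' @param roi An [roi_circle()] or [roi_polygon()].
#' @param shape Integer `(rows, cols)` of the target plane.
#' @return A logical matrix.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi"), length(shape) == 2L, all(shape > 0))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  cy <- matrix(seq_len(nr) - 0.5, nr, nc)
  cx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  mask <- if (roi$shape == "circle") {
    (cy - roi$cy)^2 + (cx - roi$cx)^2 <= roi$radius^2 + 1e-12
  } else {
    m <- matrix(FALSE, nr, nc)
    # restrict to the polygon bounding box for speed
    i_rng <- max(1L, floor(min(roi$vy) + 0.5)):min(nr, ceiling(max(roi$vy) + 0.5))
    j_rng <- max(1L, floor(min(roi$vx) + 0.5)):min(nc, ceiling(max(roi$vx) + 0.5))
    for (i in i_rng) for (j in j_rng)
      m[i, j] <- .point_in_polygon(i - 0.5, j - 0.5, roi$vy, roi$vx)
    m
  }
  if (!any(mask))
    stop("roi '", roi$label, "' does not cover any pixel center in a ",
         nr, "x", nc, " image")
  mask
}

.roi_slices <- function(roi, nz) {
  if (identical(roi$slices, "all") || is.null(roi$slices)) seq_len(nz)
  else {
    s <- as.integer(roi$slices)
    if (any(s < 1L | s > nz)) stop("roi '", roi$label, "' lists slices outside 1..", nz)
    s
  }
}

#' Read a table of regions of interest from CSV or JSON
#'
#' CSV columns: `label, shape, cy, cx, radius, vertices, slices, pair_id`.
#' `vertices` for polygons is `"y1 x1; y2 x2; ..."`; `slices` is `"all"` or
#' `"1 2 3"`. JSON files hold an array of objects with the same fields
#' (`vy`/`vx` arrays allowed instead of `vertices`).
#'
#' @param path CSV (`.csv`) or JSON (`.json`) file.
#' @return A list of `roi` objects.
#' @export
read_roi_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    return(lapply(recs, .roi_from_record))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) .roi_from_record(as.list(df[i, ])))
}

.roi_from_record <- function(r) {
  slices <- r$slices
  if (is.null(slices) || identical(slices, "all") || is.na(slices[1])) slices <- "all"
  else if (is.character(slices)) slices <- as.integer(strsplit(trimws(slices), "[ ,]+")[[1]])
  pair_id <- if (is.null(r$pair_id)) NA_character_ else as.character(r$pair_id)
  if (identical(r$shape, "circle")) {
    roi_circle(r$label, as.numeric(r$cy), as.numeric(r$cx), as.numeric(r$radius),
               slices = slices, pair_id = pair_id)
  } else if (identical(r$shape, "polygon")) {
    if (!is.null(r$vertices) && is.character(r$vertices)) {
      pts <- do.call(rbind, lapply(strsplit(trimws(r$vertices), ";")[[1]], function(p)
        as.numeric(strsplit(trimws(p), "[ ,]+")[[1]])))
      vy <- pts[, 1]; vx <- pts[, 2]
    } else {
      vy <- as.numeric(unlist(r$vy)); vx <- as.numeric(unlist(r$vx))
    }
    roi_polygon(r$label, vy, vx, slices = slices, pair_id = pair_id)
  } else stop("unknown roi shape: ", r$shape)
}

#' Write regions of interest to CSV
#'
#' @param rois A list of `roi` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(rois, path) {
  rows <- lapply(rois, function(r) {
    data.frame(
      label = r$label, shape = r$shape,
      cy = if (r$shape == "circle") r$cy else NA_real_,
      cx = if (r$shape == "circle") r$cx else NA_real_,
      radius = if (r$shape == "circle") r$radius else NA_real_,
      vertices = if (r$shape == "polygon")
        paste(sprintf("%g %g", r$vy, r$vx), collapse = "; ") else "",
      slices = if (identical(r$slices, "all")) "all"
               else paste(r$slices, collapse = " "),
      pair_id = r$pair_id, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_tiff(matrix(as.integer(mask) * 255L, nrow(mask), ncol(mask)),
             path, bit_depth = 8L)
}

#' Cell annotation
#'
#' Labels attached to a region pair: the cell types of the two siblings and
#' which member is the stem side. Cell identity is always an input (drawn
#' and classified by the experimenter), never computed by this package.
#'
#' @param cell_type One of `"GSC"`, `"GB"`, `"SG"`.
#' @param cycle_stage Free text, e.g. `"telophase"`.
#' @param pair_id Identifier shared by exactly two sibling annotations.
#' @param polarity `"stem"`, `"diff"`, or an arbitrary `"SG1"`/`"SG2"` tag.
#' @return An object of class `cell_annotation`.
#' @export
cell_annotation <- function(cell_type, cycle_stage, pair_id, polarity) {
  cell_type <- match.arg(cell_type, c("GSC", "GB", "SG"))
  structure(list(cell_type = cell_type, cycle_stage = cycle_stage,
                 pair_id = pair_id, polarity = polarity),
            class = "cell_annotation")
}

#' Measurement table
#'
#' The tidy long-format result container shared by all quantification stages:
#' one value per (pair, measure, channel).
#'
#' @param rows A data.frame with columns `pair_id, cell_type, stage, measure,
#'   channel, value, units` (missing columns are filled with `NA`).
#' @param provenance Named list recording source files and parameters.
#' @return A data.frame of class `measurement_table`.
#' @export
measurement_table <- function(rows, provenance = list()) {
  cols <- c("pair_id", "cell_type", "stage", "measure", "channel", "value", "units")
  for (cl in cols) if (!cl %in% names(rows)) rows[[cl]] <- NA
  rows <- rows[, cols]
  if (!all(is.finite(rows$value) | is.na(rows$value)))
    stop("measurement values must be finite or NA")
  key <- paste(rows$pair_id, rows$measure, rows$channel, rows$cell_type)
  if (anyDuplicated(key))
    stop("duplicate (pair_id, measure, channel) entries in measurement table")
  structure(rows, class = c("measurement_table", "data.frame"),
            provenance = provenance)
}

#' Write a measurement table as CSV or JSON
#'
#' @param table A [measurement_table()].
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(provenance = attr(table, "provenance"),
                              rows = as.data.frame(table)),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}
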