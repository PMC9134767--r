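# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the code paths they check.

# point-in-polygon by winding angle sum (vs the package's even-odd ray cast)
oracle_in_polygon <- function(py, px, vy, vx) {
  ang <- atan2(vy - py, vx - px)
  d <- diff(c(ang, ang[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi # winding number != 0
}

# largest inscribed axis-aligned square by exhaustive enumeration
oracle_largest_square <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  best <- list(top = NA, left = NA, side = 0L)
  for (side in seq_len(min(nr, nc))) {
    for (top in seq_len(nr - side + 1L)) {
      for (left in seq_len(nc - side + 1L)) {
        if (all(mask[top:(top + side - 1L), left:(left + side - 1L)])) {
          if (side > best$side ||
              (side == best$side && (top < best$top ||
                (top == best$top && left < best$left)))) {
            # exhaustive scan visits (top, left) in increasing order per side,
            # so the first hit at a given side is already the tie-break winner
            if (side > best$side) best <- list(top = top, left = left, side = side)
          }
        }
      }
    }
  }
  best
}

# masked sum by explicit double loop
oracle_masked_sum <- function(image, mask) {
  s <- 0
  for (i in seq_len(nrow(image))) for (j in seq_len(ncol(image)))
    if (mask[i, j]) s <- s + image[i, j]
  s
}

# Spearman rho by the no-ties rank-difference formula 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman_noties <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group labelings
oracle_mw_exact_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  min_u <- function(idx_a) {
    r <- rank(pooled)
    u_a <- sum(r[idx_a]) - n_a * (n_a + 1) / 2
    min(u_a, n_a * n_b - u_a)
  }
  obs <- min_u(seq_len(n_a))
  combos <- utils::combn(n_a + n_b, n_a)
  us <- apply(combos, 2, min_u)
  mean(us <= obs)
}

# numeric arc length of a polyline by fine sampling
oracle_polyline_length <- function(pts, pixel_size, n_samples = 200000L) {
  seg_d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cum <- c(0, cumsum(seg_d))
  s <- seq(0, cum[length(cum)], length.out = n_samples)
  i <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(seg_d))
  t <- (s - cum[i]) / seg_d[i]
  y <- pts[i, 1] + t * (pts[i + 1L, 1] - pts[i, 1])
  x <- pts[i, 2] + t * (pts[i + 1L, 2] - pts[i, 2])
  sum(sqrt(diff(y)^2 + diff(x)^2)) * pixel_size
}

# rectangle polygon covering exactly `h` x `w` whole pixels starting at (top, left)
rect_roi <- function(label, top, left, h, w, ...) {
  roi_polygon(label,
              vy = c(top - 1, top - 1, top - 1 + h, top - 1 + h),
              vx = c(left - 1, left - 1 + w, left - 1 + w, left - 1), ...)
}

# build a one-channel stack from a list of per-slice matrices
stack_from_slices <- function(slices, channel = "ch", ...) {
  d <- dim(slices[[1]])
  a <- array(0, dim = c(length(slices), d[1], d[2]))
  for (z in seq_along(slices)) a[z, , ] <- slices[[z]]
  image_stack(stats::setNames(list(a), channel), ...)
}
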