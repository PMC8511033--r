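`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
"_PACKAGE"

## Euclidean distance from points (px, py) to the segment (x1,y1)-(x2,y2).
## Vectorized over the points.
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return(sqrt((px - x1)^2 + (py - y1)^2))
  }
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

## Do two segments (given as c(x1, y1, x2, y2)) properly intersect?
segs_intersect <- function(a, b) {
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
  d2 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
  d3 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
  d4 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

## Minimum distance between two segments.
seg_seg_dist <- function(a, b) {
  if (segs_intersect(a, b)) {
    return(0)
  }
  min(
    point_seg_dist(a[1], a[2], b[1], b[2], b[3], b[4]),
    point_seg_dist(a[3], a[4], b[1], b[2], b[3], b[4]),
    point_seg_dist(b[1], b[2], a[1], a[2], a[3], a[4]),
    point_seg_dist(b[3], b[4], a[1], a[2], a[3], a[4])
  )
}

## Shoelace polygon area (vertices in order, not necessarily closed).
poly_area <- function(x, y) {
  n <- length(x)
  if (n < 3) {
    return(0)
  }
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Stationary AR(1) series with marginal standard deviation `sd`.
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0 || n == 0L) {
    return(numeric(n))
  }
  innov_sd <- sd * sqrt(1 - phi^2)
  x0 <- stats::rnorm(1L, 0, sd)
  e <- stats::rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
}

## Round-half-up helper used where printed values are integer percents.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(abs(x) * p + 0.5) / p * sign(x)
}
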