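#' Rasterize a dot-array stimulus
#'
#' Renders the stimulus onto a square luminance grid. Ink is the union of
#' all discs and rectangles, so overlapping items are never double-counted;
#' ink pixels take the black or white luminance level according to the
#' stimulus polarity and all other pixels the background level.
#'
#' @param stim A `dot_array`.
#' @param config A [geometry_config()] (supplies `ppd` and luminances).
#' @param half_extent Half-width of the square rendering field in degrees;
#'   by default just large enough to contain every item plus a margin, so
#'   ink measurement never clips. Pass a fixed value when comparing images
#'   across stimuli (e.g. for Fourier spectra).
#' @param ppd Pixels per degree (defaults to `config$ppd`).
#' @return A list of class `"stimulus_raster"` with elements `image`
#'   (luminance matrix, rows = y), `mask` (logical ink matrix), `ink_area`
#'   (deg^2), `ppd` and `axis` (pixel-center coordinates in degrees).
#' @export
rasterize_stimulus <- function(stim, config, half_extent = NULL, ppd = NULL) {
  ppd <- ppd %||% config$ppd
  stopifnot(ppd > 0)
  d <- stim$dots
  co <- stim$connectors
  if (is.null(half_extent)) {
    ext <- max(abs(c(d$x + d$diameter / 2, d$x - d$diameter / 2,
                     d$y + d$diameter / 2, d$y - d$diameter / 2,
                     if (nrow(co)) c(co$x1, co$x2, co$y1, co$y2) + max(co$width),
                     if (nrow(co)) c(co$x1, co$x2, co$y1, co$y2) - max(co$width))))
    half_extent <- ext + 0.5
  }
  n <- as.integer(2L * ceiling(half_extent * ppd))
  half <- n / (2 * ppd)
  ax <- (seq_len(n) - 0.5) / ppd - half
  mask <- matrix(FALSE, n, n)
  pxm <- 1 / ppd  # one-pixel guard band on bounding boxes
  for (k in seq_len(nrow(d))) {
    r <- d$diameter[k] / 2
    ix <- which(ax >= d$x[k] - r - pxm & ax <= d$x[k] + r + pxm)
    iy <- which(ax >= d$y[k] - r - pxm & ax <= d$y[k] + r + pxm)
    if (!length(ix) || !length(iy)) next
    sub <- outer((ax[iy] - d$y[k])^2, (ax[ix] - d$x[k])^2, "+") <= r^2
    mask[iy, ix] <- mask[iy, ix] | sub
  }
  for (k in seq_len(nrow(co))) {
    w <- co$width[k]
    cx <- (co$x1[k] + co$x2[k]) / 2
    cy <- (co$y1[k] + co$y2[k]) / 2
    len <- sqrt((co$x2[k] - co$x1[k])^2 + (co$y2[k] - co$y1[k])^2)
    u <- c(co$x2[k] - co$x1[k], co$y2[k] - co$y1[k]) / len
    bb <- len / 2 + w / 2 + pxm
    ix <- which(ax >= cx - bb & ax <= cx + bb)
    iy <- which(ax >= cy - bb & ax <= cy + bb)
    if (!length(ix) || !length(iy)) next
    ## coordinates along (t) and across (s) the connector axis
    tmat <- outer((ax[iy] - cy) * u[2], (ax[ix] - cx) * u[1], "+")
    smat <- outer((ax[iy] - cy) * u[1], (ax[ix] - cx) * (-u[2]), "+")
    sub <- abs(tmat) <= len / 2 & abs(smat) <= w / 2
    mask[iy, ix] <- mask[iy, ix] | sub
  }
  lum <- config$luminance
  ink_level <- if (stim$polarity == "black") lum[["min"]] else lum[["max"]]
  img <- matrix(lum[["background"]], n, n)
  img[mask] <- ink_level
  structure(list(image = img, mask = mask, ink_area = sum(mask) / ppd^2,
                 ppd = ppd, axis = ax),
            class = "stimulus_raster")
}

#' Total ink area of a stimulus
#'
#' Union area covered by all dots and connectors, in deg^2, measured on the
#' raster grid.
#'
#' @inheritParams rasterize_stimulus
#' @return Ink area in deg^2.
#' @export
ink_area <- function(stim, config, ppd = NULL) {
  rasterize_stimulus(stim, config, ppd = ppd)$ink_area
}

## Support points for the hull: the outer ink extents (sampled dot
## boundaries and connector rectangle corners), not the dot centers.
hull_support_points <- function(stim, n_circle = 64L) {
  th <- seq(0, 2 * pi, length.out = n_circle + 1L)[-(n_circle + 1L)]
  d <- stim$dots
  pts <- do.call(rbind, lapply(seq_len(nrow(d)), function(k) {
    r <- d$diameter[k] / 2
    cbind(d$x[k] + r * cos(th), d$y[k] + r * sin(th))
  }))
  co <- stim$connectors
  if (nrow(co)) {
    for (k in seq_len(nrow(co))) {
      len <- sqrt((co$x2[k] - co$x1[k])^2 + (co$y2[k] - co$y1[k])^2)
      u <- c(co$x2[k] - co$x1[k], co$y2[k] - co$y1[k]) / len
      v <- c(-u[2], u[1]) * co$width[k] / 2
      pts <- rbind(pts,
                   c(co$x1[k] + v[1], co$y1[k] + v[2]),
                   c(co$x1[k] - v[1], co$y1[k] - v[2]),
                   c(co$x2[k] + v[1], co$y2[k] + v[2]),
                   c(co$x2[k] - v[1], co$y2[k] - v[2]))
    }
  }
  pts
}

#' Convex-hull area of a stimulus
#'
#' Area (deg^2) of the convex hull of the outer ink extents: dot boundaries
#' and connector corners, so the hull measures covered area rather than the
#' spread of the dot centers.
#'
#' @param x A `dot_array`, or a two-column matrix/data.frame of points.
#' @param n_circle Number of boundary samples per dot.
#' @return Hull area in deg^2.
#' @export
convex_hull_area <- function(x, n_circle = 64L) {
  pts <- if (inherits(x, "dot_array")) {
    hull_support_points(x, n_circle)
  } else {
    as.matrix(x)
  }
  stopifnot(ncol(pts) == 2)
  if (nrow(unique(pts)) < 3) stop("degenerate input: fewer than 3 distinct support points")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  area <- poly_area(pts[h, 1], pts[h, 2])
  if (area <= 0) stop("degenerate input: support points are collinear")
  area
}

#' Radially averaged Fourier amplitude spectrum
#'
#' Computes the modulus of the centered 2-D discrete Fourier transform of a
#' (background-subtracted) luminance image and averages it in annular bins
#' of spatial frequency, reporting the profile over a frequency band.
#'
#' @param image Square numeric matrix (luminance).
#' @param ppd Pixels per degree of the image.
#' @param background Background level subtracted before transforming;
#'   defaults to the image mean (removes the DC component).
#' @param band Frequency band in cycles/degree, default 0.3 to 10.
#' @param bin_width Radial bin width in cycles/degree.
#' @return A data.frame of class `"spectrum_profile"` with columns
#'   `frequency` (bin centers, cpd) and `amplitude` (arbitrary units).
#' @export
radial_fourier_amplitude <- function(image, ppd, background = NULL,
                                     band = c(0.3, 10), bin_width = 0.1) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  n <- nrow(image)
  img <- image - (background %||% mean(image))
  amp <- Mod(stats::fft(img))
  half <- n %/% 2
  f1 <- c(0:half, if (n - half - 1L > 0) -((n - half - 1L):1)) * ppd / n
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  centers <- seq(band[1], band[2], by = bin_width)
  edges <- c(centers - bin_width / 2, centers[length(centers)] + bin_width / 2)
  bin <- findInterval(fr, edges)
  sel <- bin >= 1 & bin <= length(centers)
  prof <- vapply(seq_along(centers), function(b) {
    v <- amp[sel & bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out <- data.frame(frequency = centers, amplitude = prof)
  class(out) <- c("spectrum_profile", "data.frame")
  out
}

#' Write a stimulus to disk
#'
#' Writes the stimulus geometry and achieved constraint values as JSON, the
#' radial amplitude spectrum as CSV, and (when the \pkg{png} package is
#' available) the rendered 8-bit grayscale image as PNG.
#'
#' @param stim A `dot_array`.
#' @param path_prefix File path without extension.
#' @param config A [geometry_config()].
#' @param png Write the rendered image too?
#' @return Invisibly, the paths written.
#' @export
write_stimulus <- function(stim, path_prefix, config, png = FALSE) {
  paths <- character(0)
  meta <- list(
    numerosity = stim$numerosity, connectedness = stim$connectedness,
    polarity = stim$polarity, experiment = stim$experiment,
    dots = stim$dots,
    connectors = stim$connectors[, c("x1", "y1", "x2", "y2", "width")],
    achieved = attr(stim, "achieved")
  )
  jp <- paste0(path_prefix, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- c(paths, jp)
  ras <- rasterize_stimulus(stim, config)
  sp <- radial_fourier_amplitude(ras$image, ras$ppd,
                                 background = config$luminance[["background"]])
  cp <- paste0(path_prefix, "_spectrum.csv")
  utils::write.csv(sp, cp, row.names = FALSE)
  paths <- c(paths, cp)
  if (png && requireNamespace("png", quietly = TRUE)) {
    g <- ras$image / max(ras$image)
    pp <- paste0(path_prefix, ".png")
    png::writePNG(g, pp)
    paths <- c(paths, pp)
  }
  invisible(paths)
}
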