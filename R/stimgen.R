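#' Geometry configuration for dot-array stimuli
#'
#' Bundles every geometric parameter needed to build and constraint-match a
#' dot-array stimulus: item sizes, the minimum item separation, the target
#' ink (covered) area and convex-hull area, the placement field, raster
#' resolution and matching tolerances. Defaults reproduce the two stimulus
#' families used in the connectedness-illusion pupillometry experiments:
#' experiment 1 (connecting lines displaced in the isolated condition) and
#' experiment 2 (connecting lines removed and absorbed into the dots).
#'
#' @param experiment 1 or 2, selecting the stimulus family.
#' @param numerosity Number of dots, 18 or 24 in the default designs (other
#'   even counts are accepted and use the nearest default dot diameter).
#' @param min_separation Minimum clearance between item boundaries, degrees.
#' @param dot_diameter Dot diameter in degrees; default depends on
#'   experiment and numerosity (2.2 for 18 dots, 1.9 for 24).
#' @param connector_width Line width, degrees (1.03 for experiment 1, 0.6
#'   for experiment 2).
#' @param connector_length_range Allowed visible line length, degrees.
#' @param target_ink Target total covered area in deg^2 (92.7 / 82.3).
#' @param target_hull Target convex-hull area in deg^2 (513).
#' @param field_radius Radius of the circular placement region, degrees.
#' @param ppd Raster resolution, pixels per degree, used for ink measurement.
#' @param ink_tolerance,hull_tolerance Relative matching tolerances.
#' @param max_iterations Iteration cap for placement and matching loops.
#' @param placement_margin Extra clearance (degrees) demanded at placement
#'   time so that the iterative matching steps cannot push items below
#'   `min_separation`.
#' @param luminance Named vector with `min`, `max` and `background` screen
#'   luminances in cd/m^2, used when rendering.
#' @return A list of class `"geometry_config"`.
#' @export
geometry_config <- function(experiment = 1L,
                            numerosity = 18L,
                            min_separation = 0.5,
                            dot_diameter = NULL,
                            connector_width = NULL,
                            connector_length_range = NULL,
                            target_ink = NULL,
                            target_hull = 513,
                            field_radius = 13.5,
                            ppd = 20,
                            ink_tolerance = 0.005,
                            hull_tolerance = 0.005,
                            max_iterations = 500L,
                            placement_margin = 0.3,
                            luminance = c(min = 12.6, max = 256, background = 129.3)) {
  experiment <- as.integer(experiment)
  stopifnot(experiment %in% c(1L, 2L), numerosity %% 2 == 0, numerosity > 0)
  dot_diameter <- dot_diameter %||% if (numerosity >= 24) 1.9 else 2.2
  connector_width <- connector_width %||% if (experiment == 1L) 1.03 else 0.6
  connector_length_range <- connector_length_range %||%
    if (experiment == 1L) c(2, 3) else c(1.6, 2.8)
  target_ink <- target_ink %||% if (experiment == 1L) 92.7 else 82.3
  stopifnot(
    min_separation >= 0, dot_diameter > 0, connector_width > 0,
    length(connector_length_range) == 2, all(connector_length_range > 0),
    target_ink > 0, target_hull > 0, field_radius > 0, ppd > 0,
    ink_tolerance > 0, hull_tolerance > 0, max_iterations >= 1
  )
  structure(
    list(
      experiment = experiment, numerosity = as.integer(numerosity),
      min_separation = min_separation, dot_diameter = dot_diameter,
      connector_width = connector_width,
      connector_length_range = connector_length_range,
      target_ink = target_ink, target_hull = target_hull,
      field_radius = field_radius, ppd = ppd,
      ink_tolerance = ink_tolerance, hull_tolerance = hull_tolerance,
      max_iterations = as.integer(max_iterations),
      placement_margin = placement_margin, luminance = luminance
    ),
    class = "geometry_config"
  )
}

#' Construct a dot-array stimulus
#'
#' @param dots data.frame with columns `x`, `y`, `diameter` (degrees).
#' @param connectors data.frame with columns `x1`, `y1`, `x2`, `y2`,
#'   `width` and, for connected stimuli, the member dot indices `dot1`,
#'   `dot2` (NA for free-floating lines). May be NULL.
#' @param connectedness One of `"connected"`, `"isolated-displaced"`,
#'   `"isolated-removed"`.
#' @param polarity `"black"` or `"white"`.
#' @param experiment 1 or 2.
#' @return An object of class `"dot_array"`.
#' @export
dot_array <- function(dots, connectors = NULL,
                      connectedness = c("isolated-displaced", "connected",
                                        "isolated-removed"),
                      polarity = c("white", "black"), experiment = 1L) {
  connectedness <- match.arg(connectedness)
  polarity <- match.arg(polarity)
  dots <- as.data.frame(dots)
  stopifnot(all(c("x", "y", "diameter") %in% names(dots)),
            all(dots$diameter > 0))
  if (is.null(connectors)) {
    connectors <- data.frame(x1 = numeric(0), y1 = numeric(0),
                             x2 = numeric(0), y2 = numeric(0),
                             width = numeric(0), dot1 = integer(0),
                             dot2 = integer(0))
  } else {
    connectors <- as.data.frame(connectors)
    if (is.null(connectors$dot1)) connectors$dot1 <- NA_integer_
    if (is.null(connectors$dot2)) connectors$dot2 <- NA_integer_
    stopifnot(all(connectors$width > 0))
    len <- sqrt((connectors$x2 - connectors$x1)^2 +
                  (connectors$y2 - connectors$y1)^2)
    stopifnot(all(len > 0))
  }
  n <- nrow(dots)
  if (connectedness == "connected") {
    stopifnot(nrow(connectors) == n / 2,
              !anyNA(connectors$dot1), !anyNA(connectors$dot2))
    used <- c(connectors$dot1, connectors$dot2)
    stopifnot(sort(used) == seq_len(n))
  }
  if (connectedness == "isolated-removed") stopifnot(nrow(connectors) == 0)
  structure(
    list(dots = dots, connectors = connectors, numerosity = n,
         connectedness = connectedness, polarity = polarity,
         experiment = as.integer(experiment)),
    class = "dot_array"
  )
}

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("Dot-array stimulus: %d %s dots (%s, experiment %d), %d connector(s)\n",
              x$numerosity, x$polarity, x$connectedness, x$experiment,
              nrow(x$connectors)))
  ach <- attr(x, "achieved")
  if (!is.null(ach)) {
    cat(sprintf("  ink %.1f deg^2, hull %.1f deg^2 (%d matching iterations)\n",
                ach$ink, ach$hull, ach$iterations %||% 0L))
  }
  invisible(x)
}

connector_length <- function(connectors) {
  sqrt((connectors$x2 - connectors$x1)^2 + (connectors$y2 - connectors$y1)^2)
}

#' Minimum clearance between stimulus items
#'
#' Smallest boundary-to-boundary distance over all pairs of items (dots and
#' connectors). For connected stimuli the clearance between a connector and
#' the two dots it joins is ignored (they touch by construction).
#'
#' @param stim A `dot_array`.
#' @return Minimum clearance in degrees (Inf for a single item).
#' @export
min_clearance <- function(stim) {
  d <- stim$dots
  co <- stim$connectors
  r <- d$diameter / 2
  cl <- Inf
  nd <- nrow(d)
  nc <- nrow(co)
  if (nd > 1) {
    dm <- as.matrix(stats::dist(cbind(d$x, d$y)))
    gap <- dm - outer(r, r, "+")
    cl <- min(cl, min(gap[upper.tri(gap)]))
  }
  if (nc > 0 && nd > 0) {
    for (k in seq_len(nc)) {
      dist_k <- point_seg_dist(d$x, d$y, co$x1[k], co$y1[k], co$x2[k], co$y2[k]) -
        r - co$width[k] / 2
      skip <- c(co$dot1[k], co$dot2[k])
      skip <- skip[!is.na(skip)]
      if (length(skip)) dist_k[skip] <- Inf
      cl <- min(cl, min(dist_k))
    }
  }
  if (nc > 1) {
    for (k in seq_len(nc - 1L)) {
      for (l in (k + 1L):nc) {
        cl <- min(cl, seg_seg_dist(unlist(co[k, c("x1", "y1", "x2", "y2")]),
                                   unlist(co[l, c("x1", "y1", "x2", "y2")])) -
                    co$width[k] / 2 - co$width[l] / 2)
      }
    }
  }
  cl
}

## Clearance of a candidate disc against existing items.
cand_dot_clearance <- function(cx, cy, r, dots, conns) {
  cl <- Inf
  if (nrow(dots)) {
    cl <- min(cl, sqrt((dots$x - cx)^2 + (dots$y - cy)^2) -
                dots$diameter / 2 - r)
  }
  if (nrow(conns)) {
    for (k in seq_len(nrow(conns))) {
      cl <- min(cl, point_seg_dist(cx, cy, conns$x1[k], conns$y1[k],
                                   conns$x2[k], conns$y2[k]) -
                  conns$width[k] / 2 - r)
    }
  }
  cl
}

## Clearance of a candidate segment (with half-width w/2) against items.
cand_seg_clearance <- function(seg, w, dots, conns) {
  cl <- Inf
  if (nrow(dots)) {
    cl <- min(cl, point_seg_dist(dots$x, dots$y, seg[1], seg[2],
                                 seg[3], seg[4]) -
                dots$diameter / 2 - w / 2)
  }
  if (nrow(conns)) {
    for (k in seq_len(nrow(conns))) {
      cl <- min(cl, seg_seg_dist(seg, unlist(conns[k, c("x1", "y1", "x2", "y2")])) -
                  conns$width[k] / 2 - w / 2)
    }
  }
  cl
}

#' Randomly place dots and candidate line positions
#'
#' Builds the unconnected (isolated) layout: `n_dots` dots placed as
#' `n_dots / 2` dot pairs whose boundary separation falls inside the
#' configured connector length range (so that a dumbbell pairing exists),
#' plus `n_dots / 2` free-floating candidate lines. All item clearances
#' respect the minimum separation with the configured placement margin, and
#' every item lies inside the circular placement field.
#'
#' @param n_dots Even number of dots.
#' @param config A [geometry_config()].
#' @param seed Optional integer seed for reproducible layouts.
#' @return A `dot_array` with connectedness `"isolated-displaced"`.
#' @export
place_items <- function(n_dots, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_dots <- as.integer(n_dots)
  if (n_dots %% 2L != 0L) stop("n_dots must be even")
  r <- config$dot_diameter / 2
  lr <- config$connector_length_range
  clear <- config$min_separation + config$placement_margin
  R <- config$field_radius
  if (R < r + max(lr) / 2) {
    stop(sprintf(paste0("placement failed: field_radius %.2f cannot hold a ",
                        "dot pair at min_separation %.2f"),
                 R, config$min_separation))
  }
  dots <- data.frame(x = numeric(0), y = numeric(0), diameter = numeric(0))
  conns <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), width = numeric(0),
                      dot1 = integer(0), dot2 = integer(0))
  rand_point <- function(rmax) {
    a <- stats::runif(1, 0, 2 * pi)
    rad <- rmax * sqrt(stats::runif(1))
    c(rad * cos(a), rad * sin(a))
  }
  ## dot pairs
  for (p in seq_len(n_dots / 2L)) {
    placed <- FALSE
    for (it in seq_len(config$max_iterations)) {
      len <- stats::runif(1, lr[1], lr[2])
      dcent <- len + 2 * r
      th <- stats::runif(1, 0, 2 * pi)
      mid <- rand_point(max(R - dcent / 2 - r, 0))
      p1 <- mid + dcent / 2 * c(cos(th), sin(th))
      p2 <- mid - dcent / 2 * c(cos(th), sin(th))
      if (sqrt(sum(p1^2)) + r > R || sqrt(sum(p2^2)) + r > R) next
      if (cand_dot_clearance(p1[1], p1[2], r, dots, conns) < clear) next
      if (cand_dot_clearance(p2[1], p2[2], r, dots, conns) < clear) next
      dots[nrow(dots) + 1L, ] <- list(p1[1], p1[2], config$dot_diameter)
      dots[nrow(dots) + 1L, ] <- list(p2[1], p2[2], config$dot_diameter)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(paste0("placement failed after %d attempts: cannot place ",
                          "dot pair %d at min_separation %.2f inside ",
                          "field_radius %.2f"),
                   config$max_iterations, p, config$min_separation, R))
    }
  }
  ## free candidate lines
  w <- config$connector_width
  for (q in seq_len(n_dots / 2L)) {
    placed <- FALSE
    for (it in seq_len(config$max_iterations)) {
      len <- stats::runif(1, lr[1], lr[2])
      th <- stats::runif(1, 0, 2 * pi)
      mid <- rand_point(max(R - len / 2 - w / 2, 0))
      seg <- c(mid - len / 2 * c(cos(th), sin(th)),
               mid + len / 2 * c(cos(th), sin(th)))
      if (max(sqrt(seg[1]^2 + seg[2]^2), sqrt(seg[3]^2 + seg[4]^2)) + w / 2 > R) next
      if (cand_seg_clearance(seg, w, dots, conns) < clear) next
      conns[nrow(conns) + 1L, ] <- list(seg[1], seg[2], seg[3], seg[4], w,
                                        NA_integer_, NA_integer_)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(paste0("placement failed after %d attempts: cannot place ",
                          "line %d at min_separation %.2f inside ",
                          "field_radius %.2f"),
                   config$max_iterations, q, config$min_separation, R))
    }
  }
  dot_array(dots, conns, connectedness = "isolated-displaced",
            experiment = config$experiment)
}

## Rebuild connectors from dot centers for a connected stimulus: endpoints
## sit on the dot boundaries along the center-to-center line.
rebuild_connectors <- function(dots, pairs, width) {
  out <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                    y2 = numeric(0), width = numeric(0),
                    dot1 = integer(0), dot2 = integer(0))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$dot1[k]
    j <- pairs$dot2[k]
    v <- c(dots$x[j] - dots$x[i], dots$y[j] - dots$y[i])
    dcent <- sqrt(sum(v^2))
    u <- v / dcent
    ri <- dots$diameter[i] / 2
    rj <- dots$diameter[j] / 2
    a <- c(dots$x[i], dots$y[i]) + ri * u
    b <- c(dots$x[j], dots$y[j]) - rj * u
    out[k, ] <- list(a[1], a[2], b[1], b[2], width, i, j)
  }
  out
}

#' Connect dot pairs into dumbbells
#'
#' Finds a perfect matching of the dots such that each matched pair's
#' boundary separation lies within the configured connector length range,
#' then joins each pair with a line (endpoints on the dot boundaries).
#' Free-floating candidate lines in the input layout are discarded.
#'
#' @param layout A `dot_array` with an even number of dots.
#' @param config A [geometry_config()].
#' @param seed Optional seed controlling the randomized pairing search.
#' @return A connected `dot_array` with `numerosity / 2` connectors.
#' @export
connect_pairs <- function(layout, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- layout$dots
  n <- nrow(d)
  if (n %% 2L != 0L) stop("numerosity must be even")
  r <- d$diameter / 2
  dm <- as.matrix(stats::dist(cbind(d$x, d$y))) - outer(r, r, "+")
  lr <- config$connector_length_range
  feasible <- dm >= lr[1] & dm <= lr[2]
  diag(feasible) <- FALSE
  if (any(rowSums(feasible) == 0)) {
    stop("no valid pairing: some dots have no partner within the connector length range")
  }
  ## randomized greedy matching with restarts
  for (restart in seq_len(max(config$max_iterations, 200L))) {
    order_ <- sample.int(n)
    used <- logical(n)
    pairs <- data.frame(dot1 = integer(0), dot2 = integer(0))
    ok <- TRUE
    for (i in order_) {
      if (used[i]) next
      cand <- which(feasible[i, ] & !used)
      cand <- setdiff(cand, i)
      if (!length(cand)) {
        ok <- FALSE
        break
      }
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      used[i] <- used[j] <- TRUE
      pairs[nrow(pairs) + 1L, ] <- list(i, j)
    }
    if (ok) {
      conns <- rebuild_connectors(d, pairs, config$connector_width)
      out <- dot_array(d, conns, connectedness = "connected",
                       polarity = layout$polarity,
                       experiment = layout$experiment)
      return(out)
    }
  }
  stop("no valid pairing within the connector length range was found")
}

#' Isolate a connected stimulus by displacing its lines
#'
#' Keeps the dots, and moves each connector to a random free position
#' (preserving its length and width) with the required clearance from every
#' other item. This is the experiment-1 isolated control.
#'
#' @param connected A connected `dot_array`.
#' @param config A [geometry_config()].
#' @param seed Optional seed.
#' @return A `dot_array` with connectedness `"isolated-displaced"`.
#' @export
isolate_by_displacement <- function(connected, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(connected$connectors) == 0) {
    return(connected)
  }
  d <- connected$dots
  lens <- connector_length(connected$connectors)
  widths <- connected$connectors$width
  clear <- config$min_separation + config$placement_margin
  R <- config$field_radius
  conns <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), width = numeric(0),
                      dot1 = integer(0), dot2 = integer(0))
  for (k in seq_along(lens)) {
    placed <- FALSE
    for (it in seq_len(config$max_iterations)) {
      th <- stats::runif(1, 0, 2 * pi)
      a <- stats::runif(1, 0, 2 * pi)
      rad <- max(R - lens[k] / 2 - widths[k] / 2, 0) * sqrt(stats::runif(1))
      mid <- c(rad * cos(a), rad * sin(a))
      seg <- c(mid - lens[k] / 2 * c(cos(th), sin(th)),
               mid + lens[k] / 2 * c(cos(th), sin(th)))
      if (cand_seg_clearance(seg, widths[k], d, conns) < clear) next
      conns[nrow(conns) + 1L, ] <- list(seg[1], seg[2], seg[3], seg[4],
                                        widths[k], NA_integer_, NA_integer_)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(paste0("placement failed after %d attempts: cannot ",
                          "displace line %d at min_separation %.2f"),
                   config$max_iterations, k, config$min_separation))
    }
  }
  dot_array(d, conns, connectedness = "isolated-displaced",
            polarity = connected$polarity, experiment = connected$experiment)
}

#' Isolate a connected stimulus by removing its lines
#'
#' Removes the connectors and enlarges the dots so that the total ink area
#' (measured on the raster union) matches that of the connected input within
#' half the configured ink tolerance. This is the experiment-2 isolated
#' control ("lines absorbed into the dots").
#'
#' @param connected A connected `dot_array`.
#' @param config A [geometry_config()].
#' @return A `dot_array` with connectedness `"isolated-removed"`.
#' @export
isolate_by_removal <- function(connected, config) {
  target <- ink_area(connected, config)
  d <- connected$dots
  out <- dot_array(d, NULL, connectedness = "isolated-removed",
                   polarity = connected$polarity,
                   experiment = connected$experiment)
  tol <- config$ink_tolerance / 2
  for (it in seq_len(50L)) {
    ink <- ink_area(out, config)
    if (abs(ink - target) <= tol * target) break
    area <- pi * (out$dots$diameter / 2)^2 + (target - ink) / nrow(out$dots)
    if (any(area <= 0)) stop("ink matching drove a dot area non-positive")
    out$dots$diameter <- 2 * sqrt(area / pi)
  }
  out
}

#' Iteratively match ink and convex hull to a reference
#'
#' Alternates an ink-adjustment step (connected: symmetric stretching of the
#' pair separations; displaced lines: symmetric stretching of the line
#' lengths; removed lines: uniform adjustment of the dot areas) with a hull
#' adjustment step (radial scaling of all item positions about fixation),
#' until the rasterized ink area and the convex-hull area both sit within
#' half the configured tolerances of the reference. The halved internal
#' threshold guarantees that any two stimuli matched to the same reference
#' differ by at most the full tolerance.
#'
#' @param stim The `dot_array` to adjust.
#' @param reference Either a `dot_array` (its measured ink and hull become
#'   the targets) or a list with elements `ink` and `hull` (deg^2).
#' @param config A [geometry_config()].
#' @return The adjusted `dot_array`, with an `achieved` attribute recording
#'   the final ink, hull and iteration count.
#' @export
match_constraints <- function(stim, reference, config) {
  tgt <- if (inherits(reference, "dot_array")) {
    list(ink = ink_area(reference, config),
         hull = convex_hull_area(reference))
  } else {
    stopifnot(!is.null(reference$ink), !is.null(reference$hull))
    reference
  }
  tol_i <- config$ink_tolerance / 2
  tol_h <- config$hull_tolerance / 2
  pairs <- stim$connectors[, c("dot1", "dot2")]
  iterations <- 0L
  for (it in seq_len(config$max_iterations)) {
    ink <- ink_area(stim, config)
    hull <- convex_hull_area(stim)
    ei <- (tgt$ink - ink) / tgt$ink
    eh <- (tgt$hull - hull) / tgt$hull
    if (abs(ei) <= tol_i && abs(eh) <= tol_h) {
      if (min_clearance(stim) < config$min_separation - 1e-9) {
        stop("constraint matching violated the minimum separation")
      }
      attr(stim, "achieved") <- list(ink = ink, hull = hull,
                                     iterations = iterations)
      return(stim)
    }
    iterations <- iterations + 1L
    if (abs(ei) > tol_i) {
      stim <- adjust_ink(stim, tgt$ink - ink, config, pairs)
    }
    if (abs(eh) > tol_h) {
      hull2 <- convex_hull_area(stim)
      stim <- adjust_hull(stim, sqrt(tgt$hull / hull2), config, pairs)
    }
  }
  stop(sprintf(paste0("constraint matching did not converge after %d ",
                      "iterations (ink residual %.2f%%, hull residual %.2f%%)"),
               config$max_iterations, 100 * abs(ei), 100 * abs(eh)))
}

adjust_ink <- function(stim, delta_ink, config, pairs) {
  if (stim$connectedness == "connected") {
    nconn <- nrow(stim$connectors)
    dl <- delta_ink / (nconn * config$connector_width)
    for (k in seq_len(nconn)) {
      i <- pairs$dot1[k]
      j <- pairs$dot2[k]
      v <- c(stim$dots$x[j] - stim$dots$x[i], stim$dots$y[j] - stim$dots$y[i])
      dcent <- sqrt(sum(v^2))
      u <- v / dcent
      ri <- stim$dots$diameter[i] / 2
      rj <- stim$dots$diameter[j] / 2
      new_len <- max(dcent - ri - rj + dl, 0.2)
      shift <- (new_len - (dcent - ri - rj)) / 2
      stim$dots$x[i] <- stim$dots$x[i] - shift * u[1]
      stim$dots$y[i] <- stim$dots$y[i] - shift * u[2]
      stim$dots$x[j] <- stim$dots$x[j] + shift * u[1]
      stim$dots$y[j] <- stim$dots$y[j] + shift * u[2]
    }
    stim$connectors <- rebuild_connectors(stim$dots, pairs,
                                          config$connector_width)
  } else if (stim$connectedness == "isolated-displaced") {
    co <- stim$connectors
    nconn <- nrow(co)
    if (nconn == 0) return(stim)
    dl <- delta_ink / (nconn * mean(co$width))
    for (k in seq_len(nconn)) {
      mx <- (co$x1[k] + co$x2[k]) / 2
      my <- (co$y1[k] + co$y2[k]) / 2
      len <- sqrt((co$x2[k] - co$x1[k])^2 + (co$y2[k] - co$y1[k])^2)
      u <- c(co$x2[k] - co$x1[k], co$y2[k] - co$y1[k]) / len
      new_len <- max(len + dl, 0.2)
      co$x1[k] <- mx - new_len / 2 * u[1]
      co$y1[k] <- my - new_len / 2 * u[2]
      co$x2[k] <- mx + new_len / 2 * u[1]
      co$y2[k] <- my + new_len / 2 * u[2]
    }
    stim$connectors <- co
  } else {
    area <- pi * (stim$dots$diameter / 2)^2 + delta_ink / nrow(stim$dots)
    if (any(area <= 0)) stop("ink matching drove a dot area non-positive")
    stim$dots$diameter <- 2 * sqrt(area / pi)
  }
  stim
}

adjust_hull <- function(stim, s, config, pairs) {
  stim$dots$x <- stim$dots$x * s
  stim$dots$y <- stim$dots$y * s
  if (stim$connectedness == "connected") {
    stim$connectors <- rebuild_connectors(stim$dots, pairs,
                                          config$connector_width)
  } else if (nrow(stim$connectors) > 0) {
    co <- stim$connectors
    mx <- (co$x1 + co$x2) / 2 * s
    my <- (co$y1 + co$y2) / 2 * s
    hx <- (co$x2 - co$x1) / 2
    hy <- (co$y2 - co$y1) / 2
    co$x1 <- mx - hx
    co$y1 <- my - hy
    co$x2 <- mx + hx
    co$y2 <- my + hy
    stim$connectors <- co
  }
  stim
}

#' Generate a full constraint-matched condition set
#'
#' Builds, for each requested numerosity, a connected stimulus and its
#' isolated control (displaced lines for experiment 1, removed lines for
#' experiment 2), with every stimulus matched to the experiment's target
#' ink area and to the common 513 deg^2 convex hull.
#'
#' @param experiment 1 or 2.
#' @param seed Integer seed; the whole set is reproducible from it.
#' @param numerosities Dot counts to generate (default both 18 and 24).
#' @param polarity `"white"` or `"black"` label attached to the stimuli
#'   (geometry is polarity-invariant).
#' @return A list of class `"stimulus_set"` with one `dot_array` per
#'   condition, named e.g. `"N18_connected"`, and a `summary` attribute
#'   (data.frame of achieved ink and hull areas).
#' @export
generate_stimulus_set <- function(experiment = 1L, seed = 1L,
                                  numerosities = c(18L, 24L),
                                  polarity = "white") {
  out <- list()
  summ <- data.frame()
  for (i in seq_along(numerosities)) {
    nn <- numerosities[i]
    cfg <- geometry_config(experiment, nn)
    res <- NULL
    for (attempt in 0:4) {
      seed_k <- as.integer(seed + 1000L * (i - 1L) + attempt)
      res <- tryCatch({
        layout <- place_items(nn, cfg, seed = seed_k)
        conn <- connect_pairs(layout, cfg, seed = seed_k + 100L)
        conn <- match_constraints(conn, list(ink = cfg$target_ink,
                                             hull = cfg$target_hull), cfg)
        iso <- if (experiment == 1L) {
          isolate_by_displacement(conn, cfg, seed = seed_k + 200L)
        } else {
          isolate_by_removal(conn, cfg)
        }
        iso <- match_constraints(iso, list(ink = cfg$target_ink,
                                           hull = cfg$target_hull), cfg)
        list(conn = conn, iso = iso)
      }, error = function(e) NULL)
      if (!is.null(res)) break
    }
    if (is.null(res)) {
      stop(sprintf("stimulus set generation failed for numerosity %d", nn))
    }
    res$conn$polarity <- polarity
    res$iso$polarity <- polarity
    out[[sprintf("N%d_connected", nn)]] <- res$conn
    out[[sprintf("N%d_isolated", nn)]] <- res$iso
    for (s in list(res$conn, res$iso)) {
      ach <- attr(s, "achieved")
      summ <- rbind(summ, data.frame(
        experiment = experiment, numerosity = nn,
        connectedness = s$connectedness, ink = ach$ink, hull = ach$hull,
        iterations = ach$iterations
      ))
    }
  }
  structure(out, summary = summ, class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Constraint-matched stimulus set\n")
  print(attr(x, "summary"))
  invisible(x)
}
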