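#' Construct a pupil trace
#'
#' A uniform-rate recording of pupil diameter and gaze position with a
#' per-sample validity flag.
#'
#' @param pupil Pupil diameter, mm.
#' @param sampling_rate Sampling rate in Hz.
#' @param time Sample times in seconds (default `0, 1/rate, ...`).
#' @param gaze_x,gaze_y Gaze position in degrees.
#' @param valid Logical validity flags.
#' @return A data.frame of class `"pupil_trace"` with attribute
#'   `sampling_rate`.
#' @export
pupil_trace <- function(pupil, sampling_rate, time = NULL,
                        gaze_x = 0, gaze_y = 0, valid = TRUE) {
  n <- length(pupil)
  time <- time %||% ((seq_len(n) - 1L) / sampling_rate)
  stopifnot(length(time) == n, sampling_rate > 0)
  dt <- 1 / sampling_rate
  if (n > 1 && max(abs(diff(time) - dt)) > 1e-6 * dt) {
    stop("time must be a uniform grid at the stated sampling rate")
  }
  out <- data.frame(time = time, pupil = pupil,
                    gaze_x = rep_len(gaze_x, n), gaze_y = rep_len(gaze_y, n),
                    valid = rep_len(valid, n))
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("pupil_trace", "data.frame")
  out
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("Pupil trace: %d samples at %g Hz (%.1f s), %.1f%% valid\n",
              nrow(x), attr(x, "sampling_rate"),
              nrow(x) / attr(x, "sampling_rate"), 100 * mean(x$valid)))
  invisible(x)
}

sampling_rate <- function(trace) attr(trace, "sampling_rate")

#' Mark artifactual samples invalid
#'
#' Applies the three exclusion rules for blinks and signal losses: a sample
#' is invalid if the pupil is unrealistically small (`< min_pupil` mm), if
#' it deviates by more than `max_deviation` mm from the median of its trial
#' (computed on the raw span from 1 s before onset to 1 s after offset,
#' before any masking), or if it falls within a `pad_ms` window centered on
#' any sample whose absolute rate of change exceeds `max_velocity` mm/s
#' (the first difference is attributed to both bracketing samples). Masks
#' only ever grow: already-invalid samples stay invalid.
#'
#' @param trace A [pupil_trace()].
#' @param events Optional event table (`onset_s`, `offset_s` columns) that
#'   defines the trial spans for the median rule; outside any trial the
#'   whole-trace median is used.
#' @param min_pupil,max_deviation,max_velocity,pad_ms Rule thresholds.
#' @return The trace with its `valid` column updated.
#' @export
mark_invalid <- function(trace, events = NULL, min_pupil = 0.1,
                         max_deviation = 1, max_velocity = 25, pad_ms = 20) {
  fs <- sampling_rate(trace)
  if (is.null(fs)) stop("trace has no sampling_rate attribute")
  p <- trace$pupil
  n <- length(p)
  bad <- !is.finite(p) | p < min_pupil
  med <- rep(stats::median(p, na.rm = TRUE), n)
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      idx <- which(trace$time >= events$onset_s[k] - 1 &
                     trace$time <= events$offset_s[k] + 1)
      if (length(idx)) med[idx] <- stats::median(p[idx], na.rm = TRUE)
    }
  }
  bad <- bad | (is.finite(p) & abs(p - med) > max_deviation)
  if (n > 1) {
    v <- diff(p) * fs
    fast <- which(is.finite(v) & abs(v) > max_velocity)
    if (length(fast)) {
      centers <- unique(c(fast, fast + 1L))
      half <- ceiling(pad_ms / 2000 * fs)
      idx <- unique(as.vector(outer(centers, (-half):half, "+")))
      idx <- idx[idx >= 1L & idx <= n]
      bad[idx] <- TRUE
    }
  }
  trace$valid <- trace$valid & !bad
  trace
}

#' Downsample a trace by bin averaging
#'
#' Each output sample is the mean of the valid input samples in its bin
#' (500 Hz to 20 Hz uses 25-sample bins); bins with no valid sample are
#' marked invalid. Bin times are bin centers.
#'
#' @param trace A [pupil_trace()].
#' @param target_rate Output rate in Hz; must divide the input rate.
#' @return A [pupil_trace()] at `target_rate`.
#' @export
downsample_trace <- function(trace, target_rate = 20) {
  fs <- sampling_rate(trace)
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9) {
    stop("target_rate must divide the sampling rate evenly")
  }
  fac <- as.integer(round(fac))
  n <- nrow(trace)
  nb <- n %/% fac
  if (nb == 0L) stop("trace too short to downsample")
  keep <- seq_len(nb * fac)
  g <- rep(seq_len(nb), each = fac)
  v <- as.numeric(trace$valid[keep])
  nv <- rowsum(v, g)[, 1]
  wmean <- function(x) {
    s <- rowsum(ifelse(trace$valid[keep], x[keep], 0), g)[, 1]
    out <- s / nv
    out[nv == 0] <- NA_real_
    out
  }
  pupil_trace(
    pupil = wmean(trace$pupil),
    sampling_rate = target_rate,
    time = rowsum(trace$time[keep], g)[, 1] / fac,
    gaze_x = wmean(trace$gaze_x),
    gaze_y = wmean(trace$gaze_y),
    valid = nv > 0
  )
}

#' Square-window (boxcar) filtering of a trace
#'
#' Convolves the pupil channel with a unit-area square window of the given
#' duration, i.e. a centered moving average, normalizing by the valid
#' weight inside the window so that invalid samples never contribute. The
#' default mode returns the moving average itself (the stated convolution);
#' `mode = "subtract"` instead removes the moving average from the trace (a
#' true high-pass variant, off by default because it also removes sustained
#' stimulus-driven components).
#'
#' @param trace A [pupil_trace()].
#' @param window_ms Window length in ms (default 500).
#' @param mode `"smooth"` (default) or `"subtract"`.
#' @return The filtered [pupil_trace()].
#' @export
square_window_filter <- function(trace, window_ms = 500,
                                 mode = c("smooth", "subtract")) {
  mode <- match.arg(mode)
  fs <- sampling_rate(trace)
  w <- max(1L, as.integer(round(window_ms / 1000 * fs)))
  if (window_ms / 1000 < 1 / fs) stop("window shorter than one sample period")
  v <- as.numeric(trace$valid)
  x <- ifelse(trace$valid & is.finite(trace$pupil), trace$pupil, 0)
  kern <- rep(1, w)
  num <- stats::filter(x * v, kern, sides = 2)
  den <- stats::filter(v, kern, sides = 2)
  sm <- as.numeric(num) / as.numeric(den)
  ## filter() leaves NAs at the edges; fall back to the raw samples there
  edge <- is.na(sm) & trace$valid
  sm[edge] <- trace$pupil[edge]
  out <- trace
  out$pupil <- if (mode == "smooth") sm else trace$pupil - sm
  out$valid <- trace$valid & !is.na(sm)
  out
}

#' Cut a trace into baseline-corrected epochs
#'
#' Extracts per-trial epochs on a common relative-time grid and subtracts
#' each trial's mean pupil diameter over the `baseline_ms` window preceding
#' stimulus onset. Epochs whose baseline window holds no valid sample are
#' dropped with a warning.
#'
#' @param trace A (preprocessed) [pupil_trace()].
#' @param events Event table with `onset_s` and condition columns.
#' @param pre,post Epoch extent in seconds before/after onset.
#' @param baseline_ms Baseline window length, ms.
#' @return An object of class `"pupil_epochs"`: list with `rel_time`,
#'   trial-by-time matrices `pupil` (baseline-corrected) and `valid`, gaze
#'   matrices, and the retained `events`.
#' @export
epoch_and_baseline <- function(trace, events, pre = 1, post = 7,
                               baseline_ms = 200) {
  fs <- sampling_rate(trace)
  rel_idx <- seq.int(-round(pre * fs), round(post * fs) - 1L)
  rel_time <- rel_idx / fs
  nt <- nrow(events)
  m <- matrix(NA_real_, nt, length(rel_idx))
  vm <- matrix(FALSE, nt, length(rel_idx))
  gx <- matrix(NA_real_, nt, length(rel_idx))
  gy <- matrix(NA_real_, nt, length(rel_idx))
  base <- numeric(nt)
  keep <- logical(nt)
  bwin <- rel_time >= -baseline_ms / 1000 & rel_time < 0
  for (k in seq_len(nt)) {
    oi <- which.min(abs(trace$time - events$onset_s[k]))
    idx <- oi + rel_idx
    if (idx[1] < 1L || idx[length(idx)] > nrow(trace)) {
      stop(sprintf("event %d extends outside the trace", k))
    }
    p <- trace$pupil[idx]
    v <- trace$valid[idx] & is.finite(p)
    bv <- v & bwin
    if (!any(bv)) {
      keep[k] <- FALSE
      next
    }
    base[k] <- mean(p[bv])
    m[k, ] <- p - base[k]
    vm[k, ] <- v
    gx[k, ] <- trace$gaze_x[idx]
    gy[k, ] <- trace$gaze_y[idx]
    keep[k] <- TRUE
  }
  if (!all(keep)) {
    warning(sprintf("dropped %d epoch(s) with no valid baseline sample",
                    sum(!keep)))
  }
  structure(
    list(rel_time = rel_time, pupil = m[keep, , drop = FALSE],
         valid = vm[keep, , drop = FALSE],
         gaze_x = gx[keep, , drop = FALSE], gaze_y = gy[keep, , drop = FALSE],
         events = events[keep, , drop = FALSE],
         baseline = base[keep]),
    class = "pupil_epochs"
  )
}

#' @export
print.pupil_epochs <- function(x, ...) {
  cat(sprintf("Pupil epochs: %d trials x %d samples (%.1f to %.1f s)\n",
              nrow(x$pupil), length(x$rel_time), min(x$rel_time),
              max(x$rel_time)))
  invisible(x)
}

#' Average epochs into a condition time course
#'
#' Validity-aware mean across a subset of trials: each time point averages
#' the valid samples only, and carries the count of contributing trials.
#'
#' @param epochs A [epoch_and_baseline()] result.
#' @param which Logical or integer selection of trials (default all).
#' @return An `epoch_average` data.frame with `rel_time`, `pupil`, `n`
#'   (contributing trials) and `valid`.
#' @export
average_epochs <- function(epochs, which = NULL) {
  sel <- which %||% seq_len(nrow(epochs$pupil))
  p <- epochs$pupil[sel, , drop = FALSE]
  v <- epochs$valid[sel, , drop = FALSE]
  n <- colSums(v)
  num <- colSums(ifelse(v, p, 0))
  avg <- num / n
  avg[n == 0] <- NA_real_
  out <- data.frame(rel_time = epochs$rel_time, pupil = avg,
                    n = as.integer(n), valid = n > 0)
  class(out) <- c("epoch_average", "data.frame")
  out
}

#' Full preprocessing chain
#'
#' Applies the preprocessing stages in their fixed order: artifact masking,
#' downsampling to the analysis rate, square-window filtering, and
#' epoching with baseline correction.
#'
#' @param trace Raw [pupil_trace()].
#' @param events Event table.
#' @param target_rate Analysis rate, Hz.
#' @param window_ms Filter window, ms.
#' @param filter_mode `"smooth"` or `"subtract"` (see
#'   [square_window_filter()]).
#' @param pre,post,baseline_ms Epoching parameters.
#' @return A `pupil_epochs` object.
#' @export
preprocess_trace <- function(trace, events, target_rate = 20,
                             window_ms = 500, filter_mode = "smooth",
                             pre = 1, post = 7, baseline_ms = 200) {
  trace <- mark_invalid(trace, events)
  trace <- downsample_trace(trace, target_rate)
  trace <- square_window_filter(trace, window_ms, mode = filter_mode)
  epoch_and_baseline(trace, events, pre = pre, post = post,
                     baseline_ms = baseline_ms)
}
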