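#' Pupil response function parameters
#'
#' The pupil impulse response is a shifted Gamma density with an integer
#' number of filter stages `n`, a change-rate constant `tau` and an onset
#' delay `delta`. `tau` and `delta` are in milliseconds; the constraint
#' boxes (1-8, 10-800 ms, 0-200 ms) are the ranges within which the
#' per-observer fit is performed.
#'
#' @param n Integer number of filters, 1..8.
#' @param tau Change rate in milliseconds, 10..800.
#' @param delta Response delay in milliseconds, 0..200.
#' @return A list of class `"prf_params"`.
#' @export
prf_params <- function(n = 4L, tau = 250, delta = 100) {
  if (length(n) != 1 || n < 1 || n > 8 || n != round(n)) {
    stop("n must be an integer between 1 and 8")
  }
  if (length(tau) != 1 || tau < 10 || tau > 800) {
    stop("tau must lie in [10, 800] ms")
  }
  if (length(delta) != 1 || delta < 0 || delta > 200) {
    stop("delta must lie in [0, 200] ms")
  }
  structure(list(n = as.integer(n), tau = as.numeric(tau),
                 delta = as.numeric(delta)),
            class = "prf_params")
}

#' @export
print.prf_params <- function(x, ...) {
  cat(sprintf("Gamma pupil response function: n = %d, tau = %.1f ms, delta = %.1f ms\n",
              x$n, x$tau, x$delta))
  invisible(x)
}

#' Gamma pupil response function
#'
#' Evaluates the kernel
#' \deqn{h(t) = \frac{((t-\delta)/\tau)^{n-1} e^{-(t-\delta)/\tau}}{\tau\,(n-1)!}}
#' for `t >= delta` (zero before the delay). This is a Gamma density with
#' integer shape `n` and scale `tau`, shifted by `delta`, so it integrates
#' to one and peaks at `delta + (n - 1) tau`.
#'
#' @param t Time points in seconds.
#' @param params A [prf_params()] object.
#' @return Kernel values (1/s units), non-negative.
#' @export
gamma_prf <- function(t, params) {
  if (!inherits(params, "prf_params")) {
    params <- do.call(prf_params, as.list(params))
  }
  tau <- params$tau / 1000
  delta <- params$delta / 1000
  x <- t - delta
  h <- numeric(length(t))
  pos <- x >= 0
  h[pos] <- (x[pos] / tau)^(params$n - 1L) * exp(-x[pos] / tau) /
    (tau * factorial(params$n - 1L))
  h
}

## Causal discrete convolution: y[i] = dt * sum_j x[j] k[i - j + 1].
conv_causal <- function(x, k, dt) {
  n <- length(x)
  stats::convolve(x, rev(k), type = "open")[seq_len(n)] * dt
}

#' Build the three-predictor pupil GLM design
#'
#' The model has an impulse at stimulus onset, an impulse at stimulus
#' offset, and a boxcar spanning the presentation; each predictor is
#' normalized to unit integral on the analysis grid and then convolved with
#' the Gamma pupil response function.
#'
#' @param times Uniform analysis grid in seconds (relative to onset).
#' @param params A [prf_params()] kernel parameterization.
#' @param onset,offset Stimulus onset and offset times on the grid, s.
#' @return A numeric matrix with columns `onset`, `offset`, `sustained`
#'   and attributes `times`, `params`, `onset`, `offset`.
#' @export
build_design <- function(times, params, onset = 0, offset = 6) {
  stopifnot(length(times) > 2, offset > onset)
  dt <- diff(times[1:2])
  if (max(abs(diff(times) - dt)) > 1e-6 * dt) {
    stop("times must be a uniform grid")
  }
  n <- length(times)
  p_on <- numeric(n)
  p_on[which.min(abs(times - onset))] <- 1 / dt
  p_off <- numeric(n)
  p_off[which.min(abs(times - offset))] <- 1 / dt
  box <- as.numeric(times >= onset & times < offset)
  if (!any(box > 0)) stop("stimulus window does not intersect the grid")
  p_sus <- box / (sum(box) * dt)
  span <- (params$delta + 8 * params$n * params$tau) / 1000
  kt <- seq(0, max(span, 2 * dt), by = dt)
  k <- gamma_prf(kt, params)
  ## renormalize the sampled kernel to unit discrete mass so the regressor
  ## scale (hence the betas) is invariant to the analysis rate
  k <- k / (sum(k) * dt)
  X <- cbind(onset = conv_causal(p_on, k, dt),
             offset = conv_causal(p_off, k, dt),
             sustained = conv_causal(p_sus, k, dt))
  attr(X, "times") <- times
  attr(X, "params") <- params
  attr(X, "onset") <- onset
  attr(X, "offset") <- offset
  X
}
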