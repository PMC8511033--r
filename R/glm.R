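#' Fit condition beta-weights with the pupil response function fixed
#'
#' Validity-weighted ordinary least squares of a baseline-corrected pupil
#' time course on the three convolved predictors. No intercept is used:
#' traces are baseline-corrected, so the model passes through zero by
#' construction. Variance explained is reported as `1 - SSE / SST` with the
#' uncentered total sum of squares on the valid samples (the appropriate
#' reference for an intercept-free fit of a zero-baselined trace).
#'
#' @param pupil Numeric pupil time course (mm, baseline-corrected).
#' @param design Design matrix from [build_design()].
#' @param valid Logical validity mask (default: all finite samples).
#' @return An object of class `"pupil_glm"` with elements `coefficients`
#'   (beta_onset, beta_offset, beta_sustained), `r.squared`, `sse`,
#'   `fitted`, `residuals`, `n_valid` and a `degenerate` flag (all-zero
#'   input trace).
#' @export
fit_condition_betas <- function(pupil, design, valid = NULL) {
  stopifnot(length(pupil) == nrow(design))
  valid <- (valid %||% rep(TRUE, length(pupil))) & is.finite(pupil)
  if (!any(valid)) stop("no valid samples to fit")
  X <- design[valid, , drop = FALSE]
  y <- pupil[valid]
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  degenerate <- all(abs(y) < 1e-12)
  beta <- if (degenerate) {
    stats::setNames(numeric(ncol(X)), colnames(X))
  } else {
    fit <- stats::lm.fit(X, y)
    stats::setNames(fit$coefficients, colnames(X))
  }
  fitted_all <- as.numeric(design %*% beta)
  res <- pupil - fitted_all
  sse <- sum(res[valid]^2)
  sst <- sum(y^2)
  r2 <- if (degenerate || sst == 0) NA_real_ else 1 - sse / sst
  structure(
    list(coefficients = beta, r.squared = r2, sse = sse,
         fitted = fitted_all, residuals = res, n_valid = sum(valid),
         degenerate = degenerate, design = design),
    class = "pupil_glm"
  )
}

#' @export
print.pupil_glm <- function(x, ...) {
  cat("Pupil GLM fit (PRF fixed)\n")
  print(round(x$coefficients, 5))
  cat(sprintf("  R^2 = %s on %d valid samples%s\n",
              ifelse(is.na(x$r.squared), "NA", sprintf("%.3f", x$r.squared)),
              x$n_valid, if (x$degenerate) " [degenerate: all-zero trace]" else ""))
  invisible(x)
}

#' @export
coef.pupil_glm <- function(object, ...) object$coefficients

as_epoch_average <- function(avg) {
  if (inherits(avg, "epoch_average")) {
    return(avg)
  }
  avg <- as.data.frame(avg)
  stopifnot(all(c("rel_time", "pupil") %in% names(avg)))
  if (is.null(avg$valid)) avg$valid <- is.finite(avg$pupil)
  if (is.null(avg$n)) avg$n <- as.integer(avg$valid)
  class(avg) <- c("epoch_average", "data.frame")
  avg
}

#' Fit the pupil response function and beta-weights to an average trace
#'
#' Two-stage estimator of the pupil model. The Gamma kernel parameters are
#' found by enumerating the integer filter count `n` over 1..8 and, for
#' each `n`, minimizing the validity-weighted residual sum of squares over
#' (`tau`, `delta`) with bounded quasi-Newton optimization from several
#' seeded starts (the beta-weights are profiled out by least squares at
#' every evaluation). The globally best triplet defines the observer's
#' kernel; the returned object also carries the associated beta-weights and
#' variance explained.
#'
#' @param avg An `epoch_average` (or data.frame with `rel_time`, `pupil`
#'   and optionally `valid`): typically the observer's average response
#'   time course across conditions.
#' @param onset,offset Stimulus onset/offset in epoch time, s.
#' @param n_range Integer filter counts to enumerate.
#' @param tau_bounds,delta_bounds Box constraints in ms.
#' @param n_starts Number of random (tau, delta) starts per `n`.
#' @param seed Seed for the multi-start draws.
#' @return An object of class `"prf_fit"`.
#' @export
fit_prf <- function(avg, onset = 0, offset = 6, n_range = 1:8,
                    tau_bounds = c(10, 800), delta_bounds = c(0, 200),
                    n_starts = 5L, seed = 1L) {
  avg <- as_epoch_average(avg)
  times <- avg$rel_time
  y <- avg$pupil
  v <- avg$valid & is.finite(y)
  if (!any(v)) stop("all samples invalid")
  if (all(abs(y[v]) < 1e-12)) {
    params <- prf_params(n_range[1], mean(tau_bounds), mean(delta_bounds))
    X <- build_design(times, params, onset, offset)
    g <- fit_condition_betas(y, X, v)
    out <- list(prf = params, glm = g, sse = 0, data = avg,
                onset = onset, offset = offset, degenerate = TRUE)
    class(out) <- "prf_fit"
    return(out)
  }
  sse_of <- function(n, tau, delta) {
    X <- build_design(times, prf_params(n, tau, delta), onset, offset)
    Xv <- X[v, , drop = FALSE]
    fit <- stats::lm.fit(Xv, y[v])
    sum(fit$residuals^2)
  }
  set.seed(seed)
  starts <- cbind(stats::runif(n_starts * length(n_range),
                               tau_bounds[1], tau_bounds[2]),
                  stats::runif(n_starts * length(n_range),
                               delta_bounds[1], delta_bounds[2]))
  best <- NULL
  row <- 0L
  for (n in n_range) {
    for (s in seq_len(n_starts)) {
      row <- row + 1L
      opt <- stats::nlminb(
        start = starts[row, ],
        objective = function(p) sse_of(n, p[1], p[2]),
        lower = c(tau_bounds[1], delta_bounds[1]),
        upper = c(tau_bounds[2], delta_bounds[2])
      )
      if (is.null(best) || opt$objective < best$sse) {
        best <- list(n = n, tau = opt$par[1], delta = opt$par[2],
                     sse = opt$objective, convergence = opt$convergence)
      }
    }
  }
  params <- prf_params(best$n, best$tau, best$delta)
  X <- build_design(times, params, onset, offset)
  g <- fit_condition_betas(y, X, v)
  out <- list(prf = params, glm = g, sse = best$sse, data = avg,
              onset = onset, offset = offset,
              convergence = best$convergence, degenerate = FALSE)
  class(out) <- "prf_fit"
  out
}

#' @export
print.prf_fit <- function(x, ...) {
  cat("Pupil response function fit\n  ")
  print(x$prf)
  cat("  beta-weights (mm):\n")
  print(round(x$glm$coefficients, 5))
  cat(sprintf("  variance explained: %s%s\n",
              ifelse(is.na(x$glm$r.squared), "NA",
                     sprintf("%.1f%%", 100 * x$glm$r.squared)),
              if (x$degenerate) " [degenerate: all-zero trace]" else ""))
  invisible(x)
}

#' @export
coef.prf_fit <- function(object, ...) object$glm$coefficients

#' @export
fitted.prf_fit <- function(object, ...) object$glm$fitted

#' @export
residuals.prf_fit <- function(object, ...) object$glm$residuals

#' @export
summary.prf_fit <- function(object, ...) {
  structure(list(prf = object$prf, coefficients = object$glm$coefficients,
                 r.squared = object$glm$r.squared, sse = object$sse,
                 n_valid = object$glm$n_valid,
                 degenerate = object$degenerate),
            class = "summary.prf_fit")
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat(sprintf("Gamma kernel: n = %d, tau = %.1f ms, delta = %.1f ms\n",
              x$prf$n, x$prf$tau, x$prf$delta))
  cat(sprintf("beta_onset = %.4f, beta_offset = %.4f, beta_sustained = %.4f mm\n",
              x$coefficients[["onset"]], x$coefficients[["offset"]],
              x$coefficients[["sustained"]]))
  cat(sprintf("SSE = %.5g over %d valid samples, R^2 = %s\n", x$sse,
              x$n_valid,
              ifelse(is.na(x$r.squared), "NA", sprintf("%.3f", x$r.squared))))
  invisible(x)
}

#' Predicted pupil time course from a fitted model
#'
#' @param object A `prf_fit`.
#' @param times Optional new uniform time grid (s, epoch time).
#' @param ... Unused.
#' @return Predicted baseline-corrected pupil values.
#' @export
predict.prf_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    return(object$glm$fitted)
  }
  X <- build_design(times, object$prf, object$onset, object$offset)
  as.numeric(X %*% object$glm$coefficients)
}

#' @export
plot.prf_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$rel_time, d$pupil, type = "l", col = "gray40",
                 xlab = "time from stimulus onset (s)",
                 ylab = "pupil change (mm)", ...)
  graphics::lines(d$rel_time, x$glm$fitted, col = "firebrick", lwd = 2)
  graphics::abline(v = c(x$onset, x$offset), lty = 3)
  graphics::legend("topright", c("observed", "fitted"),
                   col = c("gray40", "firebrick"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate traces from a fitted pupil model
#'
#' @param object A `prf_fit`.
#' @param nsim Number of traces.
#' @param seed Optional seed.
#' @param noise_sd Marginal AR(1) noise standard deviation, mm.
#' @param noise_ar1 AR(1) coefficient.
#' @param ... Unused.
#' @return A matrix with `nsim` columns of simulated traces on the fit grid.
#' @export
simulate.prf_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.05, noise_ar1 = 0.9, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$glm$fitted
  vapply(seq_len(nsim),
         function(i) mu + ar1_noise(length(mu), noise_sd, noise_ar1),
         numeric(length(mu)))
}

#' Dark-minus-light pupil difference trace
#'
#' Pointwise difference of two epoch averages on the same grid (black minus
#' white responses), isolating the net pupillary response to luminance.
#'
#' @param dark,light `epoch_average` objects sharing the time grid.
#' @return An `epoch_average` of the difference; a sample is valid only
#'   where both inputs are valid.
#' @export
difference_trace <- function(dark, light) {
  dark <- as_epoch_average(dark)
  light <- as_epoch_average(light)
  if (length(dark$rel_time) != length(light$rel_time) ||
      max(abs(dark$rel_time - light$rel_time)) > 1e-9) {
    stop("time grids do not match")
  }
  out <- data.frame(
    rel_time = dark$rel_time,
    pupil = dark$pupil - light$pupil,
    n = pmin(dark$n, light$n),
    valid = dark$valid & light$valid
  )
  out$pupil[!out$valid] <- NA_real_
  class(out) <- c("epoch_average", "data.frame")
  out
}

#' Mean pupil response over a fixed analysis window
#'
#' Validity-weighted mean of an epoch average over `[start, end)` seconds
#' after stimulus onset; samples are weighted by the number of trials that
#' contributed to them.
#'
#' @param avg An `epoch_average`.
#' @param start,end Window bounds in seconds (default 1 to 6).
#' @return Scalar mean in mm.
#' @export
window_mean <- function(avg, start = 1, end = 6) {
  avg <- as_epoch_average(avg)
  if (end <= start) stop("empty window: end must exceed start")
  sel <- avg$rel_time >= start & avg$rel_time < end & avg$valid &
    is.finite(avg$pupil)
  if (!any(sel)) stop("no valid samples in the analysis window")
  w <- avg$n[sel]
  if (all(w == 0)) w <- rep(1, sum(sel))
  sum(avg$pupil[sel] * w) / sum(w)
}
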