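normalize_response_table <- function(table) {
  table <- as.data.frame(table)
  if (!is.null(table$probe_numerosity) && is.null(table$probe)) {
    table$probe <- table$probe_numerosity
  }
  if (!is.null(table$n_probe_more) && is.null(table$n_more)) {
    table$n_more <- table$n_probe_more
  }
  stopifnot(all(c("probe", "n_trials", "n_more") %in% names(table)))
  if (any(table$n_more < 0 | table$n_more > table$n_trials)) {
    stop("n_more must lie between 0 and n_trials")
  }
  table
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of `P(more) = pnorm((probe - pse) / sigma)` to a
#' binomial response table (optionally with a fixed lapse rate, zero by
#' default). The likelihood is the product of binomial terms, so unequal
#' trial counts across probe levels are weighted correctly; the fitted
#' function's median is the point of subjective equality (PSE).
#'
#' @param table Response table with columns `probe`, `n_trials`, `n_more`
#'   (aliases `probe_numerosity` / `n_probe_more` accepted); at least three
#'   distinct probe levels.
#' @param lapse Fixed lapse probability (default 0).
#' @return An object of class `"psychfit"` with `pse`, `sigma`,
#'   `log_likelihood`, a `converged` flag, a `pinned` flag (sigma at its
#'   lower bound, i.e. perfectly separated data) and the data.
#' @export
fit_cumulative_gaussian <- function(table, lapse = 0) {
  table <- normalize_response_table(table)
  if (length(unique(table$probe)) < 3) {
    stop("need at least 3 distinct probe levels")
  }
  if (sum(table$n_more) == 0 || sum(table$n_more) == sum(table$n_trials)) {
    stop("non-identifiable: all responses identical")
  }
  rng <- diff(range(table$probe))
  sigma_lo <- 1e-3 * rng
  sigma_hi <- 100 * rng
  ## perfect separation: every level answered all-"less" or all-"more";
  ## the step location is identified but the spread is not
  prop <- table$n_more / table$n_trials
  if (all(prop %in% c(0, 1))) {
    o <- order(table$probe)
    lo <- max(table$probe[o][prop[o] == 0])
    hi <- min(table$probe[o][prop[o] == 1])
    warning("perfect separation: sigma pinned at its lower bound")
    return(structure(
      list(pse = (lo + hi) / 2, sigma = sigma_lo, log_likelihood = 0,
           converged = TRUE, pinned = TRUE, lapse = lapse, data = table),
      class = "psychfit"
    ))
  }
  ## probit GLM starting values
  start <- tryCatch({
    g <- suppressWarnings(stats::glm(
      cbind(n_more, n_trials - n_more) ~ probe,
      family = stats::binomial(link = "probit"), data = table
    ))
    b <- stats::coef(g)
    if (!all(is.finite(b)) || b[2] <= 0) stop("fallback")
    c(-b[1] / b[2], 1 / b[2])
  }, error = function(e) c(stats::weighted.mean(table$probe,
                                                table$n_trials),
                           rng / 4))
  nll <- function(par) {
    pse <- par[1]
    sigma <- exp(par[2])
    p <- lapse / 2 + (1 - lapse) * stats::pnorm((table$probe - pse) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(stats::dbinom(table$n_more, table$n_trials, p, log = TRUE))
  }
  opt <- stats::optim(
    c(start[1], log(min(max(start[2], sigma_lo), sigma_hi))), nll,
    method = "L-BFGS-B",
    lower = c(min(table$probe) - 2 * rng, log(sigma_lo)),
    upper = c(max(table$probe) + 2 * rng, log(sigma_hi))
  )
  ## polish with a derivative-free pass; L-BFGS-B occasionally reports an
  ## abnormal line search on an already-flat likelihood
  polish <- stats::optim(opt$par, nll, method = "Nelder-Mead")
  if (polish$value <= opt$value) opt <- polish
  opt$par[2] <- min(max(opt$par[2], log(sigma_lo)), log(sigma_hi))
  sigma <- exp(opt$par[2])
  pinned <- sigma <= sigma_lo * (1 + 1e-6)
  if (pinned) {
    warning("perfect separation: sigma pinned at its lower bound")
  }
  structure(
    list(pse = unname(opt$par[1]), sigma = unname(sigma),
         log_likelihood = -opt$value,
         converged = opt$convergence == 0, pinned = pinned, lapse = lapse,
         data = table),
    class = "psychfit"
  )
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Cumulative-Gaussian psychometric fit: PSE = %.2f, sigma = %.2f (logL = %.2f)%s\n",
              x$pse, x$sigma, x$log_likelihood,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(pse = object$pse, sigma = object$sigma)
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$log_likelihood, df = 2L, class = "logLik")
}

#' Predicted proportion-"more" responses
#'
#' @param object A `psychfit`.
#' @param probe Probe numerosities (default: the fitted levels).
#' @param ... Unused.
#' @return Predicted probabilities of judging the probe more numerous.
#' @export
predict.psychfit <- function(object, probe = NULL, ...) {
  probe <- probe %||% object$data$probe
  object$lapse / 2 + (1 - object$lapse) *
    stats::pnorm((probe - object$pse) / object$sigma)
}

#' @export
plot.psychfit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$probe, d$n_more / d$n_trials, pch = 19,
                 xlab = "probe numerosity (dots)",
                 ylab = "proportion judged more numerous",
                 ylim = c(0, 1), ...)
  xx <- seq(min(d$probe), max(d$probe), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(h = 0.5, v = x$pse, lty = 3)
  invisible(x)
}

#' Simulate response tables from a fitted psychometric function
#'
#' @param object A `psychfit`.
#' @param nsim Number of tables.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of response tables with the fitted design's trial counts.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  p <- predict(object)
  lapply(seq_len(nsim), function(i) {
    data.frame(probe = d$probe, n_trials = d$n_trials,
               n_more = stats::rbinom(nrow(d), d$n_trials, p))
  })
}

#' Numerosity bias index
#'
#' Percentage deviation of the point of subjective equality from the
#' reference numerosity, `100 * (PSE / N - 1)`; negative values mean the
#' array is underestimated.
#'
#' @param pse PSE in dots, or a `psychfit` object.
#' @param reference Reference numerosity N (> 0), dots.
#' @return Bias in percent.
#' @export
bias_index <- function(pse, reference) {
  if (inherits(pse, "psychfit")) pse <- pse$pse
  if (any(reference <= 0)) stop("reference numerosity must be positive")
  100 * (pse / reference - 1)
}

#' Perceived numerosity implied by a bias
#'
#' @param physical Physical numerosity, dots.
#' @param bias Bias in percent (negative = underestimation).
#' @return Predicted perceived numerosity, dots.
#' @export
predicted_perceived_numerosity <- function(physical, bias) {
  physical * (1 + bias / 100)
}
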