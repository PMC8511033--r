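#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject ANOVA for a 2 (factor A) x 2 (factor B) design: each
#' effect (A, B, A x B) is tested against its own participant-by-effect
#' interaction stratum, and partial eta squared is reported as
#' `SS_effect / (SS_effect + SS_error)`. Sums of squares come from
#' [stats::aov()] with an `Error(participant/(A*B))` term; F and p are
#' recomputed from the extracted sums of squares so that degenerate
#' zero-error designs yield an infinite F with a flag rather than `NaN`.
#'
#' @param data Long-format data.frame.
#' @param value,participant,factor_a,factor_b Column names.
#' @return A data.frame of class `"rm_anova"` with one row per effect:
#'   `effect`, `df1`, `df2`, `ss`, `ss_error`, `F`, `p`, `partial_eta_sq`,
#'   `degenerate`.
#' @export
rm_anova_2x2 <- function(data, value = "value", participant = "participant",
                         factor_a = "numerosity",
                         factor_b = "connectedness") {
  d <- data.frame(
    subj = factor(data[[participant]]),
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]]),
    y = as.numeric(data[[value]])
  )
  stopifnot(nlevels(d$A) == 2, nlevels(d$B) == 2)
  tab <- table(d$subj, d$A, d$B)
  complete <- apply(tab == 1, 1, all)
  if (!all(complete)) {
    warning(sprintf("dropping %d participant(s) with incomplete cells",
                    sum(!complete)))
    d <- droplevels(d[d$subj %in% names(complete)[complete], ])
  }
  if (nlevels(d$subj) < 2) stop("need at least 2 complete participants")
  fit <- stats::aov(y ~ A * B + Error(subj / (A * B)), data = d)
  s <- summary(fit)
  grab <- function(stratum, term) {
    tb <- s[[paste0("Error: ", stratum)]][[1]]
    rn <- trimws(rownames(tb))
    list(ss = tb[rn == term, "Sum Sq"], df = tb[rn == term, "Df"],
         ss_err = tb[rn == "Residuals", "Sum Sq"],
         df_err = tb[rn == "Residuals", "Df"])
  }
  effects <- list(
    c("subj:A", "A"), c("subj:B", "B"), c("subj:A:B", "A:B")
  )
  out <- do.call(rbind, lapply(effects, function(e) {
    g <- grab(e[1], e[2])
    degenerate <- g$ss_err < 1e-12
    f <- if (degenerate) Inf else (g$ss / g$df) / (g$ss_err / g$df_err)
    p <- if (degenerate) 0 else stats::pf(f, g$df, g$df_err,
                                          lower.tail = FALSE)
    if (degenerate && g$ss < 1e-12) {
      f <- 0
      p <- 1
    }
    data.frame(df1 = g$df, df2 = g$df_err, ss = g$ss, ss_error = g$ss_err,
               F = f, p = p,
               partial_eta_sq = if (g$ss + g$ss_err > 0) {
                 g$ss / (g$ss + g$ss_err)
               } else NA_real_,
               degenerate = degenerate)
  }))
  out <- cbind(effect = c(factor_a, factor_b,
                          paste(factor_a, factor_b, sep = " x ")), out)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s F(%d,%d) = %.3g, p = %.4g, partial eta^2 = %.3g%s\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$partial_eta_sq[i],
                if (x$degenerate[i]) " [zero error variance]" else ""))
  }
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test; the effect size is the standardized mean
#' difference `mean(a - b) / sd(a - b)`.
#'
#' @param a,b Paired per-participant values (equal length >= 2).
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  dd <- a - b
  if (stats::sd(dd) == 0) {
    stop("zero-variance difference: paired t-test undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = mean(dd) / stats::sd(dd),
       mean_diff = mean(dd))
}

#' Bivariate contour ellipse area (fixation stability)
#'
#' Area of the ellipse covering a given proportion of the bivariate-normal
#' gaze distribution: `2 * pi * k * sd_x * sd_y * sqrt(1 - rho^2)` with
#' `k = -log(1 - P)`.
#'
#' @param gaze_x,gaze_y Gaze samples, degrees (>= 3 samples).
#' @param coverage Coverage proportion P (default 0.68, the field's usual
#'   one-sigma convention).
#' @return BCEA in deg^2.
#' @export
bcea <- function(gaze_x, gaze_y, coverage = 0.68) {
  stopifnot(length(gaze_x) == length(gaze_y), coverage > 0, coverage < 1)
  ok <- is.finite(gaze_x) & is.finite(gaze_y)
  gaze_x <- gaze_x[ok]
  gaze_y <- gaze_y[ok]
  if (length(gaze_x) < 3) stop("need at least 3 finite gaze samples")
  sx <- stats::sd(gaze_x)
  sy <- stats::sd(gaze_y)
  if (sx == 0 || sy == 0) stop("degenerate gaze samples: zero variance")
  rho <- stats::cor(gaze_x, gaze_y)
  if (abs(rho) >= 1 - 1e-12) {
    stop("degenerate gaze samples: perfectly correlated")
  }
  k <- -log(1 - coverage)
  2 * pi * k * sx * sy * sqrt(1 - rho^2)
}
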