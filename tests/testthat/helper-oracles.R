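# Independent oracle implementations used to cross-check the package.
# These deliberately take the naive route (brute force, closed form,
# textbook sums of squares) and share no code with the implementation.

## Gift-wrapping (Jarvis march) convex hull area.
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  stopifnot(n >= 3)
  start <- which.min(pts[, 1])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (length(hull) == 1) setdiff(seq_len(n), p) else seq_len(n)[-p]
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  x <- pts[hull, 1]
  y <- pts[hull, 2]
  j <- c(length(x), seq_len(length(x) - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Textbook within-subject sums of squares for a 2x2 repeated design.
## data: participant, A, B, value (complete cells).
oracle_rm_anova <- function(d) {
  d$participant <- factor(d$participant)
  d$A <- factor(d$A)
  d$B <- factor(d$B)
  ns <- nlevels(d$participant)
  grand <- mean(d$value)
  m_s <- tapply(d$value, d$participant, mean)
  m_a <- tapply(d$value, d$A, mean)
  m_b <- tapply(d$value, d$B, mean)
  m_ab <- tapply(d$value, list(d$A, d$B), mean)
  m_sa <- tapply(d$value, list(d$participant, d$A), mean)
  m_sb <- tapply(d$value, list(d$participant, d$B), mean)
  ss_a <- 2 * ns * sum((m_a - grand)^2)
  ss_b <- 2 * ns * sum((m_b - grand)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a - grand, m_b - grand, "+") - grand)^2)
  ss_sa <- 2 * sum((sweep(sweep(m_sa, 1, m_s), 2, m_a) + grand)^2)
  ss_sb <- 2 * sum((sweep(sweep(m_sb, 1, m_s), 2, m_b) + grand)^2)
  cell <- tapply(d$value, list(d$participant, d$A, d$B), mean)
  resid <- cell
  for (s in seq_len(ns)) {
    for (a in 1:2) {
      for (b in 1:2) {
        resid[s, a, b] <- cell[s, a, b] - m_sa[s, a] - m_sb[s, b] -
          m_ab[a, b] + m_s[s] + m_a[a] + m_b[b] - grand
      }
    }
  }
  ss_sab <- sum(resid^2)
  f_and_p <- function(ss, ss_err, df1, df2) {
    f <- (ss / df1) / (ss_err / df2)
    c(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  df_err <- ns - 1
  list(
    A = c(ss = ss_a, ss_err = ss_sa, f_and_p(ss_a, ss_sa, 1, df_err),
          peta = ss_a / (ss_a + ss_sa)),
    B = c(ss = ss_b, ss_err = ss_sb, f_and_p(ss_b, ss_sb, 1, df_err),
          peta = ss_b / (ss_b + ss_sb)),
    AB = c(ss = ss_ab, ss_err = ss_sab, f_and_p(ss_ab, ss_sab, 1, df_err),
           peta = ss_ab / (ss_ab + ss_sab))
  )
}

## Dense grid-search maximizer of the cumulative-Gaussian likelihood.
oracle_psych_grid <- function(tab, pse_grid, sigma_grid) {
  best <- c(NA, NA, -Inf)
  for (pse in pse_grid) {
    for (sigma in sigma_grid) {
      p <- pnorm((tab$probe - pse) / sigma)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- sum(dbinom(tab$n_more, tab$n_trials, p, log = TRUE))
      if (ll > best[3]) best <- c(pse, sigma, ll)
    }
  }
  names(best) <- c("pse", "sigma", "logLik")
  best
}

## Asymptotic (Fisher information) standard error of the fitted PSE for a
## binomial cumulative-Gaussian design.
oracle_pse_se <- function(pse, sigma, levels, n_per) {
  z <- (levels - pse) / sigma
  p <- pnorm(z)
  w <- dnorm(z)^2 / (p * (1 - p))
  i11 <- sum(n_per * w) / sigma^2
  i12 <- sum(n_per * w * z) / sigma^2
  i22 <- sum(n_per * w * z^2) / sigma^2
  v <- solve(matrix(c(i11, i12, i12, i22), 2))
  sqrt(v[1, 1])
}

## Trapezoid quadrature of the kernel mass, with the grid aligned on the
## delay so the n = 1 jump discontinuity sits on a grid point.
oracle_kernel_mass <- function(pars, span = 40, dt = 1e-4) {
  tt <- pars$delta / 1000 + seq(0, span, by = dt)
  h <- pupilnum::gamma_prf(tt, pars)
  (sum(h) - (h[1] + h[length(h)]) / 2) * dt
}

## Ordinary normal-equations solve for the GLM betas.
oracle_ols <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

make_epoch_average <- function(rel_time, pupil, valid = TRUE) {
  out <- data.frame(rel_time = rel_time, pupil = pupil,
                    n = 1L, valid = rep_len(valid, length(rel_time)))
  class(out) <- c("epoch_average", "data.frame")
  out
}
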