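test_that("the Gamma kernel is a unit-mass, causal, shifted Gamma density", {
  dt <- 1e-3
  tt <- seq(0, 60, by = dt)
  set.seed(3)
  for (i in 1:8) {
    pars <- prf_params(sample(1:8, 1), runif(1, 10, 800), runif(1, 0, 200))
    h <- gamma_prf(tt, pars)
    expect_true(all(h >= 0))
    expect_lt(abs(oracle_kernel_mass(pars) - 1), 1e-3)  # quadrature mass
    expect_true(all(h[tt < pars$delta / 1000] == 0))
    ## mode at delta + (n - 1) tau
    expect_lt(abs(tt[which.max(h)] -
                    (pars$delta + (pars$n - 1) * pars$tau) / 1000),
              2 * dt + 1e-9)
    ## agrees with the shifted Gamma density
    oracle <- dgamma(tt - pars$delta / 1000, shape = pars$n,
                     scale = pars$tau / 1000)
    oracle[tt < pars$delta / 1000] <- 0
    expect_equal(h, oracle, tolerance = 1e-10)
  }
  expect_error(prf_params(9, 100, 50), "n must")
  expect_error(prf_params(4, 5, 50), "tau")
  expect_error(prf_params(4, 100, 300), "delta")
})

test_that("design regressors are causal translates with unit-integral inputs", {
  tt <- seq(-1, 7, by = 0.05)[-161]
  pars <- prf_params(4, 250, 100)
  X <- build_design(tt, pars, 0, 6)
  expect_equal(colnames(X), c("onset", "offset", "sustained"))
  expect_true(all(abs(X[tt < 0 + pars$delta / 1000 - 0.05, ]) < 1e-12))
  ## offset regressor is the onset regressor shifted by the duration
  shift <- round(6 / 0.05)
  on_part <- X[seq_len(nrow(X) - shift), "onset"]
  off_part <- X[(shift + 1):nrow(X), "offset"]
  expect_equal(off_part, on_part, tolerance = 1e-9)

  ## near-delta kernel: sustained regressor approaches the scaled boxcar
  sharp <- build_design(tt, prf_params(1, 10, 0), 0, 6)
  box <- as.numeric(tt >= 0 & tt < 6) / 6
  mid <- tt > 0.5 & tt < 5.5
  expect_lt(max(abs(sharp[mid, "sustained"] - box[mid])), 0.01)
})

test_that("condition betas solve least squares exactly", {
  tt <- seq(-1, 7, by = 0.05)[-161]
  X <- build_design(tt, prf_params(4, 250, 100), 0, 6)
  y <- 2 * X[, "sustained"]
  fit <- fit_condition_betas(y, X)
  expect_equal(unname(fit$coefficients),
               c(0, 0, 2), tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)

  set.seed(4)
  y2 <- X %*% c(-0.1, -0.05, 0.8) + rnorm(length(tt), 0, 0.02)
  fit2 <- fit_condition_betas(as.numeric(y2), X)
  expect_equal(unname(fit2$coefficients),
               unname(oracle_ols(as.numeric(y2), X)), tolerance = 1e-9)

  ## pure noise: variance explained stays near zero
  r2s <- replicate(30, {
    yy <- rnorm(length(tt), 0, 0.05)
    fit_condition_betas(yy, X)$r.squared
  })
  expect_lt(mean(r2s), 0.1)

  expect_error(fit_condition_betas(y, cbind(X, X[, 1])), "rank-deficient")
})

test_that("noiseless beta recovery is exact across the parameter box", {
  tt <- seq(-1, 7, by = 0.05)[-161]
  set.seed(5)
  for (i in 1:50) {
    pars <- prf_params(sample(1:8, 1), runif(1, 10, 800), runif(1, 0, 200))
    X <- build_design(tt, pars, 0, 6)
    beta <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3), runif(1, -2, 2))
    y <- as.numeric(X %*% beta)
    fit <- fit_condition_betas(y, X)
    expect_lt(max(abs(fit$coefficients - beta)), 1e-6)
  }
})

test_that("PRF parameters are recovered from a noiseless average trace", {
  cfg <- sim_config(sampling_rate = 20, noise_sd = 0)
  tr <- simulate_trial(cfg, 24, "isolated", "black", noise = FALSE)
  ep <- epoch_and_baseline(tr, attr(tr, "events"))
  fit <- fit_prf(average_epochs(ep), seed = 1)
  expect_equal(fit$prf$n, 4L)
  expect_lt(abs(fit$prf$tau - 250) / 250, 0.05)
  expect_lt(abs(fit$prf$delta - 100), 10)
  expect_gt(fit$glm$r.squared, 0.999)
})

test_that("an all-zero trace yields a flagged degenerate fit", {
  tt <- seq(-1, 7, by = 0.05)[-161]
  fit <- fit_prf(make_epoch_average(tt, rep(0, length(tt))), seed = 1)
  expect_true(fit$degenerate)
  expect_true(all(fit$glm$coefficients == 0))
})

test_that("a trial-averaged noisy trace is fitted with high variance explained", {
  cfg <- sim_config(sampling_rate = 20)
  tt <- seq(-1, 7, by = 0.05)[-161]
  X <- build_design(tt, cfg$prf, 0, 6)
  beta <- pupilnum:::trial_betas(cfg, 24, "isolated", "black")
  mu <- as.numeric(X %*% beta)
  set.seed(6)
  trials <- replicate(60, mu + pupilnum:::ar1_noise(length(mu), 0.05, 0.9))
  avg <- make_epoch_average(tt, rowMeans(trials))
  fit <- fit_prf(avg, seed = 2)
  expect_gt(fit$glm$r.squared, 0.8)
})

test_that("difference traces subtract pointwise with validity propagation", {
  tt <- seq(-1, 7, by = 0.05)[-161]
  d <- make_epoch_average(tt, sin(tt))
  l <- make_epoch_average(tt, -sin(tt))
  diff0 <- difference_trace(d, d)
  expect_true(all(abs(diff0$pupil) < 1e-12))
  diff2 <- difference_trace(d, l)
  expect_equal(diff2$pupil, 2 * sin(tt))

  l$valid[3] <- FALSE
  expect_false(difference_trace(d, l)$valid[3])
  short <- make_epoch_average(tt[-1], sin(tt[-1]))
  expect_error(difference_trace(d, short), "grids")
})

test_that("window means integrate the expected trace segment", {
  tt <- seq(-1, 7, by = 0.05)[-161]
  expect_equal(window_mean(make_epoch_average(tt, rep(-0.3, 160))), -0.3)
  ramp <- ifelse(tt >= 0 & tt < 6, tt / 6, 0)
  expect_equal(window_mean(make_epoch_average(tt, ramp), 1, 6), 7 / 12,
               tolerance = 0.01)
  expect_error(window_mean(make_epoch_average(tt, ramp), 2, 2), "empty")
  bad <- make_epoch_average(tt, ramp, valid = FALSE)
  expect_error(window_mean(bad, 1, 6), "no valid")
})

test_that("window means and sustained betas agree in sign and ordering", {
  cfg <- sim_config(sampling_rate = 20, noise_sd = 0)
  tt <- seq(-1, 7, by = 0.05)[-161]
  X <- build_design(tt, cfg$prf, 0, 6)
  cells <- list(c(18, "connected"), c(24, "connected"),
                c(18, "isolated"), c(24, "isolated"))
  wm <- bb <- numeric(4)
  for (i in seq_along(cells)) {
    beta <- pupilnum:::trial_betas(cfg, as.numeric(cells[[i]][1]),
                                   cells[[i]][2], "black")
    y <- as.numeric(X %*% beta)
    wm[i] <- window_mean(make_epoch_average(tt, y))
    bb[i] <- fit_condition_betas(y, X)$coefficients[["sustained"]]
  }
  expect_true(all(wm > 0) && all(bb > 0))
  expect_equal(order(wm), order(bb))
})
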