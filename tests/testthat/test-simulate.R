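test_that("the noiseless forward model obeys baseline, sign and linearity", {
  cfg0 <- sim_config(sampling_rate = 100, noise_sd = 0, beta_onset = 0,
                     beta_offset = 0, beta_sustained = 0)
  tr0 <- simulate_trial(cfg0, noise = FALSE)
  expect_true(all(tr0$pupil == cfg0$baseline))

  cfg <- sim_config(sampling_rate = 100, noise_sd = 0, post = 3)
  trw <- simulate_trial(cfg, 18, "isolated", "white", noise = FALSE)
  stim <- trw$time >= cfg$pre & trw$time < cfg$pre + cfg$duration
  expect_lt(min(trw$pupil[stim]), cfg$baseline)  # constriction to white
  ## decays back toward baseline once the kernel has run out after offset
  tail_dev <- abs(trw$pupil[length(trw$pupil)] - cfg$baseline)
  expect_lt(tail_dev, max(abs(trw$pupil[stim] - cfg$baseline)) / 2)

  trb <- simulate_trial(cfg, 18, "isolated", "black", noise = FALSE)
  expect_gt(max(trb$pupil[stim]), cfg$baseline)  # dilation to black

  ## doubling all betas doubles the deviation from baseline
  cfg2 <- cfg
  cfg2$beta_onset <- 2 * cfg$beta_onset
  cfg2$beta_offset <- 2 * cfg$beta_offset
  cfg2$beta_sustained <- 2 * cfg$beta_sustained
  tr2 <- simulate_trial(cfg2, 18, "isolated", "white", noise = FALSE)
  expect_equal(tr2$pupil - cfg$baseline, 2 * (trw$pupil - cfg$baseline),
               tolerance = 1e-10)
})

test_that("noiseless simulated trials refit to the generating betas", {
  cfg <- sim_config(sampling_rate = 20, noise_sd = 0)
  for (cond in list(c(18, "connected", "white"), c(24, "isolated", "black"))) {
    tr <- simulate_trial(cfg, as.numeric(cond[1]), cond[2], cond[3],
                         noise = FALSE)
    ep <- epoch_and_baseline(tr, attr(tr, "events"))
    avg <- average_epochs(ep)
    X <- build_design(avg$rel_time, cfg$prf, 0, cfg$duration)
    fit <- fit_condition_betas(avg$pupil, X, avg$valid)
    beta <- pupilnum:::trial_betas(cfg, as.numeric(cond[1]), cond[2], cond[3])
    expect_lt(max(abs(fit$coefficients - beta)), 1e-6)
    expect_gt(fit$r.squared, 0.999)
  }
})

test_that("blink injection trips the small-pupil and velocity rules", {
  cfg <- sim_config()
  tr <- simulate_trial(cfg, seed = 1)
  expect_identical(inject_artifacts(tr, sim_config(blink_rate = 0)), tr)

  cfg_b <- sim_config(blink_rate = 40)
  trb <- inject_artifacts(tr, cfg_b, seed = 2)
  expect_true(any(trb$pupil < 0.1))
  v <- abs(diff(trb$pupil)) * 500
  expect_true(any(v > 25))

  ## preprocessing removes the artifacts: window means agree within 2%
  des <- session_design(cfg, n_trials = 10, numerosity = 24,
                        polarity = "black", seed = 3)
  sess <- simulate_session(des, cfg, seed = 4)
  sess_b <- sess
  sess_b$trace <- inject_artifacts(sess$trace, sim_config(blink_rate = 10),
                                   seed = 5)
  avg_clean <- average_epochs(preprocess_trace(sess$trace, sess$events))
  avg_blink <- average_epochs(preprocess_trace(sess_b$trace, sess$events))
  wm_c <- window_mean(avg_clean)
  wm_b <- window_mean(avg_blink)
  expect_lt(abs(wm_b - wm_c) / abs(wm_c), 0.02)
})

test_that("sessions lay out trials on the stated schedule", {
  cfg <- sim_config()
  des <- session_design(cfg, n_trials = 60, seed = 1)
  expect_equal(nrow(des), 60)
  expect_true(all(diff(des$onset_s) == cfg$duration + cfg$isi))
  expect_equal(sum(des$connectedness == "connected"), 30)

  sess <- simulate_session(des, cfg, seed = 2, noise = FALSE)
  expect_equal(nrow(sess$events), 60)
  expect_equal(attr(sess$trace, "sampling_rate"), 500)

  empty <- simulate_session(des[0, ], cfg, seed = 3, noise = FALSE)
  expect_true(all(empty$trace$pupil == cfg$baseline))

  bad <- des
  bad$onset_s[2] <- bad$onset_s[1] + 2
  expect_error(simulate_session(bad, cfg), "overlap")
})

test_that("identical seeds reproduce identical sessions", {
  cfg <- sim_config()
  des <- session_design(cfg, n_trials = 5, seed = 9)
  s1 <- simulate_session(des, cfg, seed = 10, artifacts = TRUE)
  s2 <- simulate_session(des, cfg, seed = 10, artifacts = TRUE)
  expect_identical(s1$trace$pupil, s2$trace$pupil)
  expect_identical(s1$trace$gaze_x, s2$trace$gaze_x)
})

test_that("2AFC responses follow the observer's psychometric function", {
  obs <- observer_spec(18, 2)
  at_pse <- simulate_2afc(obs, 18, 4000, seed = 1)
  expect_lt(abs(at_pse$n_more / at_pse$n_trials - 0.5), 0.03)
  far <- simulate_2afc(obs, 40, 500, seed = 2)
  expect_equal(far$n_more, far$n_trials)

  ## lapse flattens the asymptotes
  obs_l <- observer_spec(18, 2, lapse = 0.2)
  far_l <- simulate_2afc(obs_l, 60, 5000, seed = 3)
  expect_lt(abs(far_l$n_more / far_l$n_trials - 0.9), 0.02)
})

test_that("PSE recovery from the 2AFC design matches the Fisher oracle", {
  lv <- c(8, 10, 12, 14, 16, 20, 22, 24)
  obs <- observer_spec(12.6, 2)
  pses <- vapply(1:200, function(i) {
    fit_cumulative_gaussian(simulate_2afc(obs, lv, 15, seed = i))$pse
  }, numeric(1))
  se <- oracle_pse_se(12.6, 2, lv, 15)
  expect_lt(abs(mean(pses) - 12.6), 3 * se / sqrt(200))  # unbiased
  expect_lt(abs(sd(pses) - se) / se, 0.25)               # oracle spread
  cover <- mean(abs(pses - 12.6) <= 0.5)
  pred <- 2 * pnorm(0.5 / se) - 1
  expect_lt(abs(cover - pred), 0.08)
})
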