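test_that("artifact rules flag small, deviant and fast samples", {
  fs <- 500
  p <- rep(3, 1000)
  tr <- pupil_trace(p, fs)
  expect_true(all(mark_invalid(tr)$valid))

  ## small-pupil rule plus velocity fallout on the neighbors
  p2 <- p
  p2[500] <- 0.05
  m <- mark_invalid(pupil_trace(p2, fs))
  expect_false(m$valid[500])
  half <- ceiling(0.01 * fs)
  expect_true(all(!m$valid[(500 - half):(500 + half)]))
  expect_true(m$valid[500 - half - 3])

  ## deviation-from-median rule: a slow 1.2 mm excursion (per-sample rate
  ## well under threshold) is caught by the 1 mm rule alone
  p4 <- c(rep(3, 400), seq(3, 4.2, length.out = 50), rep(4.2, 100),
          seq(4.2, 3, length.out = 50), rep(3, 400))
  m4 <- mark_invalid(pupil_trace(p4, fs))
  expect_true(all(!m4$valid[451:550]))
  expect_true(m4$valid[100])
})

test_that("a one-sample 0.2 mm step at 500 Hz trips the velocity rule", {
  fs <- 500
  p <- rep(3, 400)
  p[201:400] <- 3.2  # 0.2 mm across one 2 ms sample = 100 mm/s
  m <- mark_invalid(pupil_trace(p, fs))
  half <- ceiling(0.01 * fs)
  expect_true(all(!m$valid[(200 - half):(201 + half)]))
  expect_true(all(m$valid[1:(200 - half - 1)]))
  expect_true(all(m$valid[(201 + half + 1):400]))
})

test_that("mark_invalid is idempotent and masks only grow", {
  set.seed(1)
  p <- 3 + cumsum(rnorm(2000, 0, 0.01))
  p[c(300, 900)] <- 0.01
  tr <- pupil_trace(p, 500)
  m1 <- mark_invalid(tr)
  m2 <- mark_invalid(m1)
  expect_identical(m1$valid, m2$valid)
  pre <- tr
  pre$valid[1:50] <- FALSE
  m3 <- mark_invalid(pre)
  expect_true(all(!m3$valid[1:50]))
})

test_that("downsampling averages valid samples per bin", {
  tr <- pupil_trace(rep(3, 500), 500)
  ds <- downsample_trace(tr, 20)
  expect_equal(nrow(ds), 20)
  expect_true(all(ds$pupil == 3))
  expect_equal(attr(ds, "sampling_rate"), 20)

  alt <- pupil_trace(rep(c(2, 4), 100), 40)  # even bins of 2 samples
  expect_true(all(downsample_trace(alt, 20)$pupil == 3))

  tr2 <- pupil_trace(rep(3, 500), 500)
  tr2$valid[1:25] <- FALSE
  ds2 <- downsample_trace(tr2, 20)
  expect_false(ds2$valid[1])
  expect_true(is.na(ds2$pupil[1]))
  expect_true(all(ds2$valid[-1]))
})

test_that("square-window filter is the stated boxcar convolution", {
  tr <- pupil_trace(rep(2.5, 100), 20)
  expect_equal(square_window_filter(tr)$pupil, rep(2.5, 100))

  imp <- pupil_trace(c(rep(0, 50), 1, rep(0, 49)), 20)
  sm <- square_window_filter(imp)$pupil
  expect_equal(sum(sm > 1e-12), 10)
  expect_equal(max(sm), 1 / 10, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)

  set.seed(2)
  wn <- pupil_trace(rnorm(2000), 20)
  expect_lt(var(square_window_filter(wn)$pupil), var(wn$pupil))

  ## subtract mode removes the moving average
  sub <- square_window_filter(imp, mode = "subtract")$pupil
  expect_equal(sub + sm, imp$pupil, tolerance = 1e-12)
})

test_that("epoching subtracts the 200 ms pre-onset baseline", {
  fs <- 20
  tr <- pupil_trace(rep(4, 200), fs)
  ev <- data.frame(trial = 1, onset_s = 2, offset_s = 8)
  ep <- epoch_and_baseline(tr, ev, pre = 1, post = 7)
  expect_true(all(abs(ep$pupil) < 1e-12))
  expect_equal(length(ep$rel_time), 160)

  ## baseline 3.5, stimulus window 3.3 -> corrected window mean -0.2
  p <- rep(3.5, 200)
  stim_idx <- which((seq_len(200) - 1) / fs >= 2 & (seq_len(200) - 1) / fs < 8)
  p[stim_idx] <- 3.3
  ep2 <- epoch_and_baseline(pupil_trace(p, fs), ev)
  avg <- average_epochs(ep2)
  expect_equal(window_mean(avg, 0, 6), -0.2, tolerance = 1e-12)

  expect_error(epoch_and_baseline(tr, data.frame(trial = 1, onset_s = 9.8,
                                                 offset_s = 15)),
               "outside")
})

test_that("epochs with an all-invalid baseline are dropped with a warning", {
  fs <- 20
  tr <- pupil_trace(rep(4, 400), fs)
  tr$valid[which(tr$time >= 1.7 & tr$time < 2)] <- FALSE
  ev <- data.frame(trial = 1:2, onset_s = c(2, 11), offset_s = c(8, 17))
  expect_warning(ep <- epoch_and_baseline(tr, ev), "dropped 1 epoch")
  expect_equal(nrow(ep$pupil), 1)
  expect_equal(ep$events$trial, 2)
})

test_that("corrected epochs recover the noiseless forward model", {
  cfg <- sim_config(sampling_rate = 500, noise_sd = 0)
  tr <- simulate_trial(cfg, 18, "connected", "black", noise = FALSE)
  ev <- attr(tr, "events")
  ## mask -> downsample -> epoch (no smoothing, to compare with the model)
  tr <- mark_invalid(tr, ev)
  ds <- downsample_trace(tr, 20)
  ep <- epoch_and_baseline(ds, ev)
  avg <- average_epochs(ep)
  X <- build_design(avg$rel_time, cfg$prf, 0, 6)
  beta <- pupilnum:::trial_betas(cfg, 18, "connected", "black")
  model <- as.numeric(X %*% beta)
  expect_lt(max(abs(avg$pupil - model)), 0.01)
})

test_that("trace and event tables round-trip through their file formats", {
  cfg <- sim_config()
  des <- session_design(cfg, n_trials = 3, seed = 1)
  sess <- simulate_session(des, cfg, seed = 2)
  td <- tempfile("io")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  write_trace(sess$trace, file.path(td, "trace.csv"))
  write_events(sess$events, file.path(td, "events.csv"))
  tr2 <- read_trace(file.path(td, "trace.csv"))
  ev2 <- read_events(file.path(td, "events.csv"))
  expect_equal(tr2$pupil, sess$trace$pupil)
  expect_equal(attr(tr2, "sampling_rate"), 500, tolerance = 1e-6)
  expect_equal(ev2$onset_s, sess$events$onset_s)
  expect_equal(ev2$connectedness, sess$events$connectedness)
})
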