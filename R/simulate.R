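#' Simulation configuration
#'
#' Ground-truth parameters of the forward model used to synthesize pupil
#' recordings: the generating Gamma kernel, the three beta-weights, a
#' multiplicative sustained-response gain per perceived-numerosity cell,
#' AR(1) measurement noise, blink statistics and gaze jitter. The sustained
#' beta is signed by polarity (negative for white stimuli, which drive
#' constriction; positive for black, which drive dilation); the transient
#' onset/offset weights are shared across conditions. The default gains —
#' 0.70, 1.00, 0.93 and 1.23 for 18-connected, 18-isolated, 24-connected
#' and 24-isolated — order the cells by perceived numerosity (connected
#' arrays are seen roughly 30% less numerous) through a compressive,
#' additive-in-both-factors mapping, the pattern the analysis should
#' recover: both main effects, no interaction, with 18-isolated and
#' 24-connected nearly equivalent.
#'
#' @param prf Generating [prf_params()].
#' @param baseline Baseline pupil diameter, mm.
#' @param beta_onset,beta_offset Transient weights, mm (constriction < 0).
#' @param beta_sustained Base sustained weight magnitude, mm.
#' @param sustained_gain Named gains, keys `"<numerosity>.<connectedness>"`.
#' @param noise_sd Marginal AR(1) noise SD, mm.
#' @param noise_ar1 AR(1) coefficient in `[0, 1)`.
#' @param blink_rate Blink events per minute.
#' @param blink_duration Blink plateau duration, ms.
#' @param sampling_rate Hz.
#' @param gaze_jitter_sd Fixational gaze jitter SD, degrees.
#' @param gaze_ar1 AR(1) coefficient of the gaze jitter.
#' @param pre,duration,post Trial structure, s (fixation, stimulus, post).
#' @param isi Gap between stimulus offset and the next onset, s (the 1 s
#'   post-stimulus interval plus the next trial's 1 s fixation).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(prf = prf_params(4, 250, 100),
                       baseline = 4.5,
                       beta_onset = -0.08,
                       beta_offset = -0.05,
                       beta_sustained = 0.9,
                       sustained_gain = c("18.connected" = 0.70,
                                          "18.isolated" = 1.00,
                                          "24.connected" = 0.93,
                                          "24.isolated" = 1.23),
                       noise_sd = 0.05,
                       noise_ar1 = 0.9,
                       blink_rate = 6,
                       blink_duration = 150,
                       sampling_rate = 500,
                       gaze_jitter_sd = 0.3,
                       gaze_ar1 = 0.995,
                       pre = 1, duration = 6, post = 1, isi = 2) {
  stopifnot(sampling_rate > 0, noise_sd >= 0, noise_ar1 >= 0, noise_ar1 < 1,
            blink_rate >= 0, blink_duration > 0, duration > 0, pre >= 0,
            post >= 0, isi >= 0, baseline > 0)
  structure(as.list(environment()), class = "sim_config")
}

condition_gain <- function(cfg, numerosity, connectedness) {
  key <- paste(numerosity, connectedness, sep = ".")
  g <- cfg$sustained_gain[key]
  if (is.na(g)) stop(sprintf("no sustained gain configured for '%s'", key))
  unname(g)
}

trial_betas <- function(cfg, numerosity, connectedness, polarity) {
  sgn <- if (polarity == "black") 1 else -1
  c(onset = cfg$beta_onset, offset = cfg$beta_offset,
    sustained = sgn * cfg$beta_sustained *
      condition_gain(cfg, numerosity, connectedness))
}

#' Simulate a single pupil trial
#'
#' The noiseless trace is the baseline plus the beta-weighted sum of the
#' three unit-integral predictors convolved with the generating kernel;
#' AR(1) noise and fixational gaze jitter are added on top.
#'
#' @param cfg A [sim_config()].
#' @param numerosity,connectedness,polarity Condition of the trial.
#' @param seed Optional seed.
#' @param noise Add AR(1) noise? (FALSE gives the deterministic trace.)
#' @return A [pupil_trace()] spanning fixation, stimulus and post period,
#'   with the trial event table attached as attribute `"events"`.
#' @export
simulate_trial <- function(cfg, numerosity = 18, connectedness = "isolated",
                           polarity = "white", seed = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  times <- seq(0, cfg$pre + cfg$duration + cfg$post - dt / 2, by = dt)
  rel <- times - cfg$pre
  X <- build_design(rel, cfg$prf, onset = 0, offset = cfg$duration)
  beta <- trial_betas(cfg, numerosity, connectedness, polarity)
  dev <- as.numeric(X %*% beta)
  n <- length(times)
  p <- cfg$baseline + dev
  if (noise) p <- p + ar1_noise(n, cfg$noise_sd, cfg$noise_ar1)
  tr <- pupil_trace(
    pupil = p, sampling_rate = fs, time = times,
    gaze_x = if (noise) ar1_noise(n, cfg$gaze_jitter_sd, cfg$gaze_ar1) else 0,
    gaze_y = if (noise) ar1_noise(n, cfg$gaze_jitter_sd, cfg$gaze_ar1) else 0
  )
  attr(tr, "events") <- data.frame(
    trial = 1L, onset_s = cfg$pre, offset_s = cfg$pre + cfg$duration,
    numerosity = numerosity, connectedness = connectedness,
    polarity = polarity, stringsAsFactors = FALSE
  )
  tr
}

#' Inject blink artifacts into a trace
#'
#' Places Poisson-distributed blink events: the pupil channel ramps down to
#' near zero over 20 ms, stays there for the blink duration, and ramps back
#' over 20 ms, so each blink trips both the small-pupil rule (< 0.1 mm) and
#' the velocity rule (> 25 mm/s).
#'
#' @param trace A [pupil_trace()].
#' @param cfg A [sim_config()] (supplies `blink_rate`, `blink_duration`).
#' @param seed Optional seed.
#' @return The trace with blink artifacts written into the pupil channel.
#' @export
inject_artifacts <- function(trace, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$blink_rate <= 0) {
    return(trace)
  }
  fs <- sampling_rate(trace)
  n <- nrow(trace)
  dur_min <- n / fs / 60
  n_blinks <- stats::rpois(1, cfg$blink_rate * dur_min)
  if (n_blinks == 0) {
    return(trace)
  }
  ramp <- max(1L, round(0.020 * fs))
  plateau <- max(1L, round(cfg$blink_duration / 1000 * fs))
  total <- 2L * ramp + plateau
  starts <- sort(sample.int(max(n - total - 1L, 1L), n_blinks, replace = TRUE))
  floor_mm <- 0.02
  for (s in starts) {
    i0 <- s
    p0 <- trace$pupil[i0]
    p1 <- trace$pupil[min(i0 + total, n)]
    down <- seq(p0, floor_mm, length.out = ramp + 1L)[-1L]
    up <- seq(floor_mm, p1, length.out = ramp + 1L)[-1L]
    idx <- i0 + seq_len(total)
    idx <- idx[idx <= n]
    vals <- c(down, rep(floor_mm, plateau), up)[seq_along(idx)]
    trace$pupil[idx] <- vals
  }
  trace
}

#' Default session design
#'
#' Trial order and timing for one recording session: a fixed numerosity and
#' polarity with connected and isolated trials intermixed in pseudo-random
#' order, onsets every `duration + isi` seconds (1 s fixation, 6 s
#' stimulus, 1 s post, next fixation after a 2 s interstimulus interval).
#'
#' @param cfg A [sim_config()].
#' @param n_trials Trials in the session.
#' @param numerosity,polarity Session-level condition.
#' @param connectedness_levels Levels to intermix, half the trials each.
#' @param seed Optional seed for the trial order.
#' @return Event-table data.frame with onset/offset times and conditions.
#' @export
session_design <- function(cfg, n_trials = 60, numerosity = 18,
                           polarity = "white",
                           connectedness_levels = c("connected", "isolated"),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conn <- sample(rep(connectedness_levels, length.out = n_trials))
  onsets <- cfg$pre + (seq_len(n_trials) - 1L) * (cfg$duration + cfg$isi)
  data.frame(
    trial = seq_len(n_trials), onset_s = onsets,
    offset_s = onsets + cfg$duration, numerosity = numerosity,
    connectedness = conn, polarity = polarity, stringsAsFactors = FALSE
  )
}

#' Simulate a full recording session
#'
#' Builds the session-long drive (impulses at every onset and offset, one
#' unit-integral boxcar per stimulus, each weighted by its trial's
#' beta-weights), convolves it once with the generating kernel, and adds
#' baseline, AR(1) noise, gaze jitter and (optionally) blink artifacts.
#'
#' @param design Event table from [session_design()] (columns `onset_s`,
#'   `offset_s`, `numerosity`, `connectedness`, `polarity`).
#' @param cfg A [sim_config()].
#' @param seed Optional seed.
#' @param noise Add AR(1) noise?
#' @param artifacts Inject blinks?
#' @return List with the session `trace` and the `events` table.
#' @export
simulate_session <- function(design, cfg, seed = NULL, noise = TRUE,
                             artifacts = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(design) == 0) {
    n <- as.integer(cfg$sampling_rate * 10)
    tr <- pupil_trace(rep(cfg$baseline, n), cfg$sampling_rate)
    if (noise) tr$pupil <- tr$pupil + ar1_noise(n, cfg$noise_sd, cfg$noise_ar1)
    return(list(trace = tr, events = design))
  }
  ord <- order(design$onset_s)
  design <- design[ord, , drop = FALSE]
  if (any(design$onset_s[-1] < design$offset_s[-nrow(design)])) {
    stop("overlapping trials: stimulus windows must not intersect")
  }
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  total <- max(design$offset_s) + cfg$post + cfg$isi
  n <- as.integer(round(total * fs))
  times <- (seq_len(n) - 1L) * dt
  drive <- numeric(n)
  for (k in seq_len(nrow(design))) {
    beta <- trial_betas(cfg, design$numerosity[k], design$connectedness[k],
                        design$polarity[k])
    oi <- which.min(abs(times - design$onset_s[k]))
    fi <- which.min(abs(times - design$offset_s[k]))
    drive[oi] <- drive[oi] + beta[["onset"]] / dt
    drive[fi] <- drive[fi] + beta[["offset"]] / dt
    box <- oi:(fi - 1L)
    drive[box] <- drive[box] + beta[["sustained"]] / (length(box) * dt)
  }
  span <- (cfg$prf$delta + 8 * cfg$prf$n * cfg$prf$tau) / 1000
  k <- gamma_prf(seq(0, max(span, 2 * dt), by = dt), cfg$prf)
  dev <- conv_causal(drive, k, dt)
  p <- cfg$baseline + dev
  if (noise) p <- p + ar1_noise(n, cfg$noise_sd, cfg$noise_ar1)
  tr <- pupil_trace(
    pupil = p, sampling_rate = fs, time = times,
    gaze_x = if (noise) ar1_noise(n, cfg$gaze_jitter_sd, cfg$gaze_ar1) else 0,
    gaze_y = if (noise) ar1_noise(n, cfg$gaze_jitter_sd, cfg$gaze_ar1) else 0
  )
  if (artifacts) tr <- inject_artifacts(tr, cfg)
  list(trace = tr, events = design)
}

#' Ideal-observer specification for the 2AFC task
#'
#' @param pse Point of subjective equality, dots.
#' @param sigma Gaussian spread (discrimination noise), dots.
#' @param lapse Lapse probability in `[0, 0.5]`.
#' @return A list of class `"observer_spec"`.
#' @export
observer_spec <- function(pse, sigma, lapse = 0) {
  stopifnot(sigma > 0, lapse >= 0, lapse <= 0.5)
  structure(list(pse = pse, sigma = sigma, lapse = lapse),
            class = "observer_spec")
}

#' Simulate two-alternative forced-choice numerosity judgments
#'
#' Bernoulli responses from a cumulative-Gaussian observer: the probability
#' of judging the probe more numerous than the reference is
#' `lapse/2 + (1 - lapse) * pnorm((probe - pse) / sigma)`.
#'
#' @param observer An [observer_spec()].
#' @param probe_levels Probe numerosities.
#' @param trials_per_level Trials per probe level (>= 1).
#' @param seed Optional seed.
#' @return A response table data.frame with columns `probe`, `n_trials`,
#'   `n_more`.
#' @export
simulate_2afc <- function(observer, probe_levels, trials_per_level,
                          seed = NULL) {
  stopifnot(trials_per_level >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- observer$lapse / 2 + (1 - observer$lapse) *
    stats::pnorm((probe_levels - observer$pse) / observer$sigma)
  data.frame(
    probe = probe_levels,
    n_trials = as.integer(trials_per_level),
    n_more = stats::rbinom(length(probe_levels), trials_per_level, p)
  )
}
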