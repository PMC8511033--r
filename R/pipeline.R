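#' Configuration for a full synthetic study run
#'
#' Bundles the design of a complete simulated experiment: participant
#' count, the pupillometry session plan (one session per numerosity and
#' polarity with connected and isolated trials intermixed, as in the
#' source design: 4 sessions of 60 trials), the psychophysics plan (3
#' sessions of 40 trials per condition), the generating model, observer
#' variability, and a master seed from which every stage derives its own
#' sub-seed.
#'
#' @param experiment 1 or 2.
#' @param n_participants Number of simulated participants.
#' @param trials_per_session Pupillometry trials per session.
#' @param psych_sessions,psych_trials 2AFC sessions and trials per session.
#' @param sim A [sim_config()].
#' @param illusion_bias Mean connectedness bias of the simulated observers
#'   (fraction; 0.30 means connected arrays are seen 30% less numerous).
#' @param illusion_sd Between-participant SD of the illusion fraction.
#' @param observer_sigma Psychometric spread, dots.
#' @param participant_gain_sd Between-participant SD of the (log) sustained
#'   response gain.
#' @param probe_levels Probe numerosities for the 2AFC task.
#' @param reference_numerosity Reference (standard) numerosity, dots.
#' @param seed Master seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(experiment = 1L, n_participants = 16L,
                            trials_per_session = 60L, psych_sessions = 3L,
                            psych_trials = 40L, sim = sim_config(),
                            illusion_bias = 0.30, illusion_sd = 0.05,
                            observer_sigma = 2, participant_gain_sd = 0.15,
                            probe_levels = c(8, 10, 12, 14, 16, 20, 22, 24),
                            reference_numerosity = 18, seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_session >= 2,
            psych_sessions >= 1, psych_trials >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

## Sub-seed derivation: deterministic, collision-free across stages, and
## kept below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i) %% 2147483647
  as.integer(s)
}

#' Run the full synthetic pipeline
#'
#' Simulates and analyzes a complete study: for every participant, one
#' pupillometry session per numerosity-by-polarity cell (connected and
#' isolated intermixed) is generated with blink artifacts, preprocessed
#' (artifact rejection, 20 Hz downsampling, 500 ms square-window
#' filtering, 200 ms baseline correction), and reduced to dark-minus-light
#' difference traces per condition. The per-participant Gamma kernel is
#' fitted on the grand-average difference trace and then frozen for the
#' per-condition beta fits; window means (1-6 s) provide the model-free
#' companion measure. Psychophysics is simulated and fitted per
#' connectedness condition, and condition-level statistics (repeated-
#' measures ANOVAs, the strongest-vs-weakest paired test, fixation-
#' stability BCEAs) are assembled into a report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all tables, a config
#'   echo, a log and a checksum manifest are written there.
#' @return An object of class `"pupilnum_run"`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_participants < 1) stop("invalid config: no participants")
  cfg <- config$sim
  cells <- expand.grid(numerosity = c(18, 24),
                       connectedness = c("connected", "isolated"),
                       stringsAsFactors = FALSE)
  cell_names <- paste(cells$numerosity, cells$connectedness, sep = ".")
  np <- config$n_participants
  wmat <- matrix(NA_real_, np, 4, dimnames = list(NULL, cell_names))
  bmat <- matrix(NA_real_, np, 4, dimnames = list(NULL, cell_names))
  bcea_mat <- matrix(NA_real_, np, 4, dimnames = list(NULL, cell_names))
  prf_tab <- data.frame()
  psych_tab <- data.frame()
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  logf("pupilnum run: experiment %d, %d participants, master seed %d",
       config$experiment, np, config$seed)

  for (p in seq_len(np)) {
    pseed <- derive_seed(config$seed, 1L, p)
    set.seed(pseed)
    gain_p <- exp(stats::rnorm(1, 0, config$participant_gain_sd))
    cfg_p <- cfg
    cfg_p$beta_sustained <- cfg$beta_sustained * gain_p
    ## one session per numerosity x polarity, connectedness intermixed
    cond_avg <- list()
    gaze_by_cell <- stats::setNames(vector("list", 4), cell_names)
    sess_i <- 0L
    for (nn in c(18, 24)) {
      for (pol in c("black", "white")) {
        sess_i <- sess_i + 1L
        sseed <- derive_seed(pseed, 2L, sess_i)
        des <- session_design(cfg_p, config$trials_per_session,
                              numerosity = nn, polarity = pol, seed = sseed)
        sess <- simulate_session(des, cfg_p, seed = sseed + 1L,
                                 artifacts = TRUE)
        ep <- suppressWarnings(preprocess_trace(sess$trace, sess$events))
        for (cc in c("connected", "isolated")) {
          key <- paste(nn, cc, pol, sep = ".")
          sel <- ep$events$connectedness == cc
          cond_avg[[key]] <- average_epochs(ep, sel)
          cell <- paste(nn, cc, sep = ".")
          stim_win <- ep$rel_time >= 0 & ep$rel_time < cfg$duration
          gaze_by_cell[[cell]] <- rbind(
            gaze_by_cell[[cell]],
            cbind(as.vector(ep$gaze_x[sel, stim_win]),
                  as.vector(ep$gaze_y[sel, stim_win]))
          )
        }
      }
    }
    ## dark-minus-light difference traces per cell
    diffs <- lapply(seq_len(4), function(i) {
      key_b <- paste(cells$numerosity[i], cells$connectedness[i], "black",
                     sep = ".")
      key_w <- paste(cells$numerosity[i], cells$connectedness[i], "white",
                     sep = ".")
      difference_trace(cond_avg[[key_b]], cond_avg[[key_w]])
    })
    names(diffs) <- cell_names
    grand <- diffs[[1]]
    grand$pupil <- rowMeans(sapply(diffs, function(d) d$pupil))
    grand$valid <- Reduce(`&`, lapply(diffs, function(d) d$valid))
    pfit <- fit_prf(grand, onset = 0, offset = cfg$duration,
                    seed = derive_seed(pseed, 3L))
    prf_tab <- rbind(prf_tab, data.frame(
      participant = p, n = pfit$prf$n, tau = pfit$prf$tau,
      delta = pfit$prf$delta, r_squared = pfit$glm$r.squared
    ))
    X <- build_design(grand$rel_time, pfit$prf, 0, cfg$duration)
    for (i in seq_len(4)) {
      g <- fit_condition_betas(diffs[[i]]$pupil, X, diffs[[i]]$valid)
      bmat[p, i] <- g$coefficients[["sustained"]]
      wmat[p, i] <- window_mean(diffs[[i]])
      gz <- gaze_by_cell[[i]]
      bcea_mat[p, i] <- bcea(gz[, 1], gz[, 2])
    }
    ## psychophysics: PSE per connectedness condition
    oseed <- derive_seed(pseed, 4L)
    set.seed(oseed)
    illusion <- stats::rnorm(1, config$illusion_bias, config$illusion_sd)
    pse_conn <- config$reference_numerosity * (1 - illusion)
    pse_iso <- config$reference_numerosity *
      (1 + stats::rnorm(1, 0, 0.03))
    tpl <- config$psych_sessions * config$psych_trials /
      length(config$probe_levels)
    for (cc in c("connected", "isolated")) {
      obs <- observer_spec(if (cc == "connected") pse_conn else pse_iso,
                           config$observer_sigma)
      tab <- simulate_2afc(obs, config$probe_levels, round(tpl),
                           seed = derive_seed(oseed, match(cc, c("connected",
                                                                 "isolated"))))
      fit <- fit_cumulative_gaussian(tab)
      psych_tab <- rbind(psych_tab, data.frame(
        participant = p, connectedness = cc, pse = fit$pse,
        sigma = fit$sigma,
        bias = bias_index(fit, config$reference_numerosity)
      ))
    }
    logf("participant %d: PRF n=%d tau=%.0f delta=%.0f, R^2=%.2f",
         p, pfit$prf$n, pfit$prf$tau, pfit$prf$delta, pfit$glm$r.squared)
  }

  to_long <- function(mat) {
    data.frame(
      participant = rep(seq_len(np), 4),
      numerosity = rep(cells$numerosity, each = np),
      connectedness = rep(cells$connectedness, each = np),
      value = as.vector(mat)
    )
  }
  run <- structure(list(
    config = config,
    window_means = wmat,
    sustained_betas = bmat,
    bcea = bcea_mat,
    prf = prf_tab,
    psychometrics = psych_tab,
    anova_window = rm_anova_2x2(to_long(wmat)),
    anova_beta = rm_anova_2x2(to_long(bmat)),
    anova_bcea = rm_anova_2x2(to_long(bcea_mat)),
    t_window = paired_t(wmat[, "24.isolated"], wmat[, "18.connected"]),
    t_beta = paired_t(bmat[, "24.isolated"], bmat[, "18.connected"]),
    log = log_lines
  ), class = "pupilnum_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run to disk
#'
#' Emits every result table as CSV, the configuration echo as JSON, the run
#' log, a Markdown summary, and a manifest listing every written file with
#' its MD5 checksum.
#'
#' @param run A `pupilnum_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wrote <- character(0)
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    wrote <<- c(wrote, p)
  }
  wcsv(run$window_means, "window_means.csv")
  wcsv(run$sustained_betas, "sustained_betas.csv")
  wcsv(run$bcea, "bcea.csv")
  wcsv(run$prf, "prf_parameters.csv")
  wcsv(run$psychometrics, "psychometrics.csv")
  wcsv(run$anova_window, "anova_window.csv")
  wcsv(run$anova_beta, "anova_beta.csv")
  wcsv(run$anova_bcea, "anova_bcea.csv")
  cfgp <- file.path(out_dir, "config.json")
  cfg <- run$config
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$prf <- unclass(cfg$sim$prf)
  jsonlite::write_json(unclass(cfg), cfgp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  wrote <- c(wrote, cfgp)
  logp <- file.path(out_dir, "run.log")
  writeLines(run$log, logp)
  wrote <- c(wrote, logp)
  sump <- file.path(out_dir, "summary.md")
  writeLines(utils::capture.output(print(run)), sump)
  wrote <- c(wrote, sump)
  manifest <- data.frame(file = basename(wrote),
                         md5 = unname(tools::md5sum(wrote)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @export
print.pupilnum_run <- function(x, ...) {
  cat(sprintf("Synthetic numerosity-pupillometry run: %d participants, experiment %d\n\n",
              x$config$n_participants, x$config$experiment))
  cat("Condition means (dark - light), 1-6 s window (mm):\n")
  print(round(colMeans(x$window_means), 4))
  cat("\nSustained beta-weights (mm):\n")
  print(round(colMeans(x$sustained_betas), 4))
  cat("\nWindow-mean ANOVA:\n")
  print(x$anova_window)
  cat("\nSustained-beta ANOVA:\n")
  print(x$anova_beta)
  cat(sprintf("\n24-isolated vs 18-connected (window means): t(%d) = %.2f, p = %.4g, d = %.2f\n",
              x$t_window$df, x$t_window$t, x$t_window$p,
              x$t_window$cohens_d))
  cat(sprintf("\nMean connectedness bias: %.1f%% (connected), %.1f%% (isolated)\n",
              mean(x$psychometrics$bias[x$psychometrics$connectedness ==
                                          "connected"]),
              mean(x$psychometrics$bias[x$psychometrics$connectedness ==
                                          "isolated"])))
  invisible(x)
}
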