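#' Read and write pupil traces and event tables
#'
#' Delimited-text formats shared by all pipeline stages. Traces are CSV
#' with columns `time_s`, `pupil_mm`, `gaze_x_deg`, `gaze_y_deg`, `valid`;
#' events are CSV with columns `trial`, `onset_s`, `offset_s`,
#' `numerosity`, `connectedness`, `polarity`; 2AFC response tables are CSV
#' with `probe`, `n_trials`, `n_more` plus any condition columns.
#'
#' @param trace A [pupil_trace()].
#' @param path File path.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  out <- data.frame(time_s = trace$time, pupil_mm = trace$pupil,
                    gaze_x_deg = trace$gaze_x, gaze_y_deg = trace$gaze_y,
                    valid = as.integer(trace$valid))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path)
  dt <- stats::median(diff(d$time_s))
  pupil_trace(pupil = d$pupil_mm, sampling_rate = 1 / dt, time = d$time_s,
              gaze_x = d$gaze_x_deg, gaze_y = d$gaze_y_deg,
              valid = as.logical(d$valid))
}

#' @rdname trace_io
#' @param events Event table.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname trace_io
#' @param responses 2AFC response table.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_responses <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export epochs as a tidy table
#'
#' One row per trial and time point: `trial`, condition columns,
#' `rel_time_s`, `pupil_mm`, `valid`.
#'
#' @param epochs A `pupil_epochs` object.
#' @param path File path.
#' @export
write_epochs <- function(epochs, path) {
  nt <- nrow(epochs$pupil)
  ns <- length(epochs$rel_time)
  ev <- epochs$events
  out <- data.frame(
    trial = rep(ev$trial, each = ns),
    numerosity = rep(ev$numerosity, each = ns),
    connectedness = rep(ev$connectedness, each = ns),
    polarity = rep(ev$polarity, each = ns),
    rel_time_s = rep(epochs$rel_time, times = nt),
    pupil_mm = as.vector(t(epochs$pupil)),
    valid = as.integer(as.vector(t(epochs$valid)))
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
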