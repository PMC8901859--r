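#' Read and write trace tables as CSV
#'
#' The table has `time_s` as its first column and one column per neuron.
#'
#' @param traces a `trace_set`.
#' @param path file path.
#' @param f sampling rate; inferred from the time column on read if omitted.
#' @return `write_traces_csv` the path; `read_traces_csv` a `trace_set`.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- data.frame(time_s = traces$time_s, traces$F)
  names(df) <- c("time_s", traces$neuron_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, f = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_s") stop("first column must be time_s")
  if (is.null(f)) {
    dt <- diff(df$time_s)
    if (length(dt) < 1 || any(dt <= 0)) stop("cannot infer sampling rate")
    f <- 1 / stats::median(dt)
  }
  trace_set(as.matrix(df[, -1, drop = FALSE]), f = f,
            neuron_ids = names(df)[-1])
}

#' Read and write binary event matrices as CSV
#'
#' Rows are neurons, columns frames; values 0/1 with a transient peak
#' marked 1.
#'
#' @param events an `event_train_set`.
#' @param path file path.
#' @param f sampling rate, Hz (stored in a header comment on write,
#'   required on read).
#' @return `write_events_csv` the path; `read_events_csv` an
#'   `event_train_set`.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_train_set"))
  utils::write.table(events$B, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, f) {
  B <- as.matrix(utils::read.csv(path, header = FALSE))
  event_train_set(B, f = f)
}

#' Serialize a protocol to YAML and back
#' @param protocol a `stim_protocol`.
#' @param path file path.
#' @return `write_protocol_yaml` the path; `read_protocol_yaml` a
#'   `stim_protocol`.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  yaml::write_yaml(list(
    stimuli = as.list(protocol$trials$stimulus),
    onsets_s = as.list(protocol$trials$onset_s),
    duration_s = protocol$duration_s,
    isi_s = protocol$isi_s,
    diameters_deg = as.list(protocol$diameters_deg)
  ), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stim <- unlist(y$stimuli)
  onsets <- unlist(y$onsets_s)
  trials <- data.frame(stimulus = stim,
                       trial = stats::ave(seq_along(stim), stim,
                                          FUN = seq_along),
                       onset_s = onsets, duration_s = y$duration_s,
                       stringsAsFactors = FALSE)
  structure(list(trials = trials, stimuli = unique(stim),
                 diameters_deg = unlist(y$diameters_deg),
                 repeats = max(trials$trial), duration_s = y$duration_s,
                 isi_s = y$isi_s,
                 total_s = max(onsets) + y$duration_s + y$isi_s),
            class = "stim_protocol")
}

#' Write simulation ground truth as a JSON sidecar
#' @param gt a `ground_truth`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(list(
    spike_frames = gt$spike_frames,
    population_event_frames = gt$population_events$frame,
    recruited = gt$recruited,
    evoked = if (!is.null(gt$evoked)) apply(gt$evoked, 1, which,
                                            simplify = FALSE) else NULL
  ), path, auto_unbox = FALSE)
  invisible(path)
}
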