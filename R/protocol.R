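#' Build a visual stimulation protocol
#'
#' A protocol is a table of stimulus presentations: white spots of different
#' angular diameter shown on a black screen, each for a fixed duration and
#' separated by a black-screen inter-stimulus interval. The default follows
#' the two-stimulus design used throughout the package: the weak stimulus S1
#' (10.2 degrees) and the strong stimulus S4 (70.8 degrees), each repeated 5
#' times in randomized order, 2 s on, 20 s ISI.
#'
#' @param stimuli character vector of stimulus labels to include.
#' @param diameters_deg named numeric vector of angular diameters (degrees)
#'   for each label.
#' @param repeats presentations per stimulus.
#' @param duration_s stimulus duration in seconds.
#' @param isi_s inter-stimulus (black screen) interval in seconds.
#' @param pre_s lead-in time before the first presentation, seconds.
#' @param randomize randomize presentation order? If `FALSE`, stimuli are
#'   interleaved in label order.
#' @param seed RNG seed used only for the presentation order.
#' @return An object of class `stim_protocol`: a list with `trials` (a
#'   data.frame with columns `stimulus`, `trial`, `onset_s`, `duration_s`),
#'   `diameters_deg`, `isi_s` and `total_s`.
#' @examples
#' p <- stim_protocol(seed = 1)
#' head(p$trials)
#' @export
stim_protocol <- function(stimuli = c("S1", "S4"),
                          diameters_deg = c(S1 = 10.2, S2 = 20.2,
                                            S3 = 39.1, S4 = 70.8),
                          repeats = 5L,
                          duration_s = 2,
                          isi_s = 20,
                          pre_s = 5,
                          randomize = TRUE,
                          seed = NULL) {
  stopifnot(length(stimuli) >= 1, repeats >= 1, duration_s > 0, isi_s >= 0)
  order_vec <- rep(stimuli, each = repeats)
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    order_vec <- sample(order_vec)
  }
  n_pres <- length(order_vec)
  onsets <- pre_s + (seq_len(n_pres) - 1) * (duration_s + isi_s)
  trial_idx <- stats::ave(seq_len(n_pres), order_vec, FUN = seq_along)
  trials <- data.frame(
    stimulus = order_vec,
    trial = trial_idx,
    onset_s = onsets,
    duration_s = duration_s,
    stringsAsFactors = FALSE
  )
  structure(list(
    trials = trials,
    stimuli = stimuli,
    diameters_deg = diameters_deg,
    repeats = as.integer(repeats),
    duration_s = duration_s,
    isi_s = isi_s,
    total_s = max(onsets) + duration_s + isi_s
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d presentations of {%s}, %.3g s on / %.3g s ISI, total %.4g s\n",
              nrow(x$trials), paste(x$stimuli, collapse = ", "),
              x$duration_s, x$isi_s, x$total_s))
  invisible(x)
}

validate_protocol <- function(protocol, T_s = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  on_s <- protocol$trials$onset_s
  if (is.unsorted(on_s, strictly = TRUE))
    stop("protocol onsets must be strictly increasing")
  if (any(diff(on_s) < protocol$duration_s))
    stop("protocol presentations overlap")
  if (!is.null(T_s) &&
      max(on_s + protocol$trials$duration_s) > T_s)
    stop("protocol extends beyond the recording duration")
  invisible(protocol)
}
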