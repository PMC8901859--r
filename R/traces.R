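#' Extract per-ROI fluorescence traces from a movie
#'
#' The trace of an ROI at each frame is the mean gray value of all pixels
#' inside its mask.
#'
#' @param movie numeric array height x width x frames.
#' @param roiset list of logical mask matrices.
#' @param f sampling rate, Hz.
#' @return A `trace_set` (frames x ROIs).
#' @export
extract_roi_traces <- function(movie, roiset, f) {
  stopifnot(length(dim(movie)) == 3)
  dims <- dim(movie)
  Tn <- dims[3]
  flat <- matrix(movie, dims[1] * dims[2], Tn)
  F <- matrix(0, Tn, length(roiset))
  for (i in seq_along(roiset)) {
    mask <- roiset[[i]]
    if (!all(dim(mask) == dims[1:2]))
      stop(sprintf("ROI %d mask does not match frame dimensions", i))
    idx <- which(mask)
    if (length(idx) == 0) stop(sprintf("ROI %d has an empty mask", i))
    F[, i] <- colMeans(flat[idx, , drop = FALSE])
  }
  trace_set(F, f = f)
}

#' Compute relative fluorescence change dF/F0
#'
#' @param traces a `trace_set`.
#' @param protocol a `stim_protocol`, required for `"prestim-mean"`.
#' @param baseline_mode `"global-median"` uses the per-neuron median of the
#'   whole trace (spontaneous recordings); `"prestim-mean"` additionally
#'   re-baselines each stimulus epoch to the mean of the 1-s window before
#'   its onset, applied from 1 s before onset to 1 s after offset.
#' @return The `trace_set` with `dff` (frames x neurons) and `F0` filled in.
#' @export
compute_dff <- function(traces, protocol = NULL,
                        baseline_mode = c("global-median", "prestim-mean")) {
  stopifnot(inherits(traces, "trace_set"))
  baseline_mode <- match.arg(baseline_mode)
  F <- traces$F
  F0 <- apply(F, 2, stats::median)
  if (any(F0 <= 0)) stop("nonpositive baseline F0; cannot form dF/F0")
  dff <- sweep(sweep(F, 2, F0, "-"), 2, F0, "/")
  if (baseline_mode == "prestim-mean") {
    if (is.null(protocol)) stop("prestim-mean baseline requires a protocol")
    f <- traces$f
    Tn <- traces$n_frames
    for (j in seq_len(nrow(protocol$trials))) {
      on <- protocol$trials$onset_s[j]
      dur <- protocol$trials$duration_s[j]
      pre <- frames_in_window(on - 1, on, f, Tn)
      if (length(pre) == 0) stop("no prestimulus frames before an onset")
      win <- frames_in_window(on - 1, on + dur + 1, f, Tn)
      F0_trial <- colMeans(F[pre, , drop = FALSE])
      if (any(F0_trial <= 0)) stop("nonpositive prestimulus baseline")
      dff[win, ] <- sweep(sweep(F[win, , drop = FALSE], 2, F0_trial, "-"),
                          2, F0_trial, "/")
    }
  }
  traces$dff <- dff
  traces$F0 <- F0
  traces$baseline_mode <- baseline_mode
  traces
}

# robust baseline mean/SD of a dF/F trace by iterative 3-sigma clipping
baseline_stats <- function(x, clip_k = 3, max_iter = 20) {
  keep <- rep(TRUE, length(x))
  for (it in seq_len(max_iter)) {
    m <- mean(x[keep])
    s <- stats::sd(x[keep])
    if (!is.finite(s) || s == 0) break
    new_keep <- abs(x - m) <= clip_k * s
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  c(mean = m, sd = s)
}

#' Detect calcium transients by thresholded peak-picking
#'
#' A transient is accepted at a strict local maximum of the dF/F0 trace whose
#' height exceeds the baseline mean plus `k_sd` baseline standard deviations.
#' The baseline is estimated on the whole trace by iterative 3-sigma
#' clipping. Calcium transients rise fast and decay over ~1 s, so two shape
#' checks reject spurious maxima: a rise check - the peak must stand at
#' least the threshold height above the minimum of the preceding `rise_s`
#' window - discards ripples riding on the decay of an earlier transient,
#' and a sustained-elevation check - every frame within `sustain_s` after
#' the peak must stay above `sustain_frac` of the threshold - discards
#' single-frame noise excursions. A minimum peak separation is enforced
#' (the larger peak wins; ties go to the earlier frame).
#'
#' @param traces a `trace_set` with `dff` (see [compute_dff()]).
#' @param k_sd detection threshold in baseline SD units (default 2.5).
#' @param min_sep_s minimum separation between accepted peaks, seconds.
#' @param sustain_s post-peak window that must remain elevated, seconds;
#'   0 disables the check.
#' @param sustain_frac fraction of the threshold the post-peak window must
#'   exceed.
#' @param rise_s pre-peak window over which the rise is measured, seconds;
#'   0 disables the check.
#' @return An `event_train_set`: list with binary `B` (neurons x frames, 1 at
#'   transient peaks), `f`, `T_s`, `total_n` (frame count), `threshold`
#'   (per-neuron absolute threshold).
#' @export
detect_transients <- function(traces, k_sd = 2.5, min_sep_s = 0.25,
                              sustain_s = 0.2, sustain_frac = 0.5,
                              rise_s = 0.5) {
  stopifnot(inherits(traces, "trace_set"), k_sd > 0)
  if (is.null(traces$dff)) stop("run compute_dff() first")
  dff <- traces$dff
  Tn <- nrow(dff)
  n <- ncol(dff)
  min_sep <- max(1L, round(min_sep_s * traces$f))
  B <- matrix(0L, n, Tn)
  thr_out <- numeric(n)
  for (i in seq_len(n)) {
    x <- dff[, i]
    bs <- baseline_stats(x)
    if (!is.finite(bs["sd"]) || bs["sd"] == 0)
      stop(sprintf("neuron %d has zero baseline variance", i))
    thr <- bs["mean"] + k_sd * bs["sd"]
    thr_out[i] <- thr
    cand <- which(x > thr)
    cand <- cand[cand > 1 & cand < Tn]
    cand <- cand[x[cand] > x[cand - 1] & x[cand] >= x[cand + 1]]
    lo <- bs["mean"] + sustain_frac * (thr - bs["mean"])
    if (rise_s > 0 && length(cand)) {
      n_rise <- max(1L, round(rise_s * traces$f))
      rise_ok <- vapply(cand, function(p) {
        w <- max(1, p - n_rise):(p - 1)
        m <- stats::median(x[w])
        # onset must climb the full threshold height from a pre-peak level
        # that has settled near baseline (rejects ripples on a decay tail)
        x[p] - m >= thr - bs["mean"] && m <= lo
      }, logical(1))
      cand <- cand[rise_ok]
    }
    if (sustain_s > 0 && length(cand)) {
      n_sus <- round(sustain_s * traces$f)
      ok <- vapply(cand, function(p) {
        w <- p:min(Tn, p + n_sus)
        all(x[w] >= lo)
      }, logical(1))
      cand <- cand[ok]
    }
    if (length(cand) > 1) {
      ord <- cand[order(-x[cand], cand)]
      accepted <- integer(0)
      for (p in ord)
        if (!length(accepted) || all(abs(accepted - p) >= min_sep))
          accepted <- c(accepted, p)
      cand <- sort(accepted)
    }
    B[i, cand] <- 1L
  }
  event_train_set(B, f = traces$f, threshold = thr_out,
                  positions = traces$positions)
}

#' Construct an event train set
#' @param B binary neurons x frames matrix, 1 at transient peaks.
#' @param f sampling rate, Hz.
#' @param threshold optional per-neuron detection threshold.
#' @param positions optional neuron coordinates.
#' @return list of class `event_train_set` with `total_n` = frame count.
#' @export
event_train_set <- function(B, f, threshold = NULL, positions = NULL) {
  B <- as.matrix(B)
  if (!all(B %in% c(0L, 1L))) stop("event matrix must be binary")
  storage.mode(B) <- "integer"
  structure(list(B = B, f = f, T_s = ncol(B) / f, total_n = ncol(B),
                 n_neurons = nrow(B), threshold = threshold,
                 positions = positions),
            class = "event_train_set")
}

#' Classify stimulus-responsive neurons trial by trial
#'
#' A neuron is responsive in a trial when at least one transient peak falls
#' inside the 2-s stimulus window `[onset, onset + duration)` (half-open,
#' frame time = (frame - 1)/f). The per-stimulus response probability is the
#' responsive-trial fraction.
#'
#' @param events an `event_train_set`.
#' @param protocol a `stim_protocol` on the same timebase.
#' @return A `response_table`: list with `responded` (neurons x
#'   presentations logical), `prob` (neurons x stimuli), `percent` (named
#'   vector: mean over trials of the per-trial percentage of responding
#'   neurons), `ever_percent` (percentage of neurons responding in >= 1
#'   trial), `trials`, `n_trials`.
#' @export
classify_responsive <- function(events, protocol) {
  stopifnot(inherits(events, "event_train_set"))
  validate_protocol(protocol)
  trials <- protocol$trials
  n <- events$n_neurons
  responded <- matrix(FALSE, n, nrow(trials))
  for (j in seq_len(nrow(trials))) {
    w <- frames_in_window(trials$onset_s[j],
                          trials$onset_s[j] + trials$duration_s[j],
                          events$f, events$total_n)
    if (length(w))
      responded[, j] <- rowSums(events$B[, w, drop = FALSE]) > 0
  }
  stim_levels <- unique(c(intersect(protocol$stimuli, trials$stimulus),
                          trials$stimulus))
  prob <- sapply(stim_levels, function(s) {
    cols <- which(trials$stimulus == s)
    rowMeans(responded[, cols, drop = FALSE])
  })
  prob <- matrix(prob, nrow = n, dimnames = list(NULL, stim_levels))
  percent <- vapply(stim_levels, function(s) {
    cols <- which(trials$stimulus == s)
    mean(colMeans(responded[, cols, drop = FALSE])) * 100
  }, numeric(1))
  ever_percent <- vapply(stim_levels, function(s)
    mean(prob[, s] > 0) * 100, numeric(1))
  n_trials <- vapply(stim_levels, function(s)
    sum(trials$stimulus == s), integer(1))
  structure(list(responded = responded, prob = prob, percent = percent,
                 ever_percent = ever_percent, trials = trials,
                 n_trials = n_trials, stimuli = stim_levels),
            class = "response_table")
}

#' Per-neuron, per-stimulus response amplitude
#'
#' The amplitude for a responsive trial is the peak dF/F0 within the
#' stimulus window; per neuron and stimulus, amplitudes are averaged over
#' responsive trials only. Neurons with no responsive trial get `NA`.
#'
#' @param traces a `trace_set` with `dff`.
#' @param events the matching `event_train_set`.
#' @param protocol a `stim_protocol`.
#' @return neurons x stimuli numeric matrix of mean amplitudes.
#' @export
response_amplitude <- function(traces, events, protocol) {
  stopifnot(inherits(traces, "trace_set"), !is.null(traces$dff))
  rt <- classify_responsive(events, protocol)
  trials <- protocol$trials
  n <- ncol(traces$dff)
  amp_trial <- matrix(NA_real_, n, nrow(trials))
  for (j in seq_len(nrow(trials))) {
    w <- frames_in_window(trials$onset_s[j],
                          trials$onset_s[j] + trials$duration_s[j],
                          traces$f, traces$n_frames)
    if (length(w)) {
      pk <- apply(traces$dff[w, , drop = FALSE], 2, max)
      amp_trial[rt$responded[, j], j] <- pk[rt$responded[, j]]
    }
  }
  out <- sapply(rt$stimuli, function(s) {
    cols <- which(trials$stimulus == s)
    rowMeans(amp_trial[, cols, drop = FALSE], na.rm = TRUE)
  })
  out <- matrix(out, nrow = n, dimnames = list(NULL, rt$stimuli))
  out[is.nan(out)] <- NA_real_
  out
}

#' Neural activity index (NAI)
#'
#' Ratio of the percentage of neurons responding to the weak stimulus over
#' the percentage responding to the strong stimulus. Percentages are the
#' mean over trials of the per-trial responding percentage (see
#' [classify_responsive()]).
#'
#' @param response_table a `response_table`, or a named numeric vector of
#'   percentages.
#' @param weak,strong stimulus labels.
#' @return NAI, a single number.
#' @export
compute_nai <- function(response_table, weak = "S1", strong = "S4") {
  pct <- if (inherits(response_table, "response_table"))
    response_table$percent else response_table
  if (!all(c(weak, strong) %in% names(pct)))
    stop("both stimuli must be present in the response table")
  if (pct[[strong]] == 0)
    stop("NAI undefined: no neurons respond to the strong stimulus")
  unname(pct[[weak]] / pct[[strong]])
}
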