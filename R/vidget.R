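#' Downsampled, rectified relative piezo signal
#'
#' Shared front end of the vidget statistics: the raw voltage is
#' down-sampled by block averaging (1000 -> 100 Hz by default), referenced
#' to the session-mean baseline F0, expressed as (F - F0)/F0, and rectified
#' elementwise (sqrt(x^2) = |x|) to eliminate negative values.
#'
#' @param piezo a `piezo_recording`.
#' @param target_hz output rate after block averaging.
#' @return list with `rect` (rectified relative signal), `rel` (signed
#'   relative signal), `fs` (output rate), `time_s`, `F0`.
#' @export
piezo_preprocess <- function(piezo, target_hz = 100) {
  stopifnot(inherits(piezo, "piezo_recording"), target_hz > 0)
  block <- piezo$fs / target_hz
  if (abs(block - round(block)) > 1e-9)
    stop("sampling rate must be an integer multiple of target_hz")
  block <- as.integer(round(block))
  v <- piezo$voltage
  nblk <- floor(length(v) / block)
  ds <- colMeans(matrix(v[seq_len(nblk * block)], block, nblk))
  F0 <- mean(ds)
  if (F0 == 0) stop("session-mean baseline is zero")
  rel <- (ds - F0) / F0
  list(rect = abs(rel), rel = rel, fs = target_hz,
       time_s = (seq_len(nblk) - 1) / target_hz, F0 = F0)
}

#' Vidget score per stimulus presentation
#'
#' The score of a presentation is the mean of the rectified relative piezo
#' signal over the `window_s` (default 0.5 s) following stimulus onset, in
#' arbitrary units.
#'
#' @param piezo a `piezo_recording` (onsets taken from it).
#' @param window_s averaging window after onset, seconds.
#' @param target_hz downsampling rate, Hz.
#' @return data.frame with `onset_s`, `score`, and the stimulus label when a
#'   protocol is attached.
#' @export
vidget_score <- function(piezo, window_s = 0.5, target_hz = 100) {
  pp <- piezo_preprocess(piezo, target_hz)
  scores <- vapply(piezo$onsets_s, function(on) {
    idx <- which(pp$time_s >= on & pp$time_s < on + window_s)
    if (length(idx) < window_s * target_hz)
      stop("onset too close to the end of the recording")
    mean(pp$rect[idx])
  }, numeric(1))
  out <- data.frame(onset_s = piezo$onsets_s, score = scores)
  if (!is.null(piezo$protocol))
    out$stimulus <- piezo$protocol$trials$stimulus
  out
}

#' Vidget response delay per presentation
#'
#' The delay is the first time after onset at which the rectified relative
#' signal exceeds the pre-onset baseline mean plus `k_sd` baseline SDs
#' continuously for at least `sustain_s`. Presentations that never cross
#' return `NA`.
#'
#' @param piezo a `piezo_recording`.
#' @param k_sd threshold in baseline SD units.
#' @param sustain_s minimum supra-threshold duration, seconds.
#' @param baseline_s pre-onset baseline length, seconds (>= 2 recommended).
#' @param target_hz downsampling rate, Hz.
#' @return data.frame with `onset_s`, `delay_s` (NA when no crossing).
#' @export
vidget_delay <- function(piezo, k_sd = 3, sustain_s = 0.05,
                         baseline_s = 2, target_hz = 100) {
  pp <- piezo_preprocess(piezo, target_hz)
  need <- max(1L, as.integer(round(sustain_s * target_hz)))
  delays <- vapply(piezo$onsets_s, function(on) {
    base_idx <- which(pp$time_s >= on - baseline_s & pp$time_s < on)
    if (length(base_idx) < 2)
      stop("insufficient pre-onset baseline for delay estimation")
    thr <- mean(pp$rect[base_idx]) + k_sd * stats::sd(pp$rect[base_idx])
    post <- which(pp$time_s >= on)
    above <- pp$rect[post] > thr
    if (!any(above)) return(NA_real_)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values & r$lengths >= need)
    if (!length(ok)) return(NA_real_)
    pp$time_s[post[starts[ok[1]]]] - on
  }, numeric(1))
  data.frame(onset_s = piezo$onsets_s, delay_s = delays)
}

#' Piecewise-linear fit of the cumulative vidget magnitude
#'
#' The rectified relative signal is cumulated over a window spanning
#' `pre_s` before to `post_s` after each onset; two ordinary least-squares
#' lines are fitted with the breakpoint fixed at the stimulus onset. The
#' slopes are in a.u./s on the cumulative scale.
#'
#' @param piezo a `piezo_recording`.
#' @param pre_s baseline span before onset, seconds.
#' @param post_s span after onset, seconds.
#' @param target_hz downsampling rate, Hz.
#' @return data.frame with `onset_s`, `k_baseline`, `k_stimulus`.
#' @export
cumulative_fit <- function(piezo, pre_s = 2, post_s = 2, target_hz = 100) {
  pp <- piezo_preprocess(piezo, target_hz)
  fit1 <- function(t, y) unname(stats::coef(stats::lm(y ~ t))[2])
  res <- lapply(piezo$onsets_s, function(on) {
    idx <- which(pp$time_s >= on - pre_s & pp$time_s < on + post_s)
    if (length(idx) < 6) stop("window too short for piecewise fit")
    cum <- cumsum(pp$rect[idx])
    t <- pp$time_s[idx] - on
    pre <- t < 0
    if (sum(pre) <= 2 || sum(!pre) <= 2)
      stop("need more than 2 points on each side of the breakpoint")
    c(k_baseline = fit1(t[pre], cum[pre]),
      k_stimulus = fit1(t[!pre], cum[!pre]))
  })
  out <- do.call(rbind, res)
  data.frame(onset_s = piezo$onsets_s,
             k_baseline = out[, "k_baseline"],
             k_stimulus = out[, "k_stimulus"])
}

#' Piecewise slopes of a precomputed cumulative series
#'
#' Fits the two fixed-breakpoint least-squares lines directly to a
#' cumulative magnitude series, for callers that already built it.
#'
#' @param time_s time axis, seconds (breakpoint at 0).
#' @param cum cumulative magnitude values.
#' @return named vector `c(k_baseline, k_stimulus)`.
#' @export
piecewise_slopes <- function(time_s, cum) {
  stopifnot(length(time_s) == length(cum))
  pre <- time_s < 0
  if (sum(pre) <= 2 || sum(!pre) <= 2)
    stop("need more than 2 points on each side of the breakpoint")
  f <- function(t, y) unname(stats::coef(stats::lm(y ~ t))[2])
  c(k_baseline = f(time_s[pre], cum[pre]),
    k_stimulus = f(time_s[!pre], cum[!pre]))
}
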