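#' Preprocess a dF/F0 trace for pairwise correlation
#'
#' Low-pass Butterworth filtering (zero-phase, forward-backward), exact
#' inverse deconvolution of the discrete exponential calcium kernel
#' (d[t] = x[t] - exp(-1/(f tau)) x[t-1]), and thresholding: samples below
#' `zero_k` standard deviations of the deconvolved trace are set to zero,
#' leaving a sparse nonnegative activity vector.
#'
#' @param dff numeric dF/F0 vector (or frames x neurons matrix).
#' @param f sampling rate, Hz.
#' @param butter_order Butterworth order.
#' @param cutoff_hz low-pass cutoff, Hz (must be below Nyquist).
#' @param tau deconvolution kernel time constant, seconds (default 3).
#' @param zero_k zeroing threshold in SD units (default 2).
#' @return deconvolved, thresholded vector (or matrix, by column).
#' @export
preprocess_trace <- function(dff, f, butter_order = 4, cutoff_hz = 2,
                             tau = 3, zero_k = 2) {
  if (is.matrix(dff))
    return(apply(dff, 2, preprocess_trace, f = f,
                 butter_order = butter_order, cutoff_hz = cutoff_hz,
                 tau = tau, zero_k = zero_k))
  if (cutoff_hz >= f / 2) stop("cutoff must be below the Nyquist frequency")
  if (all(dff == 0)) return(dff)
  bf <- signal::butter(butter_order, cutoff_hz / (f / 2), type = "low")
  x <- signal::filtfilt(bf, dff)
  decay <- exp(-1 / (f * tau))
  d <- c(x[1], x[-1] - decay * x[-length(x)])
  s <- stats::sd(d)
  d[d < zero_k * s] <- 0
  d
}

#' Pairwise activity coefficient (cosine similarity)
#'
#' Coefficient(A, B) = A.B / (||A|| ||B||) on the deconvolved, thresholded
#' activity vectors of a neuron pair. Undefined (NA, with a warning) when
#' either vector is all zero.
#'
#' @param A,B equal-length numeric vectors.
#' @return coefficient in [-1, 1], or NA.
#' @export
pair_coefficient <- function(A, B) {
  if (length(A) != length(B)) stop("vectors must have equal length")
  na <- sqrt(sum(A^2))
  nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0) {
    warning("zero activity vector: coefficient undefined")
    return(NA_real_)
  }
  sum(A * B) / (na * nb)
}

#' All pairwise coefficients of an activity matrix
#'
#' @param act frames x neurons matrix of preprocessed activity.
#' @return symmetric neurons x neurons coefficient matrix, diagonal NA.
#' @export
coefficient_matrix <- function(act) {
  act <- as.matrix(act)
  norms <- sqrt(colSums(act^2))
  cm <- crossprod(act)
  denom <- outer(norms, norms)
  cm <- ifelse(denom > 0, cm / denom, NA_real_)
  diag(cm) <- NA
  cm
}

#' Distance-binned pairwise correlation structure
#'
#' Pairs neurons, computes Euclidean distances between their positions,
#' assigns each pair to a half-open distance bin [lo, hi), and summarizes
#' the coefficient per bin.
#'
#' @param coeffs symmetric coefficient matrix (see [coefficient_matrix()]),
#'   or a vector aligned with the pair order of `dist(positions)`.
#' @param positions n x 2 matrix of coordinates, micrometers.
#' @param bin_um bin width, micrometers (default 50).
#' @return list of class `distance_correlation`: `pairs` (data.frame i, j,
#'   distance_um, coefficient, bin), `by_bin` (data.frame bin_lo, bin_hi,
#'   n_pairs, mean_coefficient), `ecdf` (cumulative distribution function of
#'   the coefficients).
#' @export
distance_binned_correlation <- function(coeffs, positions, bin_um = 50) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  d <- as.matrix(stats::dist(positions))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  dist_v <- d[ut]
  coef_v <- if (is.matrix(coeffs)) coeffs[ut] else as.numeric(coeffs)
  if (length(coef_v) != nrow(ut))
    stop("coefficient count does not match the number of pairs")
  bin <- floor(dist_v / bin_um)
  pairs <- data.frame(i = ut[, 1], j = ut[, 2], distance_um = dist_v,
                      coefficient = coef_v, bin = bin)
  agg <- stats::aggregate(coefficient ~ bin, data = pairs,
                          FUN = function(v) mean(v, na.rm = TRUE))
  cnt <- stats::aggregate(coefficient ~ bin, data = pairs, FUN = length)
  by_bin <- data.frame(bin_lo = agg$bin * bin_um,
                       bin_hi = (agg$bin + 1) * bin_um,
                       n_pairs = cnt$coefficient,
                       mean_coefficient = agg$coefficient)
  ok <- !is.na(coef_v)
  structure(list(pairs = pairs, by_bin = by_bin,
                 ecdf = if (any(ok)) stats::ecdf(coef_v[ok]) else NULL,
                 bin_um = bin_um, n_neurons = n),
            class = "distance_correlation")
}
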