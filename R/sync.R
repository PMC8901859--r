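#' Total number of points in a binary event time series
#'
#' Frame count of a recording: duration times sampling rate, rounded up.
#' For the reference 73.5-s recording at 20.4 Hz this is 1,500 frames.
#'
#' @param T_s recording length, seconds.
#' @param f sampling rate, Hz.
#' @return integer frame count.
#' @examples
#' total_points(73.5, 20.4)  # 1500
#' @export
total_points <- function(T_s, f) {
  if (T_s <= 0 || f <= 0) stop("T_s and f must be positive")
  as.integer(ceiling(T_s * f))
}

#' Randomly subsample a circuit of N neurons
#'
#' Circuit sizes vary across recordings; synchrony statistics are therefore
#' computed on random N-neuron subgroups drawn without replacement.
#'
#' @param events an `event_train_set`.
#' @param N subgroup size (default 30).
#' @param seed RNG seed.
#' @return an `event_train_set` with N rows (neuron order preserved).
#' @export
subsample_circuit <- function(events, N = 30, seed = NULL) {
  stopifnot(inherits(events, "event_train_set"))
  if (events$n_neurons < N) stop("population smaller than subgroup size N")
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(events$n_neurons, N))
  event_train_set(events$B[keep, , drop = FALSE], f = events$f,
                  threshold = events$threshold[keep],
                  positions = events$positions[keep, , drop = FALSE])
}

#' n-order firing counts
#'
#' Firing(n) is the number of frames in which exactly n neurons emit a
#' simultaneous transient peak, n = 1..N. Frames with no spikes are not
#' counted.
#'
#' @param events an `event_train_set` (or a binary neurons x frames matrix).
#' @return integer vector Firing(1..N), named by n.
#' @export
firing_counts <- function(events) {
  B <- if (inherits(events, "event_train_set")) events$B else as.matrix(events)
  if (!all(B %in% c(0L, 1L))) stop("event matrix must be binary")
  N <- nrow(B)
  s <- colSums(B)
  out <- tabulate(s[s > 0], nbins = N)
  names(out) <- seq_len(N)
  out
}

#' n-order correlation probability
#'
#' Correlation_prob(n) = Firing(n) / Total_n.
#'
#' @param firing integer vector from [firing_counts()].
#' @param total_n frame count from [total_points()].
#' @return numeric vector of probabilities, named by n.
#' @export
correlation_prob <- function(firing, total_n) {
  if (total_n <= 0) stop("total_n must be positive")
  firing / total_n
}

#' Monte-Carlo independent model for n-order synchrony
#'
#' Destroys cross-neuron structure while preserving each neuron's spike
#' count by independently permuting every neuron's frame indices
#' (`method = "permute"`, default) or circularly shifting its spike train
#' (`method = "circshift"`), then recomputes Correlation_prob(n) on each of
#' `n_shuffles` surrogates.
#'
#' @param events an `event_train_set`.
#' @param n_shuffles number of surrogates (default 10000).
#' @param seed RNG seed.
#' @param method shuffle family.
#' @param ranges list of n-ranges (lo, hi) aggregated per surrogate.
#' @param ci central quantile pair for the per-n envelope.
#' @return list of class `sync_null`: `null_probs` (n_shuffles x N matrix of
#'   Correlation_prob), `mean` (per-n null mean), `lower`/`upper` (per-n
#'   envelope), `range_null` (n_shuffles x length(ranges)), `range_upper`
#'   (97.5th-percentile style bound per range), `n_shuffles`, `method`.
#' @export
shuffle_null <- function(events, n_shuffles = 10000, seed = NULL,
                         method = c("permute", "circshift"),
                         ranges = list(c(1, 10), c(11, Inf)),
                         ci = c(0.025, 0.975)) {
  stopifnot(inherits(events, "event_train_set"), n_shuffles >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  spikes <- apply(events$B, 1, function(r) which(r == 1L) - 1L,
                  simplify = FALSE)
  firing <- cpp_shuffle_firing(spikes, events$total_n, as.integer(n_shuffles),
                               if (method == "permute") 0L else 1L)
  null_probs <- firing / events$total_n
  colnames(null_probs) <- seq_len(events$n_neurons)
  range_null <- sapply(ranges, function(r) {
    cols <- range_cols(r, events$n_neurons)
    if (length(cols)) rowSums(null_probs[, cols, drop = FALSE]) else
      rep(0, n_shuffles)
  })
  range_null <- matrix(range_null, nrow = n_shuffles,
                       dimnames = list(NULL, range_labels(ranges)))
  structure(list(
    null_probs = null_probs,
    mean = colMeans(null_probs),
    lower = apply(null_probs, 2, stats::quantile, probs = ci[1]),
    upper = apply(null_probs, 2, stats::quantile, probs = ci[2]),
    range_null = range_null,
    range_mean = colMeans(range_null),
    range_upper = apply(range_null, 2, stats::quantile, probs = ci[2]),
    n_shuffles = n_shuffles, method = method, ranges = ranges, ci = ci
  ), class = "sync_null")
}

range_cols <- function(r, N) {
  lo <- max(1, r[1])
  hi <- min(N, r[2])
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

range_labels <- function(ranges) {
  vapply(ranges, function(r)
    paste0(r[1], "-", if (is.finite(r[2])) r[2] else "Inf"), character(1))
}

#' One count-preserving shuffle of an event train set
#'
#' Mostly useful for inspecting the null; [shuffle_null()] generates
#' surrogates in bulk without materializing them.
#'
#' @param events an `event_train_set`.
#' @param seed RNG seed.
#' @return an `event_train_set` with identical per-neuron spike counts.
#' @export
shuffle_events <- function(events, seed = NULL) {
  stopifnot(inherits(events, "event_train_set"))
  if (!is.null(seed)) set.seed(seed)
  B <- events$B
  out <- matrix(0L, nrow(B), ncol(B))
  for (i in seq_len(nrow(B))) {
    c_i <- sum(B[i, ])
    if (c_i > 0) out[i, sample.int(ncol(B), c_i)] <- 1L
  }
  stopifnot(all(rowSums(out) == rowSums(B)))
  event_train_set(out, f = events$f, threshold = events$threshold,
                  positions = events$positions)
}

#' Aggregate correlation probabilities over n-ranges
#'
#' @param probs per-n Correlation_prob vector.
#' @param ranges list of disjoint (lo, hi) ranges; `Inf` allowed.
#' @return named numeric vector of range sums.
#' @export
aggregate_ranges <- function(probs, ranges = list(c(1, 10), c(11, Inf))) {
  N <- length(probs)
  cols <- lapply(ranges, range_cols, N = N)
  all_cols <- unlist(cols)
  if (anyDuplicated(all_cols)) stop("ranges must be disjoint")
  out <- vapply(cols, function(cc) sum(probs[cc]), numeric(1))
  names(out) <- range_labels(ranges)
  out
}

#' Pairwise synchronization counts by functional assembly
#'
#' count(i, j) is the number of frames in which neurons i and j both emit a
#' transient peak. Counts are summarized within and between the four
#' functional assemblies.
#'
#' @param events an `event_train_set`.
#' @param type_assignment integer vector of assembly labels (1..4), one per
#'   neuron.
#' @return list of class `assembly_sync`: `counts` (symmetric matrix,
#'   diagonal NA), `assembly_mean` (4 x 4 mean count over pairs by assembly
#'   combination), `overall_mean` (mean over all distinct pairs).
#' @export
pairwise_sync_counts <- function(events, type_assignment) {
  stopifnot(inherits(events, "event_train_set"))
  n <- events$n_neurons
  if (length(type_assignment) != n)
    stop("type assignment must cover every neuron")
  B <- events$B
  counts <- B %*% t(B)
  diag(counts) <- NA
  types <- sort(unique(type_assignment))
  am <- matrix(NA_real_, length(types), length(types),
               dimnames = list(types, types))
  for (a in seq_along(types)) for (b in seq_len(a)) {
    ia <- which(type_assignment == types[a])
    ib <- which(type_assignment == types[b])
    vals <- counts[ia, ib, drop = FALSE]
    vals <- vals[!is.na(vals)]
    if (length(vals)) am[a, b] <- am[b, a] <- mean(vals)
  }
  structure(list(counts = counts, assembly_mean = am,
                 overall_mean = mean(counts[upper.tri(counts)])),
            class = "assembly_sync")
}

#' Full n-order synchrony analysis with subsampling and null
#'
#' Convenience wrapper: repeatedly subsamples N-neuron circuits, averages
#' the observed Correlation_prob over subsamples, and pools the shuffle null
#' across them.
#'
#' @param events an `event_train_set`.
#' @param N circuit subgroup size.
#' @param n_subsamples number of random subgroups averaged (used only when
#'   the population exceeds N).
#' @param n_shuffles surrogates per subgroup.
#' @param ranges n-ranges to aggregate.
#' @param seed RNG seed.
#' @return list: `observed_probs` (per-n, averaged), `observed_ranges`,
#'   `null` (pooled `sync_null`-like summary), `N`, `n_subsamples`.
#' @export
sync_analysis <- function(events, N = 30, n_subsamples = 20,
                          n_shuffles = 1000,
                          ranges = list(c(1, 10), c(11, Inf)), seed = NULL) {
  stopifnot(inherits(events, "event_train_set"))
  if (!is.null(seed)) set.seed(seed)
  m <- if (events$n_neurons > N) n_subsamples else 1L
  probs_acc <- NULL
  range_null_acc <- NULL
  null_probs_mean_acc <- NULL
  for (r in seq_len(m)) {
    sub <- if (events$n_neurons > N) subsample_circuit(events, N) else events
    obs <- correlation_prob(firing_counts(sub), sub$total_n)
    nul <- shuffle_null(sub, n_shuffles = n_shuffles, ranges = ranges)
    probs_acc <- if (is.null(probs_acc)) obs / m else probs_acc + obs / m
    null_probs_mean_acc <- if (is.null(null_probs_mean_acc))
      nul$mean / m else null_probs_mean_acc + nul$mean / m
    range_null_acc <- rbind(range_null_acc, nul$range_null)
  }
  list(observed_probs = probs_acc,
       observed_ranges = aggregate_ranges(probs_acc, ranges),
       null_mean = null_probs_mean_acc,
       null_range_upper = apply(range_null_acc, 2, stats::quantile, 0.975),
       null_range_mean = colMeans(range_null_acc),
       N = N, n_subsamples = m, n_shuffles = n_shuffles)
}
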