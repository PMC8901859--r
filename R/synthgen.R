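#' Simulation configuration
#'
#' Collects the imaging and kinetic parameters shared by the synthetic
#' generators. Defaults mirror the recording conditions the analysis assumes:
#' 20.4 Hz frame rate, ~73.5 s spontaneous recordings, and OGB-1-like
#' single-exponential calcium transients.
#'
#' @param f imaging frame rate, Hz.
#' @param T_s recording duration, seconds.
#' @param tau_decay calcium transient decay constant, seconds.
#' @param amp transient peak amplitude in dF/F0 units.
#' @param noise_sd per-frame Gaussian noise SD in dF/F0 units.
#' @param bg_rate background (spontaneous) transient rate per neuron, Hz.
#' @param sync_rate rate of shared population events, Hz (0 = independent).
#' @param sync_recruit probability that a given neuron joins a population
#'   event.
#' @param F0 baseline fluorescence, arbitrary units.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(f = 20.4, T_s = 73.5, tau_decay = 1.0, amp = 0.12,
                       noise_sd = 0.01, bg_rate = 0.02,
                       sync_rate = 0, sync_recruit = 0.5, F0 = 100) {
  stopifnot(f > 0, T_s > 0, tau_decay > 0, amp >= 0, noise_sd >= 0,
            bg_rate >= 0, sync_rate >= 0,
            sync_recruit >= 0, sync_recruit <= 1, F0 > 0)
  structure(list(f = f, T_s = T_s, tau_decay = tau_decay, amp = amp,
                 noise_sd = noise_sd, bg_rate = bg_rate,
                 sync_rate = sync_rate, sync_recruit = sync_recruit,
                 F0 = F0, n_frames = total_points(T_s, f)),
            class = "sim_config")
}

#' Generate a synthetic neuron population
#'
#' Places `n` neurons in a square field of view and assigns each a functional
#' type with per-stimulus response probabilities. The four types follow the
#' standard 2x2 classification against a weak (S1) and a strong (S4)
#' stimulus: type 1 responds to S4 only, type 2 to S1 only, type 3 to both,
#' type 4 to neither.
#'
#' @param n number of neurons.
#' @param fov_um side length of the square field of view, micrometers.
#' @param type_fractions length-4 numeric, fractions of types 1..4; must sum
#'   to 1.
#' @param p_resp_by_type 4 x 2 matrix of per-trial response probabilities,
#'   rows = types 1..4, columns = (S1, S4).
#' @param clustering `NULL` for complete spatial randomness, or a list
#'   `list(n_clusters =, sd_um =)` for a mixture of isotropic Gaussians
#'   (coordinates reflected back into the field of view).
#' @param seed RNG seed.
#' @return A list of class `population` with `positions` (n x 2 matrix, um),
#'   `type` (integer 1..4), `p_resp` (n x 2 matrix, columns S1/S4), `fov_um`.
#' @examples
#' pop <- make_population(50, seed = 1)
#' table(pop$type)
#' @export
make_population <- function(n, fov_um = 517.77,
                            type_fractions = c(0.40, 0.10, 0.10, 0.40),
                            p_resp_by_type = default_p_resp(),
                            clustering = NULL, seed = NULL) {
  stopifnot(n >= 1, fov_um > 0)
  if (length(type_fractions) != 4 || any(type_fractions < 0))
    stop("type_fractions must be 4 nonnegative numbers")
  if (abs(sum(type_fractions) - 1) > 1e-8)
    stop("type_fractions must sum to 1")
  p_resp_by_type <- as.matrix(p_resp_by_type)
  if (!all(dim(p_resp_by_type) == c(4, 2)) ||
      any(p_resp_by_type < 0) || any(p_resp_by_type > 1))
    stop("p_resp_by_type must be a 4 x 2 matrix of probabilities")
  if (!is.null(seed)) set.seed(seed)

  type <- sample.int(4L, n, replace = TRUE, prob = type_fractions)
  if (is.null(clustering)) {
    positions <- cbind(stats::runif(n, 0, fov_um), stats::runif(n, 0, fov_um))
  } else {
    k <- clustering$n_clusters
    sd_um <- clustering$sd_um
    stopifnot(k >= 1, sd_um > 0)
    centers <- cbind(stats::runif(k, 0, fov_um), stats::runif(k, 0, fov_um))
    assign <- sample.int(k, n, replace = TRUE)
    positions <- centers[assign, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, 0, sd_um), ncol = 2)
    # reflect strays back into the field of view
    positions <- abs(positions)
    positions <- fov_um - abs(fov_um - positions)
  }
  colnames(positions) <- c("x_um", "y_um")
  p_resp <- p_resp_by_type[type, , drop = FALSE]
  colnames(p_resp) <- c("S1", "S4")
  structure(list(positions = positions, type = type, p_resp = p_resp,
                 fov_um = fov_um, n = n),
            class = "population")
}

#' Default per-trial response probabilities by functional type
#'
#' Rows are types 1..4 (S4-only, S1-only, both, neither), columns (S1, S4).
#' With the default type fractions these give population-mean per-trial
#' probabilities near 0.10 for S1 and 0.30 for S4, i.e. a wild-type-like
#' contrast between the weak and strong stimulus.
#' @return 4 x 2 numeric matrix.
#' @export
default_p_resp <- function() {
  matrix(c(0.0, 0.6,
           0.5, 0.0,
           0.5, 0.6,
           0.0, 0.0), nrow = 4, byrow = TRUE,
         dimnames = list(paste0("type", 1:4), c("S1", "S4")))
}

#' Simulate spiking ground truth for a population under a protocol
#'
#' Per presentation, each neuron emits an evoked transient with its
#' per-stimulus Bernoulli probability, placed uniformly inside the stimulus
#' window. Background transients arrive as a Poisson process, and optional
#' shared population events recruit random neuron subsets in a single frame,
#' creating high-order synchrony.
#'
#' @param pop a `population` from [make_population()].
#' @param protocol a `stim_protocol`, or `NULL` for a spontaneous recording.
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return A list of class `ground_truth`: `spike_frames` (per-neuron sorted
#'   1-based frame indices), `evoked` (n x presentations logical matrix or
#'   NULL), `population_events` (data.frame frame/n_recruited),
#'   `recruited` (list of neuron index vectors per event), `config`,
#'   `protocol`.
#' @export
simulate_activity <- function(pop, protocol, config = sim_config(),
                              seed = NULL) {
  stopifnot(inherits(pop, "population"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- pop$n
  f <- config$f
  Tn <- config$n_frames
  spike_frames <- vector("list", n)

  evoked <- NULL
  if (!is.null(protocol)) {
    validate_protocol(protocol, T_s = config$T_s)
    trials <- protocol$trials
    evoked <- matrix(FALSE, n, nrow(trials))
    for (j in seq_len(nrow(trials))) {
      stim <- trials$stimulus[j]
      p <- if (stim %in% colnames(pop$p_resp)) pop$p_resp[, stim] else rep(0, n)
      hit <- stats::runif(n) < p
      evoked[, j] <- hit
      if (any(hit)) {
        w <- frames_in_window(trials$onset_s[j],
                              trials$onset_s[j] + trials$duration_s[j], f, Tn)
        frames <- w[sample.int(length(w), sum(hit), replace = TRUE)]
        idx <- which(hit)
        for (ii in seq_along(idx))
          spike_frames[[idx[ii]]] <- c(spike_frames[[idx[ii]]], frames[ii])
      }
    }
  }

  if (config$bg_rate > 0) {
    counts <- stats::rpois(n, config$bg_rate * config$T_s)
    for (i in seq_len(n)) if (counts[i] > 0)
      spike_frames[[i]] <- c(spike_frames[[i]],
                             sample.int(Tn, min(counts[i], Tn)))
  }

  pop_events <- data.frame(frame = integer(0), n_recruited = integer(0))
  recruited <- list()
  if (config$sync_rate > 0) {
    n_ev <- stats::rpois(1, config$sync_rate * config$T_s)
    if (n_ev > 0) {
      ev_frames <- sample.int(Tn, min(n_ev, Tn))
      for (e in seq_along(ev_frames)) {
        members <- which(stats::runif(n) < config$sync_recruit)
        recruited[[e]] <- members
        for (i in members)
          spike_frames[[i]] <- c(spike_frames[[i]], ev_frames[e])
      }
      pop_events <- data.frame(frame = ev_frames,
                               n_recruited = vapply(recruited, length, 1L))
    }
  }

  spike_frames <- lapply(spike_frames, function(x) sort(unique(as.integer(x))))
  structure(list(spike_frames = spike_frames, evoked = evoked,
                 population_events = pop_events, recruited = recruited,
                 config = config, protocol = protocol, n = n),
            class = "ground_truth")
}

# 1-based frame indices whose time (frame-1)/f lies in [t0, t1)
frames_in_window <- function(t0, t1, f, n_frames) {
  lo <- ceiling(t0 * f) + 1
  hi <- ceiling(t1 * f)
  lo <- max(1L, as.integer(lo))
  hi <- min(n_frames, as.integer(hi))
  if (hi < lo) integer(0) else lo:hi
}

#' Render fluorescence traces from spiking ground truth
#'
#' Each spike injects a single-exponential calcium transient of peak
#' amplitude `amp` (dF/F0 units) decaying with `tau_decay`; i.i.d. Gaussian
#' noise is added in relative units, and the result is scaled by the
#' baseline: F(t) = F0 * (1 + amp * sum kernel(t - t_spike) + noise).
#'
#' @param gt a `ground_truth` from [simulate_activity()].
#' @param config a `sim_config`; defaults to the one stored in `gt`.
#' @param pop optional `population` used to attach positions.
#' @param seed RNG seed (noise only).
#' @return A `trace_set`: list with `F` (frames x neurons matrix), `f`,
#'   `time_s`, `F0` (per-neuron baseline), `positions`, `n_frames`.
#' @export
render_traces <- function(gt, config = gt$config, pop = NULL, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- gt$n
  Tn <- config$n_frames
  kern_len <- min(Tn, ceiling(6 * config$tau_decay * config$f))
  kern <- exp(-(0:(kern_len - 1)) / (config$tau_decay * config$f))
  dff <- matrix(0, Tn, n)
  for (i in seq_len(n)) {
    for (s in gt$spike_frames[[i]]) {
      idx <- s:min(Tn, s + kern_len - 1)
      dff[idx, i] <- dff[idx, i] + config$amp * kern[seq_along(idx)]
    }
  }
  if (config$noise_sd > 0)
    dff <- dff + matrix(stats::rnorm(Tn * n, 0, config$noise_sd), Tn, n)
  F <- config$F0 * (1 + dff)
  trace_set(F, f = config$f,
            positions = if (!is.null(pop)) pop$positions else NULL,
            F0 = rep(config$F0, n))
}

#' Construct a trace set
#'
#' @param F frames x neurons fluorescence matrix (arbitrary units).
#' @param f sampling rate, Hz.
#' @param F0 optional per-neuron baseline; estimated downstream if omitted.
#' @param positions optional n x 2 matrix of neuron coordinates, um.
#' @param neuron_ids optional identifiers; defaults to column names or 1..n.
#' @return A list of class `trace_set`.
#' @export
trace_set <- function(F, f, F0 = NULL, positions = NULL, neuron_ids = NULL) {
  F <- as.matrix(F)
  stopifnot(f > 0, nrow(F) >= 1)
  n <- ncol(F)
  if (is.null(neuron_ids))
    neuron_ids <- if (!is.null(colnames(F))) colnames(F) else as.character(seq_len(n))
  structure(list(F = F, f = f, F0 = F0, positions = positions,
                 neuron_ids = neuron_ids,
                 n_frames = nrow(F),
                 time_s = (seq_len(nrow(F)) - 1) / f),
            class = "trace_set")
}

#' Make circular ROI masks for a movie
#'
#' @param centers_px n x 2 matrix of (row, col) centers in pixels.
#' @param radius_px disc radius in pixels.
#' @param dims c(height, width) of the movie frames.
#' @return List of logical mask matrices, one per ROI.
#' @export
make_roiset <- function(centers_px, radius_px, dims) {
  centers_px <- as.matrix(centers_px)
  rr <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1])
  cc <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1])
  lapply(seq_len(nrow(centers_px)), function(i) {
    (rr - centers_px[i, 1])^2 + (cc - centers_px[i, 2])^2 <= radius_px^2
  })
}

#' Render a synthetic imaging movie from traces
#'
#' Paints each ROI's fluorescence value uniformly over its mask on a constant
#' background, optionally blurs with an isotropic Gaussian and adds pixel
#' noise. Overlapping masks are allowed (later ROIs overwrite) and reported
#' via a warning.
#'
#' @param traces a `trace_set`.
#' @param roiset list of logical masks from [make_roiset()].
#' @param dims c(height, width); defaults to the mask dimensions.
#' @param background constant background intensity.
#' @param noise_sd per-pixel Gaussian noise SD (same units as F).
#' @param seed RNG seed (noise only).
#' @return numeric array height x width x frames.
#' @export
render_movie <- function(traces, roiset, dims = dim(roiset[[1]]),
                         background = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(traces, "trace_set"), length(roiset) == ncol(traces$F))
  if (!is.null(seed)) set.seed(seed)
  overlap <- Reduce(`+`, lapply(roiset, function(m) m * 1L))
  if (any(overlap > 1)) warning("overlapping ROI masks")
  Tn <- traces$n_frames
  mov <- array(background, c(dims[1], dims[2], Tn))
  for (i in seq_along(roiset)) {
    idx <- which(roiset[[i]])
    for (t in seq_len(Tn)) {
      frame <- mov[, , t]
      frame[idx] <- traces$F[t, i]
      mov[, , t] <- frame
    }
  }
  if (noise_sd > 0)
    mov <- mov + array(stats::rnorm(length(mov), 0, noise_sd), dim(mov))
  mov
}

#' Write / read a movie as a 16-bit multi-page TIFF
#'
#' Values are stored as round(value) 16-bit integers, so movies with integer
#' intensities in [0, 65535] round-trip losslessly.
#'
#' @param movie numeric array height x width x frames.
#' @param path output file.
#' @return `read_movie_tiff` returns the array; `write_movie_tiff` the path.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3)
  if (any(movie < 0) || any(movie > 65535))
    stop("movie intensities must be within [0, 65535] for 16-bit storage")
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(t) round(movie[, , t]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * 65535
  round(arr)
}

#' Simulate a piezo voltage recording of the vidget response
#'
#' The sensor sits under the forepaws and reports limb movement as voltage.
#' Each stimulus presentation evokes, after `latency_s`, an exponentially
#' decaying deflection of relative amplitude `evoked_amp` on top of a
#' constant baseline voltage with Gaussian noise.
#'
#' @param protocol a `stim_protocol`.
#' @param evoked_amp peak deflection relative to baseline voltage.
#' @param latency_s response latency after stimulus onset, seconds.
#' @param decay_s deflection decay constant, seconds.
#' @param noise_sd relative noise SD.
#' @param fs sampling rate, Hz (>= 200).
#' @param baseline_v baseline voltage.
#' @param T_s recording length, seconds; defaults to the protocol span.
#' @param seed RNG seed.
#' @return A list of class `piezo_recording`: `voltage`, `fs`, `time_s`,
#'   `onsets_s`, `protocol`.
#' @export
simulate_piezo <- function(protocol, evoked_amp = 0.5, latency_s = 0.1,
                           decay_s = 0.3, noise_sd = 0.02, fs = 1000,
                           baseline_v = 2, T_s = protocol$total_s,
                           seed = NULL) {
  stopifnot(fs >= 200, evoked_amp >= 0, latency_s >= 0, decay_s > 0)
  if (!is.null(seed)) set.seed(seed)
  nsamp <- ceiling(T_s * fs)
  t <- (seq_len(nsamp) - 1) / fs
  rel <- numeric(nsamp)
  for (on in protocol$trials$onset_s) {
    t0 <- on + latency_s
    idx <- which(t >= t0 & t < t0 + 8 * decay_s)
    rel[idx] <- rel[idx] + evoked_amp * exp(-(t[idx] - t0) / decay_s)
  }
  if (noise_sd > 0) rel <- rel + stats::rnorm(nsamp, 0, noise_sd)
  piezo_recording(baseline_v * (1 + rel), fs = fs,
                  onsets_s = protocol$trials$onset_s, protocol = protocol)
}

#' Construct a piezo recording object
#' @param voltage numeric vector of voltage samples.
#' @param fs sampling rate, Hz.
#' @param onsets_s stimulus onset times, seconds.
#' @param protocol optional `stim_protocol`.
#' @return list of class `piezo_recording`.
#' @export
piezo_recording <- function(voltage, fs, onsets_s, protocol = NULL) {
  stopifnot(fs > 0, all(onsets_s >= 0),
            all(onsets_s < length(voltage) / fs))
  structure(list(voltage = as.numeric(voltage), fs = fs,
                 time_s = (seq_along(voltage) - 1) / fs,
                 onsets_s = onsets_s, protocol = protocol),
            class = "piezo_recording")
}

#' Generate a random branched dendritic tree
#'
#' Grows `n_primary` dendrites from a soma at the origin. Each segment has an
#' exponentially distributed length; at each segment tip the dendrite
#' bifurcates with probability `branch_prob` (up to `max_order` branch
#' orders), otherwise terminates. One SWC node is emitted per segment tip.
#'
#' @param n_primary number of primary dendrites (>= 1).
#' @param branch_prob bifurcation probability at each segment tip.
#' @param mean_seg_len mean segment length, micrometers.
#' @param max_order maximum centrifugal branch order.
#' @param seed RNG seed.
#' @return An `swc_tree` (see [read_swc()]): data.frame of SWC nodes.
#' @export
make_morphology <- function(n_primary = 4, branch_prob = 0.4,
                            mean_seg_len = 40, max_order = 5, seed = NULL) {
  stopifnot(n_primary >= 1, branch_prob >= 0, branch_prob <= 1,
            mean_seg_len > 0, max_order >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list(data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                          radius = 6, parent = -1L))
  next_id <- 2L
  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  grow <- function(parent_id, pos, dir, order) {
    len <- stats::rexp(1, 1 / mean_seg_len)
    new_pos <- pos + dir * len
    id <- next_id
    next_id <<- next_id + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, type = 3L, x = new_pos[1], y = new_pos[2], z = new_pos[3],
      radius = 0.5, parent = parent_id)
    if (order < max_order && stats::runif(1) < branch_prob) {
      for (b in 1:2) {
        d <- dir + 0.8 * rand_dir()
        d <- d / sqrt(sum(d^2))
        grow(id, new_pos, d, order + 1L)
      }
    }
  }
  for (p in seq_len(n_primary)) grow(1L, c(0, 0, 0), rand_dir(), 1L)
  tree <- do.call(rbind, rows)
  rownames(tree) <- NULL
  structure(tree, class = c("swc_tree", "data.frame"))
}
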