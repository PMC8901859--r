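#' Four-type functional classification
#'
#' Classifies neurons by their responses to the weak (S1) and strong (S4)
#' stimulus: type 1 responds to S4 only, type 2 to S1 only, type 3 to both,
#' type 4 to neither. "Responds" means response probability above
#' `p_threshold` (default 0: any response across trials).
#'
#' @param response_table a `response_table`, or a neurons x stimuli
#'   probability matrix with columns including `weak` and `strong`.
#' @param p_threshold probability cutoff.
#' @param weak,strong stimulus labels.
#' @return integer vector of type labels (1..4).
#' @export
assign_types <- function(response_table, p_threshold = 0,
                         weak = "S1", strong = "S4") {
  prob <- if (inherits(response_table, "response_table"))
    response_table$prob else as.matrix(response_table)
  if (!all(c(weak, strong) %in% colnames(prob)))
    stop("probability matrix must have both stimulus columns")
  r_weak <- prob[, weak] > p_threshold
  r_strong <- prob[, strong] > p_threshold
  ifelse(r_strong & !r_weak, 1L,
         ifelse(r_weak & !r_strong, 2L,
                ifelse(r_weak & r_strong, 3L, 4L)))
}

# exact expected NND of one neuron against random k-subgroups: mean of the
# minimum distance over all C(m, k) subsets of the candidate pool
exact_subgroup_nnd <- function(d_row, k) {
  subsets <- utils::combn(length(d_row), k)
  mean(apply(subsets, 2, function(s) min(d_row[s])))
}

#' Random k-subgroup nearest-neighbor-distance dispersion
#'
#' Group sizes differ between functional assemblies, which biases the plain
#' NND. For each neuron of a group, k other neurons are repeatedly drawn at
#' random (by default from the whole recorded population) and the distance
#' to the nearest of them recorded; the per-neuron value is the running mean
#' of this minimum distance, iterated until it converges (relative change
#' below `tol` over 100 consecutive repetitions, capped at `max_reps`). The
#' group's dispersion is the mean over its member neurons.
#'
#' @param positions n x 2 coordinate matrix, micrometers.
#' @param group_ids group label per neuron.
#' @param k subgroup size (default 5).
#' @param tol relative convergence tolerance.
#' @param max_reps repetition cap.
#' @param pool `"population"` draws the k others from all recorded neurons;
#'   `"group"` restricts to the neuron's own group.
#' @param seed RNG seed.
#' @return list of class `nnd_result`: `per_neuron` (data.frame neuron,
#'   group, nnd_um, reps), `dispersion` (named per-group mean), `k`, `tol`.
#' @export
knn_subgroup_nnd <- function(positions, group_ids, k = 5, tol = 1e-3,
                             max_reps = 10000, pool = c("population", "group"),
                             seed = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(length(group_ids) == n, k >= 1)
  pool <- match.arg(pool)
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(stats::dist(positions))
  groups <- sort(unique(group_ids))

  per <- lapply(seq_len(n), function(i) {
    cand <- if (pool == "population") setdiff(seq_len(n), i) else
      setdiff(which(group_ids == group_ids[i]), i)
    if (length(cand) < k)
      stop(sprintf("neuron %d: candidate pool smaller than k", i))
    d_row <- d[i, cand]
    if (length(cand) == k)  # only one possible subgroup: deterministic
      return(c(nnd = min(d_row), reps = 1))
    run_sum <- 0
    reps <- 0L
    stable <- 0L
    m_prev <- NA_real_
    chunk <- 100L
    while (reps < max_reps) {
      nn <- vapply(seq_len(chunk), function(z)
        min(d_row[sample.int(length(cand), k)]), numeric(1))
      for (v in nn) {
        reps <- reps + 1L
        run_sum <- run_sum + v
        m <- run_sum / reps
        if (!is.na(m_prev) && m_prev > 0 &&
            abs(m - m_prev) / m_prev < tol) {
          stable <- stable + 1L
        } else stable <- 0L
        m_prev <- m
        if (stable >= 100L) break
      }
      if (stable >= 100L) break
    }
    c(nnd = run_sum / reps, reps = reps)
  })
  per <- do.call(rbind, per)
  per_neuron <- data.frame(neuron = seq_len(n), group = group_ids,
                           nnd_um = per[, "nnd"], reps = per[, "reps"])
  dispersion <- tapply(per_neuron$nnd_um, per_neuron$group, mean)
  structure(list(per_neuron = per_neuron,
                 dispersion = dispersion[as.character(groups)],
                 k = k, tol = tol, pool = pool),
            class = "nnd_result")
}

#' Dispersion across a range of subgroup sizes
#'
#' Runs [knn_subgroup_nnd()] for each k and checks that the mean dispersion
#' is nonincreasing in k (the minimum over more draws cannot grow in
#' expectation).
#'
#' @inheritParams knn_subgroup_nnd
#' @param k_range integer vector of subgroup sizes (default 5:10).
#' @return data.frame with columns `k`, `group`, `dispersion_um`.
#' @export
nnd_k_sweep <- function(positions, group_ids, k_range = 5:10, tol = 1e-3,
                        max_reps = 10000, pool = c("population", "group"),
                        seed = NULL) {
  pool <- match.arg(pool)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(k_range, function(k) {
    res <- knn_subgroup_nnd(positions, group_ids, k = k, tol = tol,
                            max_reps = max_reps, pool = pool)
    data.frame(k = k, group = names(res$dispersion),
               dispersion_um = as.numeric(res$dispersion))
  })
  out <- do.call(rbind, rows)
  overall <- tapply(out$dispersion_um, out$k, mean)
  if (any(diff(overall) > tol * 20 * overall[-length(overall)]))
    warning("dispersion not monotone in k beyond tolerance")
  out
}
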