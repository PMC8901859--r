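# Shared fixtures and independent oracles used across the suite.

# event_train_set from a list of per-neuron spike-frame vectors
make_events <- function(spike_frames, n_frames, f = 20.4) {
  B <- matrix(0L, length(spike_frames), n_frames)
  for (i in seq_along(spike_frames)) B[i, spike_frames[[i]]] <- 1L
  event_train_set(B, f = f)
}

# ground_truth wrapper for hand-placed spikes
make_gt <- function(spike_frames, config, protocol = NULL) {
  structure(list(spike_frames = lapply(spike_frames, as.integer),
                 evoked = NULL,
                 population_events = data.frame(frame = integer(0),
                                                n_recruited = integer(0)),
                 recruited = list(), config = config, protocol = protocol,
                 n = length(spike_frames)),
            class = "ground_truth")
}

# brute-force recount of Firing(n): loop over frames, count spiking neurons
oracle_firing <- function(B) {
  N <- nrow(B)
  out <- integer(N)
  for (t in seq_len(ncol(B))) {
    s <- 0L
    for (i in seq_len(N)) s <- s + B[i, t]
    if (s > 0) out[s] <- out[s] + 1L
  }
  out
}

# brute-force pairwise synchronization counts (AND-and-sum)
oracle_pair_counts <- function(B) {
  n <- nrow(B)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- sum(B[i, ] == 1 & B[j, ] == 1)
  out
}

# exact expected k-subgroup NND for every neuron: enumerate all C(m, k)
# subsets of the other neurons
oracle_knn_nnd <- function(positions, k) {
  d <- as.matrix(dist(positions))
  n <- nrow(positions)
  vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    subs <- combn(others, k)
    mean(apply(subs, 2, function(s) min(d[i, s])))
  }, numeric(1))
}

# independent recursive traversal of an SWC tree: computes the branch
# metrics by plain depth-first search over an adjacency list
oracle_branch_metrics <- function(tree) {
  root <- tree$id[tree$parent == -1]
  dend <- tree[tree$type %in% c(3, 4) | tree$id == root, ]
  kids <- split(dend$id, factor(dend$parent, levels = dend$id))
  getrow <- function(id) dend[dend$id == id, ]
  n_nodes <- 0; n_ends <- 0; total <- 0; term_orders <- integer(0)
  walk <- function(id, order) {
    ch <- kids[[as.character(id)]]
    ch <- ch[!is.na(ch)]
    if (id != root) {
      if (length(ch) == 0) {
        n_ends <<- n_ends + 1
        term_orders <<- c(term_orders, order)
      } else if (length(ch) >= 2) n_nodes <<- n_nodes + 1
    }
    for (c_id in ch) {
      a <- getrow(id); b <- getrow(c_id)
      total <<- total + sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      walk(c_id, order + (if (id == root) 1 else if (length(ch) >= 2) 1 else 0))
    }
  }
  walk(root, 0)
  primaries <- kids[[as.character(root)]]
  list(n_primary = length(primaries[!is.na(primaries)]), n_nodes = n_nodes,
       n_ends = n_ends, total_length_um = total,
       terminal_orders = sort(term_orders))
}

# grid-accelerated nearest-neighbor distances for large point sets
grid_nnd <- function(pts, cell) {
  n <- nrow(pts)
  cx <- floor(pts[, 1] / cell)
  cy <- floor(pts[, 2] / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  vapply(seq_len(n), function(i) {
    best <- Inf
    r <- 1
    repeat {
      cand <- integer(0)
      for (dx in -r:r) for (dy in -r:r) {
        b <- buckets[[paste(cx[i] + dx, cy[i] + dy)]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      cand <- setdiff(cand, i)
      if (length(cand)) {
        dd <- sqrt((pts[cand, 1] - pts[i, 1])^2 +
                     (pts[cand, 2] - pts[i, 2])^2)
        best <- min(dd)
        if (best <= r * cell) return(best)
      }
      r <- r + 1
      if (r > 50) return(best)
    }
  }, numeric(1))
}
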