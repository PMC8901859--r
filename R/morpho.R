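#' Read a neuron reconstruction in SWC format
#'
#' SWC is the standard seven-column plain-text format for traced neurons:
#' id, structure type, x, y, z, radius, parent (-1 for the root). The tree
#' is validated: unique ids, existing parents, a single root, no cycles.
#' Node order in the file is arbitrary; the result is canonicalized so that
#' every parent precedes its children.
#'
#' @param path SWC file.
#' @return An `swc_tree`: data.frame with columns id, type, x, y, z, radius,
#'   parent.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d: expected 7 fields",
                 which(keep)[bad[1]]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("SWC parse error: non-numeric field")
  tree <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                     x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                     parent = as.integer(m[, 7]))
  validate_swc(tree)
}

validate_swc <- function(tree) {
  if (anyDuplicated(tree$id)) stop("SWC error: duplicate node ids")
  roots <- tree$parent == -1
  if (sum(roots) != 1) stop("SWC error: tree must have exactly one root")
  if (!all(tree$parent[!roots] %in% tree$id))
    stop("SWC error: orphan parent reference")
  # canonical order: parents before children; also proves acyclicity
  order_ids <- tree$id[roots]
  remaining <- tree[!roots, , drop = FALSE]
  while (nrow(remaining) > 0) {
    ready <- remaining$parent %in% order_ids
    if (!any(ready)) stop("SWC error: cycle detected")
    order_ids <- c(order_ids, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  tree <- tree[match(order_ids, tree$id), , drop = FALSE]
  rownames(tree) <- NULL
  structure(tree, class = c("swc_tree", "data.frame"))
}

#' Write an SWC file
#' @param tree an `swc_tree`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "swc_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.3f %d",
                     tree$id, tree$type, tree$x, tree$y, tree$z,
                     tree$radius, tree$parent), con)
  invisible(path)
}

#' Dendritic branch metrics
#'
#' Computes, over the dendritic compartment of a reconstruction (SWC types
#' 3 and 4; the axon is excluded): number of primary dendrites (dendrites
#' rooted at the soma), number of nodes (branch points), number of branch
#' terminals, total and mean dendrite length (micrometers), and the
#' centrifugal branch order of every terminal (primary segment = order 1,
#' +1 at each branch point).
#'
#' @param tree an `swc_tree`.
#' @param mean_length_per `"primary"` (default: total length / number of
#'   primary dendrites) or `"segment"` (total length / number of
#'   branch-point-delimited segments).
#' @return list of class `morpho_metrics`: `n_primary`, `n_nodes`,
#'   `n_ends`, `total_length_um`, `mean_length_um`, `terminal_orders`.
#' @export
branch_metrics <- function(tree, mean_length_per = c("primary", "segment")) {
  stopifnot(inherits(tree, "swc_tree"))
  mean_length_per <- match.arg(mean_length_per)
  tree <- validate_swc(tree)
  root_id <- tree$id[tree$parent == -1]
  dend <- tree$type %in% c(3L, 4L)
  keep <- dend | tree$id == root_id
  tree <- tree[keep, , drop = FALSE]
  if (sum(tree$id != root_id) == 0) stop("tree has no dendrite nodes")

  idx <- match(tree$parent, tree$id)  # NA at root
  n_children <- tabulate(idx[!is.na(idx)], nbins = nrow(tree))
  is_root <- tree$id == root_id

  # edge length from each non-root node to its parent
  seg_len <- numeric(nrow(tree))
  nz <- which(!is.na(idx))
  seg_len[nz] <- sqrt((tree$x[nz] - tree$x[idx[nz]])^2 +
                        (tree$y[nz] - tree$y[idx[nz]])^2 +
                        (tree$z[nz] - tree$z[idx[nz]])^2)

  n_primary <- sum(!is.na(idx) & is_root[idx])
  if (n_primary == 0) stop("no primary dendrites attached to the soma")
  # branch points: non-root nodes with >= 2 children
  n_nodes <- sum(n_children >= 2 & !is_root)
  leaves <- n_children == 0 & !is_root
  n_ends <- sum(leaves)
  total_length <- sum(seg_len)

  # centrifugal order: children of soma start at 1, +1 after a branch point
  ord <- integer(nrow(tree))
  for (i in seq_len(nrow(tree))) {  # canonical order: parent already set
    if (is_root[i]) next
    p <- idx[i]
    ord[i] <- if (is_root[p]) 1L else
      ord[p] + (if (n_children[p] >= 2) 1L else 0L)
  }
  terminal_orders <- ord[leaves]

  # a segment starts at each child of the soma or of a branch point
  seg_start <- !is.na(idx) & (is_root[idx] | n_children[idx] >= 2)
  n_segments <- sum(seg_start)
  mean_length <- if (mean_length_per == "primary")
    total_length / n_primary else total_length / n_segments
  structure(list(n_primary = n_primary, n_nodes = n_nodes, n_ends = n_ends,
                 total_length_um = total_length,
                 mean_length_um = mean_length,
                 terminal_orders = terminal_orders,
                 mean_length_per = mean_length_per),
            class = "morpho_metrics")
}

#' Dendritic complexity (DC)
#'
#' DC = (sum of terminal branch orders + number of terminals) x
#' (total dendritic length / number of primary dendrites).
#'
#' @param metrics a `morpho_metrics` from [branch_metrics()], or an
#'   `swc_tree` (metrics are computed first).
#' @return DC, a single nonnegative number.
#' @export
dendritic_complexity <- function(metrics) {
  if (inherits(metrics, "swc_tree")) metrics <- branch_metrics(metrics)
  stopifnot(inherits(metrics, "morpho_metrics"))
  if (metrics$n_primary < 1) stop("DC undefined without primary dendrites")
  (sum(metrics$terminal_orders) + metrics$n_ends) *
    (metrics$total_length_um / metrics$n_primary)
}

#' Summarize metrics for a set of trees
#'
#' @param trees list of `swc_tree` objects.
#' @return data.frame, one row per tree, with the six standard measurements
#'   (primary/node/end counts, total and mean length, DC).
#' @export
morpho_table <- function(trees) {
  rows <- lapply(trees, function(tr) {
    m <- branch_metrics(tr)
    data.frame(n_primary = m$n_primary, n_nodes = m$n_nodes,
               n_ends = m$n_ends, total_length_um = m$total_length_um,
               mean_length_um = m$mean_length_um,
               dc = dendritic_complexity(m))
  })
  do.call(rbind, rows)
}

#' Normalize morphometrics to a reference-group mean
#'
#' Each metric is divided by the corresponding mean in the reference group,
#' so the reference group normalizes to 1.00 and other groups become
#' relative proportions.
#'
#' @param metrics_table data.frame of metrics (e.g. from [morpho_table()]).
#' @param reference_mean named numeric vector of reference means, or a
#'   data.frame whose column means are used.
#' @return data.frame of relative proportions, same shape as the input.
#' @export
normalize_to_reference <- function(metrics_table, reference_mean) {
  if (is.data.frame(reference_mean))
    reference_mean <- colMeans(reference_mean)
  cols <- intersect(names(metrics_table), names(reference_mean))
  if (!length(cols)) stop("no shared metric columns to normalize")
  if (any(reference_mean[cols] == 0))
    stop("reference mean of zero: normalization undefined")
  out <- metrics_table
  for (cc in cols) out[[cc]] <- metrics_table[[cc]] / reference_mean[[cc]]
  out
}
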