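#' Network density
#'
#' Proportion of observed edges out of all possible edges:
#' `2 E / (N (N - 1))` where `E` counts unordered node pairs with strictly
#' positive weight.
#'
#' @param c A `connectome`.
#' @return Density in \[0, 1\].
#' @export
net_density <- function(c) {
  stopifnot(inherits(c, "connectome"))
  n <- length(c$node_ids)
  if (n < 2) return(0)
  e <- sum(c$weights[upper.tri(c$weights)] > 0)
  2 * e / (n * (n - 1))
}

#' @rdname net_density
#' @param x A `connectome` (method for the [stats::density()] generic).
#' @param ... Ignored.
#' @export
density.connectome <- function(x, ...) net_density(x)

#' Nodal strength
#'
#' Per-node sum of incident edge weights. The strengths sum to twice the total
#' edge weight.
#'
#' @param c A `connectome`.
#' @return Named numeric vector (one entry per node).
#' @export
nodal_strength <- function(c) {
  stopifnot(inherits(c, "connectome"))
  rowSums(c$weights)
}

#' Nodal degree
#'
#' Per-node count of incident edges (binary support of the weight matrix).
#'
#' @param c A `connectome`.
#' @return Named integer vector.
#' @export
nodal_degree <- function(c) {
  stopifnot(inherits(c, "connectome"))
  rowSums(c$weights > 0)
}

# mean inverse shortest-path length over ordered pairs of a weight matrix,
# with edge length = 1/weight and 1/Inf = 0
efficiency_of_weights <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- distances_of_weights(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

distances_of_weights <- function(w) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(ew)) 1 / ew else NULL,
                         algorithm = "dijkstra")
  d
}

#' Pairwise shortest-path lengths
#'
#' Edge length is the reciprocal of edge weight (strong connections are
#' short), the convention of weighted brain-network toolboxes. Unreachable
#' pairs have infinite distance; the diagonal is zero.
#'
#' @param c A `connectome`.
#' @return Symmetric numeric matrix of distances with node_id dimnames.
#' @export
shortest_path_lengths <- function(c) {
  stopifnot(inherits(c, "connectome"))
  d <- distances_of_weights(c$weights)
  dimnames(d) <- list(c$node_ids, c$node_ids)
  d
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, a network
#' integration measure; disconnected pairs contribute zero.
#'
#' @param c A `connectome`.
#' @return Scalar efficiency (0 for an empty or single-node graph).
#' @export
global_efficiency <- function(c) {
  stopifnot(inherits(c, "connectome"))
  efficiency_of_weights(c$weights)
}

#' Nodal efficiency
#'
#' For each node, the efficiency (mean inverse shortest-path length, as in
#' [global_efficiency()]) of the subgraph induced by the node's neighbours,
#' using the original edge weights among those neighbours. Nodes with fewer
#' than two neighbours score zero. This per-node quantity is a segregation
#' measure; its average over nodes is the network's local efficiency.
#'
#' @param c A `connectome`.
#' @return Named numeric vector in \[0, 1\] for weight-normalized graphs.
#' @export
nodal_efficiency <- function(c) {
  stopifnot(inherits(c, "connectome"))
  w <- c$weights
  n <- nrow(w)
  out <- numeric(n)
  names(out) <- c$node_ids
  for (v in seq_len(n)) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) next
    out[v] <- efficiency_of_weights(w[nb, nb, drop = FALSE])
  }
  out
}

#' Local efficiency
#'
#' Average of [nodal_efficiency()] over all nodes.
#'
#' @param c A `connectome`.
#' @return Scalar.
#' @export
local_efficiency <- function(c) {
  mean(nodal_efficiency(c))
}

#' Global metric summary of a connectome
#'
#' @param c A `connectome`.
#' @return One-row data.frame: `density`, `mean_strength`,
#'   `global_efficiency`, `local_efficiency`.
#' @export
global_metrics <- function(c) {
  data.frame(
    density = net_density(c),
    mean_strength = mean(nodal_strength(c)),
    global_efficiency = global_efficiency(c),
    local_efficiency = local_efficiency(c)
  )
}

#' Nodal metric summary of a connectome
#'
#' @param c A `connectome`.
#' @return data.frame with `node_id`, `strength`, `degree`,
#'   `nodal_efficiency`.
#' @export
nodal_metrics <- function(c) {
  data.frame(
    node_id = c$node_ids,
    strength = unname(nodal_strength(c)),
    degree = unname(nodal_degree(c)),
    nodal_efficiency = unname(nodal_efficiency(c)),
    stringsAsFactors = FALSE
  )
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Proportional thresholding to a target density
#'
#' Retains the `k = round(target_density * N(N-1)/2)` strongest edges (weights
#' are kept, not binarized). Rounding is half-away-from-zero. If the network
#' already has at most `k` edges it is returned unchanged. Ties in weight are
#' broken by lexicographic node-pair order so the result is deterministic.
#'
#' @param c A `connectome`.
#' @param target_density Target density in (0, 1\].
#' @return A thresholded `connectome`.
#' @export
proportional_threshold <- function(c, target_density) {
  stopifnot(inherits(c, "connectome"))
  if (!(target_density > 0 && target_density <= 1)) {
    stop("target_density must be in (0, 1]", call. = FALSE)
  }
  n <- length(c$node_ids)
  npairs <- n * (n - 1) / 2
  k <- round_half_away(target_density * npairs)
  w <- c$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) <= k) return(c)
  wt <- w[idx]
  ord <- order(-wt, idx[, 1], idx[, 2])
  drop <- idx[ord[seq.int(k + 1, nrow(idx))], , drop = FALSE]
  w[drop] <- 0
  w[drop[, c(2, 1), drop = FALSE]] <- 0
  out <- c
  out$weights <- w
  out
}

#' Default cost-correction density grid
#'
#' Densities 0.05 to 0.50 in steps of 0.01 (46 values).
#'
#' @return Numeric vector of length 46.
#' @export
default_density_grid <- function() round(seq(0.05, 0.50, by = 0.01), 2)

#' Cost-corrected graph metrics over a density sweep
#'
#' Differences in raw network density between subjects confound comparisons of
#' graph metrics. The cost-correction approach thresholds each network to a
#' series of fixed densities ([proportional_threshold()]), extracts strength,
#' degree, nodal efficiency, global efficiency and local efficiency at each
#' density, and averages each feature across the grid.
#'
#' @param c A `connectome`.
#' @param density_grid Strictly increasing densities in (0, 1\]; default
#'   [default_density_grid()].
#' @return List of class `"cost_corrected"`:
#'   \describe{
#'     \item{density_grid}{the grid used}
#'     \item{global}{data.frame of per-density global metrics}
#'     \item{strength, degree, nodal_eff}{node-by-density matrices}
#'     \item{cost_corrected}{list with scalar `mean_strength`,
#'       `global_efficiency`, `local_efficiency` and a `nodal` data.frame of
#'       across-grid means per node}
#'   }
#' @export
cost_corrected_features <- function(c, density_grid = default_density_grid()) {
  stopifnot(inherits(c, "connectome"))
  if (!length(density_grid)) stop("density_grid must be nonempty", call. = FALSE)
  if (any(diff(density_grid) <= 0) || any(density_grid <= 0) ||
      any(density_grid > 1)) {
    stop("density_grid must be strictly increasing within (0, 1]", call. = FALSE)
  }
  n <- length(c$node_ids)
  ng <- length(density_grid)
  strength <- degree <- nodal_eff <- matrix(
    0, n, ng, dimnames = list(c$node_ids, NULL))
  glob <- data.frame(density = density_grid, density_realized = NA_real_,
                     mean_strength = NA_real_, global_efficiency = NA_real_,
                     local_efficiency = NA_real_)
  for (j in seq_len(ng)) {
    ct <- proportional_threshold(c, density_grid[j])
    strength[, j] <- nodal_strength(ct)
    degree[, j] <- nodal_degree(ct)
    ne <- nodal_efficiency(ct)
    nodal_eff[, j] <- ne
    glob$density_realized[j] <- net_density(ct)
    glob$mean_strength[j] <- mean(strength[, j])
    glob$global_efficiency[j] <- global_efficiency(ct)
    glob$local_efficiency[j] <- mean(ne)
  }
  structure(list(
    density_grid = density_grid,
    global = glob,
    strength = strength,
    degree = degree,
    nodal_eff = nodal_eff,
    cost_corrected = list(
      mean_strength = mean(glob$mean_strength),
      global_efficiency = mean(glob$global_efficiency),
      local_efficiency = mean(glob$local_efficiency),
      nodal = data.frame(
        node_id = c$node_ids,
        strength = unname(rowMeans(strength)),
        degree = unname(rowMeans(degree)),
        nodal_efficiency = unname(rowMeans(nodal_eff)),
        stringsAsFactors = FALSE
      )
    )
  ), class = "cost_corrected")
}

#' Long-format feature export
#'
#' Flattens a [cost_corrected_features()] result into the long table shape
#' `(subject_id, feature, node_id, density, value)` where `node_id` is
#' `"global"` for whole-network features and `density` is `"cost_corrected"`
#' for across-grid means.
#'
#' @param cc A `"cost_corrected"` object.
#' @param subject_id Subject identifier for the `subject_id` column.
#' @return data.frame in long format.
#' @export
features_long <- function(cc, subject_id) {
  stopifnot(inherits(cc, "cost_corrected"))
  grid <- cc$density_grid
  rows <- list()
  g <- cc$global
  for (feat in c("mean_strength", "global_efficiency", "local_efficiency")) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, feature = feat, node_id = "global",
      density = as.character(grid), value = g[[feat]],
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, feature = feat, node_id = "global",
      density = "cost_corrected", value = cc$cost_corrected[[feat]],
      stringsAsFactors = FALSE)
  }
  nodal_mats <- list(strength = cc$strength, degree = cc$degree,
                     nodal_efficiency = cc$nodal_eff)
  ccn <- cc$cost_corrected$nodal
  for (feat in names(nodal_mats)) {
    m <- nodal_mats[[feat]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, feature = feat,
      node_id = rep(rownames(m), times = ncol(m)),
      density = rep(as.character(grid), each = nrow(m)),
      value = as.vector(m), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subject_id, feature = feat, node_id = ccn$node_id,
      density = "cost_corrected", value = ccn[[feat]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
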