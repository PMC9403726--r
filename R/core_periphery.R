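# Core-periphery decomposition: two-group node partition in which core nodes
# are densely interconnected and peripheral nodes attach mainly to the core.
# The quality of a labeling scores core-core and core-periphery weight
# positively and periphery-periphery weight negatively, normalized by total
# weight:  q = (W_cc + W_cp - W_pp) / W_total = 1 - 2 W_pp / W_total.
# Maximizing q therefore minimizes the weight buried inside the periphery; the
# maximum is a plateau (any labeling whose core covers every positive edge
# scores 1), so ties are resolved toward the lexicographically smallest core.

#' Core-periphery partition quality
#'
#' Evaluates the normalized core-periphery objective for a given labeling:
#' total weight on core-core plus core-periphery edges minus
#' periphery-periphery weight, divided by total weight.
#'
#' @param c A `connectome`.
#' @param core Character vector of core node_ids, or a logical vector over
#'   nodes in node order.
#' @return Scalar quality in \[-1, 1\].
#' @export
core_periphery_quality <- function(c, core) {
  stopifnot(inherits(c, "connectome"))
  core <- as_core_logical(c, core)
  w <- c$weights
  tot <- sum(w) / 2
  if (tot <= 0) stop("connectome has no edges", call. = FALSE)
  periph <- !core
  wpp <- sum(w[periph, periph, drop = FALSE]) / 2
  1 - 2 * wpp / tot
}

as_core_logical <- function(c, core) {
  if (is.logical(core)) {
    stopifnot(length(core) == length(c$node_ids))
    return(core)
  }
  bad <- setdiff(core, c$node_ids)
  if (length(bad)) stop("unknown node_id(s) in core: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  c$node_ids %in% core
}

# TRUE if sorted index set a is lexicographically smaller than b
core_lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) < length(b)
}

# one Kernighan-Lin pass: move every node once (best move first, locking
# moved nodes, accepting losses), then revert to the best prefix
kl_pass <- function(w, core, tol = 1e-12) {
  n <- nrow(w)
  wp <- as.vector(w %*% ifelse(core, 0, 1))  # weight from each node into periphery
  tot <- sum(w) / 2
  cur <- core
  locked <- rep(FALSE, n)
  q0 <- 1 - sum(wp[!cur]) / tot  # W_pp = sum over periphery of wp / 2 doubled
  qs <- numeric(n)
  states <- vector("list", n)
  q <- q0
  for (s in seq_len(n)) {
    # delta in q for flipping each unlocked node
    dq <- ifelse(cur, -2 * wp / tot, 2 * wp / tot)
    dq[locked] <- -Inf
    v <- which.max(dq)
    q <- q + dq[v]
    cur[v] <- !cur[v]
    wp <- wp + (if (cur[v]) -1 else 1) * w[, v]
    locked[v] <- TRUE
    qs[s] <- q
    states[[s]] <- cur
  }
  best <- which.max(qs)
  if (qs[best] > q0 + tol) {
    list(core = states[[best]], q = qs[best], improved = TRUE)
  } else {
    list(core = core, q = q0, improved = FALSE)
  }
}

# shrink the core along the quality plateau: repeatedly demote the
# highest-index core node whose demotion leaves quality unchanged
plateau_shrink <- function(w, core, tol = 1e-12) {
  tot <- sum(w) / 2
  repeat {
    periph <- !core
    moved <- FALSE
    for (v in rev(which(core))) {
      if (sum(w[v, periph]) / tot <= tol) {
        core[v] <- FALSE
        periph[v] <- TRUE
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  core
}

#' Core-periphery decomposition by Kernighan-Lin label search
#'
#' Partitions the nodes of a weighted connectome into a core and a periphery
#' by maximizing [core_periphery_quality()] with an adapted Kernighan-Lin
#' search: from a random initial labeling, sweeps of single-node label moves
#' (each node moved at most once per sweep, locking moved nodes and accepting
#' interim losses, then reverting to the best prefix) run until no sweep
#' improves the objective. The best labeling over `n_restarts` random
#' initializations is kept. Because the objective's maximum is a plateau, the
#' result is refined deterministically toward the lexicographically smallest
#' core set (highest-index core nodes whose demotion costs nothing are
#' demoted), and ties across restarts are broken the same way.
#'
#' @param c A `connectome` with at least one edge.
#' @param seed Integer seed; per-restart seeds are derived from it, so results
#'   are reproducible given (`c`, `seed`, `n_restarts`).
#' @param n_restarts Number of random restarts (default 100).
#' @return List of class `"cp_partition"`: `labels` (named character,
#'   `"core"`/`"periphery"`), `quality`, `n_core`, `n_periphery`,
#'   `restarts_used`, `seed`.
#' @export
core_periphery_partition <- function(c, seed = 1L, n_restarts = 100L) {
  stopifnot(inherits(c, "connectome"))
  w <- c$weights
  if (sum(w) <= 0) stop("cannot partition an edgeless connectome", call. = FALSE)
  n <- nrow(w)
  best_core <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    core <- with_seed(derive_seed(seed, r),
                      stats::runif(n) < 0.5)
    if (!any(core)) core[1] <- TRUE
    repeat {
      res <- kl_pass(w, core)
      core <- res$core
      if (!res$improved) break
    }
    core <- plateau_shrink(w, core)
    q <- core_periphery_quality(c, core)
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 &&
         core_lex_less(which(core), which(best_core)))) {
      best_q <- q
      best_core <- core
    }
  }
  labels <- ifelse(best_core, "core", "periphery")
  names(labels) <- c$node_ids
  structure(list(
    labels = labels,
    quality = best_q,
    n_core = sum(best_core),
    n_periphery = sum(!best_core),
    restarts_used = as.integer(n_restarts),
    seed = as.integer(seed)
  ), class = "cp_partition")
}

#' @export
print.cp_partition <- function(x, ...) {
  cat(sprintf("<core-periphery partition> %d core / %d periphery, quality %.4f\n",
              x$n_core, x$n_periphery, x$quality))
  invisible(x)
}

#' Classify edges as core, feeder or peripheral
#'
#' An edge is `core` when both endpoints are core nodes, `peripheral` when
#' both are periphery, and `feeder` when it connects a core and a peripheral
#' node.
#'
#' @param edges data.frame with `node_a`, `node_b` columns (e.g. from
#'   [edge_list()]).
#' @param labels Named character vector of `"core"`/`"periphery"` per node
#'   (e.g. the `labels` element of a [core_periphery_partition()]), or a node
#'   table with `node_id` and `partition_label` columns.
#' @return List with `edges` (input plus a `type` column) and `counts` (named
#'   integer vector over `core`, `feeder`, `peripheral`).
#' @export
classify_edges <- function(edges, labels) {
  if (is.data.frame(labels)) {
    if (!all(c("node_id", "partition_label") %in% names(labels))) {
      stop("node table must have node_id and partition_label columns", call. = FALSE)
    }
    labels <- stats::setNames(labels$partition_label, labels$node_id)
  }
  la <- labels[edges$node_a]
  lb <- labels[edges$node_b]
  if (anyNA(la) || anyNA(lb)) {
    miss <- unique(c(edges$node_a[is.na(la)], edges$node_b[is.na(lb)]))
    stop("unlabeled edge endpoint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  type <- ifelse(la == "core" & lb == "core", "core",
                 ifelse(la == "periphery" & lb == "periphery",
                        "peripheral", "feeder"))
  edges$type <- type
  counts <- c(core = sum(type == "core"),
              feeder = sum(type == "feeder"),
              peripheral = sum(type == "peripheral"))
  list(edges = edges, counts = counts)
}

#' Element-wise mean connectome of a cohort
#'
#' @param connectomes List of `connectome` objects sharing node identity.
#' @param subject_id Identifier for the averaged network.
#' @return A `connectome` whose weights are the across-subject means.
#' @export
mean_connectome <- function(connectomes, subject_id = "group_mean") {
  stopifnot(length(connectomes) >= 1)
  ids <- connectomes[[1]]$node_ids
  for (cn in connectomes) {
    if (!identical(cn$node_ids, ids)) {
      stop("connectomes do not share node identity", call. = FALSE)
    }
  }
  w <- Reduce(`+`, lapply(connectomes, `[[`, "weights")) / length(connectomes)
  connectome(w, node_ids = ids, subject_id = subject_id)
}

#' Group-level core-periphery partition
#'
#' Two routes to a cohort-level partition: partition the element-wise mean
#' connectome (`method = "mean"`, the default), or partition each subject and
#' take a majority vote per node (`method = "consensus"`, ties to periphery).
#'
#' @param connectomes List of `connectome`s.
#' @param method `"mean"` or `"consensus"`.
#' @param seed,n_restarts Passed to [core_periphery_partition()].
#' @return A `"cp_partition"` (quality evaluated on the mean connectome).
#' @export
group_partition <- function(connectomes, method = c("mean", "consensus"),
                            seed = 1L, n_restarts = 100L) {
  method <- match.arg(method)
  mc <- mean_connectome(connectomes)
  if (method == "mean") {
    return(core_periphery_partition(mc, seed = seed, n_restarts = n_restarts))
  }
  votes <- rep(0L, length(mc$node_ids))
  for (i in seq_along(connectomes)) {
    p <- core_periphery_partition(connectomes[[i]],
                                  seed = derive_seed(seed, i),
                                  n_restarts = n_restarts)
    votes <- votes + as.integer(p$labels == "core")
  }
  core <- votes > length(connectomes) / 2
  labels <- ifelse(core, "core", "periphery")
  names(labels) <- mc$node_ids
  structure(list(
    labels = labels,
    quality = core_periphery_quality(mc, core),
    n_core = sum(core),
    n_periphery = sum(!core),
    restarts_used = as.integer(n_restarts),
    seed = as.integer(seed)
  ), class = "cp_partition")
}

#' Write a partition back into a node table
#'
#' @param node_table Node table data.frame.
#' @param partition A `"cp_partition"` or named label vector.
#' @return The node table with its `partition_label` column set.
#' @export
apply_partition <- function(node_table, partition) {
  labels <- if (inherits(partition, "cp_partition")) partition$labels else partition
  lab <- labels[node_table$node_id]
  if (anyNA(lab)) stop("partition does not label every node", call. = FALSE)
  node_table$partition_label <- unname(lab)
  node_table
}
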