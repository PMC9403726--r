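# Independent oracles used to verify the implementation on small inputs.
# These deliberately use naive algorithms (triple-loop Floyd-Warshall,
# exhaustive enumeration, explicit normal equations) so they share no code
# path with the package.

# all-pairs shortest paths with edge length = 1/weight, O(n^3) relaxation
fw_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

efficiency_oracle <- function(w) {
  n <- nrow(w)
  if (n < 2) return(0)
  d <- fw_distances(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# random symmetric nonnegative weight matrix with approximately the given
# edge density
random_weights <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- runif(length(ut)) < density
  w[ut[on]] <- runif(sum(on), 0.2, 5)
  w + t(w)
}

lex_less_oracle <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# exhaustive maximization of the core-periphery quality with the same
# lexicographic-smallest-core tie-break the package documents
exhaustive_cp <- function(w) {
  n <- nrow(w)
  tot <- sum(w) / 2
  best_q <- -Inf
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    core <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    wpp <- sum(w[!core, !core]) / 2
    q <- 1 - 2 * wpp / tot
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 && lex_less_oracle(which(core), which(best)))) {
      best_q <- q
      best <- core
    }
  }
  list(core = best, quality = best_q)
}

# planted core-periphery graph: complete core with weight wc, every periphery
# node attached to every core node with weight wf, no periphery-periphery edges
planted_cp_graph <- function(n_core, n_periph, wc = 3, wf = 1) {
  n <- n_core + n_periph
  w <- matrix(0, n, n)
  for (i in seq_len(n_core)) for (j in seq_len(n_core)) {
    if (i < j) w[i, j] <- w[j, i] <- wc
  }
  for (p in seq_len(n_periph) + n_core) for (i in seq_len(n_core)) {
    w[i, p] <- w[p, i] <- wf
  }
  w
}

# connected-component extents by breadth-first search over an edge data.frame
components_oracle <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- c(edges$node_b[edges$node_a == v], edges$node_a[edges$node_b == v])
      new <- nb[is.na(comp[nb])]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  extents <- vapply(seq_len(k), function(g) {
    sum(comp[edges$node_a] == g)
  }, integer(1))
  list(membership = comp, extents = extents)
}

# partial Spearman by explicit normal equations on ranks
partial_spearman_oracle <- function(x, y, covars) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  Z <- cbind(1, apply(as.matrix(covars), 2, rank, ties.method = "average"))
  bx <- solve(t(Z) %*% Z, t(Z) %*% rx)
  by <- solve(t(Z) %*% Z, t(Z) %*% ry)
  ex <- rx - Z %*% bx
  ey <- ry - Z %*% by
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

jaccard_edges <- function(ea, eb) {
  ka <- edge_key(ea$node_a, ea$node_b)
  kb <- edge_key(eb$node_a, eb$node_b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# standard behavioural-analysis covariate sets used across tests
behavior_covariates <- c("ga_birth", "sex", "injury_rating",
                         "cognitive_composite", "imd")
network_covariates <- c(behavior_covariates, "pma_scan")

add_age_adjusted <- function(cohort,
                             outcomes = c("internalizing_raw",
                                          "externalizing_raw")) {
  for (oc in outcomes) {
    adj <- age_adjust(cohort[[oc]], cohort$corrected_age_followup,
                      cohort$subject_id)
    cohort[[paste0(oc, "_ageadj")]] <- adj$age_adjusted
  }
  cohort
}
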