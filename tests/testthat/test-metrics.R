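test_that("density counts positive pairs over possible pairs", {
  full <- connectome(planted_cp_graph(93, 0, wc = 1))
  expect_equal(net_density(full), 1)
  expect_equal(net_density(connectome(matrix(0, 5, 5))), 0)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 2
  w[3, 4] <- w[4, 3] <- 3
  expect_equal(net_density(connectome(w)), 0.5)  # 3 of 6 pairs
})

test_that("strength sums incident weights and doubles total weight", {
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 2
  cn <- connectome(w)
  expect_equal(unname(nodal_strength(cn)), c(2, 2, 0, 0, 0))

  full <- connectome(matrix(1, 6, 6) - diag(6))
  expect_equal(unname(nodal_strength(full)), rep(5, 6))

  set.seed(11)
  rw <- random_weights(10)
  cr <- connectome(rw)
  expect_equal(nodal_strength(cr), rowSums(rw), ignore_attr = TRUE)
  expect_equal(sum(nodal_strength(cr)), 2 * sum(rw[upper.tri(rw)]))
})

test_that("shortest paths use reciprocal-weight lengths", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  d <- shortest_path_lengths(connectome(w, c("a", "b", "c")))
  expect_equal(d["a", "c"], 2)

  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 2
  d2 <- shortest_path_lengths(connectome(w2))
  expect_equal(d2[1, 2], 0.5)      # 1/weight
  expect_equal(d2[1, 3], Inf)      # disconnected
  expect_equal(diag(d2), rep(0, 3), ignore_attr = TRUE)
})

test_that("shortest paths match Floyd-Warshall exactly on random small graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    w <- random_weights(n, density = runif(1, 0.2, 0.9))
    cn <- connectome(w)
    expect_equal(unname(shortest_path_lengths(cn)), fw_distances(w),
                 tolerance = 1e-12)
  }
})

test_that("global efficiency handles complete, empty and path graphs", {
  expect_equal(global_efficiency(connectome(matrix(1, 5, 5) - diag(5))), 1)
  expect_equal(global_efficiency(connectome(matrix(0, 4, 4))), 0)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  expect_equal(global_efficiency(connectome(w)), 5 / 6)  # pair distances 1,1,2
})

test_that("nodal efficiency is the efficiency of the neighbourhood subgraph", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(unname(nodal_efficiency(connectome(tri))), rep(1, 3))

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  ne <- nodal_efficiency(connectome(star))
  expect_equal(unname(ne[1]), 0)          # leaves share no edges
  expect_equal(unname(ne[2:5]), rep(0, 4))  # degree-1 nodes

  # independent check: neighbourhood subgraph efficiency via the FW oracle
  set.seed(5)
  w <- random_weights(7, 0.6)
  cn <- connectome(w)
  ne <- nodal_efficiency(cn)
  for (v in 1:7) {
    nb <- which(w[v, ] > 0)
    want <- if (length(nb) < 2) 0 else efficiency_oracle(w[nb, nb, drop = FALSE])
    expect_equal(unname(ne[v]), want, tolerance = 1e-12)
  }
  expect_equal(local_efficiency(cn), mean(ne))
})

test_that("proportional thresholding keeps the k strongest edges", {
  w <- matrix(0, 4, 4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  wts <- c(6, 5, 4, 3, 2, 1)
  for (k in 1:6) w[pairs[k, 1], pairs[k, 2]] <- w[pairs[k, 2], pairs[k, 1]] <- wts[k]
  cn <- connectome(w)
  th <- proportional_threshold(cn, 0.5)
  kept <- edge_list(th)
  expect_equal(sort(kept$weight), c(4, 5, 6))  # the 3 largest survive
  expect_identical(proportional_threshold(cn, 1)$weights, cn$weights)
  expect_identical(proportional_threshold(th, 0.5)$weights, th$weights)

  # sort-and-cut oracle on random graphs (distinct weights)
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    w <- random_weights(n, 0.8)
    cn <- connectome(w)
    target <- runif(1, 0.1, 0.9)
    k <- floor(target * n * (n - 1) / 2 + 0.5)
    wts <- sort(w[upper.tri(w) & w > 0], decreasing = TRUE)
    th <- proportional_threshold(cn, target)
    el <- edge_list(th)
    if (k < length(wts)) {
      expect_equal(nrow(el), k)
      expect_equal(sort(el$weight, decreasing = TRUE), wts[seq_len(k)])
    } else {
      expect_equal(nrow(el), length(wts))
    }
  }
})

test_that("thresholding ties break lexicographically and deterministically", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  w[1, 3] <- w[3, 1] <- 1
  cn <- connectome(w, c("a", "b", "c", "d"))
  th <- proportional_threshold(cn, 2 / 6)  # keep 2 of 3 tied edges
  el <- edge_list(th)
  expect_equal(nrow(el), 2)
  expect_equal(el$node_a, c("a", "a"))  # (a,b) and (a,c) come first
})

test_that("cost correction averages features across the density grid", {
  expect_length(default_density_grid(), 46)
  expect_equal(default_density_grid()[c(1, 46)], c(0.05, 0.50))

  set.seed(9)
  w <- random_weights(20, 0.7)
  cn <- connectome(w)
  grid <- c(0.1, 0.2, 0.3)
  cc <- cost_corrected_features(cn, grid)
  # independent per-density loop
  ge <- vapply(grid, function(d) {
    global_efficiency(proportional_threshold(cn, d))
  }, numeric(1))
  expect_equal(cc$cost_corrected$global_efficiency, mean(ge))
  expect_equal(cc$global$global_efficiency, ge)
  le <- vapply(grid, function(d) local_efficiency(proportional_threshold(cn, d)),
               numeric(1))
  expect_equal(cc$cost_corrected$local_efficiency, mean(le))
  st <- sapply(grid, function(d) nodal_strength(proportional_threshold(cn, d)))
  expect_equal(cc$cost_corrected$nodal$strength, unname(rowMeans(st)))

  # a network already sparser than the whole grid is never thresholded
  sparse <- proportional_threshold(cn, 0.05)
  cc2 <- cost_corrected_features(sparse, grid)
  expect_equal(cc2$cost_corrected$global_efficiency, global_efficiency(sparse))
  expect_error(cost_corrected_features(cn, numeric(0)), "nonempty")
  expect_error(cost_corrected_features(cn, c(0.3, 0.2)), "increasing")
})

test_that("global efficiency is non-decreasing in density for nested networks", {
  set.seed(33)
  w <- random_weights(15, 0.8)
  cn <- connectome(w)
  ge <- vapply(seq(0.1, 0.8, by = 0.1), function(d) {
    global_efficiency(proportional_threshold(cn, d))
  }, numeric(1))
  expect_true(all(diff(ge) >= -1e-12))
})

test_that("metrics are permutation-equivariant and scale as expected", {
  set.seed(13)
  w <- random_weights(8, 0.6)
  cn <- connectome(w, node_ids = letters[1:8])
  perm <- sample(8)
  cp <- connectome(w[perm, perm], node_ids = letters[1:8][perm])
  expect_equal(global_efficiency(cp), global_efficiency(cn))
  expect_equal(net_density(cp), net_density(cn))
  expect_equal(nodal_strength(cp)[letters[1:8]], nodal_strength(cn))
  expect_equal(nodal_efficiency(cp)[letters[1:8]], nodal_efficiency(cn))

  s <- 3.7
  cs <- connectome(w * s, node_ids = letters[1:8])
  expect_equal(nodal_strength(cs), s * nodal_strength(cn))
  expect_equal(global_efficiency(cs), s * global_efficiency(cn))
  expect_equal(net_density(cs), net_density(cn))
  expect_equal(nodal_degree(cs), nodal_degree(cn))
})

test_that("features_long covers every feature at every density plus the mean", {
  set.seed(2)
  cn <- connectome(random_weights(6, 0.8), subject_id = "s1")
  grid <- c(0.2, 0.4)
  long <- features_long(cost_corrected_features(cn, grid), "s1")
  expect_setequal(unique(long$feature),
                  c("mean_strength", "global_efficiency", "local_efficiency",
                    "strength", "degree", "nodal_efficiency"))
  expect_setequal(unique(long$density), c("0.2", "0.4", "cost_corrected"))
  # 3 global feats x 3 rows + 3 nodal feats x 6 nodes x 3 rows
  expect_equal(nrow(long), 3 * 3 + 3 * 6 * 3)
})
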