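make_toy_nbs <- function(n = 12, n_nodes = 6, beta = 0, noise = 1, seed = 1,
                         n_effect = 3) {
  set.seed(seed)
  score <- rnorm(n)
  connectomes <- lapply(seq_len(n), function(s) {
    w <- matrix(0, n_nodes, n_nodes)
    ut <- which(upper.tri(w))
    vals <- 10 + rnorm(length(ut), sd = noise)
    # first n_effect upper-triangle pairs form a connected planted component
    vals[seq_len(n_effect)] <- 10 + beta * score[s] +
      rnorm(n_effect, sd = noise)
    w[ut] <- pmax(vals, 0)
    w <- w + t(w)
    connectome(w, subject_id = paste0("S", s))
  })
  cohort <- data.frame(subject_id = paste0("S", seq_len(n)), score = score,
                       nuis = rnorm(n), stringsAsFactors = FALSE)
  list(cohort = cohort, connectomes = connectomes)
}

test_that("design specification enforces its invariants", {
  expect_error(design_spec("y", alpha = 1.5), "alpha")
  expect_error(design_spec("y", n_permutations = 0), "n_permutations")
  expect_error(design_spec("y", covariates = c("y", "z")), "predictor")
  d <- design_spec("y")
  expect_equal(d$t_threshold, 3.1)
  expect_equal(d$n_permutations, 10000L)
  expect_equal(d$alpha, 0.025)
})

test_that("edgewise OLS t statistics match a closed-form oracle", {
  # single-edge toy with 6 printed subject values, one covariate
  x <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.6)
  z <- c(0.4, 1.0, -0.2, 0.7, -0.9, 0.1)
  y <- c(4.1, 2.2, 3.0, 6.5, 0.8, 3.9)
  connectomes <- lapply(1:6, function(s) {
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- y[s]
    w[1, 3] <- w[3, 1] <- 5
    w[2, 3] <- w[3, 2] <- 5
    connectome(w, subject_id = paste0("S", s))
  })
  cohort <- data.frame(subject_id = paste0("S", 1:6), x = x, z = z)
  d <- design_spec("x", covariates = "z", n_permutations = 10)
  res <- edgewise_glm(cohort, connectomes, d)
  fit <- summary(lm(y ~ z + x))
  i <- which(res$node_a == "n1" & res$node_b == "n2")
  expect_equal(res$t[i], unname(fit$coefficients["x", "t value"]),
               tolerance = 1e-10)
  expect_equal(res$beta[i], unname(fit$coefficients["x", "Estimate"]),
               tolerance = 1e-10)
  expect_equal(attr(res, "df"), 3)  # n - p = 6 - 3
  # constant edges are reported with t = 0
  expect_equal(res$t[res$node_a == "n1" & res$node_b == "n3"], 0)
})

test_that("a perfect linear relation yields the capped sentinel t", {
  x <- c(-2, -1, 0, 1, 2, 3)
  connectomes <- lapply(1:6, function(s) {
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 10 + 2 * x[s]
    w[1, 3] <- w[3, 1] <- 4
    w[2, 3] <- w[3, 2] <- 4
    connectome(w, subject_id = paste0("S", s))
  })
  cohort <- data.frame(subject_id = paste0("S", 1:6), x = x)
  res <- edgewise_glm(cohort, connectomes, design_spec("x"))
  i <- which(res$node_a == "n1" & res$node_b == "n2")
  expect_equal(res$beta[i], 2, tolerance = 1e-10)
  expect_equal(abs(res$t[i]), 1e6)
})

test_that("rank deficiency and tiny samples are rejected", {
  toy <- make_toy_nbs(n = 4)
  toy$cohort$dup <- toy$cohort$score * 2
  expect_error(
    edgewise_glm(toy$cohort, toy$connectomes,
                 design_spec("score", covariates = c("nuis", "dup"))),
    "too few|rank")
  toy <- make_toy_nbs(n = 20)
  toy$cohort$dup <- toy$cohort$nuis * 2
  expect_error(
    edgewise_glm(toy$cohort, toy$connectomes,
                 design_spec("score", covariates = c("nuis", "dup"))),
    "rank-deficient")
})

test_that("constant covariates are absorbed by the intercept", {
  toy <- make_toy_nbs(n = 16, beta = -4, seed = 57)
  toy$cohort$injury <- "none_mild"  # single level across all subjects
  d0 <- design_spec("score", covariates = "nuis", n_permutations = 5)
  d1 <- design_spec("score", covariates = c("nuis", "injury"),
                    n_permutations = 5)
  r0 <- edgewise_glm(toy$cohort, toy$connectomes, d0)
  r1 <- edgewise_glm(toy$cohort, toy$connectomes, d1)
  expect_equal(r1$t, r0$t, tolerance = 1e-12)
})

test_that("null edgewise t statistics follow the Student t distribution", {
  toy <- make_toy_nbs(n = 30, n_nodes = 15, beta = 0, seed = 3)
  res <- edgewise_glm(toy$cohort, toy$connectomes,
                      design_spec("score", covariates = "nuis"))
  ks <- ks.test(res$t, pt, df = attr(res, "df"))
  expect_gt(ks$p.value, 1e-4)
})

test_that("component extraction matches a breadth-first oracle", {
  # one 3-edge path plus an isolated edge
  et <- data.frame(node_a = c("a", "b", "c", "x", "u"),
                   node_b = c("b", "c", "d", "y", "v"),
                   t = c(-4, -4, -3.5, -4.2, -1),
                   stringsAsFactors = FALSE)
  comps <- extract_components(et, 3.1, "negative")
  expect_length(comps, 2)
  expect_equal(comps[[1]]$extent, 3)
  expect_equal(comps[[2]]$extent, 1)
  expect_equal(comps[[1]]$nodes, c("a", "b", "c", "d"))

  expect_length(extract_components(et, 10, "negative"), 0)
  all_in <- extract_components(
    data.frame(node_a = c("a", "b"), node_b = c("b", "c"), t = c(5, 5)),
    3.1, "positive")
  expect_length(all_in, 1)
  expect_equal(all_in[[1]]$extent, 2)

  # randomized comparison against the BFS oracle
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    m <- sample(1:12, 1)
    et <- data.frame(node_a = paste0("n", sample(n, m, replace = TRUE)),
                     node_b = paste0("m", sample(n, m, replace = TRUE)),
                     t = -runif(m, 3.2, 6))
    comps <- extract_components(et, 3.1, "negative")
    want <- sort(components_oracle(et)$extents, decreasing = TRUE)
    expect_equal(vapply(comps, `[[`, numeric(1), "extent"), want)
  }
})

test_that("FWE p-values follow the add-one permutation formula", {
  toy <- make_toy_nbs(n = 25, beta = -8, noise = 0.8, seed = 9)
  d <- design_spec("score", covariates = "nuis", n_permutations = 200,
                   seed = 2, edge_presence_min = 0.5)
  res <- nbs_test(toy$cohort, toy$connectomes, d)
  expect_gte(length(res$components), 1)
  expect_length(res$null_max_extents, 200)
  for (cm in res$components) {
    expect_equal(cm$p_fwe,
                 (1 + sum(res$null_max_extents >= cm$extent)) / 201)
  }
  # p is bounded below by 1/(1+B), attained when the observed extent beats
  # every permutation's maximum
  cm1 <- res$components[[1]]
  expect_gte(cm1$p_fwe, 1 / 201)
  if (cm1$extent > max(res$null_max_extents)) {
    expect_equal(cm1$p_fwe, 1 / 201)
  }
})

test_that("identical seeds give identical null distributions", {
  toy <- make_toy_nbs(n = 15, seed = 21)
  d <- design_spec("score", covariates = "nuis", n_permutations = 50, seed = 5,
                   t_threshold = 2.0)
  r1 <- nbs_test(toy$cohort, toy$connectomes, d)
  r2 <- nbs_test(toy$cohort, toy$connectomes, d)
  expect_identical(r1$null_max_extents, r2$null_max_extents)
  d2 <- d
  d2$seed <- 6L
  r3 <- nbs_test(toy$cohort, toy$connectomes, d2)
  expect_false(identical(r1$null_max_extents, r3$null_max_extents))
})

test_that("observed t statistics are invariant to joint subject reordering", {
  toy <- make_toy_nbs(n = 18, beta = -3, seed = 33)
  d <- design_spec("score", covariates = "nuis", n_permutations = 5)
  res1 <- edgewise_glm(toy$cohort, toy$connectomes, d)
  perm <- sample(18)
  res2 <- edgewise_glm(toy$cohort[perm, ], toy$connectomes[perm], d)
  expect_equal(res1$t, res2$t, tolerance = 1e-10)
})

test_that("the sensitivity sweep shares permutations across thresholds", {
  expect_length(default_sweep_thresholds(), 11)
  expect_equal(default_sweep_thresholds()[c(1, 11)], c(2.5, 3.5))

  toy <- make_toy_nbs(n = 20, beta = -6, noise = 1, seed = 41)
  d <- design_spec("score", covariates = "nuis", n_permutations = 60, seed = 3,
                   edge_presence_min = 0.5)
  sw <- sensitivity_sweep(toy$cohort, toy$connectomes, d,
                          thresholds = c(2.5, 3.0, 3.5))
  expect_equal(nrow(sw$summary), 3)
  # supra-threshold edge sets shrink, so max extent is non-increasing
  expect_true(all(diff(sw$summary$max_extent) <= 0))
  # single-threshold nbs_test with the same seed agrees with the sweep
  d31 <- d
  d31$t_threshold <- 3.0
  single <- nbs_test(toy$cohort, toy$connectomes, d31)
  expect_identical(sort(single$null_max_extents),
                   sort(sw$results[[2]]$null_max_extents))
  expect_error(sensitivity_sweep(toy$cohort, toy$connectomes, d, numeric(0)),
               "nonempty")
})
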