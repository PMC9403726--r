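# Network-based statistics: an edgewise general linear model with nuisance
# covariates, thresholding of the per-edge t statistics, extraction of
# connected supra-threshold components, and family-wise error control of
# component extent (edge count) by Freedman-Lane permutation of the
# covariate-adjusted residuals.

#' NBS design specification
#'
#' @param predictor Cohort column tested edgewise (e.g. an age-adjusted
#'   behaviour score).
#' @param covariates Character vector of nuisance covariate columns.
#' @param direction `"negative"` (reduced connectivity with higher predictor,
#'   the default) or `"positive"`; the contrast is one-sided.
#' @param t_threshold Primary t-statistic threshold (default 3.1).
#' @param n_permutations Number of permutations (default 10000).
#' @param alpha Critical FWE p-value (default 0.025, reflecting two
#'   behavioural outcomes tested).
#' @param edge_presence_min Analyze only edges nonzero in at least this
#'   fraction of subjects (default 0.9); prevents degenerate regressions on
#'   mostly-absent edges.
#' @param seed Integer seed for the permutation stream.
#' @return List of class `"design_spec"`.
#' @export
design_spec <- function(predictor, covariates = character(0),
                        direction = c("negative", "positive"),
                        t_threshold = 3.1, n_permutations = 10000L,
                        alpha = 0.025, edge_presence_min = 0.9, seed = 1L) {
  direction <- match.arg(direction)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (predictor %in% covariates) {
    stop("predictor must not be among the covariates", call. = FALSE)
  }
  structure(list(predictor = predictor, covariates = covariates,
                 direction = direction, t_threshold = t_threshold,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 edge_presence_min = edge_presence_min,
                 seed = as.integer(seed)),
            class = "design_spec")
}

# assemble aligned design matrix and edge-weight matrix; listwise deletion on
# the model variables, edge mask by presence fraction
prepare_nbs_data <- function(cohort, connectomes, design) {
  subj <- vapply(connectomes, `[[`, character(1), "subject_id")
  idx <- match(cohort$subject_id, subj)
  if (anyNA(idx)) stop("cohort subjects missing a connectome: ",
                       paste(cohort$subject_id[is.na(idx)], collapse = ", "),
                       call. = FALSE)
  vars <- c(design$predictor, design$covariates)
  miss <- setdiff(vars, names(cohort))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  mf <- as.data.frame(cohort)[, vars, drop = FALSE]
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  idx <- idx[keep]
  n <- nrow(mf)
  for (v in vars) if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  # constant covariates carry no information beyond the intercept; drop them
  covs <- design$covariates[vapply(design$covariates, function(v) {
    length(unique(mf[[v]])) > 1
  }, logical(1))]
  Z <- stats::model.matrix(
    stats::reformulate(if (length(covs)) covs else "1"),
    data = mf)
  xp <- stats::model.matrix(stats::reformulate(design$predictor), data = mf)
  xp <- xp[, -1, drop = FALSE]  # drop intercept, keep predictor column(s)
  if (ncol(xp) != 1) stop("predictor must be a single numeric column", call. = FALSE)
  X <- cbind(Z, xp)
  p <- ncol(X)
  if (n < p + 2) stop("too few subjects after listwise deletion (", n,
                      ") for ", p, " design columns", call. = FALSE)
  if (qr(X)$rank < p) stop("rank-deficient design matrix", call. = FALSE)

  ids <- connectomes[[1]]$node_ids
  nn <- length(ids)
  ut <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  Y <- matrix(0, n, nrow(ut))
  for (s in seq_len(n)) {
    Y[s, ] <- connectomes[[idx[s]]]$weights[ut]
  }
  mask <- colMeans(Y > 0) >= design$edge_presence_min
  list(Y = Y[, mask, drop = FALSE], X = X, Z = Z, n = n, p = p,
       edges = data.frame(i = ut[mask, 1], j = ut[mask, 2],
                          node_a = ids[ut[mask, 1]], node_b = ids[ut[mask, 2]],
                          stringsAsFactors = FALSE),
       node_ids = ids, n_nodes = nn)
}

# per-edge t statistics for the last column of X, all edges at once
glm_tstats <- function(Y, X, cap = 1e6) {
  n <- nrow(X)
  p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  XtY <- crossprod(X, Y)
  B <- XtXi %*% XtY
  rss <- colSums(Y * Y) - colSums(B * XtY)
  rss[rss < 0] <- 0
  df <- n - p
  se <- sqrt(rss / df * XtXi[p, p])
  beta <- B[p, ]
  # exact fits get the capped sentinel; numerically-zero fits get t = 0
  t <- ifelse(se > 0, beta / se,
              ifelse(abs(beta) > 1e-8, sign(beta) * cap, 0))
  t[abs(t) > cap] <- sign(t[abs(t) > cap]) * cap
  list(t = t, beta = beta, df = df)
}

#' Edgewise general linear model
#'
#' Fits, for every analyzed edge, an ordinary-least-squares regression of edge
#' weight on an intercept, the nuisance covariates and the predictor, and
#' returns the predictor's t statistic per edge. Edges are analyzed when
#' nonzero in at least `edge_presence_min` of the retained subjects; subjects
#' with any missing model variable are dropped (listwise deletion). Covariates
#' that are constant across the retained subjects are absorbed by the
#' intercept and silently dropped from the design.
#'
#' @param cohort Cohort table.
#' @param connectomes List of `connectome`s (matched to the cohort by
#'   `subject_id`).
#' @param design A [design_spec()].
#' @return data.frame with `node_a`, `node_b`, `beta`, `t`, plus attributes
#'   `df` and `n_used`.
#' @export
edgewise_glm <- function(cohort, connectomes, design) {
  dat <- prepare_nbs_data(cohort, connectomes, design)
  fit <- glm_tstats(dat$Y, dat$X)
  out <- data.frame(node_a = dat$edges$node_a, node_b = dat$edges$node_b,
                    beta = fit$beta, t = fit$t, stringsAsFactors = FALSE)
  attr(out, "df") <- fit$df
  attr(out, "n_used") <- dat$n
  out
}

# union-find maximum component extent (number of edges) for an edge set given
# as node index vectors
max_component_extent <- function(ii, jj, n_nodes) {
  m <- length(ii)
  if (m == 0) return(0L)
  if (m == 1) return(1L)
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(m)) {
    ra <- find(ii[k]); rb <- find(jj[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(ii, find, integer(1))
  max(tabulate(roots, nbins = n_nodes))
}

#' Extract supra-threshold components
#'
#' Builds the graph of edges whose t statistic exceeds the threshold in the
#' contrast direction (`t < -threshold` for `"negative"`, `t > threshold` for
#' `"positive"`) and returns its maximal connected components, ordered by
#' decreasing extent then lexicographic node set.
#'
#' @param edge_t data.frame with `node_a`, `node_b`, `t` (e.g. from
#'   [edgewise_glm()]).
#' @param threshold Positive t threshold.
#' @param direction `"negative"` or `"positive"`.
#' @return List of components; each has `nodes` (sorted character), `edges`
#'   (data.frame with `node_a`, `node_b`, `t`) and `extent` (edge count).
#' @export
extract_components <- function(edge_t, threshold,
                               direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  supra <- if (direction == "negative") edge_t$t < -threshold else
    edge_t$t > threshold
  sub <- edge_t[supra, , drop = FALSE]
  if (!nrow(sub)) return(list())
  g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                     directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[sub$node_a]
  comps <- lapply(sort(unique(comp_of_edge)), function(k) {
    e <- sub[comp_of_edge == k, c("node_a", "node_b", "t"), drop = FALSE]
    rownames(e) <- NULL
    list(nodes = sort(unique(c(e$node_a, e$node_b))), edges = e,
         extent = nrow(e))
  })
  ext <- vapply(comps, `[[`, numeric(1), "extent")
  key <- vapply(comps, function(x) paste(x$nodes, collapse = "\r"), character(1))
  comps[order(-ext, key)]
}

# core permutation engine shared by nbs_test and sensitivity_sweep: one set of
# Freedman-Lane permutations evaluated at every threshold
nbs_engine <- function(cohort, connectomes, design, thresholds) {
  dat <- prepare_nbs_data(cohort, connectomes, design)
  fit <- glm_tstats(dat$Y, dat$X)
  edge_t <- data.frame(node_a = dat$edges$node_a, node_b = dat$edges$node_b,
                       beta = fit$beta, t = fit$t, stringsAsFactors = FALSE)
  n <- dat$n
  # Freedman-Lane: fit the reduced (nuisance-only) model, permute its
  # residuals, re-add the fitted nuisance signal, then refit the full model
  ZtZi <- chol2inv(chol(crossprod(dat$Z)))
  Hz <- dat$Z %*% ZtZi %*% t(dat$Z)
  Yfit <- Hz %*% dat$Y
  Yres <- dat$Y - Yfit
  B <- design$n_permutations
  perms <- with_seed(design$seed,
                     lapply(seq_len(B), function(b) sample.int(n)))
  nthr <- length(thresholds)
  null_max <- matrix(0L, B, nthr)
  neg <- design$direction == "negative"
  ii <- dat$edges$i
  jj <- dat$edges$j
  for (b in seq_len(B)) {
    Yp <- Yfit + Yres[perms[[b]], , drop = FALSE]
    tp <- glm_tstats(Yp, dat$X)$t
    tv <- if (neg) -tp else tp
    for (h in seq_len(nthr)) {
      sel <- tv > thresholds[h]
      null_max[b, h] <- if (any(sel)) {
        max_component_extent(ii[sel], jj[sel], dat$n_nodes)
      } else 0L
    }
  }
  list(edge_t = edge_t, null_max = null_max, df = fit$df, n_used = n)
}

nbs_result_from_engine <- function(eng, design, threshold, null_max) {
  comps <- extract_components(eng$edge_t, threshold, design$direction)
  B <- length(null_max)
  for (k in seq_along(comps)) {
    comps[[k]]$p_fwe <- (1 + sum(null_max >= comps[[k]]$extent)) / (1 + B)
  }
  structure(list(
    edge_t = eng$edge_t,
    components = comps,
    null_max_extents = as.integer(null_max),
    t_threshold = threshold,
    direction = design$direction,
    alpha = design$alpha,
    n_permutations = B,
    df = eng$df,
    n_used = eng$n_used
  ), class = "nbs_result")
}

#' Network-based statistic permutation test
#'
#' Runs the edgewise GLM, extracts supra-threshold components at the design's
#' t threshold, and assigns each component a family-wise-error-corrected
#' p-value by comparing its extent with the permutation distribution of the
#' maximum component extent under Freedman-Lane permutation (nuisance-model
#' residuals permuted, nuisance fit re-added). The p-value includes the
#' observed statistic in the null (add-one), so `p >= 1/(1+B)`.
#'
#' @inheritParams edgewise_glm
#' @return Object of class `"nbs_result"`: `edge_t`, `components` (each with
#'   `p_fwe`), `null_max_extents`, and the design settings used.
#' @export
nbs_test <- function(cohort, connectomes, design) {
  eng <- nbs_engine(cohort, connectomes, design, design$t_threshold)
  nbs_result_from_engine(eng, design, design$t_threshold, eng$null_max[, 1])
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs result> t threshold %.2f (%s), %d permutations, %d component(s)\n",
              x$t_threshold, x$direction, x$n_permutations,
              length(x$components)))
  for (k in seq_along(x$components)) {
    cm <- x$components[[k]]
    cat(sprintf("  component %d: %d nodes, extent %d, p_FWE = %.4g%s\n",
                k, length(cm$nodes), cm$extent, cm$p_fwe,
                if (cm$p_fwe <= x$alpha) " *" else ""))
  }
  invisible(x)
}

#' Default sensitivity-sweep thresholds
#'
#' t = 2.5 to 3.5 in steps of 0.1 (11 values).
#' @return Numeric vector of length 11.
#' @export
default_sweep_thresholds <- function() round(seq(2.5, 3.5, by = 0.1), 1)

#' t-threshold sensitivity sweep
#'
#' NBS results depend on the primary t threshold, so the test is repeated over
#' a range of thresholds using a common permutation stream (results differ
#' only by threshold, not by Monte-Carlo noise).
#'
#' @inheritParams edgewise_glm
#' @param thresholds Vector of t thresholds (default
#'   [default_sweep_thresholds()]).
#' @return Object of class `"nbs_sweep"`: `summary` data.frame (threshold,
#'   n_components, max_extent, p_fwe, significant) and `results` (list of
#'   `nbs_result`).
#' @export
sensitivity_sweep <- function(cohort, connectomes, design,
                              thresholds = default_sweep_thresholds()) {
  if (!length(thresholds)) stop("thresholds must be nonempty", call. = FALSE)
  eng <- nbs_engine(cohort, connectomes, design, thresholds)
  results <- lapply(seq_along(thresholds), function(h) {
    nbs_result_from_engine(eng, design, thresholds[h], eng$null_max[, h])
  })
  summary <- data.frame(
    threshold = thresholds,
    n_components = vapply(results, function(r) length(r$components), integer(1)),
    max_extent = vapply(results, function(r) {
      if (length(r$components)) r$components[[1]]$extent else 0L
    }, integer(1)),
    p_fwe = vapply(results, function(r) {
      if (length(r$components)) r$components[[1]]$p_fwe else NA_real_
    }, numeric(1))
  )
  summary$significant <- !is.na(summary$p_fwe) & summary$p_fwe <= design$alpha
  structure(list(summary = summary, results = results),
            class = "nbs_sweep")
}

#' @export
print.nbs_sweep <- function(x, ...) {
  cat("<nbs sensitivity sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
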