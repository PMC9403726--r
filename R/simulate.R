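# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes -- 93-node symmetric nonnegative connectomes with core-periphery
# block organization and heavy-tailed (log-normal) streamline-weight-like
# edge weights, plus realistic covariate distributions and overdispersed
# behaviour counts with an age trend -- and can plant a linear
# edge-weight-behaviour effect in a designated subnetwork so that recovery by
# the downstream statistics is testable against known truth.

#' Simulation configuration
#'
#' Builds a fully defaulted configuration for [simulate_cohort()]. Defaults
#' are sized to the study design this package targets: 43 subjects, 93
#' parcellation nodes of which 34 are core, cognitive composite scores with
#' mean 93.6 and SD 10.2, gestational age near 38.6 weeks, and overdispersed
#' internalizing/externalizing raw counts with a corrected-age trend.
#'
#' @param n_subjects Number of subjects.
#' @param n_nodes Number of nodes.
#' @param n_core Number of planted core nodes (must be < `n_nodes`).
#' @param baseline_density Expected overall edge density in (0, 1]. Block
#'   presence probabilities are scaled so the core-core block is densest,
#'   then feeder, then periphery-periphery (relative ratios
#'   `block_density_ratios`).
#' @param block_density_ratios Length-3 positive ratios (core-core, feeder,
#'   periphery-periphery) of presence probabilities.
#' @param core_core_weight_mean,feeder_weight_mean,periphery_weight_mean
#'   Log-scale means of the log-normal positive edge weights per block.
#' @param weight_sigma Log-scale SD of edge weights.
#' @param effect_edges `NULL`, or a two-column matrix/data.frame of node index
#'   pairs defining the planted subnetwork (see [planted_subnetwork()]).
#' @param effect_beta Weight change per SD of the behaviour score planted on
#'   each effect edge (negative for the reduced-connectivity direction).
#' @param effect_outcome Which raw score carries the planted effect.
#' @param noise_sd SD of additive noise on effect edges (weight units).
#' @param covariates Named list of covariate distribution parameters; any
#'   subset may be overridden.
#' @param seed Integer seed; the cohort is a pure function of the config
#'   including this seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 43L,
                       n_nodes = 93L,
                       n_core = 34L,
                       baseline_density = 0.6,
                       block_density_ratios = c(1.5, 1.0, 0.75),
                       core_core_weight_mean = 4.0,
                       feeder_weight_mean = 3.2,
                       periphery_weight_mean = 2.8,
                       weight_sigma = 0.5,
                       effect_edges = NULL,
                       effect_beta = 0,
                       effect_outcome = c("externalizing_raw", "internalizing_raw"),
                       noise_sd = 2,
                       covariates = list(),
                       seed = 1L) {
  effect_outcome <- match.arg(effect_outcome)
  cov_defaults <- list(
    ga_mean = 38.6, ga_sd = 0.5,
    pma_lag_mean = 0.7, pma_lag_sd = 0.3,
    cognitive_mean = 93.6, cognitive_sd = 10.2,
    imd_meanlog = log(18.66), imd_sdlog = 0.62,
    injury_prob = 6 / 43,
    followup_age_mean = 22.1, followup_age_sd = 0.35,
    internalizing_mu = 7.5, internalizing_size = 2,
    externalizing_mu = 13, externalizing_size = 4,
    age_trend = 0.1
  )
  unknown <- setdiff(names(covariates), names(cov_defaults))
  if (length(unknown)) stop("unknown covariate parameter(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cov <- utils::modifyList(cov_defaults, covariates)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_core = as.integer(n_core), baseline_density = baseline_density,
    block_density_ratios = block_density_ratios,
    core_core_weight_mean = core_core_weight_mean,
    feeder_weight_mean = feeder_weight_mean,
    periphery_weight_mean = periphery_weight_mean,
    weight_sigma = weight_sigma,
    effect_edges = effect_edges, effect_beta = effect_beta,
    effect_outcome = effect_outcome, noise_sd = noise_sd,
    covariates = cov, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_core >= cfg$n_nodes) stop("n_core must be < n_nodes", call. = FALSE)
  if (!(cfg$baseline_density > 0 && cfg$baseline_density <= 1)) {
    stop("baseline_density must be in (0, 1]", call. = FALSE)
  }
  if (length(cfg$block_density_ratios) != 3 || any(cfg$block_density_ratios <= 0)) {
    stop("block_density_ratios must be 3 positive numbers", call. = FALSE)
  }
  bp <- block_presence_probs(cfg)
  if (any(bp > 1)) {
    stop("requested baseline_density incompatible with block ratios ",
         "(a block presence probability would exceed 1)", call. = FALSE)
  }
  if (!is.null(cfg$effect_edges)) {
    ee <- as.matrix(cfg$effect_edges)
    if (ncol(ee) != 2) stop("effect_edges must have two columns", call. = FALSE)
    if (any(ee < 1) || any(ee > cfg$n_nodes) || any(ee[, 1] == ee[, 2])) {
      stop("effect_edges reference invalid node pairs", call. = FALSE)
    }
  }
  if (cfg$weight_sigma <= 0) stop("weight_sigma must be positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# presence probability per block scaled so the expected overall density
# equals baseline_density
block_presence_probs <- function(cfg) {
  nc <- cfg$n_core
  np <- cfg$n_nodes - nc
  pairs <- c(cc = nc * (nc - 1) / 2, cp = nc * np, pp = np * (np - 1) / 2)
  r <- cfg$block_density_ratios
  mean_ratio <- sum(pairs * r) / sum(pairs)
  p <- r * cfg$baseline_density / mean_ratio
  names(p) <- c("cc", "cp", "pp")
  p
}

#' Planted effect subnetwork
#'
#' A connected subnetwork of `n_edges` edges among the lowest-index nodes:
#' node pairs among nodes `1..m` in lexicographic order, with `m` the smallest
#' size offering at least `n_edges` pairs. Used as the default location for a
#' planted edge-weight-behaviour effect.
#'
#' @param n_edges Number of edges (default 12).
#' @return Two-column integer matrix of node index pairs.
#' @export
planted_subnetwork <- function(n_edges = 12L) {
  m <- 2L
  while (m * (m - 1) / 2 < n_edges) m <- m + 1L
  pairs <- t(utils::combn(m, 2))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  pairs[seq_len(n_edges), , drop = FALSE]
}

default_node_table <- function(n_nodes, n_core) {
  hemi <- rep(c("left", "right"), length.out = n_nodes)
  data.frame(
    node_id = sprintf("R%03d", seq_len(n_nodes)),
    region_name = sprintf("Region %d %s", ceiling(seq_len(n_nodes) / 2), hemi),
    hemisphere = hemi,
    partition_label = c(rep("core", n_core), rep("periphery", n_nodes - n_core)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic cohort
#'
#' Generates per-subject connectomes from a stochastic block model with
#' core-periphery structure (edge presence Bernoulli with block-specific
#' probability, positive weights log-normal with block-specific log-mean),
#' draws covariates and overdispersed behaviour counts, and optionally plants
#' a linear effect: each effect edge's weight is shifted by
#' `effect_beta * z` (with `z` the cohort-standardized behaviour score) plus
#' Gaussian noise, floored at zero. Effect edges are always present in every
#' subject so the planted subnetwork survives edge-inclusion masking.
#' Identical configs (including seed) reproduce the cohort exactly.
#'
#' @param config A [sim_config()].
#' @return List of class `"synthetic_cohort"` with `connectomes` (list of
#'   [connectome()]), `cohort` (cohort table), `node_table` (with planted
#'   `partition_label`), and `truth` (planted effect edges, beta, outcome and
#'   partition).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  nn <- cfg$n_nodes
  cv <- cfg$covariates
  node_table <- default_node_table(nn, cfg$n_core)
  core <- node_table$partition_label == "core"

  # covariates
  ga <- stats::rnorm(n, cv$ga_mean, cv$ga_sd)
  pma <- ga + pmax(0.1, stats::rnorm(n, cv$pma_lag_mean, cv$pma_lag_sd))
  sex <- rep(c("male", "female"), length.out = n)[sample.int(n)]
  injury <- ifelse(stats::runif(n) < cv$injury_prob, "moderate_severe", "none_mild")
  cognitive <- stats::rnorm(n, cv$cognitive_mean, cv$cognitive_sd)
  imd <- stats::rlnorm(n, cv$imd_meanlog, cv$imd_sdlog)
  age <- stats::rnorm(n, cv$followup_age_mean, cv$followup_age_sd)
  internal <- stats::rnbinom(n, size = cv$internalizing_size,
                             mu = exp(log(cv$internalizing_mu) +
                                        cv$age_trend * (age - cv$followup_age_mean)))
  external <- stats::rnbinom(n, size = cv$externalizing_size,
                             mu = exp(log(cv$externalizing_mu) +
                                        cv$age_trend * (age - cv$followup_age_mean)))
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    ga_birth = ga, pma_scan = pma, sex = sex, injury_rating = injury,
    cognitive_composite = cognitive, imd = imd,
    corrected_age_followup = age,
    internalizing_raw = internal, externalizing_raw = external,
    stringsAsFactors = FALSE
  )
  cohort <- validate_cohort(cohort)

  # block structure over unordered pairs
  ut <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  blk <- ifelse(core[ut[, 1]] & core[ut[, 2]], "cc",
                ifelse(!core[ut[, 1]] & !core[ut[, 2]], "pp", "cp"))
  presence_p <- block_presence_probs(cfg)[blk]
  mulog <- c(cc = cfg$core_core_weight_mean, cp = cfg$feeder_weight_mean,
             pp = cfg$periphery_weight_mean)[blk]

  score <- cohort[[cfg$effect_outcome]]
  z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score) else score * 0

  eff_idx <- integer(0)
  if (!is.null(cfg$effect_edges)) {
    ee <- as.matrix(cfg$effect_edges)
    i <- pmin(ee[, 1], ee[, 2])
    j <- pmax(ee[, 1], ee[, 2])
    eff_idx <- match(paste(i, j), paste(ut[, 1], ut[, 2]))
  }

  npair <- nrow(ut)
  connectomes <- vector("list", n)
  for (s in seq_len(n)) {
    present <- stats::runif(npair) < presence_p
    wvec <- ifelse(present, stats::rlnorm(npair, mulog, cfg$weight_sigma), 0)
    if (length(eff_idx)) {
      base <- stats::rlnorm(length(eff_idx), mulog[eff_idx], cfg$weight_sigma)
      shift <- cfg$effect_beta * z[s] +
        stats::rnorm(length(eff_idx), 0, cfg$noise_sd)
      wvec[eff_idx] <- pmax(0, base + shift)
    }
    w <- matrix(0, nn, nn)
    w[ut] <- wvec
    w <- w + t(w)
    connectomes[[s]] <- connectome(w, node_ids = node_table$node_id,
                                   subject_id = cohort$subject_id[s])
  }

  truth <- list(
    effect_edges = if (length(eff_idx)) {
      data.frame(node_a = node_table$node_id[ut[eff_idx, 1]],
                 node_b = node_table$node_id[ut[eff_idx, 2]],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(node_a = character(0), node_b = character(0))
    },
    effect_beta = cfg$effect_beta,
    effect_outcome = cfg$effect_outcome,
    partition = stats::setNames(node_table$partition_label, node_table$node_id),
    seed = cfg$seed
  )
  structure(list(connectomes = connectomes, cohort = cohort,
                 node_table = node_table, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort> %d subjects, %d nodes (%d core), %s\n",
              length(x$connectomes), x$config$n_nodes, x$config$n_core,
              if (nrow(x$truth$effect_edges))
                sprintf("planted effect on %d edges (beta %.2f on %s)",
                        nrow(x$truth$effect_edges), x$truth$effect_beta,
                        x$truth$effect_outcome)
              else "no planted effect"))
  invisible(x)
}

#' Ensemble of independent null cohorts
#'
#' Generates `n_cohorts` cohorts with no planted effect, each from a seed
#' derived from the config's master seed, and records those seeds so any one
#' cohort can be regenerated in isolation.
#'
#' @param config A [sim_config()] with `effect_beta = 0`.
#' @param n_cohorts Number of cohorts.
#' @return List of class `"null_ensemble"`: `cohorts` (list of
#'   `synthetic_cohort`) and `seeds` (integer vector).
#' @export
simulate_null_ensemble <- function(config, n_cohorts) {
  if (config$effect_beta != 0) {
    stop("null ensemble requires effect_beta = 0", call. = FALSE)
  }
  seeds <- vapply(seq_len(n_cohorts), function(k) derive_seed(config$seed, k),
                  integer(1))
  cohorts <- lapply(seeds, function(s) {
    cfg <- unclass(config)
    cfg$seed <- s
    simulate_cohort(validate_sim_config(cfg))
  })
  structure(list(cohorts = cohorts, seeds = seeds), class = "null_ensemble")
}

#' Write a synthetic cohort to files
#'
#' Writes one connectome CSV per subject, `cohort.csv`, `node_table.csv` and a
#' `truth.tsv` describing the planted effect, in standard formats readable by
#' [read_connectome()], [read_cohort()] and [read_node_table()].
#'
#' @param sim A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort_files <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cdir <- file.path(dir, "connectomes")
  dir.create(cdir, showWarnings = FALSE)
  for (cn in sim$connectomes) {
    write_connectome(cn, file.path(cdir, paste0(cn$subject_id, ".csv")))
  }
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  write_node_table(sim$node_table, file.path(dir, "node_table.csv"))
  tr <- sim$truth$effect_edges
  tr$effect_beta <- rep(sim$truth$effect_beta, length.out = max(1, nrow(tr)))[
    seq_len(nrow(tr))]
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
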