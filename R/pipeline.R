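# Config-driven orchestration: simulate or load a cohort, extract
# cost-corrected graph metrics, partition into core/periphery, run the
# covariate-adjusted association layer with FDR, and run NBS with its
# t-threshold sensitivity sweep. A single master seed derives per-stage seeds
# so any stage can be re-run in isolation; identical config + seed reproduces
# every result table byte for byte.

pipeline_defaults <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    simulation = NULL,
    inputs = NULL,
    density_grid = list(min = 0.05, max = 0.5, step = 0.01),
    core_periphery = list(n_restarts = 100L, method = "mean"),
    outcomes = c("internalizing_raw", "externalizing_raw"),
    covariates = list(
      behavior = c("ga_birth", "sex", "injury_rating", "cognitive_composite", "imd"),
      network = c("ga_birth", "pma_scan", "sex", "injury_rating",
                  "cognitive_composite", "imd")
    ),
    nbs = list(t_threshold = 3.1, n_permutations = 10000L, alpha = 0.025,
               direction = "negative", edge_presence_min = 0.9,
               sweep = default_sweep_thresholds()),
    verbosity = 1L
  )
}

merge_checked <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(defaults, user)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills in defaults, and validates the
#' schema. Exactly one of `simulation` (a block of [sim_config()] arguments)
#' or `inputs` (paths `connectome_dir`, `cohort`, `node_table`) must be
#' present, and `seed` is mandatory. Unknown keys are rejected with the
#' offending field named.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated list of class `"pipeline_config"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  def <- pipeline_defaults()
  cfg <- merge_checked(def, config, "top level")
  if (is.null(cfg$seed)) stop("config field 'seed' is mandatory", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  has_sim <- !is.null(cfg$simulation)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp) {
    stop("config must name exactly one of 'simulation' or 'inputs'", call. = FALSE)
  }
  if (has_sim) {
    sim_args <- cfg$simulation
    if (!is.list(sim_args)) sim_args <- list()
    allowed <- names(formals(sim_config))
    unknown <- setdiff(names(sim_args), allowed)
    if (length(unknown)) stop("unknown config key(s) in simulation: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    if (!is.null(sim_args$effect_edges)) {
      sim_args$effect_edges <- matrix(unlist(sim_args$effect_edges),
                                      ncol = 2, byrow = TRUE)
    }
    sim_args$seed <- derive_seed(cfg$seed, 101L)
    cfg$simulation <- do.call(sim_config, sim_args)
  } else {
    need <- c("connectome_dir", "cohort", "node_table")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss)) stop("config inputs missing: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  cfg$density_grid <- merge_checked(def$density_grid,
                                    as.list(cfg$density_grid), "density_grid")
  cfg$core_periphery <- merge_checked(def$core_periphery,
                                      as.list(cfg$core_periphery), "core_periphery")
  if (!cfg$core_periphery$method %in% c("mean", "consensus")) {
    stop("core_periphery method must be 'mean' or 'consensus'", call. = FALSE)
  }
  cfg$nbs <- merge_checked(def$nbs, as.list(cfg$nbs), "nbs")
  if (!(cfg$nbs$alpha > 0 && cfg$nbs$alpha < 1)) {
    stop("nbs alpha must be in (0, 1)", call. = FALSE)
  }
  if (!cfg$nbs$direction %in% c("negative", "positive")) {
    stop("nbs direction must be 'negative' or 'positive'", call. = FALSE)
  }
  bad <- setdiff(cfg$outcomes, c("internalizing_raw", "externalizing_raw"))
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

config_grid <- function(cfg) {
  g <- cfg$density_grid
  round(seq(g$min, g$max, by = g$step), 10)
}

pipe_log <- function(state, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  if (state$verbosity > 0) message(line)
  cat(line, "\n", file = state$log_path, append = TRUE)
}

write_tab <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

#' Run the full connectome analysis pipeline
#'
#' Executes the stages in order: load or simulate the cohort, cost-corrected
#' graph metrics, core-periphery partition with edge typing, covariate-
#' adjusted partial Spearman associations (global and nodal, FDR within
#' family), and NBS with the t-threshold sensitivity sweep. Each stage writes
#' its result tables under `out_dir`; failure of one outcome's analysis is
#' recorded and does not abort the others. Timestamps go only to the run log,
#' so all result tables are byte-reproducible under a fixed config and seed.
#'
#' @param config A [validate_config()] result, a config list, or a YAML path.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @param stages Subset of
#'   `c("data", "metrics", "partition", "associations", "nbs")`; later stages
#'   recompute what they need from earlier ones, which always run.
#' @return List of class `"run_report"`: per-stage summaries, the echoed
#'   config, output paths, errors (empty on full success) and `ok`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("data", "metrics", "partition",
                                    "associations", "nbs")) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(verbosity = cfg$verbosity,
                log_path = file.path(out_dir, "run.log"))
  cat("", file = state$log_path)
  report <- list(config = unclass(cfg), stages = list(), outputs = character(0),
                 errors = character(0),
                 version = as.character(utils::packageVersion("neoconn")))

  # -- data -------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    pipe_log(state, "data", sprintf("simulating cohort (n=%d, seed=%d)",
                                    cfg$simulation$n_subjects, cfg$simulation$seed))
    sim <- simulate_cohort(cfg$simulation)
    cohort <- sim$cohort
    connectomes <- sim$connectomes
    node_table <- sim$node_table
    if ("data" %in% stages) {
      write_cohort_files(sim, file.path(out_dir, "data"))
      report$outputs <- c(report$outputs, file.path(out_dir, "data"))
    }
    truth <- sim$truth
  } else {
    pipe_log(state, "data", paste("loading cohort from", cfg$inputs$cohort))
    node_table <- read_node_table(cfg$inputs$node_table)
    cohort <- read_cohort(cfg$inputs$cohort)
    files <- file.path(cfg$inputs$connectome_dir,
                       paste0(cohort$subject_id, ".csv"))
    connectomes <- lapply(seq_along(files), function(i) {
      read_connectome(files[i], node_table, subject_id = cohort$subject_id[i])
    })
    truth <- NULL
  }
  report$stages$data <- list(n_subjects = nrow(cohort),
                             n_nodes = nrow(node_table))

  grid <- config_grid(cfg)

  # age-adjusted outcome scores, used by associations and NBS
  for (oc in cfg$outcomes) {
    adj <- age_adjust(cohort[[oc]], cohort$corrected_age_followup,
                      cohort$subject_id)
    cohort[[paste0(oc, "_ageadj")]] <- adj$age_adjusted
  }

  # -- metrics ----------------------------------------------------------
  cc_list <- NULL
  if (any(c("metrics", "associations") %in% stages)) {
    pipe_log(state, "metrics",
             sprintf("cost-corrected features over %d densities", length(grid)))
    cc_list <- lapply(connectomes, cost_corrected_features, density_grid = grid)
    names(cc_list) <- cohort$subject_id
    if ("metrics" %in% stages) {
      long <- do.call(rbind, lapply(cohort$subject_id, function(s) {
        features_long(cc_list[[s]], s)
      }))
      raw_dens <- data.frame(
        subject_id = cohort$subject_id, feature = "density",
        node_id = "global", density = "raw",
        value = vapply(connectomes, net_density, numeric(1)),
        stringsAsFactors = FALSE)
      report$outputs <- c(report$outputs,
                          write_tab(rbind(raw_dens, long),
                                    file.path(out_dir, "metrics.csv")))
      report$stages$metrics <- list(n_rows = nrow(long) + nrow(raw_dens))
    }
  }

  # -- partition --------------------------------------------------------
  if ("partition" %in% stages) {
    pipe_log(state, "partition",
             sprintf("core-periphery (%s, %d restarts)",
                     cfg$core_periphery$method, cfg$core_periphery$n_restarts))
    part <- group_partition(connectomes, method = cfg$core_periphery$method,
                            seed = derive_seed(cfg$seed, 202L),
                            n_restarts = cfg$core_periphery$n_restarts)
    nt_out <- apply_partition(node_table, part)
    report$outputs <- c(report$outputs,
                        write_node_table(nt_out,
                                         file.path(out_dir, "node_partition.csv")))
    mc <- mean_connectome(connectomes)
    cls <- classify_edges(edge_list(mc), part$labels)
    report$outputs <- c(report$outputs,
                        write_tab(cls$edges[, c("node_a", "node_b", "type")],
                                  file.path(out_dir, "edge_types.csv")))
    report$stages$partition <- list(n_core = part$n_core,
                                    n_periphery = part$n_periphery,
                                    quality = part$quality,
                                    edge_counts = as.list(cls$counts))
  }

  # -- associations -----------------------------------------------------
  if ("associations" %in% stages) {
    for (oc in cfg$outcomes) {
      res <- try(run_associations(cohort, connectomes, cc_list, oc, cfg),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        msg <- sprintf("associations(%s) failed: %s", oc,
                       conditionMessage(attr(res, "condition")))
        pipe_log(state, "associations", msg)
        report$errors <- c(report$errors, msg)
        next
      }
      pg <- write_tab(res$global,
                      file.path(out_dir, sprintf("associations_global_%s.csv", oc)))
      pn <- write_tab(res$nodal,
                      file.path(out_dir, sprintf("associations_nodal_%s.csv", oc)))
      report$outputs <- c(report$outputs, pg, pn)
      report$stages$associations[[oc]] <-
        list(n_global = nrow(res$global), n_nodal = nrow(res$nodal),
             min_p_fdr_nodal = suppressWarnings(min(res$nodal$p_fdr)))
      pipe_log(state, "associations",
               sprintf("%s: %d global + %d nodal tests", oc,
                       nrow(res$global), nrow(res$nodal)))
    }
  }

  # -- nbs --------------------------------------------------------------
  if ("nbs" %in% stages) {
    for (oc in cfg$outcomes) {
      res <- try({
        design <- design_spec(
          predictor = paste0(oc, "_ageadj"),
          covariates = cfg$covariates$network,
          direction = cfg$nbs$direction,
          t_threshold = cfg$nbs$t_threshold,
          n_permutations = cfg$nbs$n_permutations,
          alpha = cfg$nbs$alpha,
          edge_presence_min = cfg$nbs$edge_presence_min,
          seed = derive_seed(cfg$seed, 303L))
        sweep <- sensitivity_sweep(cohort, connectomes, design,
                                   thresholds = sort(unique(c(cfg$nbs$sweep,
                                                              cfg$nbs$t_threshold))))
        list(design = design, sweep = sweep)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        msg <- sprintf("nbs(%s) failed: %s", oc,
                       conditionMessage(attr(res, "condition")))
        pipe_log(state, "nbs", msg)
        report$errors <- c(report$errors, msg)
        next
      }
      main <- res$sweep$results[[
        which(res$sweep$summary$threshold == cfg$nbs$t_threshold)]]
      report$outputs <- c(report$outputs,
        write_tab(main$edge_t, file.path(out_dir, sprintf("nbs_edge_t_%s.csv", oc))),
        write_tab(res$sweep$summary,
                  file.path(out_dir, sprintf("nbs_sweep_%s.csv", oc))))
      comp_rows <- do.call(rbind, lapply(seq_along(main$components), function(k) {
        cm <- main$components[[k]]
        data.frame(component_id = k, node_a = cm$edges$node_a,
                   node_b = cm$edges$node_b, t = cm$edges$t,
                   extent = cm$extent, p_fwe = cm$p_fwe,
                   stringsAsFactors = FALSE)
      }))
      if (is.null(comp_rows)) {
        comp_rows <- data.frame(component_id = integer(0), node_a = character(0),
                                node_b = character(0), t = numeric(0),
                                extent = integer(0), p_fwe = numeric(0))
      }
      report$outputs <- c(report$outputs,
        write_tab(comp_rows, file.path(out_dir, sprintf("nbs_components_%s.csv", oc))))
      sig <- vapply(main$components, function(cmp) cmp$p_fwe <= main$alpha,
                    logical(1))
      report$stages$nbs[[oc]] <- list(
        n_components = length(main$components),
        n_significant = sum(sig),
        max_extent = if (length(main$components)) main$components[[1]]$extent else 0L,
        p_fwe = if (length(main$components)) main$components[[1]]$p_fwe else NA_real_)
      pipe_log(state, "nbs", sprintf("%s: %d component(s), %d significant", oc,
                                     length(main$components), sum(sig)))
    }
  }

  report$truth <- truth
  report$ok <- length(report$errors) == 0
  report_path <- file.path(out_dir, "run_report.yaml")
  echo <- report[c("version", "stages", "errors", "ok")]
  echo$seed <- cfg$seed
  yaml::write_yaml(echo, report_path)
  report$outputs <- c(report$outputs, report_path)
  class(report) <- "run_report"
  report
}

run_associations <- function(cohort, connectomes, cc_list, outcome, cfg) {
  y <- cohort[[paste0(outcome, "_ageadj")]]
  covs_net <- as.data.frame(cohort)[, cfg$covariates$network, drop = FALSE]
  glob_feats <- list(
    total_density = vapply(connectomes, net_density, numeric(1)),
    cc_mean_strength = vapply(cc_list, function(x) x$cost_corrected$mean_strength,
                              numeric(1)),
    cc_global_efficiency = vapply(cc_list,
                                  function(x) x$cost_corrected$global_efficiency,
                                  numeric(1)),
    cc_local_efficiency = vapply(cc_list,
                                 function(x) x$cost_corrected$local_efficiency,
                                 numeric(1))
  )
  glob <- do.call(rbind, lapply(names(glob_feats), function(f) {
    ps <- partial_spearman(glob_feats[[f]], y, covs_net)
    data.frame(feature = f, partial_rho = ps$partial_rho, p = ps$p_value,
               n = ps$n_used, stringsAsFactors = FALSE)
  }))
  glob$p_fdr <- fdr_adjust(glob$p)

  node_ids <- connectomes[[1]]$node_ids
  nodal_feats <- c("strength", "degree", "nodal_efficiency")
  rows <- vector("list", length(nodal_feats) * length(node_ids))
  r <- 0L
  for (f in nodal_feats) {
    vals <- vapply(cc_list, function(x) {
      v <- x$cost_corrected$nodal[[f]]
      stats::setNames(v, x$cost_corrected$nodal$node_id)
    }, numeric(length(node_ids)))
    for (nd in seq_along(node_ids)) {
      ps <- partial_spearman(vals[nd, ], y, covs_net)
      r <- r + 1L
      rows[[r]] <- data.frame(feature = f, node_id = node_ids[nd],
                              partial_rho = ps$partial_rho, p = ps$p_value,
                              n = ps$n_used, stringsAsFactors = FALSE)
    }
  }
  nodal <- do.call(rbind, rows)
  # FDR family: all nodes x metrics for this outcome
  nodal$p_fdr <- fdr_adjust(nodal$p)
  list(global = glob, nodal = nodal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run report> neoconn %s, %d output(s), %s\n", x$version,
              length(x$outputs),
              if (x$ok) "ok" else paste(length(x$errors), "error(s)")))
  invisible(x)
}
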