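#' Construct a connectome object
#'
#' A connectome is a weighted undirected brain graph: a square symmetric matrix
#' of nonnegative edge weights (for structural networks built from tractography,
#' typically sums of SIFT2-weighted streamlines) over an ordered set of
#' parcellation regions.
#'
#' @param weights Square numeric matrix, symmetric, nonnegative, zero diagonal.
#' @param node_ids Character vector of unique region identifiers, one per row of
#'   `weights`. Defaults to the matrix dimnames, or `"n1"..."nN"`.
#' @param subject_id Single string identifying the subject.
#' @param sym_tol Relative tolerance for symmetry. Pairs whose relative
#'   difference is at most `sym_tol` are averaged; larger asymmetries are an
#'   error (they usually signal transposed or corrupt input).
#' @return An object of class `"connectome"` with elements `subject_id`,
#'   `weights` (validated matrix with `node_ids` as dimnames) and `node_ids`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2
#' cn <- connectome(w, node_ids = c("a", "b", "c"), subject_id = "s1")
#' edge_list(cn)
#' @export
connectome <- function(weights, node_ids = NULL, subject_id = "subject",
                       sym_tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(weights) != ncol(weights)) {
    stop("connectome matrix must be square, got ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  }
  if (anyNA(weights)) stop("connectome weights contain missing values", call. = FALSE)
  if (is.null(node_ids)) {
    node_ids <- rownames(weights)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(weights)))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != nrow(weights)) {
    stop("length of `node_ids` (", length(node_ids),
         ") does not match matrix dimension (", nrow(weights), ")", call. = FALSE)
  }
  if (anyDuplicated(node_ids)) stop("node_ids must be unique", call. = FALSE)
  if (any(weights < 0)) stop("connectome weights must be nonnegative", call. = FALSE)
  # symmetry: average within tolerance, error beyond it
  up <- weights[upper.tri(weights)]
  lo <- t(weights)[upper.tri(weights)]
  scale <- pmax(abs(up), abs(lo))
  bad <- scale > 0 & abs(up - lo) / scale > sym_tol
  if (any(bad)) {
    stop("connectome matrix is asymmetric beyond tolerance (",
         sum(bad), " pair(s)); refusing to average", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(node_ids, node_ids)
  structure(
    list(subject_id = as.character(subject_id)[1], weights = weights,
         node_ids = node_ids),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$node_ids)
  e <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> subject %s: %d nodes, %d edges (density %.3f)\n",
              x$subject_id, n, e, if (n > 1) 2 * e / (n * (n - 1)) else 0))
  invisible(x)
}

#' Number of nodes of a connectome
#' @param c A `connectome`.
#' @return Integer node count.
#' @export
n_nodes <- function(c) {
  stopifnot(inherits(c, "connectome"))
  length(c$node_ids)
}

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a connectome matrix from delimited text
#'
#' Reads a square numeric matrix stored as CSV or TSV (dialect inferred from
#' the file extension). A header row of node identifiers is optional; when a
#' `node_table` is supplied, files with headers are reordered to its node order
#' and headerless files are assumed to be in node-table order already.
#'
#' @param path Path to a `.csv` or `.tsv` matrix file.
#' @param node_table Optional node table (see [read_node_table()]) defining
#'   node identity and order.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A validated [connectome()].
#' @export
read_connectome <- function(path, node_table = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- delim_for(path)
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(cells))))
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE, row.names = NULL)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  ids <- if (has_header) colnames(m) else NULL
  if (!is.null(node_table)) {
    want <- node_table$node_id
    if (nrow(m) != length(want)) {
      stop("matrix has ", nrow(m), " rows but node table has ", length(want),
           " nodes", call. = FALSE)
    }
    if (!is.null(ids)) {
      if (!setequal(ids, want)) {
        stop("connectome header node_ids do not match the node table", call. = FALSE)
      }
      ord <- match(want, ids)
      m <- m[ord, ord, drop = FALSE]
    }
    ids <- want
  }
  rownames(m) <- NULL
  if (is.null(subject_id)) {
    subject_id <- sub("\\.(csv|tsv)$", "", basename(path), ignore.case = TRUE)
  }
  connectome(m, node_ids = ids, subject_id = subject_id)
}

#' Write a connectome matrix to delimited text
#'
#' Writes the weight matrix with a header row of node identifiers, using full
#' double precision so that a write/read round trip reproduces the weights.
#'
#' @param c A `connectome`.
#' @param path Output `.csv` or `.tsv` path.
#' @return Invisibly, `path`.
#' @export
write_connectome <- function(c, path) {
  stopifnot(inherits(c, "connectome"))
  sep <- delim_for(path)
  m <- c$weights
  lines <- c(paste(c$node_ids, collapse = sep),
             vapply(seq_len(nrow(m)), function(i) {
               paste(format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parcellation node table
#'
#' @param path Delimited text file with header; required columns `node_id`,
#'   `region_name`, `hemisphere` (`left`/`right`/`midline`); optional
#'   `partition_label` (`core`/`periphery`), which when present must be defined
#'   for every node.
#' @return A data.frame with one row per region.
#' @export
read_node_table <- function(path) {
  tab <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("node_id", "region_name", "hemisphere")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("node table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  validate_node_table(tab)
}

#' Validate a node table data.frame
#' @param tab data.frame with the node-table columns.
#' @return The validated data.frame.
#' @export
validate_node_table <- function(tab) {
  if (anyDuplicated(tab$node_id)) stop("node_ids must be unique", call. = FALSE)
  bad_h <- setdiff(unique(tab$hemisphere), c("left", "right", "midline"))
  if (length(bad_h)) stop("invalid hemisphere value(s): ",
                          paste(bad_h, collapse = ", "), call. = FALSE)
  if ("partition_label" %in% names(tab)) {
    pl <- tab$partition_label
    if (anyNA(pl) || any(!pl %in% c("core", "periphery"))) {
      stop("partition_label, when present, must be 'core' or 'periphery' for every node",
           call. = FALSE)
    }
  }
  tab$node_id <- as.character(tab$node_id)
  tab
}

#' Write a node table
#' @param tab Node table data.frame.
#' @param path Output path (`.csv`/`.tsv`).
#' @return Invisibly, `path`.
#' @export
write_node_table <- function(tab, path) {
  utils::write.table(tab, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

cohort_required_cols <- c(
  "subject_id", "ga_birth", "pma_scan", "sex", "injury_rating",
  "cognitive_composite", "imd", "corrected_age_followup",
  "internalizing_raw", "externalizing_raw"
)

#' Read a cohort covariate table
#'
#' Loads per-subject covariates and behavioural outcomes. Blank numeric cells
#' become `NA` (missing), never zero; analyses downstream apply listwise
#' deletion per analysis.
#'
#' @param path Delimited text file with a header naming at least the required
#'   columns: `subject_id`, `ga_birth` (weeks), `pma_scan` (weeks), `sex`
#'   (`male`/`female`), `injury_rating` (`none_mild`/`moderate_severe`),
#'   `cognitive_composite`, `imd`, `corrected_age_followup` (months),
#'   `internalizing_raw`, `externalizing_raw`.
#' @return A data.frame of class `"cohort_table"`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  validate_cohort(tab)
}

#' Validate a cohort table
#' @param tab data.frame of per-subject covariates.
#' @return The validated table (class `"cohort_table"` prepended).
#' @export
validate_cohort <- function(tab) {
  miss <- setdiff(cohort_required_cols, names(tab))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicate subject_id in cohort table", call. = FALSE)
  }
  for (col in c("internalizing_raw", "externalizing_raw")) {
    v <- tab[[col]]
    ok <- is.na(v) | (v >= 0 & v == round(v))
    if (!all(ok)) stop(col, " must contain nonnegative integer counts", call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (!inherits(tab, "cohort_table")) class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Write a cohort table
#' @param tab Cohort table.
#' @param path Output path (`.csv`/`.tsv`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = delim_for(path),
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Edge list of a connectome
#'
#' @param c A `connectome`.
#' @return A data.frame with columns `node_a`, `node_b`, `weight`: one row per
#'   unordered pair with strictly positive weight, sorted by (`node_a`,
#'   `node_b`) in node-table order for determinism.
#' @export
edge_list <- function(c) {
  stopifnot(inherits(c, "connectome"))
  w <- c$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx)) idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    node_a = c$node_ids[idx[, 1]],
    node_b = c$node_ids[idx[, 2]],
    weight = w[idx],
    stringsAsFactors = FALSE
  )
}
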