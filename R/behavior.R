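# Outcome preprocessing and the covariate-adjusted association layer:
# age-residualized behaviour scores, partial Spearman correlations with
# Benjamini-Hochberg FDR, Kruskal-Wallis group comparisons, CBCL T-score
# banding, and radiological brain-injury classification rules.

#' Age-adjust raw behaviour scores
#'
#' Regresses raw scores on corrected age at follow-up (ordinary least squares
#' with intercept) and returns standardized residuals (sample mean 0, SD 1
#' over the fitted subjects). Subjects missing either value get `NA`. When the
#' fit is exact (zero residual variance) the residuals are reported as 0 and
#' flagged.
#'
#' @param scores Numeric vector of raw scores.
#' @param ages Numeric vector of corrected ages (months), same length.
#' @param subject_id Optional subject identifiers.
#' @return data.frame with `subject_id`, `raw_score`, `age_adjusted`;
#'   attribute `zero_variance` is `TRUE` when residual variance vanished.
#' @export
age_adjust <- function(scores, ages, subject_id = NULL) {
  stopifnot(length(scores) == length(ages))
  if (is.null(subject_id)) subject_id <- as.character(seq_along(scores))
  ok <- !is.na(scores) & !is.na(ages)
  if (sum(ok) < 3) stop("need at least 3 subjects with score and age", call. = FALSE)
  if (stats::sd(ages[ok]) == 0) stop("constant age vector: rank-deficient fit",
                                     call. = FALSE)
  fit <- stats::lm(scores[ok] ~ ages[ok])
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  zero_var <- s < 1e-12
  adj <- rep(NA_real_, length(scores))
  adj[ok] <- if (zero_var) 0 else (res - mean(res)) / s
  structure(
    data.frame(subject_id = subject_id, raw_score = scores, age_adjusted = adj,
               stringsAsFactors = FALSE),
    zero_variance = zero_var
  )
}

rank_avg <- function(v) rank(v, ties.method = "average")

#' Partial Spearman rank correlation
#'
#' Rank-transforms `x`, `y` and each covariate (average ranks for ties),
#' residualizes the ranked `x` and `y` on an intercept plus the ranked
#' covariates by ordinary least squares, and correlates the residuals. The
#' p-value uses the t approximation with `n - 2 - k` degrees of freedom
#' (`k` covariates); an exact permutation p-value is available for small
#' samples.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data.frame/matrix of covariates; categorical
#'   columns are expanded to dummy columns and every column is
#'   rank-transformed (for a binary dummy ranking is the identity up to
#'   scaling). Columns constant over the complete cases are absorbed by the
#'   intercept and dropped.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Permutations when `p_method = "permutation"`.
#' @param seed Seed for the permutation p-value.
#' @return List of class `"partial_spearman"`: `partial_rho`, `p_value`,
#'   `n_used`, `df`, `covariates` (names).
#' @export
partial_spearman <- function(x, y, covariates = NULL,
                             p_method = c("t", "permutation"),
                             n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  cc <- stats::complete.cases(if (is.null(cv)) data.frame(x, y) else
    cbind(data.frame(x, y), cv))
  x <- x[cc]; y <- y[cc]
  k <- 0L
  Zr <- NULL
  if (!is.null(cv)) {
    cv <- cv[cc, , drop = FALSE]
    for (nm in names(cv)) if (is.character(cv[[nm]])) cv[[nm]] <- factor(cv[[nm]])
    # constant covariates are absorbed by the intercept; drop them
    cv <- cv[, vapply(cv, function(v) length(unique(v)) > 1, logical(1)),
             drop = FALSE]
    if (ncol(cv)) {
      Z <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
      k <- ncol(Z)
      Zr <- apply(Z, 2, rank_avg)
    } else {
      cv <- NULL
    }
  }
  n <- length(x)
  if (n < k + 3) stop("need at least ", k + 3, " complete cases", call. = FALSE)
  xr <- rank_avg(x)
  yr <- rank_avg(y)
  resid_on <- function(v, Zr) {
    if (is.null(Zr)) return(v - mean(v))
    stats::lsfit(Zr, v)$residuals
  }
  rx <- resid_on(xr, Zr)
  ry <- resid_on(yr, Zr)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    stop("zero variance after rank residualization", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  if (p_method == "t") {
    rho_c <- min(max(rho, -1 + 1e-15), 1 - 1e-15)
    tval <- rho_c * sqrt(df / (1 - rho_c^2))
    p <- 2 * stats::pt(-abs(tval), df)
  } else {
    obs <- abs(rho)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        ryp <- resid_on(yr[sample.int(n)], Zr)
        if (stats::sd(ryp) < 1e-12) return(0)
        abs(stats::cor(rx, ryp)) >= obs - 1e-12
      }, numeric(1)))
    })
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(list(partial_rho = rho, p_value = p, n_used = n, df = df,
                 covariates = if (is.null(cv)) character(0) else names(cv)),
            class = "partial_spearman")
}

#' @export
print.partial_spearman <- function(x, ...) {
  cat(sprintf("partial rho = %.3f, p = %.4g (n = %d%s)\n", x$partial_rho,
              x$p_value, x$n_used,
              if (length(x$covariates))
                paste0(", covarying for ", paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment within families
#'
#' Step-up false-discovery-rate adjusted p-values, computed separately within
#' each family of tests (e.g. all nodal tests for one behavioural outcome).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param family Optional grouping vector (same length); `NULL` treats all
#'   p-values as one family.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values, family = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(family)) return(stats::p.adjust(p_values, method = "BH"))
  stopifnot(length(family) == length(p_values))
  out <- p_values
  for (f in unique(family)) {
    sel <- family == f
    out[sel] <- stats::p.adjust(p_values[sel], method = "BH")
  }
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value; suited to comparing an
#' outcome across groups of uneven size.
#'
#' @param scores Numeric vector.
#' @param group_labels Grouping vector (same length, >= 2 distinct groups).
#' @return List with `H`, `df`, `p_value`, `n_used`.
#' @export
kruskal_wallis <- function(scores, group_labels) {
  ok <- !is.na(scores) & !is.na(group_labels)
  scores <- scores[ok]
  group_labels <- factor(group_labels[ok])
  if (nlevels(group_labels) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(scores)) == 1) {
    # all observations tied: no rank variation, H is 0 by definition
    return(list(H = 0, df = nlevels(group_labels) - 1L, p_value = 1,
                n_used = length(scores)))
  }
  kt <- stats::kruskal.test(scores, group_labels)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n_used = length(scores))
}

#' Band CBCL T-scores
#'
#' Categorizes T-scores (test mean 50, SD 10) into `normal` (T < 60),
#' `borderline` (60 <= T <= 63) and `clinical` (T > 63).
#'
#' @param t Numeric vector of T-scores.
#' @return Character vector of bands.
#' @export
band_tscore <- function(t) {
  ifelse(t < 60, "normal", ifelse(t <= 63, "borderline", "clinical"))
}

#' Band counts and percentages
#'
#' @param bands Character vector of bands (from [band_tscore()]).
#' @return data.frame with `band`, `n`, `pct` (percentage of all subjects,
#'   rounded to the nearest whole percent).
#' @export
band_summary <- function(bands) {
  lv <- c("normal", "borderline", "clinical")
  n <- vapply(lv, function(b) sum(bands == b), integer(1))
  data.frame(band = lv, n = n, pct = round(100 * n / length(bands)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of subjects in the borderline or clinical bands
#'
#' @param ... One or more band vectors (one per scale, same subjects in the
#'   same order); a subject counts once if borderline or clinical on any
#'   scale.
#' @return Percentage (0-100), rounded to the nearest whole percent.
#' @export
percent_borderline_or_clinical <- function(...) {
  bands <- list(...)
  n <- length(bands[[1]])
  flagged <- Reduce(`|`, lapply(bands, function(b) b %in% c("borderline", "clinical")))
  round(100 * sum(flagged) / n)
}

#' Classify white matter injury severity
#'
#' Radiological grading by lesion count and size: `severe` for more than 10
#' foci; `moderate` for more than 3 (and at most 10) foci, or any focus larger
#' than 2 mm; `mild` for 1-3 foci all at most 2 mm; `normal` for no injury.
#'
#' @param foci_count Nonnegative integer vector of WMI focus counts.
#' @param max_focus_mm Largest focus diameter in mm (ignored when count is 0).
#' @return Character vector: `"normal"`, `"mild"`, `"moderate"` or `"severe"`.
#' @export
classify_wmi <- function(foci_count, max_focus_mm = 0) {
  stopifnot(all(foci_count >= 0), all(max_focus_mm >= 0))
  n <- max(length(foci_count), length(max_focus_mm))
  foci_count <- rep_len(foci_count, n)
  max_focus_mm <- rep_len(max_focus_mm, n)
  ifelse(foci_count == 0, "normal",
         ifelse(foci_count > 10, "severe",
                ifelse(foci_count > 3 | max_focus_mm > 2, "moderate", "mild")))
}

#' Overall brain injury rating
#'
#' Dichotomizes injury findings: `moderate_severe` when WMI is moderate or
#' severe, or a cerebellar haemorrhage exceeds 2 mm; otherwise `none_mild`
#' (which includes isolated intraventricular haemorrhage, cerebellar
#' haemorrhage up to 2 mm, and mild WMI).
#'
#' @param wmi_class Character vector from [classify_wmi()].
#' @param cerebellar_hemorrhage_mm Largest cerebellar haemorrhage in mm.
#' @param ivh_present Logical; intraventricular haemorrhage (does not escalate
#'   the rating by itself).
#' @return Character vector: `"none_mild"` or `"moderate_severe"`.
#' @export
overall_injury <- function(wmi_class, cerebellar_hemorrhage_mm = 0,
                           ivh_present = FALSE) {
  n <- max(length(wmi_class), length(cerebellar_hemorrhage_mm),
           length(ivh_present))
  wmi_class <- rep_len(wmi_class, n)
  cerebellar_hemorrhage_mm <- rep_len(cerebellar_hemorrhage_mm, n)
  ifelse(wmi_class %in% c("moderate", "severe") | cerebellar_hemorrhage_mm > 2,
         "moderate_severe", "none_mild")
}
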