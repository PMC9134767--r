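# Count indices, group summaries, and the statistical test battery.

#' Count-based index (e.g. mitotic index)
#'
#' `100 * positive / total`, e.g. the percentage of cells positive for a
#' mitosis-specific histone mark among all cells of a type.
#'
#' @param positive Number of positive cells.
#' @param total Total number of cells, > 0.
#' @return An object of class `count_index` with `positive`, `total`,
#'   `percent` (also rendered to 2 decimals by its print method).
#' @export
mitotic_index <- function(positive, total) {
  if (total <= 0) stop("total count must be > 0")
  if (positive < 0 || positive > total)
    stop("positive count must lie in [0, total]")
  structure(list(positive = positive, total = total,
                 percent = 100 * positive / total),
            class = "count_index")
}

#' @export
print.count_index <- function(x, ...) {
  cat(sprintf("%d / %d = %.2f%%\n", x$positive, x$total, x$percent))
  invisible(x)
}

#' Group summary: n, mean, SE
#'
#' The reporting convention for all measures: average plus/minus the standard
#' error, SE = sample (n-1) standard deviation / sqrt(n). At n = 1 the SE is
#' undefined and flagged.
#'
#' @param values Numeric vector, length >= 1.
#' @param measure,group Optional labels.
#' @return A list with `n`, `mean`, `se`, `measure`, `group`.
#' @export
summarize_group <- function(values, measure = NA_character_, group = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("cannot summarize an empty group")
  se <- if (n == 1L) NA_real_ else stats::sd(values) / sqrt(n)
  list(n = n, mean = mean(values), se = se, measure = measure, group = group,
       note = if (n == 1L) "SE undefined at n = 1" else NA_character_)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided. The reported U is the minimum of the two one-sided statistics.
#' With no ties and min(n) <= `exact_max` the p-value is exact (from the
#' null distribution of U); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_max Largest min(n) for which the exact branch is used
#'   (default 8).
#' @return A list with `U`, `p_value`, `method` ("exact" or "normal").
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0L || n_b == 0L) stop("both groups must be non-empty")
  combined <- c(a, b)
  r <- rank(combined) # average ranks on ties
  U_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  U_b <- n_a * n_b - U_a
  U <- min(U_a, U_b)
  ties <- any(duplicated(combined))
  if (!ties && min(n_a, n_b) <= exact_max) {
    # exact two-sided p from the symmetric null distribution of U
    p <- min(1, 2 * stats::pwilcox(U, n_a, n_b))
    return(list(U = U, p_value = p, method = "exact"))
  }
  N <- n_a + n_b
  mu <- n_a * n_b / 2
  tie_tab <- table(combined)
  sigma2 <- (n_a * n_b / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z_num <- U_a - mu
  correction <- sign(z_num) * 0.5 # continuity correction, two-sided
  z <- (z_num - correction) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal")
}

#' One-sample t test
#'
#' `t = (mean - null_value) / SE` with n - 1 degrees of freedom, two-sided,
#' used e.g. against the symmetric null log2 = 0.
#'
#' @param values Numeric vector, n >= 2, non-zero standard deviation.
#' @param null_value Null hypothesis mean.
#' @return A list with `t`, `df`, `p_value`, `mean`, `se`.
#' @export
one_sample_t <- function(values, null_value = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("one-sample t test requires n >= 2")
  s <- stats::sd(values)
  if (s == 0) stop("one-sample t test undefined for zero standard deviation")
  se <- s / sqrt(n)
  t <- (mean(values) - null_value) / se
  list(t = t, df = n - 1L, p_value = 2 * stats::pt(-abs(t), df = n - 1L),
       mean = mean(values), se = se)
}

#' Significance marker at conventional display levels
#'
#' Annotation only; no multiple-testing correction is applied.
#'
#' @param p A p-value.
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"n.s."`.
#' @export
significance_marker <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 1e-2) "**" else if (p < 0.05) "*" else "n.s."
}

#' Build a combined analysis report
#'
#' Joins measurement tables, computes group summaries per (measure, channel,
#' cell type), classifies ratios against a control group where configured,
#' and runs group comparisons. Deterministic ordering throughout.
#'
#' @param tables A list of [measurement_table()] objects (or data.frames with
#'   the same columns).
#' @param config A list with optional entries:
#'   `summaries`: character vector of measure names to summarize (default all);
#'   `classify`: list(measure=, control_group=, test_group=) using `cell_type`
#'   as the group column;
#'   `comparisons`: list of list(measure=, group_a=, group_b=) Mann-Whitney
#'   comparisons between cell types.
#' @return A list of class `analysis_report`: `measurements` (joined rows),
#'   `summaries`, `classifications`, `tests`, `qc`.
#' @export
build_report <- function(tables, config = list()) {
  if (length(tables) == 0L) stop("at least one measurement table is required")
  rows <- do.call(rbind, lapply(tables, as.data.frame))
  needed <- c("pair_id", "cell_type", "stage", "measure", "channel", "value", "units")
  if (!all(needed %in% names(rows)))
    stop("measurement tables must carry columns: ", paste(needed, collapse = ", "))
  rows <- rows[order(rows$measure, rows$cell_type, rows$pair_id, rows$channel), ,
               drop = FALSE]
  rownames(rows) <- NULL
  qc <- list(n_rows = nrow(rows), n_missing = sum(is.na(rows$value)))

  measures <- config$summaries
  if (is.null(measures)) measures <- sort(unique(rows$measure))
  summaries <- list()
  for (ms in measures) {
    for (ct in sort(unique(rows$cell_type[rows$measure == ms]))) {
      v <- rows$value[rows$measure == ms & rows$cell_type == ct]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      s <- summarize_group(v, measure = ms, group = ct)
      summaries[[length(summaries) + 1L]] <- data.frame(
        measure = ms, group = ct, n = s$n, mean = s$mean, se = s$se,
        stringsAsFactors = FALSE)
    }
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(measure = character(), group = character(), n = integer(),
               mean = numeric(), se = numeric())

  classifications <- NULL
  if (!is.null(config$classify)) {
    cz <- config$classify
    ctrl <- rows$value[rows$measure == cz$measure & rows$cell_type == cz$control_group]
    ctrl <- ctrl[!is.na(ctrl)]
    test_rows <- rows[rows$measure == cz$measure & rows$cell_type == cz$test_group, ]
    calls <- vapply(test_rows$value, function(v)
      classify_asymmetry(v, control_ratios = ctrl)$call, character(1))
    thr <- classify_asymmetry(1, control_ratios = ctrl)$threshold
    classifications <- data.frame(pair_id = test_rows$pair_id,
                                  measure = cz$measure, value = test_rows$value,
                                  threshold = thr, call = calls,
                                  stringsAsFactors = FALSE)
  }

  tests <- list()
  for (cmp in config$comparisons) {
    va <- rows$value[rows$measure == cmp$measure & rows$cell_type == cmp$group_a]
    vb <- rows$value[rows$measure == cmp$measure & rows$cell_type == cmp$group_b]
    mw <- mann_whitney(va[!is.na(va)], vb[!is.na(vb)])
    tests[[length(tests) + 1L]] <- data.frame(
      measure = cmp$measure, group_a = cmp$group_a, group_b = cmp$group_b,
      test = "mann_whitney", statistic = mw$U, p_value = mw$p_value,
      marker = significance_marker(mw$p_value), stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(measure = character(), group_a = character(),
               group_b = character(), test = character(),
               statistic = numeric(), p_value = numeric(), marker = character())

  structure(list(measurements = rows, summaries = summaries,
                 classifications = classifications, tests = tests, qc = qc),
            class = "analysis_report")
}

#' Write an analysis report to a directory
#'
#' Emits `measurements.csv`, `summaries.csv`, `tests.csv`,
#' `classifications.csv` (when present) and `summary.json`. Byte-identical
#' across re-runs on the same inputs.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(dir, "tests.csv"), row.names = FALSE)
  if (!is.null(report$classifications))
    utils::write.csv(report$classifications,
                     file.path(dir, "classifications.csv"), row.names = FALSE)
  jsonlite::write_json(list(qc = report$qc,
                            summaries = report$summaries,
                            tests = report$tests),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
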