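#' Box-plot descriptors
#'
#' Median, quartiles (type-7 linear-interpolation quantiles), IQR,
#' whiskers extending to the most extreme data points within
#' 1.5 x IQR of the quartiles, and outliers beyond.
#'
#' @param x Numeric sample (n >= 1).
#' @return An object of class `box_stats`: `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
box_stats <- function(x) {
  if (length(x) == 0) stop("empty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_low = min(x[inside]), whisker_high = max(x[inside]),
         outliers = x[!inside]),
    class = "box_stats"
  )
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf(
    "median %.3g [Q1 %.3g, Q3 %.3g], whiskers [%.3g, %.3g], %d outlier(s)\n",
    x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
    length(x$outliers)))
  invisible(x)
}

#' Summary statistics of a sample
#'
#' @param x Numeric sample (n >= 1; sd defined for n >= 2).
#' @return List with `n`, `mean`, `sd` (n-1 estimator), `sem`, and `box`
#'   (a [box_stats()]).
#' @export
summarize_sample <- function(x) {
  if (length(x) == 0) stop("empty sample")
  s <- if (length(x) >= 2) stats::sd(x) else NA_real_
  list(n = length(x), mean = mean(x), sd = s,
       sem = s / sqrt(length(x)), box = box_stats(x))
}

#' Two-group comparison
#'
#' Two-sided group comparisons in the conventions used for
#' single-molecule force statistics: Welch two-tailed t-test, Wilcoxon
#' rank-sum with midranks for ties, or Wilcoxon matched-pairs signed-rank
#' (paired, equal n). No multiple-testing correction is applied; every
#' p-value is reported unadjusted.
#'
#' @param a,b Numeric samples (each n >= 3; paired method requires equal
#'   length).
#' @param method One of `"two_tailed_t"`, `"wilcoxon_rank_sum"`,
#'   `"wilcoxon_signed_rank"`.
#' @return An object of class `comparison_result`: `method`, `statistic`,
#'   `p_value` (unadjusted), `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b,
                           method = c("two_tailed_t", "wilcoxon_rank_sum",
                                      "wilcoxon_signed_rank")) {
  method <- match.arg(method)
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations")
  if (method == "wilcoxon_signed_rank" && length(a) != length(b))
    stop("paired comparison requires equal group sizes")
  res <- switch(method,
    two_tailed_t = stats::t.test(a, b, alternative = "two.sided"),
    wilcoxon_rank_sum = stats::wilcox.test(a, b,
                                           alternative = "two.sided",
                                           exact = FALSE, correct = TRUE),
    wilcoxon_signed_rank = stats::wilcox.test(a, b, paired = TRUE,
                                              alternative = "two.sided"))
  structure(
    list(method = method, statistic = unname(res$statistic),
         p_value = res$p.value, n_a = length(a), n_b = length(b)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.3g (unadjusted), n = %d vs %d\n",
              x$method, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Seeded percentile bootstrap confidence interval
#'
#' @param statistic Function of a sample returning a scalar.
#' @param x Numeric sample.
#' @param B Number of resamples (>= 200).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)`; a degenerate (constant) sample yields a
#'   zero-width interval with attribute `degenerate = TRUE`.
#' @export
bootstrap_ci <- function(statistic, x, B = 2000, level = 0.95, seed = 1) {
  if (B < 200) stop("B must be at least 200")
  if (length(unique(x)) == 1L) {
    v <- statistic(x)
    out <- c(v, v)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  set.seed(seed)
  n <- length(x)
  stat <- vapply(seq_len(B),
                 function(b) statistic(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  alpha <- (1 - level) / 2
  out <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
  attr(out, "degenerate") <- FALSE
  out
}

summary_block <- function(forces) {
  if (length(forces) == 0)
    return(list(n = 0L, mean = NULL, sd = NULL, sem = NULL, box = NULL))
  s <- summarize_sample(forces)
  list(n = s$n, mean = s$mean, sd = s$sd, sem = s$sem,
       box = s$box[c("median", "q1", "q3", "iqr",
                     "whisker_low", "whisker_high")])
}

#' Build a machine-readable analysis report
#'
#' Collects per-condition rupture-force summaries (both pooling modes),
#' maintenance proportions, deposition efficiencies and group
#' comparisons into a single JSON-serializable document with a versioned
#' schema, the effective configuration and seeds. Missing sections are
#' explicit nulls, never silently omitted.
#'
#' @param analyses Named list of `mt_analysis` objects (one per
#'   condition).
#' @param comparisons Optional named list of [compare_groups()] results.
#' @param depositions Optional named list of [deposition_efficiency()]
#'   results.
#' @param seed Seed echoed into the report.
#' @return A list of class `mt_report` (serialize with
#'   [write_report()]).
#' @export
build_report <- function(analyses = list(), comparisons = NULL,
                         depositions = NULL, seed = NULL) {
  conditions <- lapply(analyses, function(an) {
    tabs <- lapply(c(all_cycles = "all_cycles", first_cycle = "first_cycle"),
                   function(p) {
      ft <- rupture_force_table(an, pooling = p)
      lapply(ft, summary_block)
    })
    maint <- tryCatch(maintenance_proportion(an),
                      error = function(e) NULL)
    list(preset = an$meta$preset,
         n_molecules = nrow(an$molecules),
         n_events = nrow(an$events),
         rupture_forces = tabs,
         maintenance = maint,
         config = an$config)
  })
  structure(
    list(schema_version = "1.0",
         package_version = as.character(utils::packageVersion("nucpull")),
         seed = seed,
         conditions = conditions,
         comparisons = if (is.null(comparisons)) NULL else
           lapply(comparisons, unclass),
         depositions = depositions),
    class = "mt_report"
  )
}

#' Write a report to JSON
#'
#' Deterministic serialization (fixed precision handling via
#' `digits = NA`), so identical analyses produce byte-identical files.
#'
#' @param report An `mt_report` (or any list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a report from JSON
#'
#' @param path Path written by [write_report()].
#' @return The report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
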