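# The small statistical layer applied to every group comparison: unpaired
# t-tests, one-way ANOVA, and mean-with-SEM summaries.

#' Unpaired two-sample t-test
#'
#' Two-sided unpaired t-test between two groups of measurements. The default
#' is Student's pooled-variance variant; Welch's unequal-variance form is
#' available via `variant = "welch"`. Thin wrapper around [stats::t.test()]
#' that also reports group means and SEMs.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list of class `group_test` with `statistic`,
#'   `degrees_of_freedom`, `p_value`, `group_means`, `group_sems`, `method`.
#' @export
unpaired_t_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both groups have zero variance; t-test undefined", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  structure(
    list(statistic = unname(ht$statistic),
         degrees_of_freedom = unname(ht$parameter),
         p_value = ht$p.value,
         group_means = c(mean(a), mean(b)),
         group_sems = c(mean_sem(a)$sem, mean_sem(b)$sem),
         method = sprintf("unpaired t-test (%s)", variant)),
    class = "group_test"
  )
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA (equal-variance F test) across two or more groups,
#' via [stats::oneway.test()] with `var.equal = TRUE`. With exactly two
#' groups the F statistic equals the square of the Student t statistic.
#'
#' @param groups A list of numeric vectors (one per group), each with at
#'   least 2 values; names are used as group labels.
#' @return A list of class `group_test` with the F `statistic`,
#'   `degrees_of_freedom` `c(k - 1, N - k)`, `p_value`, `group_means` and
#'   `group_sems`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop("each group needs at least 2 values", call. = FALSE)
  labels <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labels
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, sizes), levels = labels)
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(
    list(statistic = unname(ht$statistic),
         degrees_of_freedom = unname(ht$parameter),
         p_value = ht$p.value,
         group_means = vapply(groups, mean, 0),
         group_sems = vapply(groups, function(x) mean_sem(x)$sem, 0),
         method = "one-way ANOVA"),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s\n", x$method))
  cat(sprintf("  statistic %.4g, df %s, p = %.4g\n", x$statistic,
              paste(signif(x$degrees_of_freedom, 6), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Mean and standard error of the mean
#'
#' The "bars = mean with SEM" summary used in every figure-style comparison.
#' SEM is the sample standard deviation (n - 1 denominator) over the square
#' root of n, and is `NA` for a single observation.
#'
#' @param x Numeric vector with at least one value.
#' @return A list with `mean`, `sem` and `n`.
#' @export
mean_sem <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L)
    stop("empty sample", call. = FALSE)
  list(mean = mean(x),
       sem = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}
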