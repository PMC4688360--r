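#' Two-group comparison of a per-animal metric
#'
#' Two-sided Mann-Whitney rank-sum test (exact when both groups are small
#' and tie-free, normal approximation with tie/continuity correction
#' otherwise) or independent t-test (Welch by default; classic pooled
#' variance on request). Group summaries are reported as mean +/- SEM.
#'
#' @param a,b numeric metric vectors for the two groups (each n >= 2).
#' @param test `"mann_whitney"` (default) or `"t_test"`.
#' @param metric_name label carried into the result.
#' @param var_equal for the t-test: pooled variance (`TRUE`) or Welch
#'   (`FALSE`, default).
#' @param group_names length-2 character vector.
#' @return An object of class `group_comparison`: `metric_name`,
#'   `test_name`, `statistic`, `p_value`, and `group_summaries` (a
#'   data.frame with group, n, mean, sem).
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "t_test"),
                           metric_name = "metric", var_equal = FALSE,
                           group_names = c("A", "B")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (anyNA(a) || anyNA(b)) stop("metric values contain NA")
  if (test == "mann_whitney") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                              correct = TRUE))
    test_name <- "mann_whitney"
  } else {
    ht <- stats::t.test(a, b, alternative = "two.sided",
                        var.equal = var_equal)
    test_name <- if (var_equal) "t_test_pooled" else "t_test_welch"
  }
  summaries <- data.frame(
    group = group_names,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    sem = c(stats::sd(a) / sqrt(length(a)),
            stats::sd(b) / sqrt(length(b))),
    stringsAsFactors = FALSE)
  structure(list(metric_name = metric_name,
                 test_name = test_name,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_summaries = summaries),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  s <- x$group_summaries
  cat(sprintf("<group_comparison> %s [%s]: p = %.4g\n",
              x$metric_name, x$test_name, x$p_value))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n",
                s$group[i], s$mean[i], s$sem[i], s$n[i]))
  }
  invisible(x)
}

#' Frame-wise (bin-wise) group comparison of response traces
#'
#' Runs a two-sided Mann-Whitney test across animals at every time bin
#' and flags the bins significant at `alpha`. By default no multiplicity
#' correction is applied — matching the common practice of shading
#' per-frame significance — with Benjamini-Hochberg available as an
#' option.
#'
#' @param traces_a,traces_b numeric matrices `[animal x bin]` with the
#'   same bin structure.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `framewise_result`: `p_values` (per bin),
#'   `significant_bins` (integer indices), `alpha`, `adjust`.
#' @export
framewise_compare <- function(traces_a, traces_b, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(traces_a), is.matrix(traces_b))
  if (ncol(traces_a) != ncol(traces_b)) {
    stop("trace bin structures differ between groups")
  }
  if (nrow(traces_a) < 2L || nrow(traces_b) < 2L) {
    stop("each group needs n >= 2 animals")
  }
  p <- vapply(seq_len(ncol(traces_a)), function(j) {
    suppressWarnings(
      stats::wilcox.test(traces_a[, j], traces_b[, j])$p.value)
  }, numeric(1))
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  structure(list(p_values = p,
                 p_adjusted = p_adj,
                 significant_bins = which(p_adj < alpha),
                 alpha = alpha, adjust = adjust),
            class = "framewise_result")
}

#' @export
print.framewise_result <- function(x, ...) {
  cat(sprintf(
    "<framewise_result> %d / %d bins significant at alpha = %g (%s)\n",
    length(x$significant_bins), length(x$p_values), x$alpha, x$adjust))
  invisible(x)
}

#' One-way ANOVA with Fisher LSD post-hoc comparisons
#'
#' Classic one-way analysis of variance across three or more groups,
#' followed by Fisher's least-significant-difference pairwise tests:
#' t statistics built from the pooled ANOVA mean-square error with
#' `N - k` degrees of freedom, unadjusted two-sided p-values.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each
#'   n >= 2).
#' @return An object of class `anova_lsd`: `f_statistic`, `p_value`,
#'   `df`, `mse`, and `pairwise` (data.frame: group1, group2, mean_diff,
#'   t, p_value).
#' @export
anova_lsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("each group needs n >= 2")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), n), levels = names(groups))
  fit <- stats::aov(value ~ grp)
  tab <- summary(fit)[[1L]]
  mse <- tab["Residuals", "Mean Sq"]
  df_resid <- tab["Residuals", "Df"]
  means <- vapply(groups, mean, numeric(1))
  combs <- utils::combn(names(groups), 2L)
  pw <- data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
                   stringsAsFactors = FALSE)
  pw$mean_diff <- means[pw$group1] - means[pw$group2]
  se <- sqrt(mse * (1 / n[pw$group1] + 1 / n[pw$group2]))
  pw$t <- pw$mean_diff / se
  pw$p_value <- 2 * stats::pt(-abs(pw$t), df_resid)
  rownames(pw) <- NULL
  structure(list(f_statistic = tab["grp", "F value"],
                 p_value = tab["grp", "Pr(>F)"],
                 df = c(tab["grp", "Df"], df_resid),
                 mse = mse,
                 group_means = means,
                 pairwise = pw),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("<anova_lsd> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  print(x$pairwise, digits = 4)
  invisible(x)
}
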