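# Descriptive and inferential statistics for cohort comparisons: the
# five-number boxplot summary, Welch's unpaired t test, one-way ANOVA with
# Tukey's HSD, and Pearson correlation. Thin, validated wrappers around the
# stats package with a uniform result shape.

new_test_result <- function(statistic, df, p_value, method, group_labels) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 group_labels = group_labels),
            class = "plgg_test_result")
}

#' @export
print.plgg_test_result <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", df = ", paste(format(x$df), collapse = ", "),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Five-number summary
#'
#' Minimum, first quartile, median, third quartile and maximum — the five
#' values a boxplot displays. Quartiles use linear interpolation between
#' order statistics (R's default quantile type 7), fixed here for
#' reproducibility.
#'
#' @param values Nonempty numeric vector.
#' @return List of class `"five_number_summary"` with fields `minimum`,
#'   `q1`, `median`, `q3`, `maximum`.
#' @export
#' @examples
#' five_number_summary(c(1, 2, 3, 4))  # q1 = 1.75, median = 2.5, q3 = 3.25
five_number_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("cannot summarize an empty vector", class = "plgg_empty_error")
  }
  q <- unname(quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(list(minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 maximum = q[5]),
            class = "five_number_summary")
}

#' @export
print.five_number_summary <- function(x, ...) {
  cat(sprintf("min %.4g | q1 %.4g | median %.4g | q3 %.4g | max %.4g\n",
              x$minimum, x$q1, x$median, x$q3, x$maximum))
  invisible(x)
}

check_group <- function(g, label) {
  g <- g[!is.na(g)]
  if (length(g) < 2) {
    abort(paste0("group ", label, " needs at least 2 values"),
          class = "plgg_validation_error")
  }
  g
}

#' Unpaired two-sample t test
#'
#' Welch's unequal-variance variant with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value (the stats package default for an
#' unpaired comparison).
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values and
#'   not both of zero variance.
#' @return A test result: `statistic` (t), `df`, `p_value`, `method`,
#'   `group_labels`.
#' @export
unpaired_t_test <- function(group_a, group_b) {
  a <- check_group(group_a, "a")
  b <- check_group(group_b, "b")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_test_result(0, length(a) + length(b) - 2, 1,
                             "Welch two-sample t test", c("a", "b")))
    }
    abort("both groups have zero variance", class = "plgg_validation_error")
  }
  res <- stats::t.test(a, b, var.equal = FALSE)
  new_test_result(res$statistic, res$parameter, res$p.value,
                  "Welch two-sample t test", c("a", "b"))
}

as_group_frame <- function(groups) {
  if (length(groups) < 2) {
    abort("need at least 2 groups", class = "plgg_validation_error")
  }
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  labels[labels == ""] <- paste0("g", which(labels == ""))
  groups <- lapply(seq_along(groups), function(i)
    check_group(groups[[i]], labels[i]))
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(labels, lengths(groups)), levels = labels)
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F with (k - 1, N - k) degrees of
#' freedom and p from the F distribution. Identical groups give F = 0,
#' p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @return A test result with `df = c(df_between, df_within)`.
#' @export
one_way_anova <- function(groups) {
  dat <- as_group_frame(groups)
  if (var(dat$value) == 0) {
    k <- nlevels(dat$group)
    return(new_test_result(0, c(k - 1, nrow(dat) - k), 1,
                           "One-way ANOVA", levels(dat$group)))
  }
  fit <- stats::aov(value ~ group, data = dat)
  tab <- summary(fit)[[1]]
  new_test_result(tab[1, "F value"], c(tab[1, "Df"], tab[2, "Df"]),
                  tab[1, "Pr(>F)"], "One-way ANOVA", levels(dat$group))
}

#' Tukey's Honest Significant Difference test
#'
#' All pairwise mean differences after a one-way ANOVA, with familywise
#' adjusted p values from the studentized-range distribution.
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level for the pairwise intervals.
#' @return Tibble: `comparison, diff, ci_low, ci_high, p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  dat <- as_group_frame(groups)
  if (var(dat$value) == 0) {
    labels <- levels(dat$group)
    pairs <- utils::combn(labels, 2)
    return(tibble(
      comparison = paste(pairs[2, ], pairs[1, ], sep = "-"),
      diff = 0, ci_low = 0, ci_high = 0, p_adj = 1
    ))
  }
  fit <- stats::aov(value ~ group, data = dat)
  tab <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  tibble(comparison = rownames(tab), diff = unname(tab[, "diff"]),
         ci_low = unname(tab[, "lwr"]), ci_high = unname(tab[, "upr"]),
         p_adj = unname(tab[, "p adj"]))
}

#' Pearson correlation with a two-sided test
#'
#' `r` with its t-transform p value on `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return A test result whose `statistic` is `r`; `df = n - 2`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "plgg_validation_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("need at least 3 paired values", class = "plgg_validation_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("zero variance in x or y", class = "plgg_validation_error")
  }
  res <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  new_test_result(unname(res$estimate), res$parameter, res$p.value,
                  "Pearson correlation", c("x", "y"))
}
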