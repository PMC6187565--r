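# Cohort summaries and one-way ANOVA for bilateral symmetry assessment.

.anova_table <- function(ss_columns, df_columns, ss_error, df_error) {
  ms_columns <- ss_columns / df_columns
  ms_error <- ss_error / df_error
  f <- ms_columns / ms_error
  structure(list(ss_columns = ss_columns, ss_error = ss_error,
                 ss_total = ss_columns + ss_error,
                 df_columns = as.integer(df_columns),
                 df_error = as.integer(df_error),
                 df_total = as.integer(df_columns + df_error),
                 ms_columns = ms_columns, ms_error = ms_error,
                 f = f,
                 p = stats::pf(f, df_columns, df_error, lower.tail = FALSE)),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Source     SS        df   MS        F       p\n")
  cat(sprintf("Columns  %9.4g %4d %9.4g %7.3g %9.4g\n",
              x$ss_columns, x$df_columns, x$ms_columns, x$f, x$p))
  cat(sprintf("Error    %9.4g %4d %9.4g\n", x$ss_error, x$df_error,
              x$ms_error))
  cat(sprintf("Total    %9.4g %4d\n", x$ss_total, x$df_total))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Standard decomposition: between-group ("Columns") sum of squares
#' `sum n_i (mean_i - grand)^2` on `k - 1` degrees of freedom, within-group
#' ("Error") sum of squares on `N - k`, `F = MS_columns / MS_error`, p from
#' the upper tail of the F distribution.
#'
#' @param groups list of numeric vectors, one per group; at least 2 groups,
#'   each non-empty, with at least one residual degree of freedom.
#' @return an `anova_table` object (fields `ss_*`, `df_*`, `ms_*`, `f`, `p`).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("at least two groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stopf("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(x))) stopf("observations must be finite")
  if (sum(sizes) - length(groups) < 1L)
    stopf("no residual degrees of freedom")
  if (stats::var(x) == 0)
    stopf("all observations identical: F statistic undefined")
  grand <- mean(x)
  means <- vapply(groups, mean, numeric(1L))
  ss_columns <- sum(sizes * (means - grand)^2)
  ss_error <- sum(vapply(seq_along(groups),
                         function(i) sum((groups[[i]] - means[i])^2),
                         numeric(1L)))
  .anova_table(ss_columns, length(groups) - 1L, ss_error,
               sum(sizes) - length(groups))
}

#' ANOVA table from printed sums of squares
#'
#' Deterministically fills mean squares, totals, the F statistic and its
#' p-value from `(SS, df)` pairs — the verification path for published ANOVA
#' tables.
#'
#' @param ss_columns,df_columns between-group sum of squares and df.
#' @param ss_error,df_error within-group sum of squares and df.
#' @return an `anova_table` object.
#' @export
anova_from_ss <- function(ss_columns, df_columns, ss_error, df_error) {
  if (df_columns < 1L || df_error < 1L) stopf("degrees of freedom must be >= 1")
  if (ss_columns < 0 || ss_error <= 0) stopf("invalid sums of squares")
  .anova_table(ss_columns, df_columns, ss_error, df_error)
}

#' Cohort summary of gait parameters
#'
#' Mean and sample SD of each gait parameter across subjects (each subject
#' contributing their per-subject mean).
#'
#' @param subjects list of [compute_gait_parameters()] results (or data
#'   frames shaped like their `summary` element).
#' @return data frame with `parameter`, `mean`, `sd` across subjects.
#' @export
summarize_cohort <- function(subjects) {
  if (length(subjects) < 1L) stopf("at least one subject is required")
  tabs <- lapply(subjects, function(s) {
    if (inherits(s, "gait_parameters")) s$summary else s
  })
  params <- tabs[[1L]]$parameter
  vals <- vapply(tabs, function(tb) {
    tb$mean[match(params, tb$parameter)]
  }, numeric(length(params)))
  vals <- matrix(vals, nrow = length(params))
  data.frame(parameter = params,
             mean = rowMeans(vals),
             sd = if (ncol(vals) > 1L) apply(vals, 1L, stats::sd) else
               rep(0, length(params)))
}

#' Write an ANOVA table as delimited text
#'
#' Column order mirrors the conventional report layout: Source, SS, df, MS,
#' F, p.
#'
#' @param x an `anova_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anova_table <- function(x, path) {
  df <- data.frame(
    Source = c("Columns", "Error", "Total"),
    SS = c(x$ss_columns, x$ss_error, x$ss_total),
    df = c(x$df_columns, x$df_error, x$df_total),
    MS = c(x$ms_columns, x$ms_error, NA),
    F = c(x$f, NA, NA),
    p = c(x$p, NA, NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
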