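#' Paracellular permeability index
#'
#' Fold change of tracer fluorescence in the lower transwell chamber over a
#' reference (basal) measurement: `lower / reference`.
#'
#' @param lower Lower-chamber fluorescence (AU).
#' @param reference Reference (basal) fluorescence (AU, > 0); scalar or
#'   vector recycled against `lower`.
#' @return Dimensionless fold change.
#' @examples
#' permeability_index(150, 100)  # 1.5
#' @export
permeability_index <- function(lower, reference) {
  if (!is.numeric(lower) || !is.numeric(reference))
    stop_data("inputs must be numeric")
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop_data("reference fluorescence must be positive")
  lower / reference
}

#' Fold-over-basal permeability per condition
#'
#' Maps a condition table of lower-chamber readings to fold change over the
#' mean of the basal condition.
#'
#' @param values Lower-chamber fluorescence per replicate (AU).
#' @param condition Condition label per replicate.
#' @param basal Label of the basal (reference) condition.
#' @return Data frame `condition`, `value`, `fold_over_basal`.
#' @export
permeability_fold_table <- function(values, condition, basal) {
  if (length(values) != length(condition))
    stop_data("values and condition must have equal length")
  if (!basal %in% condition)
    stop_data(sprintf("basal condition '%s' not present", basal))
  ref <- mean(values[condition == basal])
  data.frame(condition = as.character(condition), value = values,
             fold_over_basal = permeability_index(values, ref),
             stringsAsFactors = FALSE)
}

#' Replicate summaries per group
#'
#' Mean, sample standard deviation (n - 1 denominator), standard error of
#' the mean (`sd / sqrt(n)`) and replicate count per group. Groups with a
#' single replicate report `NA` for sd and SEM.
#'
#' @param values Numeric replicate values.
#' @param group Group label per value.
#' @return Data frame `group`, `n`, `mean`, `sd`, `sem`.
#' @examples
#' summarize_groups(c(1, 2, 3), rep("a", 3))  # mean 2, sd 1, sem 1/sqrt(3)
#' @export
summarize_groups <- function(values, group) {
  if (length(values) == 0L) stop_data("no values supplied")
  if (length(group) != length(values))
    stop_data("values and group must have equal length")
  f <- factor(group, levels = unique(group))
  n <- as.integer(table(f))
  m <- as.numeric(tapply(values, f, mean))
  s <- as.numeric(tapply(values, f, function(v)
    if (length(v) > 1L) stats::sd(v) else NA_real_))
  data.frame(group = levels(f), n = n, mean = m, sd = s, sem = s / sqrt(n),
             stringsAsFactors = FALSE)
}

anova_table <- function(term, df, sumsq, resid_df, resid_ss) {
  meansq <- sumsq / df
  resid_ms <- resid_ss / resid_df
  f <- ifelse(sumsq == 0, 0, meansq / resid_ms)
  p <- ifelse(sumsq == 0, 1,
              stats::pf(f, df, resid_df, lower.tail = FALSE))
  structure(
    data.frame(
      term = c(term, "Residuals"),
      df = c(df, resid_df),
      sumsq = c(sumsq, resid_ss),
      meansq = c(meansq, resid_ms),
      statistic = c(f, NA_real_),
      p.value = c(p, NA_real_),
      stringsAsFactors = FALSE
    ),
    class = c("anova_result", "data.frame")
  )
}

#' One-way analysis of variance from sums of squares
#'
#' Between/within decomposition computed explicitly: `F = MSB / MSW` with
#' `(k - 1, N - k)` degrees of freedom and the p value from the upper tail
#' of the F distribution. Identical groups give `F = 0`, `p = 1`.
#'
#' @param values Numeric observations.
#' @param group Group label per observation; at least 2 groups, each with at
#'   least 2 observations.
#' @return An `anova_result` data frame (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`) with rows `group` and `Residuals`.
#' @examples
#' anova_one_way(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_one_way <- function(values, group) {
  if (length(values) != length(group))
    stop_data("values and group must have equal length")
  f <- factor(group)
  k <- nlevels(f)
  if (k < 2L) stop_data("at least 2 groups are required")
  n_g <- table(f)
  if (any(n_g < 2L)) stop_data("every group needs at least 2 observations")
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, f, mean)
  ssb <- sum(as.numeric(n_g) * (means - grand)^2)
  ssw <- sum((values - means[f])^2)
  anova_table("group", k - 1L, ssb, n - k, ssw)
}

#' Two-way analysis of variance for balanced designs
#'
#' Main effects, interaction and residual sums of squares via the balanced
#' two-factor decomposition over cell, marginal and grand means; F and p per
#' effect against the residual mean square. The components sum exactly to
#' the total sum of squares. Unbalanced tables are refused rather than
#' silently approximated (there is no unambiguous decomposition for them).
#'
#' @param data Long-format data frame.
#' @param value,factorA,factorB Column names of the response and the two
#'   factors (defaults `"value"`, `"factorA"`, `"factorB"`).
#' @return An `anova_result` data frame with rows for factor A, factor B,
#'   the interaction `A:B`, and `Residuals`.
#' @examples
#' d <- expand.grid(factorA = c("a1", "a2"), factorB = c("b1", "b2"),
#'                  rep = 1:2)
#' d$value <- c(1, 3, 5, 7, 2, 4, 6, 8)
#' anova_two_way(d)
#' @export
anova_two_way <- function(data, value = "value", factorA = "factorA",
                          factorB = "factorB") {
  if (!is.data.frame(data) ||
      !all(c(value, factorA, factorB) %in% names(data)))
    stop_data("`data` must contain the value and both factor columns")
  y <- data[[value]]
  fa <- factor(data[[factorA]])
  fb <- factor(data[[factorB]])
  a <- nlevels(fa); b <- nlevels(fb)
  if (a < 2L || b < 2L) stop_data("both factors need at least 2 levels")
  counts <- table(fa, fb)
  if (any(counts == 0L) || length(unique(as.vector(counts))) != 1L)
    stop_data("unbalanced design: two-way ANOVA here requires equal cell counts")
  n <- as.vector(counts)[1]
  if (n < 2L) stop_data("every cell needs at least 2 replicates")

  grand <- mean(y)
  mean_a <- tapply(y, fa, mean)
  mean_b <- tapply(y, fb, mean)
  mean_cell <- tapply(y, list(fa, fb), mean)

  ss_a <- n * b * sum((mean_a - grand)^2)
  ss_b <- n * a * sum((mean_b - grand)^2)
  ss_cells <- n * sum((mean_cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_ab <- max(ss_ab, 0)  # guard tiny negative rounding
  ss_resid <- sum((y - mean_cell[cbind(fa, fb)])^2)

  df_a <- a - 1L; df_b <- b - 1L; df_ab <- df_a * df_b
  df_resid <- length(y) - a * b
  anova_table(c(factorA, factorB, paste0(factorA, ":", factorB)),
              c(df_a, df_b, df_ab), c(ss_a, ss_b, ss_ab),
              df_resid, ss_resid)
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Analysis of variance (computed from sums of squares)\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}
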