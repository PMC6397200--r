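# Motor-neuron survival fractions over time and the group-comparison
# statistics used throughout: pooled-variance Student's t and one-way
# ANOVA with Fisher's LSD post hoc tests. All summaries are mean +/- SEM
# with the n - 1 sample SD.

#' Percent surviving motor neurons per explant and day
#'
#' Each explant's count at every observation day is divided by the count
#' first detected in that explant (its baseline day), times 100, so the
#' baseline maps to exactly 100.
#'
#' @param counts Count table with columns `explant_id`, `day`, `count`
#'   (plus optional `condition`).
#' @return The input with an added `percent_surviving` column, sorted by
#'   explant and day.
#' @export
percent_surviving <- function(counts) {
  required <- c("explant_id", "day", "count")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0L) {
    stop_schema(sprintf("count table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (any(counts$count < 0)) {
    stop_data("motor-neuron counts must be non-negative")
  }
  counts |>
    dplyr::arrange(.data$explant_id, .data$day) |>
    dplyr::group_by(.data$explant_id) |>
    dplyr::group_modify(function(df, key) {
      baseline <- df$count[1]
      if (baseline <= 0) {
        stop_data(sprintf("explant '%s' has a zero baseline count",
                          key$explant_id))
      }
      df$percent_surviving <- 100 * df$count / baseline
      df
    }) |>
    dplyr::ungroup()
}

#' Per-condition survival timecourse
#'
#' Mean and SEM of the per-explant survival percentage at each day,
#' grouped by condition.
#'
#' @param surv Output of [percent_surviving()] with a `condition` column.
#' @return A tibble with columns `condition`, `day`, `mean_percent`,
#'   `sem_percent`, `n_explants`.
#' @export
group_timecourse <- function(surv) {
  required <- c("explant_id", "day", "percent_surviving")
  missing <- setdiff(required, names(surv))
  if (length(missing) > 0L) {
    stop_schema(sprintf("survival table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (!"condition" %in% names(surv)) surv$condition <- "all"
  surv |>
    dplyr::group_by(.data$condition, .data$day) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent_surviving),
      sem_percent = sem0(.data$percent_surviving),
      n_explants = dplyr::n(),
      .groups = "drop"
    )
}

new_group_comparison <- function(method, groups, omnibus, pairwise) {
  structure(
    list(method = method, groups = groups, omnibus = omnibus,
         pairwise = pairwise),
    class = "group_comparison"
  )
}

group_summary_table <- function(values, labels) {
  tibble::tibble(
    group = labels,
    n = vapply(values, length, integer(1)),
    mean = vapply(values, mean, numeric(1)),
    sem = vapply(values, sem0, numeric(1))
  )
}

#' Two-sample Student's t test
#'
#' Classical pooled-variance two-sample t test (the default throughout
#' this package), with Welch's unequal-variance version behind a flag.
#'
#' @param data A data frame.
#' @param value Unquoted column of measurements.
#' @param group Unquoted column of group labels; exactly two groups, each
#'   with at least two observations.
#' @param two_sided Two-sided p value (default) or one-sided ("greater"
#'   for the first group)?
#' @param welch Use Welch's unequal-variance t test?
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
student_t <- function(data, value, group, two_sided = TRUE, welch = FALSE) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  labels <- unique(as.character(g))
  if (length(labels) != 2L) {
    stop_parameter(sprintf("`student_t()` needs exactly 2 groups (got %d)",
                           length(labels)))
  }
  values <- lapply(labels, function(l) v[g == l])
  if (any(vapply(values, length, integer(1)) < 2L)) {
    stop_parameter("each group needs at least 2 observations")
  }
  ht <- stats::t.test(values[[1]], values[[2]],
                      var.equal = !welch,
                      alternative = if (two_sided) "two.sided" else "greater")
  groups <- group_summary_table(values, labels)
  omnibus <- tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
  pairwise <- tibble::tibble(
    group_a = labels[1], group_b = labels[2],
    mean_diff = groups$mean[1] - groups$mean[2],
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
  new_group_comparison(if (welch) "welch_t" else "student_t",
                       groups, omnibus, pairwise)
}

#' One-way ANOVA with Fisher's LSD post hoc tests
#'
#' Omnibus one-way ANOVA followed by Fisher's least-significant-difference
#' pairwise comparisons: each pair is tested with a t statistic built on
#' the pooled ANOVA mean squared error with N - k degrees of freedom, and
#' the pairwise p values are left unadjusted (the LSD convention). By
#' default the post hoc tests are protected: pairwise p values are
#' withheld (set to `NA`) unless the omnibus F is significant at `alpha`.
#'
#' @inheritParams student_t
#' @param group Unquoted grouping column; at least two groups with at
#'   least two observations each.
#' @param gate_on_omnibus Protect the LSD tests behind a significant
#'   omnibus F? Default `TRUE`.
#' @param alpha Omnibus significance level for the gate (default 0.05).
#' @return A `group_comparison` object with `omnibus` (F test) and
#'   `pairwise` (LSD table) components.
#' @export
anova_fisher_lsd <- function(data, value, group, gate_on_omnibus = TRUE,
                             alpha = 0.05) {
  check_probability(alpha, "alpha")
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  labels <- unique(g)
  k <- length(labels)
  if (k < 2L) {
    stop_parameter("`anova_fisher_lsd()` needs at least 2 groups")
  }
  values <- lapply(labels, function(l) v[g == l])
  ns <- vapply(values, length, integer(1))
  if (any(ns < 2L)) {
    stop_parameter("each group needs at least 2 observations")
  }
  df_fit <- data.frame(v = v, g = factor(g, levels = labels))
  fit <- stats::aov(v ~ g, data = df_fit)
  tab <- stats::anova(fit)
  f_stat <- tab$`F value`[1]
  p_omni <- tab$`Pr(>F)`[1]
  mse <- tab$`Mean Sq`[2]
  df_resid <- tab$Df[2]
  omnibus <- tibble::tibble(
    statistic = f_stat, df1 = tab$Df[1], df2 = df_resid, p_value = p_omni
  )
  groups <- group_summary_table(values, labels)
  pairs <- utils::combn(seq_len(k), 2L)
  t_stat <- vapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    (groups$mean[i1] - groups$mean[i2]) /
      sqrt(mse * (1 / ns[i1] + 1 / ns[i2]))
  }, numeric(1))
  p_pair <- 2 * stats::pt(-abs(t_stat), df_resid)
  gated_out <- gate_on_omnibus && (is.na(p_omni) || p_omni >= alpha)
  pairwise <- tibble::tibble(
    group_a = labels[pairs[1, ]],
    group_b = labels[pairs[2, ]],
    mean_diff = groups$mean[pairs[1, ]] - groups$mean[pairs[2, ]],
    statistic = t_stat,
    df = df_resid,
    p_value = if (gated_out) NA_real_ else p_pair,
    p_unprotected = p_pair
  )
  new_group_comparison("anova_fisher_lsd", groups, omnibus, pairwise)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> method: ", x$method, "\n", sep = "")
  cat("groups (mean +/- SEM):\n")
  print(x$groups)
  cat("omnibus:\n")
  print(x$omnibus)
  if (x$method == "anova_fisher_lsd") {
    cat("pairwise (Fisher's LSD, unadjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Tidy a group comparison into pairwise rows
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$pairwise, method = x$method, .before = 1)
}

#' One-row summary of a group comparison (the omnibus test)
#'
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus statistic and p value.
#' @export
glance.group_comparison <- function(x, ...) {
  dplyr::mutate(x$omnibus, method = x$method, .before = 1)
}
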