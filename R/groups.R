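#' Welch two-sample t-test from summary statistics
#'
#' The unequal-variance (Welch) t statistic with Satterthwaite degrees
#' of freedom, computed directly from group means, standard deviations
#' and sizes — the form needed when only published summaries, not
#' specimen-level values, are available. A pooled-variance variant is
#' provided for sensitivity analysis.
#'
#' Degenerate input with both SDs zero is resolved by convention: equal
#' means give `t = 0, p = 1` (no evidence of any difference); unequal
#' means are an error, since the statistic is infinite.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group (`n1 >= 2`,
#'   `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param pooled If `TRUE`, use the pooled-variance t test with
#'   `n1 + n2 - 2` degrees of freedom instead of Welch.
#'
#' @return A list with elements `t`, `df` and `p` (two-sided).
#'
#' @examples
#' welch_t_summary(13.4, 2.8, 7, 44.1, 4.9, 7)
#'
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2, pooled = FALSE) {
  vals <- c(mean1, sd1, n1, mean2, sd2, n2)
  if (any(!is.finite(vals)))
    stop("all summary statistics must be finite", call. = FALSE)
  if (n1 < 2 || n2 < 2)
    stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("both SDs are zero but the means differ: the t statistic is ",
         "unbounded; summary-based testing is not applicable", call. = FALSE)
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs the between- and within-group sums of squares from group
#' means, standard deviations and sizes, which determine the one-way
#' ANOVA F statistic exactly (balanced or not).
#'
#' @param means,sds,ns Equal-length vectors of group means, SDs and
#'   sizes; at least two groups, each with `n >= 2`.
#'
#' @return A list with `F`, `df1`, `df2` and `p`.
#'
#' @examples
#' oneway_anova_summary(c(19, 32.3, 12.9), c(2.6, 3.0, 3.6), c(7, 7, 7))
#'
#' @export
oneway_anova_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k)
    stop("need >= 2 groups with matching means/sds/ns", call. = FALSE)
  if (any(!is.finite(c(means, sds, ns))) || any(sds < 0))
    stop("summary statistics must be finite with non-negative SDs",
         call. = FALSE)
  if (any(ns < 2))
    stop("each group needs n >= 2 for a within-group variance",
         call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2,
                                                  lower.tail = FALSE))
}

#' Per-day comparison of the two saliva conditions for each paste
#'
#' For every paste present under both saliva conditions, runs a Welch
#' test on each shared day from the summary statistics and reports the
#' unadjusted and Bonferroni-adjusted p-values side by side, together
#' with a superscript-letter rendering (same letter on both conditions
#' when the day is non-significant, different letters when it is).
#'
#' The Bonferroni family defaults to the number of days compared within
#' each paste. Because the published letter pattern for these data is
#' consistent with unadjusted per-day tests, the `significant` flag is
#' based on the unadjusted p-value at `alpha`; `significant_bonferroni`
#' carries the corrected call.
#'
#' @param table A list of [occlusion_series()] objects covering each
#'   paste under both conditions (e.g. [occlusion_table1()]). A paste
#'   present under only one condition is skipped with a warning.
#' @param alpha Significance level.
#' @param m Bonferroni family size; default the number of shared days
#'   per paste.
#' @param pooled Use the pooled-variance t test instead of Welch.
#'
#' @return A data frame of class `"condition_comparison"`, one row per
#'   paste per shared day: means and SDs per condition, `t`, `df`, `p`,
#'   `p_bonferroni`, `significant`, `significant_bonferroni`, and
#'   `letters` (e.g. `"a|b"`).
#'
#' @examples
#' compare_conditions(occlusion_table1())
#'
#' @export
compare_conditions <- function(table, alpha = 0.05, m = NULL,
                               pooled = FALSE) {
  stopifnot(is.list(table), length(table) > 0L)
  pastes <- unique(vapply(table, function(s) s$paste, character(1)))
  rows <- list()
  for (p in pastes) {
    ws <- find_series(table, p, "without_saliva")
    s <- find_series(table, p, "with_saliva")
    if (is.null(ws) || is.null(s)) {
      warning("paste '", p, "' is missing one condition; skipped")
      next
    }
    days <- intersect(ws$days, s$days)
    if (length(days) == 0L) {
      warning("paste '", p, "' has no shared days; skipped")
      next
    }
    fam <- if (is.null(m)) length(days) else m
    for (d in days) {
      iw <- which(ws$days == d)
      is_ <- which(s$days == d)
      tt <- welch_t_summary(ws$means[iw], ws$sds[iw], ws$n,
                            s$means[is_], s$sds[is_], s$n, pooled = pooled)
      p_adj <- min(1, fam * tt$p)
      sig <- tt$p < alpha
      rows[[length(rows) + 1L]] <- data.frame(
        paste = p, day = d,
        mean_ws = ws$means[iw], sd_ws = ws$sds[iw],
        mean_s = s$means[is_], sd_s = s$sds[is_],
        n = ws$n, t = tt$t, df = tt$df, p = tt$p, p_bonferroni = p_adj,
        significant = sig, significant_bonferroni = p_adj < alpha,
        letters = if (sig) "a|b" else "a|a",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("condition_comparison", "data.frame")
  out
}

find_series <- function(table, paste_label, condition) {
  for (s in table)
    if (s$paste == paste_label && s$condition == condition) return(s)
  NULL
}

#' @export
print.condition_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Per-day Welch comparison, with vs without saliva (alpha = %g)\n",
              attr(x, "alpha")))
  cat("letters: a|b = significant difference (unadjusted), a|a = none\n\n")
  df <- as.data.frame(x)
  df$t <- round(df$t, digits)
  df$df <- round(df$df, 1)
  df$p <- signif(df$p, digits)
  df$p_bonferroni <- signif(df$p_bonferroni, digits)
  print(df[, c("paste", "day", "mean_ws", "mean_s", "t", "df", "p",
               "p_bonferroni", "letters")], row.names = FALSE)
  invisible(x)
}
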