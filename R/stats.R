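#' Group summaries of scrambling kinetics
#'
#' Computes per-group mean and SEM of `t_half_s`, excluding non-scrambling
#' cells (infinite-`t_half` sentinel) entirely - they never enter a mean,
#' SEM, or test. The scrambling fraction of each group is reported
#' separately. A group whose cells all fail to scramble gets `NA` mean and
#' SEM and is flagged: mean and SEM are not assigned for such groups.
#'
#' @param results A `scrambling_result` data frame (or any data frame with
#'   `t_half_s` and `is_scrambler` columns) carrying a `group` column, or a
#'   named list of such data frames (names become group labels).
#' @return Data frame with `group`, `n_total`, `n_scramblers`,
#'   `scrambling_fraction`, `mean_t_half_s`, `sem_t_half_s`,
#'   `mean_sem_assigned`.
#' @export
summarize_groups <- function(results) {
  if (is.data.frame(results)) {
    stop_if_not("group" %in% names(results),
                "results data frame needs a group column")
    parts <- split(results, results$group)
  } else {
    stop_if_not(!is.null(names(results)), "group labels missing")
    parts <- results
  }
  out <- lapply(names(parts), function(g) {
    d <- parts[[g]]
    scr <- d[d$is_scrambler & is.finite(d$t_half_s), , drop = FALSE]
    n <- nrow(scr)
    m <- if (n >= 1) mean(scr$t_half_s) else NA_real_
    sem <- if (n >= 2) stats::sd(scr$t_half_s) / sqrt(n) else NA_real_
    data.frame(group = g, n_total = nrow(d), n_scramblers = n,
               scrambling_fraction = n / nrow(d),
               mean_t_half_s = if (n >= 1) m else NA_real_,
               sem_t_half_s = sem,
               mean_sem_assigned = n >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Display star convention at alpha = 0.05.
significance_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare scrambling kinetics between groups
#'
#' Two groups: unpaired two-sided Student's t-test (equal variances).
#' More than two: one-way ANOVA followed by Tukey's honestly-significant-
#' difference test for all pairwise comparisons. Non-scrambling cells must
#' be excluded upstream ([summarize_groups()] / the `values` lists here
#' contain finite half-times only); infinite values are dropped
#' defensively. Degenerate variance (all values identical in every group)
#' yields an undefined statistic rather than an error.
#'
#' @param groups Named list of numeric vectors (finite `t_half_s` values of
#'   scrambling cells, one vector per group), each of length >= 2.
#' @param alpha Significance level for the labels (default 0.05).
#' @return List with `test` (`"t_test_two_sided"` or `"anova_tukey"`),
#'   `statistic`, `p_value` (overall), `pairwise` (data frame of pairwise
#'   p-values and star labels), `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  stop_if_not(is.list(groups) && length(groups) >= 2,
              "need at least two groups")
  stop_if_not(!is.null(names(groups)), "groups must be named")
  groups <- lapply(groups, function(x) x[is.finite(x)])
  stop_if_not(all(vapply(groups, length, integer(1)) >= 2),
              "each group needs >= 2 finite values")
  if (length(groups) == 2L) {
    x <- groups[[1]]; y <- groups[[2]]
    if (stats::sd(c(x, y)) == 0) {
      stat <- NA_real_; p <- 1
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
    pw <- data.frame(comparison = paste(names(groups)[2], "-",
                                        names(groups)[1]),
                     p_value = p, label = significance_label(p),
                     stringsAsFactors = FALSE)
    return(list(test = "t_test_two_sided", statistic = stat, p_value = p,
                pairwise = pw, alpha = alpha))
  }
  vals <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  if (stats::sd(vals) == 0) {
    pw <- data.frame(comparison = character(), p_value = numeric(),
                     label = character(), stringsAsFactors = FALSE)
    return(list(test = "anova_tukey", statistic = NA_real_, p_value = 1,
                pairwise = pw, alpha = alpha))
  }
  fit <- stats::aov(vals ~ lab)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$lab
  pw <- data.frame(comparison = rownames(tk), p_value = tk[, "p adj"],
                   label = vapply(tk[, "p adj"], significance_label,
                                  character(1)),
                   stringsAsFactors = FALSE)
  rownames(pw) <- NULL
  list(test = "anova_tukey", statistic = an[["F value"]][1],
       p_value = an[["Pr(>F)"]][1], pairwise = pw, alpha = alpha)
}
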