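# Nested two-way linear-model comparisons of a trait between two groups and
# sexes, with per-group post-hoc t-tests and a rule-based outlier screen.

#' Nested two-way ANOVA of a trait by group and sex
#'
#' Ordinary least-squares fits of the nested models `trait ~ group`,
#' `trait ~ sex`, `trait ~ sex + group` and `trait ~ sex * group`; each F
#' statistic is a difference in residual sums of squares over the full-model
#' mean square:
#' * `group_effect` -- the group term corrected for sex
#'   (`sex` vs `sex + group`, df1 = 1);
#' * `sex_any` -- any sex effect in at least one group
#'   (`group` vs `sex * group`, df1 = 2);
#' * `interaction` -- group-specific sexual dimorphism
#'   (`sex + group` vs `sex * group`, df1 = 1).
#'
#' Post-hoc Welch t-tests compare females and males within each group.
#' Individuals with a missing trait value are excluded.
#'
#' @param values numeric trait values.
#' @param sex `"F"`/`"M"` per individual.
#' @param group group label per individual (2 groups).
#' @return An `anova_result`: `group_effect`, `sex_any`, `interaction` (each
#'   F, df1, df2, p), `posthoc` data frame (group, t, df, p, direction),
#'   `group_means` with 95% CI, `n`.
#' @export
nested_anova <- function(values, sex, group) {
  keep <- !is.na(values) & sex %in% c("F", "M") & !is.na(group)
  v <- values[keep]; sx <- factor(sex[keep]); gr <- factor(group[keep])
  if (nlevels(gr) < 2L) stop("need at least two groups")
  if (nlevels(sx) < 2L) stop("both sexes must be present")
  n <- length(v)
  rss <- function(fm) sum(stats::residuals(fm)^2)
  m_g <- stats::lm(v ~ gr); m_s <- stats::lm(v ~ sx)
  m_sg <- stats::lm(v ~ sx + gr); m_full <- stats::lm(v ~ sx * gr)
  df_full <- m_full$df.residual
  mse <- rss(m_full) / df_full
  ftest <- function(rss_red, rss_fullr, df1) {
    f <- ((rss_red - rss_fullr) / df1) / mse
    list(F = f, df1 = df1, df2 = df_full,
         p = stats::pf(f, df1, df_full, lower.tail = FALSE))
  }
  group_effect <- ftest(rss(m_s), rss(m_sg), 1L)
  sex_any <- ftest(rss(m_g), rss(m_full), 2L)
  interaction <- ftest(rss(m_sg), rss(m_full), 1L)
  posthoc <- do.call(rbind, lapply(levels(gr), function(g) {
    sel <- gr == g
    if (length(unique(sx[sel])) < 2L)
      return(data.frame(group = g, t = NA_real_, df = NA_real_, p = NA_real_,
                        direction = NA_character_))
    tt <- stats::t.test(v[sel & sx == "F"], v[sel & sx == "M"])
    data.frame(group = g, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               direction = if (tt$statistic > 0) "females_larger" else "males_larger")
  }))
  gm <- do.call(rbind, lapply(levels(gr), function(g) {
    x <- v[gr == g]
    se <- stats::sd(x) / sqrt(length(x))
    data.frame(group = g, n = length(x), mean = mean(x),
               ci_lower = mean(x) - 1.96 * se, ci_upper = mean(x) + 1.96 * se)
  }))
  structure(list(group_effect = group_effect, sex_any = sex_any,
                 interaction = interaction, posthoc = posthoc,
                 group_means = gm, n = n),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("anova_result (n = %d)\n", x$n))
  cat(sprintf("  group (corrected for sex): F = %.2f, df = (%d,%d), p = %.3g\n",
              x$group_effect$F, x$group_effect$df1, x$group_effect$df2,
              x$group_effect$p))
  cat(sprintf("  sex (any group):           F = %.2f, df = (%d,%d), p = %.3g\n",
              x$sex_any$F, x$sex_any$df1, x$sex_any$df2, x$sex_any$p))
  cat(sprintf("  sex-by-group interaction:  F = %.2f, df = (%d,%d), p = %.3g\n",
              x$interaction$F, x$interaction$df1, x$interaction$df2,
              x$interaction$p))
  invisible(x)
}

#' Screen low outliers within groups
#'
#' Flags values below `Q1 - k * IQR` within their group -- a reproducible
#' stand-in for a visual screen of aberrantly low measurements.
#'
#' @param values named numeric vector (names = individual ids).
#' @param group group label per value.
#' @param k IQR multiplier.
#' @return Character vector of flagged ids (empty if none); the rule is
#'   attached as attribute `"rule"`.
#' @export
screen_outliers <- function(values, group, k = 3) {
  stopifnot(!is.null(names(values)))
  flagged <- character(0)
  for (g in unique(group[!is.na(values)])) {
    sel <- group == g & !is.na(values)
    if (sum(sel) < 5L) next
    q1 <- stats::quantile(values[sel], 0.25, names = FALSE)
    iqr <- stats::IQR(values[sel])
    low <- sel & values < q1 - k * iqr
    flagged <- c(flagged, names(values)[which(low)])
  }
  attr(flagged, "rule") <- sprintf("value < Q1 - %g * IQR within group", k)
  flagged
}
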