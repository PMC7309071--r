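# Group-level statistical analysis: Levene's test, two-way ANOVA with
# Type III sums of squares, Cohen's d, and exact noncentral-t power /
# sample-size calculations.

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations from each group's center
#' (mean by default; median gives the Brown-Forsythe variant).
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2
#'   observations), or a single numeric vector with `g` giving group
#'   membership.
#' @param g optional grouping factor when `groups` is a vector.
#' @param center `"mean"` or `"median"`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(groups, g = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups)) {
    if (is.null(g)) stop("supply a list of groups or a grouping factor g")
    groups <- split(as.numeric(groups), g)
  }
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least 2 observations")
  cfun <- if (center == "mean") mean else median
  z <- unlist(lapply(groups, function(x) abs(x - cfun(x))))
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  fit <- anova(lm(z ~ fac))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Two-way ANOVA (condition x limb) with Type III sums of squares
#'
#' Fits `value ~ condition * limb` with sum-to-zero contrasts and reports
#' the Type III tests of the two main effects and their interaction;
#' unbalanced cells are allowed, empty cells are not.
#'
#' @param values numeric response (e.g. one gait parameter per step).
#' @param condition,limb two-level factors (coercible).
#' @return data.frame with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
two_way_anova <- function(values, condition, limb) {
  condition <- factor(condition)
  limb <- factor(limb)
  if (any(table(condition, limb) == 0L)) stop("empty cell in the design")
  d <- data.frame(y = as.numeric(values), condition = condition, limb = limb)
  fit <- lm(y ~ condition * limb, data = d,
            contrasts = list(condition = "contr.sum", limb = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  eff <- c("condition", "limb", "condition:limb")
  idx <- match(eff, rownames(a3))
  df2 <- a3[["Df"]][rownames(a3) == "Residuals"]
  data.frame(effect = eff,
             F = a3[["F value"]][idx],
             df1 = a3[["Df"]][idx],
             df2 = df2,
             p = a3[["Pr(>F)"]][idx],
             stringsAsFactors = FALSE)
}

#' Cohen's d from group summary statistics
#'
#' Standardized mean difference `|m1 - m2| / s_pooled` with the
#' equal-weight pooled SD `sqrt((sd1^2 + sd2^2)/2)` (default), or the
#' sample-size-weighted pooled SD when `pooling = "weighted"` and group
#' sizes are given.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @param n1,n2 group sizes (required for weighted pooling).
#' @param pooling `"equal"` or `"weighted"`.
#' @return Cohen's d (non-negative) with attribute `band`, the
#'   conventional interpretation (very small < 0.2 <= small < 0.5 <=
#'   medium < 0.8 <= large < 1.3 <= very large).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2, n1 = NULL, n2 = NULL,
                     pooling = c("equal", "weighted")) {
  pooling <- match.arg(pooling)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop("both groups have zero variance")
  s <- if (pooling == "equal") {
    sqrt((sd1^2 + sd2^2) / 2)
  } else {
    if (is.null(n1) || is.null(n2))
      stop("weighted pooling requires n1 and n2")
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  }
  d <- abs(mean1 - mean2) / s
  bands <- c("very small", "small", "medium", "large", "very large")
  band <- bands[findInterval(d, c(0.2, 0.5, 0.8, 1.3)) + 1L]
  structure(d, band = band)
}

#' Exact power of a two-sided two-sample t test
#'
#' Noncentral-t power at standardized effect size `d` with `n` subjects
#' per group.
#'
#' @param n subjects per group (>= 2).
#' @param d standardized effect size.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
t_test_power <- function(n, d, alpha = 0.05) {
  if (n < 2) stop("n per group must be >= 2")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- qt(1 - alpha / 2, df)
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' Minimum per-group sample size for a target power
#'
#' Smallest integer `n` per group at which the exact noncentral-t power
#' of a two-sided two-sample t test reaches the target.
#'
#' @param d standardized effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @param n_max search cap; power unreachable below it raises an error.
#' @return integer `n` per group.
#' @export
sample_size_for_power <- function(d, alpha = 0.05, power = 0.8,
                                  n_max = 1e6) {
  if (d <= 0) stop("d must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  lo <- 2; hi <- 2
  while (t_test_power(hi, d, alpha) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) stop("target power unreachable within n_max")
  }
  while (hi > lo) {
    mid <- (lo + hi) %/% 2
    if (t_test_power(mid, d, alpha) >= power) hi <- mid else lo <- mid + 1
  }
  as.integer(hi)
}

#' Gait effect-size table for two cohorts
#'
#' Cohen's d of each temporal gait parameter between cohorts (per limb
#' and pooled) and between limbs within a cohort, from a stride-level
#' data frame.
#'
#' @param strides data.frame with `cohort`, `limb` and parameter columns.
#' @param params parameter column names.
#' @param ... passed to [cohens_d()].
#' @return data.frame of comparisons x parameters.
#' @export
gait_effect_sizes <- function(strides,
                              params = c("gct", "stp", "swp", "rstp",
                                         "rswp", "cadence"), ...) {
  comp <- list(
    "acl_vs_healthy_left" = function(p)
      list(strides[[p]][strides$cohort == "acl" & strides$limb == "left"],
           strides[[p]][strides$cohort == "healthy" & strides$limb == "left"]),
    "acl_vs_healthy_right" = function(p)
      list(strides[[p]][strides$cohort == "acl" & strides$limb == "right"],
           strides[[p]][strides$cohort == "healthy" & strides$limb == "right"]),
    "acl_vs_healthy_both" = function(p)
      list(strides[[p]][strides$cohort == "acl"],
           strides[[p]][strides$cohort == "healthy"]),
    "left_vs_right_acl" = function(p)
      list(strides[[p]][strides$cohort == "acl" & strides$limb == "left"],
           strides[[p]][strides$cohort == "acl" & strides$limb == "right"]))
  rows <- lapply(names(comp), function(cn) {
    ds <- vapply(params, function(p) {
      gr <- comp[[cn]](p)
      as.numeric(cohens_d(mean(gr[[1]]), sd(gr[[1]]),
                          mean(gr[[2]]), sd(gr[[2]]), ...))
    }, numeric(1))
    data.frame(comparison = cn, t(ds), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("comparison", params)
  out
}
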