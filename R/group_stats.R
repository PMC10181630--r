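# Group-level inference: Tukey outlier correction, assumption checks,
# one-way ANOVA, Holm post hocs and JZS Bayes factors.

#' Tukey fence outlier correction (winsorization)
#'
#' Values outside `[Q1 - k*IQR, Q3 + k*IQR]` are replaced by the nearer
#' fence. Quartiles use the linear-interpolation convention (R quantile
#' type 7). Winsorizing (rather than removing) preserves the group sizes.
#'
#' @param values Numeric vector, length >= 4.
#' @param k Fence multiplier (default 1.5).
#' @return Corrected values, with the number of replacements attached as
#'   attribute `"n_corrected"`.
#' @examples
#' tukey_outlier_correct(c(1, 2, 3, 4, 100))  # 100 -> 7
#' @export
tukey_outlier_correct <- function(values, k = 1.5) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    hrvc_error("need at least 4 values for Tukey fences", "hrvc_config_error")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- clamp(values, lo, hi)
  structure(out, n_corrected = sum(out != values))
}

check_groups <- function(values, group, min_per_group = 2L, min_groups = 2L) {
  group <- as.factor(group)
  if (length(values) != length(group))
    hrvc_error("values and group must have equal length", "hrvc_config_error")
  sizes <- table(group)
  if (length(sizes) < min_groups)
    hrvc_error(sprintf("need at least %d groups", min_groups), "hrvc_config_error")
  if (any(sizes < min_per_group))
    hrvc_error(sprintf("every group needs at least %d values", min_per_group),
               "hrvc_config_error")
  droplevels(group)
}

#' One-way between-group ANOVA
#'
#' Classical between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within`, with the p value from the F distribution.
#'
#' @param values Metric per participant.
#' @param group Condition labels (coerced to factor).
#' @return List with `F`, `p`, `df` (numerator, denominator) and the mean
#'   squares.
#' @export
anova_oneway <- function(values, group) {
  group <- check_groups(values, group)
  gmeans <- tapply(values, group, mean)
  if (sum((values - gmeans[group])^2) <= 0)
    hrvc_error("zero within-group variance: ANOVA degenerate", "hrvc_degenerate")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  ms_within <- s[["Mean Sq"]][2]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]),
       ms_between = s[["Mean Sq"]][1], ms_within = ms_within)
}

#' Holm-corrected pairwise t tests
#'
#' All pairwise two-sample t tests (pooled variance by default) with Holm's
#' step-down adjustment: raw p values sorted ascending, the i-th adjusted to
#' `max_{j<=i} (m-j+1) p_j`, clipped at 1.
#'
#' @param values Metric per participant.
#' @param group Condition labels.
#' @param var_equal Pooled-variance t tests (`TRUE`, classical) or Welch.
#' @return Data frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_raw`, `p_holm`.
#' @export
holm_pairwise <- function(values, group, var_equal = TRUE) {
  group <- check_groups(values, group)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  rows <- apply(pairs, 2, function(pr) {
    tt <- stats::t.test(values[group == pr[1]], values[group == pr[2]],
                        var.equal = var_equal)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}

#' Two-sample JZS Bayes factor (natural log of BF10)
#'
#' Default Bayesian two-sample test: Cauchy prior with scale `rscale`
#' (default sqrt(2)/2) on the standardized effect size, computed by
#' one-dimensional numerical quadrature of the marginal likelihood ratio
#' over the prior's inverse-gamma mixing variable.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param rscale Cauchy prior scale.
#' @return `log(BF10)`; positive values favor a group difference.
#' @export
jzs_log_bf <- function(x, y, rscale = sqrt(2) / 2) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    hrvc_error("each sample needs at least 2 values", "hrvc_config_error")
  nu <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / nu
  if (sp2 <= 0)
    hrvc_error("zero pooled variance: Bayes factor undefined", "hrvc_degenerate")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  N <- 1 / (1 / n1 + 1 / n2)   # effective sample size
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    log_num <- -0.5 * log1p(N * g) - (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu))
    prior <- rscale / sqrt(2 * pi) * g^(-1.5) * exp(-rscale^2 / (2 * g))
    exp(log_num - log_den) * prior
  }
  bf <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                         stop.on.error = TRUE)$value
  log(bf)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk statistic and p value per group, and the Levene test
#' (centered at the mean) across groups. Reported for inspection; the ANOVA
#' is not gated on them.
#'
#' @param values Metric per participant.
#' @param group Condition labels; every group needs >= 3 values.
#' @return List with `shapiro` (data frame: group, W, p) and `levene`
#'   (list: F, df, p).
#' @export
assumption_checks <- function(values, group) {
  group <- check_groups(values, group, min_per_group = 3L)
  sh <- do.call(rbind, lapply(levels(group), function(g) {
    s <- stats::shapiro.test(values[group == g])
    data.frame(group = g, W = unname(s$statistic), p = s$p.value)
  }))
  lv <- car::leveneTest(values ~ group, center = mean)
  list(shapiro = sh,
       levene = list(F = lv[["F value"]][1], df = c(lv$Df[1], lv$Df[2]),
                     p = lv[["Pr(>F)"]][1]))
}
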