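test_that("Tukey fences winsorize under the linear-interpolation quartile convention", {
  x <- c(1, 2, 3, 4, 100)
  out <- tukey_outlier_correct(x)
  # type-7 quartiles: Q1 = 2, Q3 = 4, IQR = 2 -> upper fence 4 + 1.5*2 = 7
  expect_equal(as.numeric(out), c(1, 2, 3, 4, 7))
  expect_equal(attr(out, "n_corrected"), 1L)
  # exhaustive check of the convention
  expect_equal(unname(quantile(x, c(0.25, 0.75), type = 7)), c(2, 4))

  clean <- c(3, 4, 5, 6, 7)
  expect_equal(as.numeric(tukey_outlier_correct(clean)), clean)
  # idempotence
  twice <- tukey_outlier_correct(as.numeric(out))
  expect_equal(as.numeric(twice), as.numeric(out))
  expect_error(tukey_outlier_correct(c(1, 2, 3)), class = "hrvc_config_error")
})

test_that("one-way ANOVA matches a from-scratch sum-of-squares oracle", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_oneway(vals, grp)
  # oracle
  gm <- mean(vals)
  means <- tapply(vals, grp, mean)
  ns <- tapply(vals, grp, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((vals - means[grp])^2)
  F_o <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, F_o, tolerance = 1e-10)
  expect_equal(res$p, pf(F_o, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$df, c(2, 6))

  # identical groups: F = 0, p = 1
  same <- anova_oneway(rep(c(1, 2, 3), 3), grp)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  expect_error(anova_oneway(rep(1, 9), grp), class = "hrvc_degenerate")
})

test_that("ANOVA F is location-invariant and scale-invariant", {
  set.seed(6)
  vals <- rnorm(24)
  grp <- rep(c("a", "b", "c"), each = 8)
  f0 <- anova_oneway(vals, grp)$F
  expect_equal(anova_oneway(vals + 100, grp)$F, f0, tolerance = 1e-10)
  expect_equal(anova_oneway(vals * 7, grp)$F, f0, tolerance = 1e-10)
})

test_that("ANOVA p agrees with a permutation null on a small dataset", {
  set.seed(16)
  vals <- c(rnorm(6, 0), rnorm(6, 0.9), rnorm(6, 0.3))
  grp <- rep(c("a", "b", "c"), each = 6)
  p_f <- anova_oneway(vals, grp)$p
  B <- 20000
  f_obs <- anova_oneway(vals, grp)$F
  f_perm <- vapply(seq_len(B), function(i)
    anova_oneway(vals, sample(grp))$F, numeric(1))
  p_perm <- (1 + sum(f_perm >= f_obs)) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_f - p_perm), 4 * se + 0.01)
})

test_that("Holm step-down adjustment matches the hand computation", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  hp <- holm_pairwise(vals, grp)
  expect_equal(nrow(hp), 3L)
  expect_equal(hp$p_holm, p.adjust(hp$p_raw, "holm"))
  # hand computation for raw p = (0.01, 0.04, 0.03):
  raw <- c(0.01, 0.04, 0.03)
  o <- order(raw)
  adj_sorted <- cummax((3:1) * raw[o])
  adj <- pmin(1, adj_sorted[order(o)])
  expect_equal(adj, c(0.03, 0.06, 0.06))
  expect_equal(p.adjust(raw, "holm"), adj)
  # adjusted >= raw, monotone in the raw ordering
  expect_true(all(hp$p_holm >= hp$p_raw))
  expect_true(all(diff(hp$p_holm[order(hp$p_raw)]) >= -1e-12))
  # single pair: adjusted equals raw
  h1 <- holm_pairwise(vals[1:6], grp[1:6])
  expect_equal(h1$p_holm, h1$p_raw)
})

test_that("JZS Bayes factor: sign contracts, symmetry and quadrature oracle", {
  set.seed(17)
  x <- rnorm(15)
  expect_lt(jzs_log_bf(x, x + 1e-12 * seq_along(x)), 0)  # identical samples
  y <- rnorm(20, 2)
  x20 <- rnorm(20)
  expect_gt(jzs_log_bf(x20, y), 3)
  expect_equal(jzs_log_bf(x20, y), jzs_log_bf(y, x20), tolerance = 1e-8)
  expect_error(jzs_log_bf(rep(1, 5), rep(1, 5)), class = "hrvc_degenerate")

  # independent fine-grid Simpson quadrature of the same marginal ratio,
  # integrated over u = g/(1+g)
  oracle <- function(x, y, r = sqrt(2) / 2) {
    n1 <- length(x); n2 <- length(y); nu <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / nu
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    N <- 1 / (1 / n1 + 1 / n2)
    u <- seq(1e-9, 1 - 1e-9, length.out = 200001)
    g <- u / (1 - u)
    jac <- 1 / (1 - u)^2
    log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
    fg <- exp(-0.5 * log1p(N * g) -
                (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) - log_den) *
      r / sqrt(2 * pi) * g^(-1.5) * exp(-r^2 / (2 * g)) * jac
    h <- u[2] - u[1]
    wts <- rep(c(4, 2), length.out = length(u) - 2)
    log((h / 3) * (fg[1] + fg[length(fg)] + sum(wts * fg[2:(length(fg) - 1)])))
  }
  expect_equal(jzs_log_bf(x20, y), oracle(x20, y), tolerance = 1e-4)
  set.seed(18)
  a <- rnorm(12, 0, 2); b <- rnorm(9, 0.5, 2)
  expect_equal(jzs_log_bf(a, b), oracle(a, b), tolerance = 1e-4)
})

test_that("assumption checks behave on Gaussian, heavy-tailed and homoscedastic data", {
  # calibration: Gaussian groups rarely rejected, heavy tails usually rejected
  set.seed(19)
  gauss_p <- replicate(100, shapiro.test(rnorm(15))$p.value)
  heavy_p <- replicate(100, shapiro.test(rcauchy(30))$p.value)
  expect_gte(mean(gauss_p > 0.05), 0.9)
  expect_gte(mean(heavy_p < 0.05), 0.9)

  vals <- c(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  grp <- rep(c("a", "b", "c"), each = 10)
  rep_ <- assumption_checks(vals, grp)
  expect_equal(nrow(rep_$shapiro), 3L)
  expect_true(all(rep_$shapiro$p > 0 & rep_$shapiro$p <= 1))
  # identical spreads: Levene statistic near 0
  base <- rnorm(10)
  vals2 <- c(base, base + 5, base + 10)
  rep2 <- assumption_checks(vals2, grp)
  expect_lt(rep2$levene$F, 1e-10)
})
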