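# Statistical battery: enumeration oracles, known equivalences, regression.

test_that("median/IQR summaries use linear-interpolation quantiles", {
  expect_equal(unname(summarize_median_iqr(1:5)), c(3, 2, 4))
  expect_equal(unname(summarize_median_iqr(rep(7, 10))), c(7, 7, 7))
  expect_error(summarize_median_iqr(numeric(0)), "empty")
  x <- c(2, 9, 4, 1, 8, 3)
  expect_equal(summarize_median_iqr(x)[["q1"]],
               unname(quantile(x, 0.25, type = 7)))
})

test_that("Mann-Whitney matches exact enumeration for small samples", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(t1$statistic), 0)
  expect_equal(t1$p_value, 0.1)  # 2 / choose(6, 3)
  set.seed(21)
  for (i in 1:6) {
    x <- round(rnorm(sample(3:5, 1)), 3)
    y <- round(rnorm(sample(3:5, 1), mean = runif(1, -1, 1)), 3)
    expect_equal(mann_whitney_u(x, y)$p_value, enumerate_mw_p(x, y),
                 tolerance = 1e-12)
  }
  # symmetry and exchangeable null
  x <- c(1.2, 3.1, 0.4, 2.2); y <- c(0.9, 2.5, 1.7)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
  # large / tied samples take the corrected normal branch
  big <- mann_whitney_u(rep(1:20, 2), rep(1:20, 2) + 0.5)
  expect_match(big$method, "normal")
})

test_that("Wilcoxon signed-rank matches exact sign-pattern enumeration", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6) / 10)$p_value,
               2 / 64)
  expect_equal(wilcoxon_signed_rank(0.7)$p_value, 1)
  set.seed(31)
  for (i in 1:6) {
    d <- round(rnorm(sample(4:8, 1), mean = runif(1, -0.5, 0.5)), 3)
    d <- d[d != 0]
    expect_equal(wilcoxon_signed_rank(d)$p_value, enumerate_wilcoxon_p(d),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_signed_rank(-d)$p_value,
                 wilcoxon_signed_rank(d)$p_value)
  }
  z <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(z$degenerate)
  expect_true(is.na(z$p_value))
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3, 4, 5, 6) / 10)$p_value,
               wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6) / 10)$p_value)
})

test_that("Kruskal-Wallis matches the rank formula and the two-group deviate", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(unname(kruskal_wallis(g)$statistic), brute_kw_h(g),
               tolerance = 1e-12)
  same <- list(c(1, 5, 9), c(1, 5, 9), c(1, 5, 9))
  expect_lt(unname(kruskal_wallis(same)$statistic), 1e-10)
  expect_gt(kruskal_wallis(same)$p_value, 0.99)
  # two tie-free groups: H equals the squared MW normal deviate (no
  # continuity correction in either direction)
  x <- c(0.3, 1.7, 2.9, 4.1); y <- c(0.9, 2.1, 5.3, 6.7, 7.7)
  h <- unname(kruskal_wallis(list(x, y))$statistic)
  u <- unname(mann_whitney_u(x, y)$statistic)
  mu <- length(x) * length(y) / 2
  sg <- sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)
  expect_equal(h, ((u - mu) / sg)^2, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("Pearson correlation matches its definitional formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(unname(pearson_r(x, 2 * x + 1)["r"]), 1)
  set.seed(5)
  a <- rnorm(40); b <- 0.3 * a + rnorm(40)
  r <- pearson_r(a, b)
  expect_equal(unname(r["r"]),
               cov(a, b) / (sd(a) * sd(b)), tolerance = 1e-12)
  tt <- unname(r["r"]) * sqrt(38 / (1 - unname(r["r"])^2))
  expect_equal(unname(r["p"]), 2 * pt(-abs(tt), 38), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "variance")
  expect_error(pearson_r(1:2, 2:3), "3")
})

test_that("Shapiro-Wilk screen rejects log-normal samples", {
  rej <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    shapiro_wilk(rlnorm(120, sdlog = 0.5))["p"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("OLS panel matches the normal equations with standardized betas", {
  set.seed(8)
  X <- data.frame(a = rnorm(60), b = runif(60), c = rbinom(60, 1, 0.4))
  y <- 1 + 2 * X$a - 0.5 * X$b + 0.8 * X$c
  res <- multivariate_linear(y, X)
  expect_equal(res$B, c(2, -0.5, 0.8), tolerance = 1e-10)  # exact fit
  yn <- y + rnorm(60, sd = 0.3)
  res2 <- multivariate_linear(yn, X)
  ne <- normal_equation_ols(yn, X)
  expect_equal(res2$B, unname(ne[-1]), tolerance = 1e-8)
  expect_equal(res2$beta,
               unname(res2$B * vapply(X, sd, 1) / sd(yn)), tolerance = 1e-12)
  expect_error(multivariate_linear(yn, cbind(X, d = X$a * 2)),
               "collinear.*d|d.*collinear")
  expect_error(multivariate_linear(rnorm(3), X[1:3, ]), "covariates")
})

test_that("type-I error is controlled at the nominal level for each test", {
  n_rep <- 2000
  alpha <- 0.05
  set.seed(2026)
  mw <- wsr <- kw <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(50); y <- rnorm(50)
    mw[i] <- mann_whitney_u(x, y)$p_value < alpha
    wsr[i] <- wilcoxon_signed_rank(rnorm(50))$p_value < alpha
    kw[i] <- kruskal_wallis(list(rnorm(50), rnorm(50), rnorm(50)))$p_value < alpha
  }
  for (rate in c(mean(mw), mean(wsr), mean(kw))) {
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.07)
  }
})
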