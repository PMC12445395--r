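# Nonparametric test battery used for cohort comparisons. The tests delegate
# to the reference routines in `stats` behind a uniform result structure.

perf_test <- function(statistic, p_value, method, n, two_sided = TRUE,
                      degenerate = FALSE) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n, two_sided = two_sided,
                 degenerate = degenerate), class = "perf_test")
}

#' @export
print.perf_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention (type 7).
#'
#' @param values nonempty numeric vector (`NA`s dropped).
#' @return Named vector `c(median, q1, q3)`.
#' @export
summarize_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_invalid("cannot summarize an empty vector")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Mann-Whitney U test
#'
#' Two-sample rank test. The p-value is exact (enumeration over labelings)
#' when the combined sample size is at most 16 and there are no ties, and a
#' tie-corrected normal approximation with continuity correction otherwise.
#' The reported statistic is U for the first sample.
#'
#' @param x,y nonempty numeric vectors.
#' @param two_sided two-sided p (default); one-sided uses `greater` for `x`.
#' @return A `perf_test` with the U statistic.
#' @export
mann_whitney_u <- function(x, y, two_sided = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop_invalid("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) + length(y) <= 16
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (two_sided) "two.sided" else "greater",
    exact = exact, correct = TRUE))
  perf_test(ht$statistic, ht$p.value,
            if (exact) "Mann-Whitney U (exact)" else
              "Mann-Whitney U (normal approximation)",
            c(length(x), length(y)), two_sided)
}

#' Wilcoxon signed-rank test
#'
#' Paired-difference rank test. Zero differences are dropped before ranking;
#' the p-value is exact for at most 20 untied nonzero differences and a
#' tie-corrected normal approximation with continuity correction otherwise.
#' If every difference is zero the result is flagged degenerate (`p = NA`)
#' rather than an error.
#'
#' @param differences paired differences (`NA`s dropped).
#' @param two_sided two-sided p (default).
#' @return A `perf_test` with the signed-rank statistic V.
#' @export
wilcoxon_signed_rank <- function(differences, two_sided = TRUE) {
  d <- differences[!is.na(differences)]
  if (!length(d)) stop_invalid("no differences supplied")
  nz <- d[d != 0]
  if (!length(nz))
    return(perf_test(NA_real_, NA_real_, "Wilcoxon signed-rank",
                     length(d), two_sided, degenerate = TRUE))
  exact <- !anyDuplicated(abs(nz)) && length(nz) <= 20
  ht <- suppressWarnings(stats::wilcox.test(
    nz, alternative = if (two_sided) "two.sided" else "greater",
    exact = exact, correct = TRUE))
  perf_test(ht$statistic, ht$p.value,
            if (exact) "Wilcoxon signed-rank (exact)" else
              "Wilcoxon signed-rank (normal approximation)",
            length(nz), two_sided)
}

#' Kruskal-Wallis test
#'
#' Rank test across two or more groups; H statistic with tie correction and a
#' chi-squared p-value on k - 1 degrees of freedom.
#'
#' @param groups list of nonempty numeric vectors.
#' @return A `perf_test` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop_invalid("need at least two groups")
  if (any(!vapply(groups, function(g) length(g[!is.na(g)]) > 0, logical(1))))
    stop_invalid("every group must be nonempty")
  ht <- stats::kruskal.test(lapply(groups, function(g) g[!is.na(g)]))
  perf_test(ht$statistic, ht$p.value, "Kruskal-Wallis",
            vapply(groups, function(g) sum(!is.na(g)), integer(1)))
}

#' Pearson correlation with significance test
#'
#' Product-moment correlation; the two-sided p-value comes from the t
#' transform on n - 2 degrees of freedom. For binary covariates on fixed
#' codings this is the point-biserial coefficient.
#'
#' @param x,y numeric vectors (pairwise-complete; n >= 3 and nonzero variance
#'   required).
#' @return Named vector `c(r, p)`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_invalid("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("zero variance in x or y")
  ht <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ht$estimate), p = ht$p.value)
}

#' Shapiro-Wilk normality screen
#'
#' @param values numeric vector (3 to 5000 values after `NA` removal).
#' @return Named vector `c(W, p)`.
#' @export
shapiro_wilk <- function(values) {
  ht <- stats::shapiro.test(values[!is.na(values)])
  c(W = unname(ht$statistic), p = ht$p.value)
}

#' Multivariate linear regression with standardized coefficients
#'
#' Ordinary least squares of an outcome on a set of covariates (QR
#' decomposition via [stats::lm()]). Reports, per covariate, the
#' unstandardized coefficient B, the standardized coefficient
#' `beta = B * SD(x) / SD(y)`, and the two-sided t-test p-value. Covariate
#' codings follow the cohort convention: sex is numeric 1 (female) / 2
#' (male); AF and beta-blocker are 0/1 indicators.
#'
#' @param outcome numeric response vector.
#' @param covariates data frame of numeric covariates (already coded).
#' @return An object of class `regression_result`: data frame with rows per
#'   covariate (`B`, `beta`, `p`) plus attributes `n` and `r_squared`.
#' @export
multivariate_linear <- function(outcome, covariates) {
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(covariates) & !is.na(outcome)
  y <- outcome[ok]; X <- covariates[ok, , drop = FALSE]
  if (length(y) <= ncol(X) + 1)
    stop_invalid("need n > number of covariates + 1")
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    stop_invalid("design matrix is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ ., data = X)
  # summary.lm warns on noiseless exact fits; the coefficients are still valid
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  cn <- colnames(X)
  # lm mangles non-syntactic names; match by position (intercept first)
  B <- sm[-1, 1]; p <- sm[-1, 4]
  beta <- B * vapply(X, stats::sd, numeric(1)) / stats::sd(y)
  out <- data.frame(covariate = cn, B = unname(B), beta = unname(beta),
                    p = unname(p), row.names = NULL)
  attr(out, "n") <- length(y)
  attr(out, "r_squared") <- sfit$r.squared
  class(out) <- c("regression_result", "data.frame")
  out
}

#' @export
print.regression_result <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariate linear model (n = %d, R^2 = %.3f)\n",
              attr(x, "n"), attr(x, "r_squared")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
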