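# Independent brute-force oracles used to cross-check the statistical and
# geometric routines. These deliberately re-derive everything from first
# principles and never call the implementation under test.

# two-sided Mann-Whitney p by enumeration over all group labelings
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(n, m)
  mu <- m * (length(y)) / 2
  count <- 0
  for (i in seq_len(ncol(combs))) {
    xs <- pooled[combs[, i]]
    ys <- pooled[-combs[, i]]
    if (abs(u_stat(xs, ys) - mu) >= abs(u_obs - mu) - 1e-12) count <- count + 1
  }
  count / ncol(combs)
}

# two-sided Wilcoxon signed-rank p by enumeration over all sign patterns
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  count <- 0
  for (bits in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(bits))[seq_len(n)]
    v <- sum(r[signs == 1])
    if (abs(v - mu) >= abs(v_obs - mu) - 1e-12) count <- count + 1
  }
  count / 2^n
}

# tie-free Kruskal-Wallis H from the textbook rank formula
brute_kw_h <- function(groups) {
  allv <- unlist(groups)
  n <- length(allv)
  r <- rank(allv)
  idx <- rep(seq_along(groups), lengths(groups))
  rsum <- tapply(r, idx, sum)
  12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
}

# OLS coefficients from the closed-form normal equations
normal_equation_ols <- function(y, X) {
  Xm <- cbind(1, as.matrix(X))
  solve(t(Xm) %*% Xm, t(Xm) %*% y)[, 1]
}

# coarse grid search over Fermi parameters: best residual sum of squares of
# the forward model against a tissue curve over the fit window
grid_search_fermi_rss <- function(times, aif, tissue, win,
                                  A = seq(0.005, 0.12, length.out = 5),
                                  k = c(0.1, 0.3, 0.5, 1, 2),
                                  w = c(0.5, 1.5, 3, 6, 10),
                                  td = c(0, 0.5, 1, 2, 4)) {
  dt <- times[2] - times[1]
  tk <- times - times[1]
  best <- Inf
  for (a in A) for (kk in k) for (ww in w) for (tt in td) {
    h <- a / (1 + exp((tk - tt - ww) * kk)); h[tk < tt] <- 0
    pred <- (stats::convolve(aif, rev(h), type = "open")[seq_along(aif)] * dt)[win]
    rss <- sum((pred - tissue[win])^2)
    if (rss < best) best <- rss
  }
  best
}

# standard small phantom used across tests
default_times <- function(n = 61, dt = 1) seq(0, by = dt, length.out = n)
default_aif <- function(times) make_aif(aif_model(), times)
small_geometry <- function() phantom_geometry(grid_size = 64, endo_radius = 10,
                                              epi_radius = 15)
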