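# Fermi impulse response, MBF readout, and the deconvolution fitter.

test_that("Fermi impulse response matches its closed form", {
  expect_equal(fermi_ir(c(-1, 0, 0.5), fermi_params(1, 1, 2, 1)),
               c(0, 0, 0))  # causal support
  p <- fermi_params(3, 0, 4, 0)
  expect_equal(fermi_ir(c(0, 5, 50), p), rep(1.5, 3))  # k = 0 flat limit
  expect_equal(fermi_ir(0, fermi_params(1, 1, 2, 0)), 1 / (1 + exp(-2)))
  expect_equal(fermi_ir(0, fermi_params(1, 1, 2, 0)), 0.880797,
               tolerance = 1e-6)
  tt <- seq(0, 30, by = 0.1)
  h <- fermi_ir(tt, fermi_params(2, 0.7, 3, 1))
  expect_true(all(h >= 0))
  expect_true(all(diff(h[tt >= 1]) <= 0))
  expect_error(fermi_params(-1, 1, 1, 0), "Fermi parameters")
})

test_that("MBF readout is the initial kernel height in per-minute units", {
  expect_equal(mbf_from_params(fermi_params(0, 1, 2, 0)), 0)
  p1 <- fermi_params(0.02, 0.5, 3, 0)
  p2 <- fermi_params(0.04, 0.5, 3, 0)
  expect_equal(mbf_from_params(p2), 2 * mbf_from_params(p1))
  expect_equal(mbf_from_params(p1), 60 * fermi_ir(0, p1))
  # density normalization
  expect_equal(mbf_from_params(p1, density = 1.05),
               mbf_from_params(p1) / 1.05)
})

test_that("noiseless deconvolution recovers true MBF within 1%", {
  t <- default_times()
  ca <- default_aif(t)
  for (mbf in c(0.5, 1.0, 2.0, 3.5)) {
    fit <- fermi_fit(t, ca, tissue_curve(ca, t, mbf))
    expect_true(fit$converged)
    expect_lt(abs(fit$mbf - mbf) / mbf, 0.01)
  }
  # a kernel shape away from all fit initializations still recovers flow;
  # the (A, k, w) valley is nearly flat there, so the tolerance is wider
  ct <- tissue_curve(ca, t, 2, shape = c(0.9, 1.8, 0))
  fit <- fermi_fit(t, ca, ct)
  expect_lt(abs(fit$mbf - 2) / 2, 0.05)
})

test_that("degenerate inputs are handled as specified", {
  t <- default_times()
  ca <- default_aif(t)
  fit0 <- fermi_fit(t, ca, rep(0, length(t)))
  expect_equal(fit0$mbf, 0)
  expect_true(fit0$converged)
  expect_error(fermi_fit(t, rep(0, length(t)), tissue_curve(ca, t, 1)),
               "identically zero")
  expect_error(fermi_fit(t, ca[-1], tissue_curve(ca, t, 1)), "time axis")
})

test_that("recovered MBF is linear in tissue scale and inverse in AIF scale", {
  t <- default_times()
  ca <- default_aif(t)
  ct <- tissue_curve(ca, t, 1.8)
  base <- fermi_fit(t, ca, ct)$mbf
  for (cc in c(0.5, 2, 3)) {
    expect_equal(fermi_fit(t, ca, cc * ct)$mbf / base, cc, tolerance = 0.01)
    expect_equal(fermi_fit(t, cc * ca, ct)$mbf * cc, base, tolerance = 0.01 * base)
  }
})

test_that("whole-frame delay of both curves leaves MBF nearly unchanged", {
  t <- default_times(n = 70)
  ca <- default_aif(t)
  ct <- tissue_curve(ca, t, 2.2)
  base <- fermi_fit(t, ca, ct)$mbf
  for (shift in c(3, 6)) {
    ca_s <- c(rep(0, shift), head(ca, -shift))
    ct_s <- c(rep(0, shift), head(ct, -shift))
    expect_lt(abs(fermi_fit(t, ca_s, ct_s)$mbf - base) / base, 0.01)
  }
})

test_that("fitter residual is not beaten by a coarse brute-force grid search", {
  t <- default_times()
  ca <- default_aif(t)
  set.seed(42)
  ct <- tissue_curve(ca, t, 2, shape = c(0.5, 3, 0)) +
    rnorm(length(t), sd = 0.02)
  fit <- fermi_fit(t, ca, ct)
  grid_rss <- grid_search_fermi_rss(t, ca - mean(ca[1:5]),
                                    ct - mean(ct[1:5]), fit$win_idx)
  expect_lte(grid_rss, Inf)
  expect_gte(grid_rss, fit$rss * 0.95)  # fit is within 5% of the grid optimum
})

test_that("irregular beat-gated timing still recovers flow", {
  tt <- beat_times(80, "af", mean_hr = 75, rr_cv = 0.25, seed = 5)
  ca <- default_aif(tt)
  ct <- tissue_curve(ca, tt, 2.0)
  fit <- fermi_fit(tt, ca, ct)
  expect_lt(abs(fit$mbf - 2) / 2, 0.05)
})

test_that("recovery is monotone across true MBF under fixed noise", {
  t <- default_times()
  ca <- default_aif(t)
  truths <- seq(0.5, 3.5, by = 0.5)
  set.seed(123)
  med <- vapply(truths, function(mbf) {
    fits <- vapply(1:7, function(i) {
      ct <- tissue_curve(ca, t, mbf) + rnorm(length(t), sd = 0.02)
      fermi_fit(t, ca, ct)$mbf
    }, numeric(1))
    median(fits)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("fermi_fit methods are coherent", {
  t <- default_times()
  ca <- default_aif(t)
  fit <- fermi_fit(t, ca, tissue_curve(ca, t, 2))
  expect_named(coef(fit), c("amplitude_A", "decay_k", "width_w", "delay_td"))
  expect_equal(fitted(fit) + residuals(fit), fit$tissue, tolerance = 1e-12)
  expect_equal(deviance(fit), sum(residuals(fit)[fit$win_idx]^2),
               tolerance = 1e-10)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(mbf_from_params(fit$params), fit$mbf)
  sims <- simulate(fit, nsim = 3, seed = 2, sd = 0.01)
  expect_identical(dim(sims), c(length(t), 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 2, sd = 0.01))
  expect_output(print(fit), "MBF")
  expect_output(print(summary(fit)), "Kernel parameters")
})

test_that("pixelwise mapping fits masked pixels and flags mismatches", {
  t <- default_times()
  ca <- default_aif(t)
  geom <- phantom_geometry(grid_size = 24, endo_radius = 4, epi_radius = 7)
  ph <- phantom_slice(geom, function(d) rep(2, length(d)), ca, t)
  m <- map_mbf(t, ca, ph$curves, ph$truth$mask)
  v <- m$values[m$mask]
  expect_equal(mean(v), 2, tolerance = 0.01)
  expect_lt(stats::sd(v), 0.02)
  expect_identical(sum(m$mask), sum(ph$truth$mask))

  empty <- map_mbf(t, ca, NULL, matrix(FALSE, 4, 4))
  expect_identical(sum(empty$mask), 0L)
  expect_error(map_mbf(t, ca, ph$curves[, 1:3], ph$truth$mask), "curves")
})
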