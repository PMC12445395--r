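# Synthetic data generator: AIF, forward model, phantom slice, beat timing.

test_that("parametric AIF has gamma-variate support, scale and integral", {
  t <- seq(0, 90, by = 0.05)
  expect_equal(make_aif(aif_model(amplitude = 0), t), rep(0, length(t)))
  pre <- make_aif(aif_model(onset_time = 10, recirculation_fraction = 0), 0:9)
  expect_equal(pre, rep(0, 10))
  expect_error(make_aif(aif_model(), c(0, 1, 1, 2)), "increasing")

  # trapezoidal integral vs the analytic gamma integral, within 0.5%
  m <- aif_model(onset_time = 5, amplitude = 30, recirculation_fraction = 0)
  ca <- make_aif(m, t)
  num <- sum(diff(t) * (head(ca, -1) + tail(ca, -1)) / 2)
  ana <- m$amplitude * stats::pgamma(max(t) - m$onset_time,
                                     shape = m$shape_alpha, scale = m$scale_beta)
  expect_lt(abs(num - ana) / ana, 0.005)
  expect_true(all(ca >= 0))

  # recirculation adds its stated fraction of the first-pass area
  m2 <- aif_model(onset_time = 5, amplitude = 30, recirculation_fraction = 0.2)
  ca2 <- make_aif(m2, seq(0, 400, by = 0.05))
  num2 <- sum(0.05 * ca2)
  expect_lt(abs(num2 - 30 * 1.2) / (30 * 1.2), 0.005)
})

test_that("forward model is a scaled Fermi convolution", {
  t <- default_times()
  ca <- default_aif(t)
  expect_equal(tissue_curve(ca, t, 0), rep(0, length(t)))
  expect_error(tissue_curve(ca, t, -1), "true_mbf")

  # discrete unit impulse: the tissue curve is the Fermi kernel itself, with
  # initial height true_mbf in flow units
  dt <- 1
  imp <- c(1 / dt, rep(0, length(t) - 1))
  ct <- tissue_curve(imp, t, 2.5, shape = c(0.5, 3, 0))
  expect_equal(60 * ct[1], 2.5, tolerance = 1e-12)
  expect_true(all(diff(ct) <= 1e-12))  # non-increasing kernel

  # linearity in flow
  c1 <- tissue_curve(ca, t, 1.3)
  c2 <- tissue_curve(ca, t, 2.6)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))
})

test_that("phantom slice masks the annulus and encodes the profile", {
  t <- default_times()
  ca <- default_aif(t)
  geom <- small_geometry()
  ph <- phantom_slice(geom, function(d) rep(2, length(d)), ca, t)

  # brute-force pixel-center distance check
  px <- seq_len(geom$grid_size) - 1
  cnt <- 0L
  for (x in px) for (y in px) {
    d <- sqrt((x - geom$center[1])^2 + (y - geom$center[2])^2)
    if (d >= geom$endo_radius && d < geom$epi_radius) cnt <- cnt + 1L
  }
  expect_identical(sum(ph$truth$mask), cnt)
  expect_identical(ncol(ph$curves), cnt)  # mask conservation
  expect_true(all(ph$truth$values[ph$truth$mask] == 2))

  # monotone transmural profile: inner-half truth below outer-half truth
  ph2 <- phantom_slice(geom, function(d) 1.5 + d, ca, t)
  dist <- sqrt(outer((px - geom$center[1])^2, (px - geom$center[2])^2, "+"))
  depth <- (dist - geom$endo_radius) / (geom$epi_radius - geom$endo_radius)
  inner <- ph2$truth$mask & depth < 0.5
  outer_ <- ph2$truth$mask & depth >= 0.5
  expect_lt(mean(ph2$truth$values[inner]), mean(ph2$truth$values[outer_]))

  # seeded noise is reproducible bit for bit
  a <- phantom_slice(geom, aif = ca, times = t, noise_sd = 0.05, seed = 7)
  b <- phantom_slice(geom, aif = ca, times = t, noise_sd = 0.05, seed = 7)
  expect_identical(a$curves, b$curves)
})

test_that("beat-gated frame times follow the clock model", {
  expect_equal(beat_times(5, "sinus", mean_hr = 60), 1:5)
  expect_equal(beat_times(4, "sinus", mean_hr = 80), (60 / 80) * (1:4))
  expect_error(beat_times(5, mean_hr = 0), "mean_hr")
  expect_error(beat_times(0), "n_frames")

  tt <- beat_times(1000, "af", rr_cv = 0.25, seed = 11)
  rr <- diff(c(0, tt))
  expect_true(all(rr > 0))
  expect_lt(abs(stats::sd(rr) / mean(rr) - 0.25), 0.05)
  expect_identical(tt, beat_times(1000, "af", rr_cv = 0.25, seed = 11))
})

test_that("synthetic cohort is calibrated, conserves counts and is seeded", {
  expect_identical(nrow(make_cohort(cohort_spec(0, 0), seed = 1)), 0L)

  co <- make_cohort(cohort_spec(), seed = 3)
  expect_identical(sum(co$rhythm == "af"), 63L)
  expect_identical(sum(co$rhythm == "sinus"), 379L)
  med_af <- median(co$stress_mbf[co$rhythm == "af"])
  med_si <- median(co$stress_mbf[co$rhythm == "sinus"])
  expect_gt(med_af, 1.5); expect_lt(med_af, 2.2)
  expect_gt(med_si, 2.0); expect_lt(med_si, 2.8)
  expect_identical(co, make_cohort(cohort_spec(), seed = 3))

  # AF-lower stress MBF has the expected sign across seeds
  signs <- vapply(1:20, function(s) {
    x <- make_cohort(cohort_spec(), seed = s)
    median(x$stress_mbf[x$rhythm == "af"]) <
      median(x$stress_mbf[x$rhythm == "sinus"])
  }, logical(1))
  expect_true(all(signs))

  # endo and epi means reconstruct the global value
  expect_equal((co$stress_endo_mbf + co$stress_epi_mbf) / 2, co$stress_mbf,
               tolerance = 1e-12)
  # rest MBF only for adenosine patients with rest imaging
  expect_true(all(is.na(co$rest_mbf[co$agent == "regadenoson"])))
  expect_true(all(is.na(co$splenic_switch_off[co$agent == "regadenoson"])))
  expect_true(all(co$splenic_switch_off[co$agent == "adenosine"]))
})
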