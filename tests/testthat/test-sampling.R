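# Transmural polar sampling grid, AHA segment labels, map sampling,
# aggregation.

circle_contours <- function(level = "mid", center = c(40, 40), r_endo = 20,
                            r_epi = 30, rv_angle = pi, n = 720) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour_set(level,
              endo = cbind(center[1] + r_endo * cos(th),
                           center[2] + r_endo * sin(th)),
              epi = cbind(center[1] + r_epi * cos(th),
                          center[2] + r_epi * sin(th)),
              rv_insertion = center + r_epi * c(cos(rv_angle), sin(rv_angle)))
}

test_that("grid has 600 band-center points at analytic radii on circles", {
  ct <- circle_contours()
  g <- build_sampling_grid(ct)
  expect_identical(nrow(g), 600L)
  expect_identical(as.integer(table(g$layer_index)), rep(60L, 10))
  r <- sqrt((g$x - 40)^2 + (g$y - 40)^2)
  expect_equal(r, 20 + (g$layer_index + 0.5), tolerance = 0.02)
  # every point lies inside the annulus
  expect_true(all(r > 20 & r < 30))
})

test_that("contour validation enforces nesting and RV insertion placement", {
  th <- 2 * pi * (0:99) / 100
  big <- cbind(50 + 30 * cos(th), 50 + 30 * sin(th))
  small <- cbind(50 + 10 * cos(th), 50 + 10 * sin(th))
  expect_error(contour_set("mid", big, small, c(20, 50)), "inside")
  expect_error(contour_set("mid", small, big, c(50, 50)), "rv_insertion")
  expect_error(build_sampling_grid(
    contour_set("mid", small, big, c(20, 50)), n_circ = 60), NA)
})

test_that("rotating contours and RV insertion rotates the grid with labels", {
  g1 <- build_sampling_grid(circle_contours(rv_angle = pi))
  g2 <- build_sampling_grid(circle_contours(rv_angle = pi + pi / 2))
  # 90 degree rotation about the center maps positions onto each other
  x1 <- g1$x - 40; y1 <- g1$y - 40
  expect_equal(-y1, g2$x - 40, tolerance = 1e-8)
  expect_equal(x1, g2$y - 40, tolerance = 1e-8)
  expect_identical(g1$circ_index, g2$circ_index)
  expect_identical(g1$layer_index, g2$layer_index)
  expect_identical(g1$aha_segment, g2$aha_segment)
})

test_that("AHA segment labels partition slices as 6/6/4 sectors", {
  gb <- build_sampling_grid(circle_contours("basal"))
  gm <- build_sampling_grid(circle_contours("mid"))
  ga <- build_sampling_grid(circle_contours("apical"))
  expect_identical(as.integer(table(gb$aha_segment)), rep(100L, 6))
  expect_identical(sort(unique(gb$aha_segment)), 1:6)
  expect_identical(sort(unique(gm$aha_segment)), 7:12)
  expect_identical(as.integer(table(ga$aha_segment)), rep(150L, 4))
  expect_identical(sort(unique(ga$aha_segment)), 13:16)
  # apical cap (17) never appears across a three-slice study
  expect_identical(sort(unique(c(gb$aha_segment, gm$aha_segment,
                                 ga$aha_segment))), 1:16)
  expect_error(assign_aha_segments(0, "cap"), "slice_level")
  # boundary angle belongs to the sector whose lower edge it lies on
  expect_identical(assign_aha_segments(c(0, pi / 3, 2 * pi / 3), "basal"),
                   c(1L, 2L, 3L))
})

test_that("bilinear sampling is exact on constant and linear fields", {
  ct <- circle_contours(center = c(32, 32), r_endo = 10, r_epi = 15)
  g <- build_sampling_grid(ct)
  const <- mbf_map(matrix(2, 64, 64))
  expect_equal(sample_map(const, g)$value, rep(2, 600))
  ramp <- mbf_map(outer(0:63, rep(1, 64)))  # f(x, y) = x
  expect_equal(sample_map(ramp, g)$value, g$x, tolerance = 1e-10)
  # fully masked-out neighborhoods are flagged missing
  hole <- matrix(2, 64, 64); hole[1:64, 1:64] <- 2
  m2 <- mbf_map(hole, mask = matrix(FALSE, 64, 64) | row(hole) > 40)
  g2 <- sample_map(m2, g)
  expect_true(any(is.na(g2$value)))
  expect_error(sample_map(const, transform(g, x = x + 100)), "outside")
})

test_that("aggregation reproduces brute-force means and partitions layers", {
  levels <- c("basal", "mid", "apical")
  grids <- lapply(levels, function(l) {
    g <- build_sampling_grid(circle_contours(l, center = c(32, 32),
                                             r_endo = 10, r_epi = 15))
    g$value <- NA_real_
    g
  })
  # constant field
  for (i in 1:3) grids[[i]]$value <- 2
  s <- aggregate_grids(grids)
  expect_identical(s$n_points, 1800L)
  expect_equal(c(s$global_mbf, s$endo_mbf, s$epi_mbf), c(2, 2, 2))

  # endo 1, epi 3 split
  for (i in 1:3) grids[[i]]$value <- ifelse(grids[[i]]$layer_index < 5, 1, 3)
  s2 <- aggregate_grids(grids)
  expect_equal(c(s2$global_mbf, s2$endo_mbf, s2$epi_mbf), c(2, 1, 3))

  # random values match a direct oracle; global = mean(endo, epi)
  set.seed(9)
  for (i in 1:3) grids[[i]]$value <- runif(600, 0.5, 4)
  s3 <- aggregate_grids(grids)
  allv <- unlist(lapply(grids, `[[`, "value"))
  expect_equal(s3$global_mbf, mean(allv), tolerance = 1e-14)
  expect_equal(s3$global_mbf, (s3$endo_mbf + s3$epi_mbf) / 2,
               tolerance = 1e-14)
  segs <- unlist(lapply(grids, `[[`, "aha_segment"))
  expect_equal(unname(s3$segment_mbf[as.character(1)]),
               mean(allv[segs == 1]), tolerance = 1e-14)
  expect_identical(length(s3$segment_mbf), 16L)
})

test_that("endo/epi ratio behaves as a plain quotient with guarded zero", {
  expect_equal(endo_epi_ratio(2, 2), 1)
  expect_equal(endo_epi_ratio(1.9, 2.0), 0.95)
  expect_error(endo_epi_ratio(1, 0), "epicardial")
  g <- build_sampling_grid(circle_contours(center = c(32, 32), r_endo = 10,
                                           r_epi = 15))
  g$value <- 2
  expect_equal(endo_epi_ratio(aggregate_grids(list(g))), 1)
})
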