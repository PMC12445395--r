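#' Phantom slice geometry
#'
#' Annular left-ventricular myocardium on a square pixel grid. Coordinates are
#' 0-based pixel centers; the value grid is indexed `[x + 1, y + 1]`.
#'
#' @param grid_size pixels per side.
#' @param center numeric `c(x, y)` in pixel units; defaults to the grid center.
#' @param endo_radius,epi_radius endocardial/epicardial radii, pixels; must
#'   satisfy `0 < endo_radius < epi_radius < grid_size / 2`.
#' @param rv_insertion_angle angle of the superior RV insertion point on the
#'   epicardial contour, radians.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid_size = 128, center = NULL,
                             endo_radius = grid_size / 6.4,
                             epi_radius = grid_size / 4.27,
                             rv_insertion_angle = pi) {
  if (is.null(center)) center <- c(1, 1) * (grid_size - 1) / 2
  if (!(endo_radius > 0 && endo_radius < epi_radius &&
        epi_radius < grid_size / 2))
    stop_invalid("radii must satisfy 0 < endo < epi < grid_size/2")
  structure(list(grid_size = as.integer(grid_size), center = center,
                 endo_radius = endo_radius, epi_radius = epi_radius,
                 rv_insertion_angle = rv_insertion_angle),
            class = "phantom_geometry")
}

circle_polygon <- function(center, radius, n = 180) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

geometry_contours <- function(geometry, slice_level = "mid", n_vertices = 180) {
  rv <- geometry$center + geometry$epi_radius *
    c(cos(geometry$rv_insertion_angle), sin(geometry$rv_insertion_angle))
  contour_set(slice_level = slice_level,
              endo = circle_polygon(geometry$center, geometry$endo_radius, n_vertices),
              epi = circle_polygon(geometry$center, geometry$epi_radius, n_vertices),
              rv_insertion = rv)
}

#' Synthetic first-pass perfusion slice with known ground truth
#'
#' Builds an annular myocardial phantom: every pixel whose center lies between
#' the endocardial and epicardial radii receives a true MBF from
#' `transmural_profile` evaluated at its normalized transmural depth (0 at the
#' endocardial border, 1 at the epicardial border), and a tissue curve equal
#' to the Fermi forward model ([tissue_curve()]) plus zero-mean Gaussian noise.
#'
#' @param geometry a [phantom_geometry()].
#' @param transmural_profile function mapping depth in `[0, 1]` to MBF
#'   (mL/min/g); default uniform 2.0.
#' @param aif AIF curve on `times`.
#' @param times frame times, seconds.
#' @param noise_sd Gaussian noise SD in concentration units (0 = noiseless).
#' @param seed optional seed for the noise draw.
#' @param shape Fermi kernel shape `c(k, w, delay)` of the forward model.
#' @param slice_level `"basal"`, `"mid"` or `"apical"` (metadata on contours).
#' @return List with `truth` (an [mbf_map()] of true values), `curves` (matrix,
#'   one column per masked pixel in `which(mask)` order), `contours`
#'   (a [contour_set()]), `times` and `aif`.
#' @export
phantom_slice <- function(geometry, transmural_profile = function(d) rep(2, length(d)),
                          aif, times, noise_sd = 0, seed = NULL,
                          shape = c(0.5, 3, 0), slice_level = "mid") {
  stopifnot(inherits(geometry, "phantom_geometry"))
  check_times(times)
  n <- geometry$grid_size
  px <- seq_len(n) - 1
  dx <- outer(px - geometry$center[1], rep(1, n))
  dy <- outer(rep(1, n), px - geometry$center[2])
  dist <- sqrt(dx^2 + dy^2)
  mask <- dist >= geometry$endo_radius & dist < geometry$epi_radius
  depth <- (dist - geometry$endo_radius) /
    (geometry$epi_radius - geometry$endo_radius)
  truth <- matrix(NA_real_, n, n)
  truth[mask] <- transmural_profile(depth[mask])
  if (any(truth[mask] < 0)) stop_invalid("transmural_profile returned negative MBF")

  # tissue_curve is linear in MBF: compute a unit-flow curve once and scale
  unit <- tissue_curve(aif, times, 1, shape = shape)
  curves <- outer(unit, truth[mask])
  if (noise_sd > 0)
    curves <- curves + with_seed(seed,
      matrix(stats::rnorm(length(curves), sd = noise_sd), nrow = nrow(curves)))
  list(truth = mbf_map(truth, mask),
       curves = curves,
       contours = geometry_contours(geometry, slice_level),
       times = times, aif = aif)
}

#' Beat-gated frame times
#'
#' Frame timestamps of a beat-gated acquisition: cumulative sums of R-R
#' intervals. In `sinus` mode with `rr_cv = 0` the frames form an arithmetic
#' sequence with step `60 / mean_hr`; otherwise R-R intervals are drawn from a
#' gamma distribution with mean `60 / mean_hr` and coefficient of variation
#' `rr_cv` (the `af` mode uses an irregular default CV of 0.25).
#'
#' @param n_frames number of frames (>= 1).
#' @param mode `"sinus"` or `"af"`.
#' @param mean_hr mean heart rate, beats/min (> 0).
#' @param rr_cv coefficient of variation of the R-R intervals; defaults to 0
#'   for sinus and 0.25 for af.
#' @param seed optional seed.
#' @return Vector of `n_frames` strictly increasing times (seconds), starting
#'   at the first R-R interval.
#' @export
beat_times <- function(n_frames, mode = c("sinus", "af"), mean_hr = 60,
                       rr_cv = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  if (!is.finite(mean_hr) || mean_hr <= 0) stop_invalid("mean_hr must be > 0")
  if (is.null(rr_cv)) rr_cv <- if (mode == "af") 0.25 else 0
  if (rr_cv < 0) stop_invalid("rr_cv must be >= 0")
  rr_mean <- 60 / mean_hr
  rr <- if (rr_cv == 0) rep(rr_mean, n_frames) else with_seed(seed, {
    shp <- 1 / rr_cv^2
    stats::rgamma(n_frames, shape = shp, scale = rr_mean / shp)
  })
  cumsum(rr)
}
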