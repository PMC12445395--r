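#' Myocardial contour set for one short-axis slice
#'
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @param endo,epi closed polygons (2-column `x, y` matrices, continuous pixel
#'   coordinates, 0-based pixel centers; the closing edge last-to-first vertex
#'   is implicit). Every endo vertex must lie inside the epi polygon.
#' @param rv_insertion superior right-ventricular insertion point `c(x, y)`;
#'   must lie on or near (within 2 px of) the epicardial contour.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(slice_level = c("basal", "mid", "apical"),
                        endo, epi, rv_insertion) {
  slice_level <- match.arg(slice_level)
  endo <- as.matrix(endo); epi <- as.matrix(epi)
  if (ncol(endo) != 2 || ncol(epi) != 2 || nrow(endo) < 3 || nrow(epi) < 3)
    stop_invalid("contours must be polygons with >= 3 (x, y) vertices")
  if (!all(point_in_polygon(endo, epi)))
    stop_invalid("endocardial contour must lie strictly inside the epicardial contour")
  if (dist_to_polygon(rv_insertion, epi) > 2)
    stop_invalid("rv_insertion must lie within 2 px of the epicardial contour")
  structure(list(slice_level = slice_level, endo = endo, epi = epi,
                 rv_insertion = as.numeric(rv_insertion)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set (%s): endo %d vertices, epi %d vertices, RV insertion (%.1f, %.1f)\n",
              x$slice_level, nrow(x$endo), nrow(x$epi),
              x$rv_insertion[1], x$rv_insertion[2]))
  invisible(x)
}

# even-odd point-in-polygon test, vectorized over points
point_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  nv <- nrow(poly)
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[c(nv, seq_len(nv - 1)), 1]; yj <- poly[c(nv, seq_len(nv - 1)), 2]
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(nv)) {
    crosses <- (yi[k] > pts[, 2]) != (yj[k] > pts[, 2])
    xint <- (xj[k] - xi[k]) * (pts[, 2] - yi[k]) / (yj[k] - yi[k]) + xi[k]
    inside <- xor(inside, crosses & pts[, 1] < xint)
  }
  inside
}

dist_to_polygon <- function(p, poly) {
  nv <- nrow(poly)
  a <- poly
  b <- poly[c(2:nv, 1), ]
  ab <- b - a
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  t <- (ap[, 1] * ab[, 1] + ap[, 2] * ab[, 2]) /
    pmax(ab[, 1]^2 + ab[, 2]^2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  dx <- a[, 1] + t * ab[, 1] - p[1]
  dy <- a[, 2] + t * ab[, 2] - p[2]
  sqrt(min(dx^2 + dy^2))
}

# first positive ray-polygon intersection distance from `origin` along `dir`
ray_polygon_t <- function(origin, dir, poly) {
  nv <- nrow(poly)
  a <- poly
  b <- poly[c(2:nv, 1), ]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  denom <- dir[1] * ey - dir[2] * ex
  ok <- abs(denom) > .Machine$double.eps
  wx <- a[, 1] - origin[1]; wy <- a[, 2] - origin[2]
  t <- (wx * ey - wy * ex) / denom          # distance along the ray
  s <- (wx * dir[2] - wy * dir[1]) / -denom # position along the edge
  hit <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
  if (!any(hit)) return(NA_real_)
  min(t[hit])
}

#' Build the 60 x 10 transmural sampling grid for one slice
#'
#' Casts `n_circ` angular spokes from the myocardial centroid (mean of the
#' epicardial vertices), with spoke 0 through the RV insertion point and
#' subsequent spokes proceeding clockwise in standard short-axis display
#' orientation (y down). Each spoke is intersected with both contours and
#' sampled at transmural fractions `(j + 0.5) / n_layers` between the
#' endocardial and epicardial crossings, giving band-center positions for
#' `n_layers` transmural layers (layer 0 adjacent to the endocardium).
#' AHA segment labels are attached via [assign_aha_segments()].
#'
#' @param contours a [contour_set()].
#' @param n_circ circumferential spokes (default 60).
#' @param n_layers transmural layers (default 10).
#' @return A `sampling_grid` data frame with columns `slice_level`,
#'   `circ_index` (0-based), `layer_index` (0-based), `x`, `y`, `angle`,
#'   `aha_segment` and `value` (NA until [sample_map()] fills it); exactly
#'   `n_circ * n_layers` rows.
#' @export
build_sampling_grid <- function(contours, n_circ = 60, n_layers = 10) {
  stopifnot(inherits(contours, "contour_set"))
  centroid <- colMeans(contours$epi)
  rv <- contours$rv_insertion - centroid
  a0 <- atan2(rv[2], rv[1])
  m <- seq_len(n_circ) - 1
  # +angle is clockwise on screen with the y axis pointing down
  ang <- a0 + 2 * pi * m / n_circ
  rows <- vector("list", n_circ)
  for (i in seq_len(n_circ)) {
    d <- c(cos(ang[i]), sin(ang[i]))
    t_endo <- ray_polygon_t(centroid, d, contours$endo)
    t_epi <- ray_polygon_t(centroid, d, contours$epi)
    if (!is.finite(t_endo) || !is.finite(t_epi) || t_epi <= t_endo)
      stop_invalid("spoke %d (angle %.1f deg) does not intersect both contours",
                   m[i], 360 * m[i] / n_circ)
    fr <- (seq_len(n_layers) - 0.5) / n_layers
    tt <- t_endo + fr * (t_epi - t_endo)
    rows[[i]] <- data.frame(
      slice_level = contours$slice_level,
      circ_index = m[i], layer_index = seq_len(n_layers) - 1L,
      x = centroid[1] + tt * d[1], y = centroid[2] + tt * d[2],
      angle = 2 * pi * m[i] / n_circ)
  }
  grid <- do.call(rbind, rows)
  grid$aha_segment <- assign_aha_segments(grid$angle, contours$slice_level)
  grid$value <- NA_real_
  class(grid) <- c("sampling_grid", "data.frame")
  grid
}

#' AHA 17-segment labels for polar sampling angles
#'
#' Maps circumferential angles (radians clockwise from the superior RV
#' insertion point) to AHA segment ids: basal slices cover segments 1-6 and
#' mid slices 7-12 in 60-degree sectors; apical slices cover segments 13-16 in
#' 90-degree sectors. The apical cap (segment 17) is not covered by short-axis
#' slices. A boundary angle belongs to the sector whose lower edge it lies on.
#'
#' @param angle radians in `[0, 2*pi)` from the RV insertion spoke.
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @return Integer segment ids.
#' @export
assign_aha_segments <- function(angle, slice_level) {
  if (!slice_level %in% c("basal", "mid", "apical"))
    stop_invalid("unknown slice_level '%s'", slice_level)
  a <- angle %% (2 * pi)
  eps <- 1e-9  # boundary angles belong to the sector they open
  if (slice_level == "apical") {
    13L + as.integer(floor(a / (pi / 2) + eps)) %% 4L
  } else {
    base <- if (slice_level == "basal") 1L else 7L
    base + as.integer(floor(a / (pi / 3) + eps)) %% 6L
  }
}

#' Sample an MBF map at grid positions
#'
#' Bilinear interpolation of the map at each sampling position (0-based
#' pixel-center coordinates). Neighborhood pixels outside the myocardial mask
#' are excluded and the interpolation weights renormalized over the masked
#' neighbors; positions whose whole 4-pixel neighborhood is masked out yield a
#' flagged `NA` value, excluded from aggregation (the count is reported by
#' [aggregate_grids()]).
#'
#' @param map an [mbf_map()].
#' @param grid a `sampling_grid` from [build_sampling_grid()].
#' @return The grid with its `value` column filled.
#' @export
sample_map <- function(map, grid) {
  stopifnot(inherits(map, "mbf_map"))
  v <- map$values
  nx <- nrow(v); ny <- ncol(v)
  if (any(grid$x < 0 | grid$x > nx - 1 | grid$y < 0 | grid$y > ny - 1))
    stop_invalid("sampling position outside the image bounds")
  x0 <- pmin(floor(grid$x), nx - 2); y0 <- pmin(floor(grid$y), ny - 2)
  fx <- grid$x - x0; fy <- grid$y - y0
  val <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ix <- x0[i] + 1L; iy <- y0[i] + 1L
    nb <- c(v[ix, iy], v[ix + 1L, iy], v[ix, iy + 1L], v[ix + 1L, iy + 1L])
    w <- c((1 - fx[i]) * (1 - fy[i]), fx[i] * (1 - fy[i]),
           (1 - fx[i]) * fy[i], fx[i] * fy[i])
    ok <- !is.na(nb)
    val[i] <- if (!any(ok) || sum(w[ok]) <= 0) NA_real_
              else sum(w[ok] * nb[ok]) / sum(w[ok])
  }
  grid$value <- val
  grid
}

#' Aggregate sampled grids to a perfusion summary
#'
#' Combines the sampled grids of all slices of one state into the standard
#' summary: global MBF is the unweighted mean over all sampled points (1800
#' for a three-slice study), endocardial MBF the mean over the inner half of
#' the wall (layers 0-4), epicardial MBF the mean over the outer half (layers
#' 5-9), plus per-AHA-segment means.
#'
#' @param ... sampled `sampling_grid` objects (or a single list of them).
#' @param state `"stress"` or `"rest"`.
#' @return An object of class `perfusion_summary` with elements `global_mbf`,
#'   `endo_mbf`, `epi_mbf`, `segment_mbf` (named by segment id), `n_points`,
#'   `n_missing` and `state`.
#' @export
aggregate_grids <- function(..., state = c("stress", "rest")) {
  state <- match.arg(state)
  grids <- list(...)
  if (length(grids) == 1L && !inherits(grids[[1]], "data.frame"))
    grids <- grids[[1]]
  pts <- do.call(rbind, lapply(grids, as.data.frame))
  n_layers <- max(pts$layer_index) + 1L
  ok <- !is.na(pts$value)
  if (!any(ok)) stop_invalid("no valid sampled points to aggregate")
  inner <- pts$layer_index < n_layers / 2
  seg_means <- tapply(pts$value[ok], pts$aha_segment[ok], mean)
  structure(list(
    global_mbf = mean(pts$value[ok]),
    endo_mbf = mean(pts$value[ok & inner]),
    epi_mbf = mean(pts$value[ok & !inner]),
    segment_mbf = seg_means,
    n_points = sum(ok), n_missing = sum(!ok),
    state = state), class = "perfusion_summary")
}

#' @export
print.perfusion_summary <- function(x, ...) {
  cat(sprintf("Perfusion summary (%s), %d points%s\n", x$state, x$n_points,
              if (x$n_missing) sprintf(" (%d missing)", x$n_missing) else ""))
  cat(sprintf("  global %.3f | endo %.3f | epi %.3f mL/min/g | endo/epi %.3f\n",
              x$global_mbf, x$endo_mbf, x$epi_mbf, endo_epi_ratio(x)))
  invisible(x)
}

#' Endocardial-to-epicardial perfusion ratio
#'
#' Values below 1 indicate relative subendocardial hypoperfusion.
#'
#' @param summary a `perfusion_summary`, or the endocardial MBF if `epi` is
#'   given.
#' @param epi epicardial MBF (mL/min/g) when calling with two scalars.
#' @return `endo_mbf / epi_mbf`.
#' @export
endo_epi_ratio <- function(summary, epi = NULL) {
  if (inherits(summary, "perfusion_summary")) {
    endo <- summary$endo_mbf; epi <- summary$epi_mbf
  } else endo <- summary
  if (is.null(epi) || !is.finite(epi) || epi <= 0)
    stop_invalid("epicardial MBF must be > 0")
  endo / epi
}
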