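#' Fermi impulse-response function
#'
#' The tissue impulse response used throughout the package is the Fermi
#' function
#' \deqn{h(t) = \frac{A}{1 + \exp[(t - t_d - w)\,k]}, \quad t \ge t_d;
#'       \qquad h(t) = 0, \quad t < t_d}
#' with amplitude `A` (per-second flow units), decay rate `k` (1/s), width `w`
#' (s) and delay `t_d` (s). It is non-increasing for `t >= t_d` and its initial
#' height is `h(t_d) = A / (1 + exp(-w k))`, which encodes blood flow (see
#' [mbf_from_params()]).
#'
#' @param t time, seconds (vector).
#' @param params a [fermi_params()] object or a numeric vector
#'   `c(amplitude_A, decay_k, width_w, delay_td)`.
#' @return Impulse-response values, same length as `t`.
#' @examples
#' fermi_ir(0, fermi_params(1, 1, 2, 0))  # 1 / (1 + exp(-2))
#' @export
fermi_ir <- function(t, params) {
  p <- as_fermi_params(params)
  out <- p[["amplitude_A"]] /
    (1 + exp((t - p[["delay_td"]] - p[["width_w"]]) * p[["decay_k"]]))
  out[t < p[["delay_td"]]] <- 0
  out
}

#' Fermi impulse-response parameters
#'
#' @param amplitude_A amplitude, per-second flow units (>= 0).
#' @param decay_k decay rate, 1/s (>= 0).
#' @param width_w shoulder width, s (>= 0).
#' @param delay_td bolus arrival delay, s (>= 0).
#' @return A named numeric vector of class `fermi_params`.
#' @export
fermi_params <- function(amplitude_A, decay_k, width_w, delay_td = 0) {
  p <- c(amplitude_A = amplitude_A, decay_k = decay_k,
         width_w = width_w, delay_td = delay_td)
  if (any(!is.finite(p)) || any(p < 0))
    stop_invalid("all Fermi parameters must be finite and >= 0")
  structure(p, class = "fermi_params")
}

as_fermi_params <- function(x) {
  if (inherits(x, "fermi_params")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(fermi_params(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop_invalid("expected a fermi_params object or a numeric vector of length 4")
}

#' Myocardial blood flow implied by Fermi parameters
#'
#' Blood flow equals the initial height of the impulse response converted from
#' per-second to per-minute units and normalized by tissue density:
#' `MBF = 60 * h(delay_td) / density` with `h(delay_td) = A / (1 + exp(-w k))`.
#' Curves are assumed to be in consistent arbitrary linear concentration units
#' on a time axis in seconds.
#'
#' @param params [fermi_params()] or numeric vector of length 4.
#' @param density tissue density normalization, g/mL (default 1).
#' @return MBF in mL/min/g.
#' @export
mbf_from_params <- function(params, density = 1) {
  p <- as_fermi_params(params)
  if (density <= 0) stop_invalid("density must be > 0")
  60 * p[["amplitude_A"]] /
    (1 + exp(-p[["width_w"]] * p[["decay_k"]])) / density
}

# amplitude that makes 60 * h(td) / density equal `mbf`
amplitude_for_mbf <- function(mbf, decay_k, width_w, density = 1) {
  mbf * density * (1 + exp(-width_w * decay_k)) / 60
}

#' Forward model: tissue curve from AIF and Fermi kernel
#'
#' Convolves an AIF with a Fermi impulse response whose initial height encodes
#' the requested blood flow, using left-Riemann discrete convolution scaled by
#' the frame interval. On an irregular time axis (e.g. beat-gated frames in
#' atrial fibrillation) both curves are linearly interpolated onto a uniform
#' grid at the median frame interval, convolved there, and interpolated back.
#'
#' @param aif AIF concentration curve, same length as `times`.
#' @param times strictly increasing frame times, seconds.
#' @param true_mbf blood flow encoded in the kernel, mL/min/g (>= 0).
#' @param shape kernel shape `c(decay_k, width_w, delay_td)`.
#' @param density tissue density, g/mL.
#' @return Tissue concentration curve, same length as `times`.
#' @export
tissue_curve <- function(aif, times, true_mbf, shape = c(0.5, 3, 0),
                         density = 1) {
  check_times(times)
  if (length(aif) != length(times))
    stop_invalid("aif and times must have the same length")
  if (!is.finite(true_mbf) || true_mbf < 0)
    stop_invalid("true_mbf must be finite and >= 0")
  if (true_mbf == 0) return(numeric(length(times)))
  A <- amplitude_for_mbf(true_mbf, shape[[1]], shape[[2]], density)
  p <- fermi_params(A, shape[[1]], shape[[2]], shape[[3]])
  if (is_uniform_spacing(times)) {
    dt <- times[2] - times[1]
    h <- fermi_ir(times - times[1], p)
    pmax(conv_lr(aif, h, dt), 0)  # clamp FFT round-off
  } else {
    dt <- stats::median(diff(times))
    tg <- seq(times[1], times[length(times)], by = dt)
    ag <- stats::approx(times, aif, tg, rule = 2)$y
    hg <- fermi_ir(tg - tg[1], p)
    cg <- pmax(conv_lr(ag, hg, dt), 0)
    stats::approx(tg, cg, times, rule = 2)$y
  }
}

# ---- first-pass window -----------------------------------------------------

# Identify the fit window on a baseline-subtracted AIF. The arterial first
# pass runs from the AIF onset to the first sustained local minimum after the
# AIF peak (the dip before recirculation; fallback_frames when absent). The
# fit window is then extended past the arterial dip by `extend` times the
# arterial first-pass duration, so that the delayed tissue washout — which is
# what pins down the kernel decay — stays inside the fitted range.
first_pass_window <- function(aif, onset_frac = 0.05, fallback_frames = 30,
                              extend = 1) {
  n <- length(aif)
  pk <- which.max(aif)
  if (!is.finite(aif[pk]) || aif[pk] <= 0)
    stop_invalid("AIF has no positive peak inside the time axis")
  onset <- which(aif > onset_frac * aif[pk])[1]
  dip <- n
  if (pk < n - 1L) {
    for (i in (pk + 1L):(n - 1L)) {
      rising_next <- aif[i + 1L] > aif[i]
      rising_after <- i + 2L > n || aif[min(i + 2L, n)] >= aif[i]
      if (rising_next && rising_after) { dip <- i; break }
    }
  }
  if (dip - onset < 10L) dip <- min(n, onset + fallback_frames)
  end <- min(n, dip + as.integer(round(extend * (dip - onset))))
  list(onset = onset, end = end, dip = dip, peak = pk)
}

#' Fit options for Fermi-constrained deconvolution
#'
#' @param baseline_frames frames averaged for baseline subtraction (default 5).
#' @param density tissue density normalization, g/mL.
#' @param onset_frac AIF onset threshold as a fraction of the AIF peak.
#' @param fallback_frames arterial first-pass length used when no post-peak
#'   minimum is found.
#' @param window_extend fit-window extension beyond the arterial first-pass
#'   dip, as a multiple of the arterial first-pass duration (default 1); the
#'   extension keeps the delayed tissue washout inside the fitted range,
#'   which is what constrains the kernel decay at pixel-level noise.
#' @param lower,upper box constraints on `(A, k, w, td)`.
#' @param starts list of fixed multi-start initializations of `(k, w, td)`;
#'   the amplitude start is derived from the data scale.
#' @param maxiter,ftol,ptol Levenberg-Marquardt control.
#' @return A list of class `fermi_options`.
#' @export
fermi_options <- function(baseline_frames = 5, density = 1,
                          onset_frac = 0.05, fallback_frames = 30,
                          window_extend = 1,
                          lower = c(0, 0, 0, 0), upper = c(Inf, 10, 30, 10),
                          starts = list(c(0.5, 3, 0), c(0.15, 8, 0), c(1.2, 1.5, 1)),
                          maxiter = 200, ftol = 1e-10, ptol = 1e-10) {
  structure(list(baseline_frames = baseline_frames, density = density,
                 onset_frac = onset_frac, fallback_frames = fallback_frames,
                 window_extend = window_extend,
                 lower = lower, upper = upper, starts = starts,
                 maxiter = maxiter, ftol = ftol, ptol = ptol),
            class = "fermi_options")
}

subtract_baseline <- function(x, nb) {
  nb <- min(nb, length(x) - 1L)
  if (nb < 1L) return(x)
  x - mean(x[seq_len(nb)])
}

# core single-curve fit on a uniform grid; returns params, rss, convergence
fit_fermi_curve <- function(tk, aif, tissue, win, dt, options) {
  model_fun <- function(p) conv_lr(aif, fermi_ir(tk, p), dt)[win]
  y <- tissue[win]
  if (all(abs(y) < .Machine$double.eps^0.5)) {
    p <- c(0, options$starts[[1]])
    return(list(params = p, rss = 0, converged = TRUE, n_eval = 0L))
  }
  # data-driven delay start: tissue onset lag behind the AIF onset
  onset_of <- function(v) {
    i <- which(v > 0.05 * max(v))
    if (length(i)) i[1] else 1L
  }
  lag0 <- max(0, (onset_of(y) - onset_of(aif[win])) * dt)
  starts <- options$starts
  if (lag0 > dt / 2) starts <- c(starts, list(c(0.5, 3, min(lag0, 10))))
  best <- NULL
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    m0 <- model_fun(c(1, s))
    A0 <- if (max(m0) > 0) max(y) / max(m0) else 1
    for (a_scale in if (i == 1L) c(1, 0.5) else 1) {
      start <- pmin(pmax(c(max(a_scale * A0, 1e-8), s), options$lower),
                    options$upper)
      fit <- try(minpack.lm::nls.lm(
        par = start,
        fn = function(p) model_fun(p) - y,
        lower = options$lower, upper = options$upper,
        control = minpack.lm::nls.lm.control(
          maxiter = options$maxiter, ftol = options$ftol, ptol = options$ptol)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      rss <- sum(fit$fvec^2)
      cand <- list(params = fit$par, rss = rss,
                   converged = fit$info %in% 1:4, n_eval = fit$niter)
      if (is.null(best) || rss < best$rss - 1e-15 ||
          (abs(rss - best$rss) <= 1e-15 && cand$params[4] < best$params[4]))
        best <- cand
    }
  }
  if (is.null(best))
    best <- list(params = c(0, options$starts[[1]]), rss = sum(y^2),
                 converged = FALSE, n_eval = 0L)
  best
}

# canonicalize a (times, aif, tissue-matrix) triplet onto a uniform grid and
# precompute the fit window; shared by fermi_fit and map_mbf
prepare_series <- function(times, aif, tissue, options) {
  check_times(times)
  tissue <- as.matrix(tissue)
  if (length(aif) != length(times) || nrow(tissue) != length(times))
    stop_invalid("aif and tissue curves must share the time axis")
  if (all(aif == 0)) stop_invalid("AIF is identically zero")
  aif <- subtract_baseline(aif, options$baseline_frames)
  tissue <- apply(tissue, 2, subtract_baseline, nb = options$baseline_frames)
  tissue <- matrix(tissue, nrow = length(times))
  if (!is_uniform_spacing(times)) {
    dt <- stats::median(diff(times))
    tg <- seq(times[1], times[length(times)], by = dt)
    aif_g <- stats::approx(times, aif, tg, rule = 2)$y
    tis_g <- apply(tissue, 2, function(y) stats::approx(times, y, tg, rule = 2)$y)
    times <- tg; aif <- aif_g; tissue <- matrix(tis_g, nrow = length(tg))
  }
  dt <- times[2] - times[1]
  w <- first_pass_window(aif, options$onset_frac, options$fallback_frames,
                         options$window_extend)
  list(times = times, aif = aif, tissue = tissue, dt = dt,
       tk = times - times[1], win = seq_len(w$end), window = w)
}

#' Fermi-constrained deconvolution of a tissue curve
#'
#' Estimates myocardial blood flow from one dynamic tissue concentration curve
#' and its arterial input function by constrained nonlinear least squares: the
#' AIF is convolved with a Fermi impulse response ([fermi_ir()]) and the four
#' kernel parameters `(A, k, w, td)` are fitted to the baseline-subtracted
#' tissue curve over the first-pass window, under nonnegativity box
#' constraints, with bounded Levenberg-Marquardt iterations from three fixed
#' starting points (ties broken by lowest residual, then lowest delay). MBF is
#' read off as `60 * h(td) / density`.
#'
#' Irregularly spaced frame times (beat-gated acquisitions in atrial
#' fibrillation) are linearly interpolated onto a uniform grid at the median
#' frame interval before deconvolution.
#'
#' @param times frame times, seconds, strictly increasing.
#' @param aif arterial input function curve.
#' @param tissue tissue concentration curve (same length).
#' @param options a [fermi_options()] list.
#' @return An object of class `fermi_fit` with components `params`
#'   ([fermi_params()]), `mbf` (mL/min/g), `fitted`, `residuals`, `rss`,
#'   `converged`, `window`, and the (uniform-grid) data used.
#'   Non-convergence is flagged, not an error.
#' @examples
#' t <- seq(0, 60, by = 1)
#' ca <- make_aif(aif_model(), t)
#' ct <- tissue_curve(ca, t, true_mbf = 2)
#' fit <- fermi_fit(t, ca, ct)
#' coef(fit)
#' fit$mbf
#' @export
fermi_fit <- function(times, aif, tissue, options = fermi_options()) {
  prep <- prepare_series(times, aif, tissue, options)
  res <- fit_fermi_curve(prep$tk, prep$aif, prep$tissue[, 1], prep$win,
                         prep$dt, options)
  params <- fermi_params(res$params[1], res$params[2], res$params[3],
                         res$params[4])
  fitted_full <- conv_lr(prep$aif, fermi_ir(prep$tk, params), prep$dt)
  structure(list(
    params = params,
    mbf = mbf_from_params(params, options$density),
    times = prep$times, aif = prep$aif, tissue = prep$tissue[, 1],
    fitted = fitted_full, residuals = prep$tissue[, 1] - fitted_full,
    rss = res$rss, converged = res$converged,
    window = prep$window, win_idx = prep$win, dt = prep$dt,
    options = options), class = "fermi_fit")
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.fermi_fit <- function(x, ...) {
  cat("Fermi-constrained deconvolution fit\n")
  cat(sprintf("  MBF: %.3f mL/min/g%s\n", x$mbf,
              if (x$converged) "" else "  (NOT converged)"))
  cat(sprintf("  params: A = %.4g, k = %.4g 1/s, w = %.4g s, td = %.4g s\n",
              x$params[1], x$params[2], x$params[3], x$params[4]))
  cat(sprintf("  first-pass window: frames %d-%d of %d, RSS = %.4g\n",
              1L, x$window$end, length(x$times), x$rss))
  invisible(x)
}

#' @export
coef.fermi_fit <- function(object, ...) unclass(object$params)

#' @export
fitted.fermi_fit <- function(object, ...) object$fitted

#' @export
residuals.fermi_fit <- function(object, ...) object$residuals

#' @export
deviance.fermi_fit <- function(object, ...) object$rss

#' Predict a tissue curve from a fitted Fermi model
#'
#' @param object a [fermi_fit()].
#' @param times optional new time axis (seconds); defaults to the fitted axis.
#' @param aif optional new AIF on `times`; defaults to the fitted AIF.
#' @param ... unused.
#' @return Predicted tissue concentration curve.
#' @export
predict.fermi_fit <- function(object, times = NULL, aif = NULL, ...) {
  if (is.null(times) && is.null(aif)) return(object$fitted)
  if (is.null(times)) times <- object$times
  if (is.null(aif)) aif <- object$aif
  tissue_curve(aif, times, object$mbf,
               shape = unclass(object$params)[2:4],
               density = object$options$density)
}

#' Simulate noisy tissue curves from a fitted Fermi model
#'
#' Draws replicate tissue curves equal to the fitted curve plus zero-mean
#' Gaussian noise with the residual standard deviation (or `sd` if given).
#'
#' @param object a [fermi_fit()].
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param sd noise standard deviation; defaults to the residual SD over the
#'   fit window.
#' @param ... unused.
#' @return Matrix with one column per replicate.
#' @export
simulate.fermi_fit <- function(object, nsim = 1, seed = NULL, sd = NULL, ...) {
  if (is.null(sd)) {
    r <- object$residuals[object$win_idx]
    sd <- stats::sd(r)
    if (!is.finite(sd)) sd <- 0
  }
  with_seed(seed, {
    n <- length(object$fitted)
    matrix(object$fitted + stats::rnorm(n * nsim, sd = sd), nrow = n)
  })
}

#' @export
summary.fermi_fit <- function(object, ...) {
  win <- object$win_idx
  structure(list(
    mbf = object$mbf, params = object$params, converged = object$converged,
    rss = object$rss,
    sigma = stats::sd(object$residuals[win]),
    n_frames = length(object$times), window_end = object$window$end,
    dt = object$dt), class = "summary.fermi_fit")
}

#' @export
print.summary.fermi_fit <- function(x, ...) {
  cat("Fermi-constrained deconvolution fit\n\n")
  cat(sprintf("MBF estimate:     %.3f mL/min/g\n", x$mbf))
  cat(sprintf("Converged:        %s\n", x$converged))
  cat("Kernel parameters:\n")
  print(round(unclass(x$params), 5))
  cat(sprintf("Frames: %d (dt = %.3g s), first-pass window 1-%d\n",
              x$n_frames, x$dt, x$window_end))
  cat(sprintf("RSS = %.4g, residual SD = %.4g\n", x$rss, x$sigma))
  invisible(x)
}

#' Plot a Fermi deconvolution fit
#'
#' Shows the (baseline-subtracted) AIF, the tissue curve, the model fit and
#' the first-pass window boundary.
#'
#' @param x a [fermi_fit()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.fermi_fit <- function(x, ...) {
  graphics::plot(x$times, x$aif, type = "l", col = "grey40", lty = 2,
                 xlab = "time (s)", ylab = "concentration (a.u.)",
                 main = sprintf("Fermi fit: MBF = %.2f mL/min/g", x$mbf), ...)
  graphics::lines(x$times, x$tissue, col = "black")
  graphics::lines(x$times, x$fitted, col = "red3", lwd = 2)
  graphics::abline(v = x$times[x$window$end], col = "grey60", lty = 3)
  graphics::legend("topright", c("AIF", "tissue", "fit"),
                   col = c("grey40", "black", "red3"),
                   lty = c(2, 1, 1), lwd = c(1, 1, 2), bty = "n")
  invisible(x)
}
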