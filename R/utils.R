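# internal helpers shared across modules

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_invalid("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# truncated normal by rejection; bounds may be +-Inf
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- stats::rnorm(length(need), mean, sd)
    ok <- cand >= lower & cand <= upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

is_uniform_spacing <- function(times, tol = 1e-6) {
  d <- diff(times)
  diff(range(d)) <= tol * stats::median(d)
}

check_times <- function(times) {
  if (length(times) < 2L || any(!is.finite(times)) || any(diff(times) <= 0))
    stop_invalid("'times' must be a finite, strictly increasing vector")
  invisible(times)
}

# discrete causal convolution, left-Riemann scaling by the frame interval:
#   out[i] = dt * sum_{j<=i} x[j] * h[i-j+1]
conv_lr <- function(x, h, dt) {
  n <- length(x)
  stats::convolve(x, rev(h), type = "open")[seq_len(n)] * dt
}

# sd implied by an interquartile range of a normal (or log-normal on log scale)
sd_from_iqr <- function(q1, q3) (q3 - q1) / (2 * stats::qnorm(0.75))
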