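# Internal numerical helpers shared across modules.

# Gaussian density without normalisation: peak value = a at x = mu.
gauss_peak <- function(x, a, mu, sigma) {
  a * exp(-((x - mu)^2) / (2 * sigma^2))
}

# Area of an unnormalised Gaussian with peak amplitude a and width sigma.
gauss_area <- function(a, sigma) a * sigma * sqrt(2 * pi)

# Trapezoidal integral of y over x restricted to [lo, hi], with linear
# interpolation at the window edges so partial bins are weighted by overlap.
trapz_window <- function(x, y, lo = min(x), hi = max(x)) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  if (hi <= x[1] || lo >= x[length(x)]) {
    abort("integration window lies outside the profile support")
  }
  lo <- max(lo, x[1])
  hi <- min(hi, x[length(x)])
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(approx(x, y, lo)$y, y[inside], approx(x, y, hi)$y)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

# Intensity-weighted centroid of y(x) inside [lo, hi] (trapezoidal weights).
centroid_window <- function(x, y, lo, hi) {
  total <- trapz_window(x, y, lo, hi)
  if (total <= 0) abort("non-positive total intensity in centroid window")
  trapz_window(x, x * y, lo, hi) / total
}

# Fast sub-pixel peak centre via a log-parabola (Caruana) fit on a local
# window. Used for seeding and for bright, nearly Gaussian peaks such as the
# equatorial 1,0 during centring. x may be pixel index or q.
peak_centre_logparab <- function(x, y, half_width = 4L) {
  i0 <- which.max(y)
  idx <- max(1L, i0 - half_width):min(length(y), i0 + half_width)
  xs <- x[idx]
  ys <- y[idx] - min(y[idx])
  eps <- max(ys) * 1e-6 + .Machine$double.eps
  w <- ys^2
  fit <- lm(log(ys + eps) ~ xs + I(xs^2), weights = w)
  b <- coef(fit)
  if (!is.finite(b[[3]]) || b[[3]] >= 0) return(x[i0])
  ctr <- -b[[2]] / (2 * b[[3]])
  if (ctr < min(xs) || ctr > max(xs)) x[i0] else ctr
}

# Centred boxcar moving average with truncated, renormalised edges.
boxcar_smooth <- function(y, half_width) {
  if (half_width <= 0) return(y)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half_width):min(n, i + half_width)
    mean(y[idx])
  }, numeric(1))
}

# Lower convex hull of (x, y) with x strictly increasing (Andrew monotone
# chain, lower branch only). Returns indices of hull vertices.
lower_hull_idx <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(seq_len(n))
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2L) {
      j <- hull[length(hull) - 1L]
      k <- hull[length(hull)]
      # drop k if it lies above the chord j -> i
      cross <- (x[k] - x[j]) * (y[i] - y[j]) - (x[i] - x[j]) * (y[k] - y[j])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

# Deterministic child seed for per-frame rendering substreams.
frame_seed <- function(master_seed, frame_index) {
  as.integer((as.double(master_seed) * 1009 + frame_index * 9973) %% 2147483647)
}

# Evaluate an expression with a local RNG state, restoring the caller's.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rms <- function(x) sqrt(mean(x^2))
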