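# Small 2D geometry kernel. Angles are degrees everywhere at the interface;
# radians only appear inside these helpers.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# counterclockwise rotation of column points (2 x n or length-2)
rot2 <- function(theta_deg) {
  r <- deg2rad(theta_deg)
  matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2L, 2L)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) {
    abort("zero-length vector where a direction is required",
          class = "sitstand_degenerate_geometry")
  }
  v / n
}

# interior angle (degrees, in [0, 180]) at q formed by p--q--r;
# atan2 form keeps full precision near 0 and 180 where acos degrades
interior_angle <- function(p, q, r) {
  u <- unitv(p - q)
  v <- unitv(r - q)
  rad2deg(atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)))
}

# turning angle (degrees, in [0, 180]) at q: 0 when p,q,r are collinear
turning_angle <- function(p, q, r) 180 - interior_angle(p, q, r)

# centred rolling mean, window forced odd, edges use the partial window
roll_mean <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window == 1L || n < 3L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

stopifnot_finite <- function(..., what = "input") {
  vals <- c(...)
  if (!all(is.finite(vals))) {
    abort(paste0("non-finite ", what), class = "sitstand_validation_error")
  }
  invisible(vals)
}
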