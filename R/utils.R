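# Internal geometry and numerics helpers.
#
# Lab frame convention used throughout: x anterior (direction of progression),
# y left, z up; right-handed. Internal units are SI (m, N, kg, s); file
# interfaces use mm where stated.

G_ACC <- 9.81

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < .Machine$double.eps) stop("cannot normalize zero vector")
  v / n
}

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L, 3L)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3L, 3L)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L, 3L)
}

# Pelvis orientation: R = Rz(yaw) Ry(pitch) Rx(roll)
rot_zyx <- function(roll, pitch, yaw) rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)

euler_zyx <- function(R) {
  pitch <- asin(max(-1, min(1, -R[3L, 1L])))
  roll <- atan2(R[3L, 2L], R[3L, 3L])
  yaw <- atan2(R[2L, 1L], R[1L, 1L])
  c(roll = roll, pitch = pitch, yaw = yaw)
}

# Hip rotation Cardan sequence: R = Ry(fe) Rx(aa) Rz(ie).
rot_yxz <- function(fe, aa, ie) rot_y(fe) %*% rot_x(aa) %*% rot_z(ie)

euler_yxz <- function(R) {
  aa <- asin(max(-1, min(1, -R[2L, 3L])))
  fe <- atan2(R[1L, 3L], R[3L, 3L])
  ie <- atan2(R[2L, 1L], R[2L, 2L])
  c(fe = fe, aa = aa, ie = ie)
}

# Rotation about arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, angle) {
  n <- unit3(axis)
  K <- matrix(c(0, n[3L], -n[2L], -n[3L], 0, n[1L], n[2L], -n[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Smootherstep ramp: 0 for x <= a, 1 for x >= b, C2-continuous between.
smootherstep <- function(x, a, b) {
  t <- pmin(1, pmax(0, (x - a) / (b - a)))
  t^3 * (t * (t * 6 - 15) + 10)
}

# Evaluate code with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched, so generators are reproducible and side-effect free.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Zero-phase 2nd-order Butterworth low-pass with reflective padding; falls back
# to the identity for series too short to filter.
lowpass <- function(x, rate, cutoff = 6) {
  n <- length(x)
  if (n < 12 || cutoff >= rate / 2) return(x)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  npad <- min(n - 1L, 3L * ceiling(rate / cutoff))
  xp <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1L):(npad + n)]
}

# Central-difference derivative on a uniform grid (one-sided at the ends).
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  if (n > 2L) d[2L:(n - 1L)] <- (x[3L:n] - x[1L:(n - 2L)]) / (2 * dt)
  d[1L] <- (x[2L] - x[1L]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

# Filtered derivative of each column of a matrix.
deriv_filtered <- function(X, rate, cutoff = 6) {
  X <- as.matrix(X)
  apply(X, 2L, function(col) central_diff(lowpass(col, rate, cutoff), 1 / rate))
}

# Smooth correlated noise on a uniform grid: white Gaussian noise convolved
# with a Gaussian kernel (circular), rescaled to the requested sd.
smooth_noise <- function(n, sd, corr_len) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (corr_len > 0) {
    half <- max(1L, ceiling(3 * corr_len))
    k <- exp(-0.5 * ((-half:half) / corr_len)^2)
    k <- k / sum(k)
    idx <- (((1L - half):(n + half)) - 1L) %% n + 1L  # circular padding
    w <- stats::convolve(w[idx], rev(k), type = "filter")
  }
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s < .Machine$double.eps) return(numeric(n))
  w * sd / s
}
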