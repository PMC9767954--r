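#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict coef rnorm qnorm pnorm sd t.test runif setNames
#' @importFrom utils read.csv write.csv combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Signal a classed error so callers can distinguish validation, geometry,
# calibration, fit, prediction, generation, and evaluation failures.
hs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "handscreen_error", "error")))
}

hs_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "handscreen_warning", "warning")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v, what = "vector") {
  n <- vec_norm(v)
  if (!is.finite(n) || n < 1e-12) {
    hs_error(sprintf("degenerate geometry: %s has (near-)zero length", what),
             "hs_geometry_error")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rodrigues rotation of 3-vector v about unit axis by theta degrees.
rotate_about <- function(v, axis, theta_deg) {
  th <- deg2rad(theta_deg)
  ct <- cos(th)
  st <- sin(th)
  v * ct + cross3(axis, v) * st + axis * sum(axis * v) * (1 - ct)
}

# 3x3 rotation matrix from z-y-x Euler angles in degrees.
euler_rotation <- function(angles) {
  a <- deg2rad(angles)
  cz <- cos(a[1L]); sz <- sin(a[1L])
  cy <- cos(a[2L]); sy <- sin(a[2L])
  cx <- cos(a[3L]); sx <- sin(a[3L])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L, 3L)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L, 3L)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L, 3L)
  Rz %*% Ry %*% Rx
}

# Deterministic sub-seed derivation so one top-level seed fans out to stages
# without reuse. Result stays below 2^31 - 1.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(salt)) %% 2147483647)
}
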