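# Internal helpers shared across modules.

# Euclidean norm of a 3-vector (or rows of an n x 3 matrix).
vec_norm <- function(v) {
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) abort("cannot normalize a zero vector", class = "tcrmech_geometry_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# arccos with clamping; returns degrees.
acos_deg <- function(x) acos(pmin(1, pmax(-1, x))) * 180 / pi

deg2rad <- function(x) x * pi / 180

# Rotation matrix for angle theta (radians) about unit axis (Rodrigues).
rotation_matrix <- function(axis, theta) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Trailing (right-aligned) rolling mean of width k, truncated at the start:
# out[i] = mean(x[max(1, i-k+1):i]).
rolling_mean_trailing <- function(x, k) {
  stopifnot(k >= 1)
  n <- length(x)
  cs <- cumsum(x)
  lag <- c(rep(0, min(k, n)), cs[seq_len(max(0, n - k))])
  widths <- pmin(seq_len(n), k)
  (cs - lag) / widths
}

# Kabsch least-squares superposition: rotation R and translation t such that
# moving %*% R + t best fits fixed (both n x 3, matched rows).
kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3)
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  H <- t(sweep(moving, 2, cm)) %*% sweep(fixed, 2, cf)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, t = cf - as.vector(cm %*% R))
}

apply_kabsch <- function(coords, fit) {
  sweep(coords %*% fit$R, 2, fit$t, `+`)
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Stop unless x is a single finite number satisfying an optional predicate.
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "tcrmech_value_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name), class = "tcrmech_value_error")
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be >= 0", name), class = "tcrmech_value_error")
  }
  invisible(x)
}
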