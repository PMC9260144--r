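# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded sampling inside the package never perturbs the
#' user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Normalize a single 3-vector; errors on (near-)zero length.
unit3 <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v * v))
  if (n < tol) stop("cannot normalize a zero-length direction vector")
  v / n
}

# Rodrigues rotation matrix for a unit axis and angle (radians).
rotation_matrix <- function(axis, angle) {
  u <- unit3(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  c_ * diag(3) + s_ * ux + (1 - c_) * tcrossprod(u)
}

# Any two unit vectors orthogonal to d (and to each other).
orthonormal_basis <- function(d) {
  d <- unit3(d)
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(pracma_cross(ref, d))
  e2 <- pracma_cross(d, e1)
  cbind(e1, e2)
}

# 3-vector cross product (kept dependency-free).
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle in [0, pi] between two 3-vectors.
vec_angle <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("angle undefined for zero-length vector")
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

#' Low-discrepancy view directions on the upper hemisphere
#'
#' Fibonacci-lattice directions used for orientation averaging of
#' projection areas (projection area is antipodally symmetric, so a
#' hemisphere suffices).
#'
#' @param n Number of directions.
#' @return An `n x 3` matrix of unit vectors with non-negative z.
#' @export
fibonacci_hemisphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                      # uniform in z over (0, 1)
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Significance stars used in group comparison tables.
p_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}
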