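# Internal helpers shared across the package.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Magic angle: arccos(1/sqrt(3)) between rotor axis and B0.
MAGIC_ANGLE <- acos(1 / sqrt(3))

#' Rotation matrix for ZYZ Euler angles
#'
#' Builds the 3x3 rotation matrix `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' Applied to the z unit vector with `gamma = 0` it yields the direction
#' `(sin(beta)cos(alpha), sin(beta)sin(alpha), cos(beta))`, which is the
#' convention used throughout for molecule-to-rotor orientations.
#'
#' @param alpha,beta,gamma Euler angles in radians.
#' @return A 3x3 numeric rotation matrix.
#' @export
rotation_zyz <- function(alpha, beta, gamma = 0) {
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  cg <- cos(gamma); sg <- sin(gamma)
  matrix(c(
    ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb,
    sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb,
    -sb * cg,                sb * sg,                cb
  ), nrow = 3, byrow = TRUE)
}

# Extract ZYZ Euler angles from a rotation matrix (inverse of rotation_zyz).
# At the gimbal degeneracy (beta = 0 or pi) gamma is fixed to 0.
euler_from_rotation <- function(R) {
  cb <- max(-1, min(1, R[3, 3]))
  beta <- acos(cb)
  if (abs(abs(cb) - 1) < 1e-12) {
    alpha <- atan2(R[2, 1], R[1, 1])
    if (cb < 0) alpha <- -alpha
    gamma <- 0
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha %% (2 * pi), beta = beta, gamma = gamma %% (2 * pi))
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_input("non-finite values in %s", what)
  invisible(x)
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
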