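# Molecular orientation distributions for partially aligned samples:
# uniform-area sampling on a prolate spheroid (a, a, c) projected radially
# onto the unit sphere.  c/a = 1 is the unaligned (powder) case; larger
# c/a concentrates orientations towards the rotor axis.

#' Orientation distribution specification
#'
#' @param n_points Number of orientations (>= 1).
#' @param c_over_a Prolate aspect ratio c/a >= 1 of the generating ellipsoid
#'   (long axis c along the rotor axis, short axes a = b).  1 gives a uniform
#'   sphere; the study default emulating aligned collagen fibres is 10,
#'   i.e. axes (10, 1, 1).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param method `"random"` for area-uniform rejection sampling (default) or
#'   `"quasi"` for a deterministic low-discrepancy grid (stratified inverse-CDF
#'   polar angles with golden-angle azimuths), useful for low-variance sweeps.
#' @return An object of class `distribution_spec`.
#' @export
distribution_spec <- function(n_points = 800, c_over_a = 10, seed = 1,
                              method = c("random", "quasi")) {
  method <- match.arg(method)
  if (!is.numeric(n_points) || n_points < 1)
    stop_input("n_points must be >= 1")
  if (!is.numeric(c_over_a) || c_over_a < 1)
    stop_input("c_over_a must be >= 1 (oblate ellipsoids are not modeled)")
  structure(list(n_points = as.integer(n_points), c_over_a = c_over_a,
                 seed = seed, method = method),
            class = "distribution_spec")
}

# Surface-area density of the spheroid (a,a,c) over u = cos(theta) of the
# *parameter* angle, and the projected polar angle of the surface point.
ellipsoid_area_density <- function(u, c_over_a) {
  sqrt(c_over_a^2 * (1 - u^2) + u^2)
}

ellipsoid_projected_cosbeta <- function(u, c_over_a) {
  c_over_a * u / sqrt((1 - u^2) + c_over_a^2 * u^2)
}

#' Quadrature value of the order parameter for an ellipsoid-projected grid
#'
#' Computes \eqn{\langle P_2(\cos\beta)\rangle} for the exact area-weighted
#' projected density by 1-D quadrature over the ellipsoid parameter angle:
#' the analytic reference against which the Monte-Carlo samplers are checked.
#'
#' @param c_over_a Aspect ratio >= 1.
#' @return The order parameter in `[0, 1]` (0 at c/a = 1, -> 1 as c/a -> Inf).
#' @export
ellipsoid_order_parameter <- function(c_over_a) {
  if (c_over_a < 1) stop_input("c_over_a must be >= 1")
  f <- function(u) ellipsoid_area_density(u, c_over_a)
  p2 <- function(u) {
    cb <- ellipsoid_projected_cosbeta(u, c_over_a)
    (3 * cb^2 - 1) / 2
  }
  num <- stats::integrate(function(u) p2(u) * f(u), -1, 1,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(f, -1, 1, rel.tol = 1e-10)$value
  num / den
}

new_orientation_set <- function(angles, weights, spec) {
  colnames(angles) <- c("alpha", "beta", "gamma")
  structure(list(angles = angles, weights = weights / sum(weights),
                 spec = spec),
            class = "orientation_set")
}

#' Sample molecule-to-rotor orientations from an ellipsoid projection
#'
#' Draws points uniformly with respect to surface area on the prolate
#' spheroid (a, a, c), projects each radially onto the unit sphere, and
#' converts the projected direction to ZYZ Euler angles
#' (\eqn{\beta = \arccos v_z}, \eqn{\alpha = \mathrm{atan2}(v_y, v_x)}).
#' The third angle \eqn{\gamma} (rotation about the molecular long axis) is
#' drawn uniformly; the sideband engine is exactly invariant to it.  All
#' points carry equal weight — alignment is encoded purely in point density.
#'
#' @param spec A [distribution_spec()].
#' @return An `orientation_set`: list with `angles` (n x 3 matrix, radians),
#'   `weights` (summing to 1) and `spec`.
#' @export
sample_ellipsoid_projected <- function(spec = distribution_spec()) {
  stopifnot(inherits(spec, "distribution_spec"))
  n <- spec$n_points
  ca <- spec$c_over_a
  if (spec$method == "quasi") {
    # deterministic: stratified inverse-CDF in u, golden-angle azimuths
    ug <- seq(-1, 1, length.out = 4097)
    dens <- ellipsoid_area_density(ug, ca)
    cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(ug))
    cdf <- c(0, cdf / cdf[length(cdf)])
    u <- stats::approx(cdf, ug, xout = (seq_len(n) - 0.5) / n,
                       ties = "ordered")$y
    golden <- pi * (3 - sqrt(5))
    phi <- (seq_len(n) * golden) %% (2 * pi)
    gamma <- (seq_len(n) * golden * golden) %% (2 * pi)
  } else {
    draw <- function(m) {
      u0 <- stats::runif(m, -1, 1)
      acc <- stats::runif(m) <= ellipsoid_area_density(u0, ca) / ca
      u0[acc]
    }
    u <- with_seed(spec$seed, {
      got <- numeric(0)
      while (length(got) < n) got <- c(got, draw(2L * n))
      u <- got[seq_len(n)]
      phi <- stats::runif(n, 0, 2 * pi)
      gamma <- stats::runif(n, 0, 2 * pi)
      list(u = u, phi = phi, gamma = gamma)
    })
    phi <- u$phi; gamma <- u$gamma; u <- u$u
  }
  cb <- ellipsoid_projected_cosbeta(u, ca)
  beta <- acos(pmax(-1, pmin(1, cb)))
  angles <- cbind(phi %% (2 * pi), beta, gamma)
  new_orientation_set(angles, rep(1 / n, n), spec)
}

#' Sample uniformly distributed orientations on the sphere
#'
#' The unaligned (powder) limit: directions uniform on the unit sphere,
#' equal weights.  Equivalent to [sample_ellipsoid_projected()] at
#' `c_over_a = 1`.
#'
#' @param spec A [distribution_spec()]; its `c_over_a` must be 1.
#' @return An `orientation_set`.
#' @export
sample_uniform_sphere <- function(spec = distribution_spec(c_over_a = 1)) {
  stopifnot(inherits(spec, "distribution_spec"))
  if (spec$c_over_a != 1)
    stop_input("sample_uniform_sphere requires c_over_a = 1")
  sample_ellipsoid_projected(spec)
}

#' Euler angles of a direction vector
#'
#' Maps a unit vector to ZYZ Euler angles `(alpha, beta, gamma = 0)` with
#' \eqn{\beta = \arccos v_z} and \eqn{\alpha = \mathrm{atan2}(v_y, v_x)}
#' in `[0, 2\pi)`; rotating the z unit vector by
#' `rotation_zyz(alpha, beta, 0)` recovers `v`.  At the poles alpha is
#' arbitrary and returned as 0.
#'
#' @param v Numeric length-3 vector with `|v|` within 1e-6 of 1.
#' @return Named numeric vector `c(alpha, beta, gamma)`.
#' @export
vector_to_euler_zyz <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3 || !all(is.finite(v))) stop_input("v must be a finite 3-vector")
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop_input("zero vector has no direction")
  if (abs(nv - 1) > 1e-6)
    stop_input("|v| = %.8f is not within 1e-6 of 1", nv)
  v <- v / nv
  beta <- acos(max(-1, min(1, v[3])))
  alpha <- if (abs(v[1]) < 1e-300 && abs(v[2]) < 1e-300) 0
           else atan2(v[2], v[1]) %% (2 * pi)
  c(alpha = alpha, beta = beta, gamma = 0)
}

#' Alignment order parameter of an orientation set
#'
#' The weighted mean of the second Legendre polynomial
#' \eqn{P_2(\cos\beta) = (3\cos^2\beta - 1)/2} over the set: 0 for a uniform
#' distribution, 1 for perfect alignment with the rotor axis, -0.5 for all
#' orientations perpendicular to it.
#'
#' @param set An `orientation_set`.
#' @return A number in `[-0.5, 1]`.
#' @export
order_parameter <- function(set) {
  stopifnot(inherits(set, "orientation_set"))
  if (nrow(set$angles) == 0) stop_input("empty orientation set")
  cb <- cos(set$angles[, "beta"])
  sum(set$weights * (3 * cb^2 - 1) / 2)
}

#' @export
print.orientation_set <- function(x, ...) {
  cat(sprintf(
    "Orientation set: %d points, c/a = %g, method = %s, <P2> = %.4f\n",
    nrow(x$angles), x$spec$c_over_a, x$spec$method, order_parameter(x)))
  invisible(x)
}

#' Write / read an orientation set as delimited text
#'
#' Columns `(alpha_deg, beta_deg, gamma_deg, weight)`; `#`-prefixed header
#' lines carry `n`, `c_over_a`, `seed` and `method`.
#'
#' @param set An `orientation_set`.
#' @param path File path.
#' @return `write_orientation_set` returns the path invisibly;
#'   `read_orientation_set` returns an `orientation_set`.
#' @export
write_orientation_set <- function(set, path) {
  stopifnot(inherits(set, "orientation_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n=%d", nrow(set$angles)),
               sprintf("# c_over_a=%.10g", set$spec$c_over_a),
               sprintf("# seed=%s", if (is.null(set$spec$seed)) "NA"
                       else format(set$spec$seed)),
               sprintf("# method=%s", set$spec$method)), con)
  df <- data.frame(alpha_deg = rad2deg(set$angles[, "alpha"]),
                   beta_deg = rad2deg(set$angles[, "beta"]),
                   gamma_deg = rad2deg(set$angles[, "gamma"]),
                   weight = set$weights)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_orientation_set
#' @export
read_orientation_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^\\s*#", lines, value = TRUE)
  kv <- list()
  for (m in sub("^\\s*#\\s*", "", meta)) {
    p <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(p) == 2) kv[[trimws(p[1])]] <- trimws(p[2])
  }
  body <- lines[!grepl("^\\s*#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  seed <- if (is.null(kv$seed) || kv$seed == "NA") NULL else as.numeric(kv$seed)
  spec <- distribution_spec(
    n_points = nrow(df),
    c_over_a = if (is.null(kv$c_over_a)) 1 else as.numeric(kv$c_over_a),
    seed = seed,
    method = if (is.null(kv$method)) "random" else kv$method)
  new_orientation_set(cbind(deg2rad(df$alpha_deg), deg2rad(df$beta_deg),
                            deg2rad(df$gamma_deg)),
                      df$weight, spec)
}
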