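# MAS spinning-sideband engine for an isolated spin-1/2 with CSA.
#
# The instantaneous shift under MAS is the lab-frame zz component of the
# rotor-frame shift tensor A probed along the field direction
# b(phi) = (sin(theta_m) cos(phi), sin(theta_m) sin(phi), cos(theta_m)),
# phi = omega_r t.  Expanding b'Ab gives the isotropic term (the magic angle
# cancels the DC anisotropy) plus first and second rotor harmonics with
# coefficients
#   C1 = 2 sin(theta_m) cos(theta_m) A_xz,   S1 = 2 sin(theta_m) cos(theta_m) A_yz,
#   C2 = sin^2(theta_m) (A_xx - A_yy)/2,     S2 = sin^2(theta_m) A_xy.
# The periodic phase Phi(t) = int omega_aniso dt' has a closed form, and the
# rotor-phase-averaged sideband intensities are I_N = |F_N|^2 where F_N are
# the Fourier coefficients of exp(i Phi) over one rotor period — computed
# exactly (to FFT sampling) from a single period.  Parseval gives
# sum_N I_N = 1 identically.

#' Spectrometer / simulation configuration
#'
#' @param larmor_MHz Observe-nucleus Larmor frequency in MHz (default 150.9,
#'   the carbon-13 frequency at 14.1 T).
#' @param mas_rate_Hz Rotor spinning rate in Hz (default 2200).
#' @param n_sidebands_max Largest |sideband index| kept when reporting or
#'   rendering (default 15; intensities are always computed over the full
#'   FFT window and conservation is checked there).
#' @param n_time_points Samples per rotor period for the Fourier analysis; a
#'   power of two >= 32 (default 128).  Convergence is checked automatically
#'   and the grid is doubled if spectral weight reaches the window edge.
#' @return An object of class `spectrometer_config`.
#' @export
spectrometer_config <- function(larmor_MHz = 150.9, mas_rate_Hz = 2200,
                                n_sidebands_max = 15, n_time_points = 128) {
  if (!is.numeric(larmor_MHz) || larmor_MHz <= 0)
    stop_input("larmor_MHz must be > 0")
  if (!is.numeric(mas_rate_Hz) || mas_rate_Hz <= 0)
    stop_input("mas_rate_Hz must be > 0")
  if (!is_power_of_two(n_time_points) || n_time_points < 32)
    stop_input("n_time_points must be a power of two >= 32")
  structure(list(larmor_MHz = larmor_MHz, mas_rate_Hz = mas_rate_Hz,
                 n_sidebands_max = as.integer(n_sidebands_max),
                 n_time_points = as.integer(n_time_points)),
            class = "spectrometer_config")
}

#' Sideband spacing in ppm
#'
#' Adjacent spinning sidebands are separated by `mas_rate_Hz / larmor_MHz`
#' ppm (e.g. 2200 Hz at 150.9 MHz gives 14.58 ppm).
#'
#' @param config A [spectrometer_config()].
#' @return Spacing in ppm.
#' @export
sideband_spacing_ppm <- function(config) config$mas_rate_Hz / config$larmor_MHz

new_sideband_pattern <- function(index, intensity, delta_iso, config,
                                 normalization = "none") {
  o <- order(index)
  structure(list(index = as.integer(index[o]), intensity = intensity[o],
                 delta_iso = delta_iso, config = config,
                 normalization = normalization),
            class = "sideband_pattern")
}

#' @export
print.sideband_pattern <- function(x, ...) {
  cat(sprintf(
    "Sideband pattern: delta_iso = %.3f ppm, %g Hz MAS at %g MHz (norm: %s)\n",
    x$delta_iso, x$config$mas_rate_Hz, x$config$larmor_MHz, x$normalization))
  keep <- abs(x$index) <= min(6, max(abs(x$index)))
  print(round(stats::setNames(x$intensity[keep], x$index[keep]), 5))
  invisible(x)
}

#' Intensity at a given sideband index
#'
#' @param pattern A `sideband_pattern`.
#' @param n Integer sideband index (0 = isotropic/centreband).
#' @return Intensity (0 if the index lies outside the computed window).
#' @export
sideband_intensity <- function(pattern, n) {
  i <- match(as.integer(n), pattern$index)
  out <- pattern$intensity[i]
  out[is.na(out)] <- 0
  out
}

# Rotor-frame molecular tensor from Haeberlen parameters + PAS orientation.
tensor_in_molecular_frame <- function(params) {
  pv <- haeberlen_principal(params$delta_iso, params$zeta, params$eta)
  A <- diag(pv)
  pas <- params$pas_orientation
  if (!is.null(pas) && any(pas != 0)) {
    R <- rotation_zyz(pas[1], pas[2], pas[3])
    A <- R %*% A %*% t(R)
    A <- (A + t(A)) / 2
  }
  A
}

# Harmonic coefficients (C1, S1, C2, S2) of the rotor-frame tensor for a set
# of molecular->rotor ZYZ Euler angles (n x 3 matrix).  Vectorized: returns
# an n x 4 matrix.  A_mol is the tensor in the molecular frame.
rotor_harmonics <- function(A_mol, angles) {
  a <- angles[, 1]; b <- angles[, 2]; g <- angles[, 3]
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  # rows of R = Rz(a) Ry(b) Rz(g)
  r1 <- cbind(ca * cb * cg - sa * sg, -ca * cb * sg - sa * cg, ca * sb)
  r2 <- cbind(sa * cb * cg + ca * sg, -sa * cb * sg + ca * cg, sa * sb)
  r3 <- cbind(-sb * cg, sb * sg, cb)
  M1 <- r1 %*% A_mol
  M2 <- r2 %*% A_mol
  B_xz <- rowSums(M1 * r3)
  B_yz <- rowSums(M2 * r3)
  B_xx <- rowSums(M1 * r1)
  B_yy <- rowSums(M2 * r2)
  B_xy <- rowSums(M1 * r2)
  s <- sin(MAGIC_ANGLE); c <- cos(MAGIC_ANGLE)
  cbind(C1 = 2 * s * c * B_xz,
        S1 = 2 * s * c * B_yz,
        C2 = s^2 * (B_xx - B_yy) / 2,
        S2 = s^2 * B_xy)
}

# Weighted sideband intensities for a matrix of harmonic coefficients.
# Returns list(index, intensity) with the full FFT window; intensities are
# the weight-averaged |F_N|^2.  Chunked to bound memory.
sidebands_from_harmonics <- function(coefs, weights, config,
                                     chunk = 20000L) {
  n_t <- config$n_time_points
  repeat {
    phi <- 2 * pi * (seq_len(n_t) - 1) / n_t
    # closed-form periodic phase: Phi(phi) = (nu_L/nu_r) * g(phi)
    basis <- cbind(sin(phi), 1 - cos(phi), sin(2 * phi) / 2,
                   (1 - cos(2 * phi)) / 2)
    scale <- config$larmor_MHz / config$mas_rate_Hz
    n_or <- nrow(coefs)
    acc <- numeric(n_t)
    for (start in seq(1L, n_or, by = chunk)) {
      idx <- start:min(n_or, start + chunk - 1L)
      Phi <- scale * (basis %*% t(coefs[idx, , drop = FALSE]))
      Fm <- stats::mvfft(exp(1i * Phi)) / n_t
      acc <- acc + as.numeric(Mod(Fm)^2 %*% weights[idx])
    }
    N <- c(0:(n_t / 2 - 1), -(n_t / 2):-1)
    # auto-convergence: weight must not reach the window edge
    edge <- sum(acc[abs(N) >= n_t / 4])
    if (edge <= 1e-10 || n_t >= 4096) break
    n_t <- 2L * n_t
  }
  list(index = N, intensity = acc, n_time_points = n_t)
}

#' Sideband pattern of a single crystallite
#'
#' Computes the MAS spinning-sideband intensities for one molecular
#' orientation `(alpha, beta, gamma)` (ZYZ, molecule-to-rotor frame) of a
#' CSA tensor.  Intensities are exactly averaged over the rotor phase, so
#' they are invariant to `gamma` for a tensor stored with its PAS in the
#' molecular frame, and satisfy \eqn{\sum_N I_N = 1} by Parseval's theorem.
#'
#' @param params A `shift_tensor` (see [shift_tensor()]).
#' @param alpha,beta,gamma Molecular-to-rotor Euler angles in radians.
#' @param config A [spectrometer_config()].
#' @return A `sideband_pattern`.
#' @export
crystallite_sidebands <- function(params, alpha = 0, beta = 0, gamma = 0,
                                  config = spectrometer_config()) {
  stopifnot(inherits(params, "shift_tensor"),
            inherits(config, "spectrometer_config"))
  A <- tensor_in_molecular_frame(params)
  co <- rotor_harmonics(A, matrix(c(alpha, beta, gamma), 1, 3))
  sb <- sidebands_from_harmonics(co, 1, config)
  new_sideband_pattern(sb$index, sb$intensity, params$delta_iso, config)
}

#' Ensemble-averaged sideband pattern
#'
#' Averages crystallite sideband patterns over an orientation set (and
#' optionally over several tensors with weights).  For each orientation the
#' tensor's PAS-to-molecular rotation composes with the grid angles; the
#' rotor phase is averaged exactly inside the engine.
#'
#' @param tensors A single `shift_tensor` or a list of them.
#' @param orientations An `orientation_set`.
#' @param config A [spectrometer_config()].
#' @param tensor_weights Optional non-negative weights, one per tensor
#'   (default equal); normalized internally.
#' @return A `sideband_pattern` whose `delta_iso` is the tensor-weighted
#'   mean isotropic shift.
#' @export
ensemble_pattern <- function(tensors, orientations,
                             config = spectrometer_config(),
                             tensor_weights = NULL) {
  if (inherits(tensors, "shift_tensor")) tensors <- list(tensors)
  if (length(tensors) == 0) stop_input("empty tensor list")
  stopifnot(inherits(orientations, "orientation_set"))
  if (nrow(orientations$angles) == 0) stop_input("empty orientation set")
  if (is.null(tensor_weights)) tensor_weights <- rep(1, length(tensors))
  if (any(tensor_weights < 0) || sum(tensor_weights) <= 0)
    stop_input("tensor weights must be non-negative and not all zero")
  tensor_weights <- tensor_weights / sum(tensor_weights)

  total <- NULL
  for (k in seq_along(tensors)) {
    A <- tensor_in_molecular_frame(tensors[[k]])
    co <- rotor_harmonics(A, orientations$angles)
    sb <- sidebands_from_harmonics(co, orientations$weights, config)
    contrib <- tensor_weights[k] * sb$intensity
    if (is.null(total)) {
      total <- contrib; index <- sb$index
    } else if (length(contrib) == length(total)) {
      total <- total + contrib
    } else {
      # align windows if the auto-convergence widened one of them
      m <- match(index, sb$index)
      grown <- numeric(length(sb$index)); grown[m[!is.na(m)]] <- total[!is.na(m)]
      total <- grown + contrib; index <- sb$index
    }
  }
  iso <- sum(tensor_weights * vapply(tensors, `[[`, numeric(1), "delta_iso"))
  new_sideband_pattern(index, total, iso, config)
}

#' Render a sideband pattern as a 1D spectrum
#'
#' Places one lineshape per sideband at
#' \eqn{\delta_{iso} + N\,(\nu_r/\nu_L)} ppm with area proportional to
#' \eqn{I_N}.  `linewidth_ppm = 0` gives stick mode: each intensity is
#' deposited on the nearest axis point as `I_N / dx` so the numerical
#' integral is preserved.
#'
#' @param pattern A `sideband_pattern`.
#' @param linewidth_ppm Full width at half maximum in ppm (>= 0).
#' @param axis Strictly monotone ppm grid; default spans all sidebands with
#'   intensity above 1e-8 plus a margin, at 4096 points.
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return A two-column matrix `(ppm, intensity)`.
#' @export
render_spectrum <- function(pattern, linewidth_ppm = 1, axis = NULL,
                            lineshape = c("lorentzian", "gaussian")) {
  stopifnot(inherits(pattern, "sideband_pattern"))
  lineshape <- match.arg(lineshape)
  if (linewidth_ppm < 0) stop_input("linewidth_ppm must be >= 0")
  sp <- sideband_spacing_ppm(pattern$config)
  keep <- pattern$intensity > 1e-8 &
    abs(pattern$index) <= pattern$config$n_sidebands_max
  pos <- pattern$delta_iso + pattern$index[keep] * sp
  amp <- pattern$intensity[keep]
  if (is.null(axis)) {
    pad <- sp + 5 * max(linewidth_ppm, 0.5)
    axis <- seq(min(pos) - pad, max(pos) + pad, length.out = 4096)
  }
  d <- diff(axis)
  if (length(axis) < 2 || any(d == 0) || (any(d > 0) && any(d < 0)))
    stop_input("axis must be strictly monotone")
  if (min(pos) < min(axis) || max(pos) > max(axis))
    warning("ppm axis does not cover all sidebands; spectrum truncated")
  y <- numeric(length(axis))
  if (linewidth_ppm == 0) {
    dx <- stats::median(abs(d))
    for (j in seq_along(pos)) {
      i <- which.min(abs(axis - pos[j]))
      y[i] <- y[i] + amp[j] / dx
    }
  } else if (lineshape == "lorentzian") {
    hw <- linewidth_ppm / 2
    for (j in seq_along(pos))
      y <- y + amp[j] * (hw / pi) / ((axis - pos[j])^2 + hw^2)
  } else {
    sd <- linewidth_ppm / (2 * sqrt(2 * log(2)))
    for (j in seq_along(pos))
      y <- y + amp[j] * stats::dnorm(axis, pos[j], sd)
  }
  cbind(ppm = axis, intensity = y)
}

#' Write / read a sideband pattern as delimited text
#'
#' Columns `(sideband_index, intensity)`; header comments carry `delta_iso`,
#' `mas_rate_Hz`, `larmor_MHz` and the normalization mode.
#'
#' @param pattern A `sideband_pattern`.
#' @param path File path.
#' @return `write_sideband_pattern` returns the path invisibly;
#'   `read_sideband_pattern` returns a `sideband_pattern`.
#' @export
write_sideband_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# delta_iso=%.10g", pattern$delta_iso),
               sprintf("# mas_rate_Hz=%.10g", pattern$config$mas_rate_Hz),
               sprintf("# larmor_MHz=%.10g", pattern$config$larmor_MHz),
               sprintf("# normalization=%s", pattern$normalization)), con)
  keep <- pattern$intensity > 1e-12 | pattern$index == 0L
  df <- data.frame(sideband_index = pattern$index[keep],
                   intensity = pattern$intensity[keep])
  utils::write.table(format(df, digits = 15, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sideband_pattern
#' @export
read_sideband_pattern <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- sub("^\\s*#\\s*", "", grep("^\\s*#", lines, value = TRUE))
  kv <- list()
  for (m in meta) {
    p <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(p) == 2) kv[[trimws(p[1])]] <- trimws(p[2])
  }
  df <- utils::read.table(text = lines[!grepl("^\\s*#", lines)],
                          header = TRUE, sep = "\t")
  cfg <- spectrometer_config(
    larmor_MHz = if (is.null(kv$larmor_MHz)) 150.9 else as.numeric(kv$larmor_MHz),
    mas_rate_Hz = if (is.null(kv$mas_rate_Hz)) 2200 else as.numeric(kv$mas_rate_Hz))
  new_sideband_pattern(df$sideband_index, df$intensity,
                       if (is.null(kv$delta_iso)) 0 else as.numeric(kv$delta_iso),
                       cfg,
                       if (is.null(kv$normalization)) "none" else kv$normalization)
}
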