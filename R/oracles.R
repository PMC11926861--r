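# Independent reference implementations used for validation: a brute-force
# time-domain FID + DFT route for single crystallites, and a dense
# quadrature powder average.  These deliberately avoid the closed-form
# phase and single-period Fourier analysis of the production engine.

#' Brute-force sideband intensities from a long FID
#'
#' Reference implementation: samples the instantaneous anisotropic shift
#' directly from the rotating field direction (no harmonic decomposition),
#' integrates the phase numerically by cumulative trapezoids over many rotor
#' periods, Fourier-transforms the FID, and reads intensities at the
#' sideband bins.  Slow but independent of [crystallite_sidebands()].
#'
#' @param params A `shift_tensor`.
#' @param alpha,beta,gamma Molecule-to-rotor Euler angles (radians).
#' @param config A [spectrometer_config()].
#' @param n_periods Number of rotor periods in the FID (default 128).
#' @param oversample Time points per rotor period (default 4096).
#' @param n_max Largest |sideband index| reported (default 20).
#' @return A `sideband_pattern`.
#' @export
fid_dft_sidebands <- function(params, alpha = 0, beta = 0, gamma = 0,
                              config = spectrometer_config(),
                              n_periods = 128L, oversample = 4096L,
                              n_max = 20L) {
  stopifnot(inherits(params, "shift_tensor"))
  A_mol <- tensor_in_molecular_frame(params)
  R <- rotation_zyz(alpha, beta, gamma)
  A <- R %*% A_mol %*% t(R)
  iso <- sum(diag(A)) / 3

  n_tot <- n_periods * oversample
  t_r <- 1 / config$mas_rate_Hz
  dt <- t_r / oversample
  # field direction in the rotor frame at each time step (one period repeats)
  phi <- 2 * pi * (seq_len(oversample + 1L) - 1) / oversample
  s <- sin(MAGIC_ANGLE); c <- cos(MAGIC_ANGLE)
  b <- cbind(s * cos(phi), s * sin(phi), c)
  w_one <- rowSums((b %*% A) * b) - iso            # ppm, one period + endpoint
  w_one <- w_one * config$larmor_MHz               # Hz (ppm * MHz)
  ph_one <- pracma::cumtrapz(2 * pi * w_one)[, 1] * dt
  per_period <- ph_one[oversample + 1L]
  k <- rep(0:(n_periods - 1L), each = oversample)
  phase <- ph_one[rep(seq_len(oversample), n_periods)] + k * per_period
  fid <- exp(1i * phase)
  Fm <- stats::fft(fid) / n_tot
  idx <- seq(-n_max, n_max)
  bins <- ifelse(idx >= 0, idx * n_periods, n_tot + idx * n_periods) + 1L
  new_sideband_pattern(idx, Mod(Fm[bins])^2, params$delta_iso, config)
}

#' Dense quadrature powder pattern
#'
#' Averages crystallite sideband intensities over the full orientation
#' sphere by Gauss-Legendre quadrature in cos(beta) crossed with an equally
#' spaced grid in gamma, the rotation about the molecular z axis.  The third
#' SO(3) angle — rotation about the rotor axis — is exactly equivalent to a
#' rotor-phase shift and needs no grid: the engine's rotor-phase averaging
#' removes it.  Serves both as the uniform-powder reference for the
#' Monte-Carlo ensemble route and as the forward model for powder CSA
#' fitting.
#'
#' @param params A `shift_tensor`.
#' @param config A [spectrometer_config()].
#' @param n_beta Gauss-Legendre nodes in cos(beta) (default 64).
#' @param n_gamma Equally spaced gamma nodes (default 16; reduced to 1
#'   automatically for axially symmetric tensors in their PAS, which are
#'   gamma-invariant).
#' @return A `sideband_pattern`.
#' @export
powder_pattern <- function(params, config = spectrometer_config(),
                           n_beta = 64L, n_gamma = 16L) {
  stopifnot(inherits(params, "shift_tensor"))
  axial_in_pas <- params$eta < 1e-12 &&
    (is.null(params$pas_orientation) || all(params$pas_orientation == 0))
  if (axial_in_pas) n_gamma <- 1L
  gl <- pracma::gaussLegendre(n_beta, -1, 1)
  beta <- acos(gl$x)
  gamma <- 2 * pi * (seq_len(n_gamma) - 0.5) / n_gamma
  grid <- expand.grid(gamma = gamma, beta = beta)
  w <- rep(gl$w, each = n_gamma)
  w <- w / sum(w)
  A <- tensor_in_molecular_frame(params)
  co <- rotor_harmonics(A, cbind(0, grid$beta, grid$gamma))
  sb <- sidebands_from_harmonics(co, w, config)
  new_sideband_pattern(sb$index, sb$intensity, params$delta_iso, config)
}
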