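# Shared fixtures for the test suite: a default 14.1 T / 2.2 kHz
# configuration, representative carbonyl tensors, and small helpers.

cfg_default <- function() spectrometer_config()

carbonyl_tensor <- function() shift_tensor(170, -80, 0.6)

# random symmetric 3x3 matrix with entries of carbonyl-shielding scale
random_symmetric <- function() {
  m <- matrix(stats::rnorm(9, 0, 40), 3, 3)
  (m + t(m)) / 2 + diag(100, 3)
}

# random rotation matrix via QR of a Gaussian matrix, det +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_pattern_close <- function(p1, p2, tol, idx = -10:10) {
  expect_lt(max(abs(sideband_intensity(p1, idx) -
                      sideband_intensity(p2, idx))), tol)
}
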