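# MAS sideband engine: crystallites, ensembles, rendering.

test_that("no anisotropy puts all intensity in the centreband", {
  p <- crystallite_sidebands(shift_tensor(172, 0, 0), beta = 1)
  expect_equal(sideband_intensity(p, 0L), 1, tolerance = 1e-12)
  expect_lt(max(sideband_intensity(p, c(-5:-1, 1:5))), 1e-12)
})

test_that("fast spinning collapses the pattern onto the centreband", {
  # anisotropy 0.2 ppm * 150.9 MHz ~ 30 Hz << 2.2 kHz MAS (> 50x)
  p <- crystallite_sidebands(shift_tensor(172, 0.2, 0.4), beta = 1.1)
  expect_gt(sideband_intensity(p, 0L), 0.999)
})

test_that("the engine agrees with the brute-force FID + DFT oracle", {
  cfg <- cfg_default()
  st <- shift_tensor(170, -80, 0.6)
  a <- 40 * pi / 180; b <- 60 * pi / 180
  p_eng <- crystallite_sidebands(st, a, b, config = cfg)
  p_ora <- fid_dft_sidebands(st, a, b, config = cfg)
  expect_pattern_close(p_eng, p_ora, 1e-4, idx = -15:15)

  set.seed(21)
  for (i in 1:5) {
    st <- shift_tensor(170, stats::runif(1, -120, 120), stats::runif(1))
    b <- stats::runif(1, 0, pi); a <- stats::runif(1, 0, 2 * pi)
    expect_pattern_close(crystallite_sidebands(st, a, b, config = cfg),
                         fid_dft_sidebands(st, a, b, config = cfg),
                         1e-4, idx = -15:15)
  }
})

test_that("total sideband intensity is conserved", {
  set.seed(22)
  cfg <- cfg_default()
  for (i in 1:50) {
    st <- shift_tensor(170, stats::runif(1, -120, 120), stats::runif(1))
    p <- crystallite_sidebands(st, stats::runif(1, 0, 2 * pi),
                               stats::runif(1, 0, pi), config = cfg)
    expect_equal(sum(p$intensity), 1, tolerance = 1e-6)
    expect_true(all(p$intensity >= 0))
  }
})

test_that("axially symmetric tensors are independent of alpha", {
  cfg <- cfg_default()
  st <- shift_tensor(170, -70, 0)
  p0 <- crystallite_sidebands(st, 0, 1.0, config = cfg)
  for (a in c(0.7, 2.1, 4.9)) {
    pa <- crystallite_sidebands(st, a, 1.0, config = cfg)
    expect_pattern_close(p0, pa, 1e-10)
  }
})

test_that("negating the anisotropy mirrors the sideband envelope", {
  cfg <- cfg_default()
  for (eta in c(0, 0.5)) {
    pp <- crystallite_sidebands(shift_tensor(170, 75, eta), 0.4, 1.2,
                                config = cfg)
    pm <- crystallite_sidebands(shift_tensor(170, -75, eta), 0.4, 1.2,
                                config = cfg)
    idx <- -12:12
    expect_lt(max(abs(sideband_intensity(pp, idx) -
                        sideband_intensity(pm, -idx))), 1e-8)
  }
})

test_that("rotation about the rotor axis is equivalent to a rotor-phase shift", {
  # exact rotor-phase averaging makes intensities invariant under alpha for
  # ANY tensor, and under gamma (spin about the molecular long axis) for
  # tensors axial about that axis
  cfg <- cfg_default()
  st <- shift_tensor(170, -80, 0.6)
  p0 <- crystallite_sidebands(st, 0, 1.0, 0.4, config = cfg)
  for (a in c(0.3, 1.7, 5.2)) {
    pa <- crystallite_sidebands(st, a, 1.0, 0.4, config = cfg)
    expect_pattern_close(p0, pa, 1e-10)
  }
  ax <- shift_tensor(170, -70, 0)
  q0 <- crystallite_sidebands(ax, 0.5, 1.0, 0, config = cfg)
  for (g in c(0.3, 1.7, 5.2)) {
    qg <- crystallite_sidebands(ax, 0.5, 1.0, g, config = cfg)
    expect_pattern_close(q0, qg, 1e-10)
  }
})

test_that("doubling the time grid leaves intensities unchanged", {
  st <- shift_tensor(170, -90, 0.8)
  p1 <- crystallite_sidebands(st, 0.9, 0.7, config = spectrometer_config())
  p2 <- crystallite_sidebands(st, 0.9, 0.7,
                              config = spectrometer_config(n_time_points = 256))
  expect_pattern_close(p1, p2, 1e-6, idx = -20:20)
})

test_that("an ensemble of one repeated orientation equals the crystallite", {
  cfg <- cfg_default()
  st <- shift_tensor(170, -80, 0.6)
  os <- sample_uniform_sphere(distribution_spec(4, 1, seed = 1))
  os$angles[, "alpha"] <- 0.8; os$angles[, "beta"] <- 1.1
  os$angles[, "gamma"] <- 0
  pe <- ensemble_pattern(st, os, cfg)
  pc <- crystallite_sidebands(st, 0.8, 1.1, config = cfg)
  expect_pattern_close(pe, pc, 1e-12)
  expect_equal(sum(pe$intensity), 1, tolerance = 1e-6)
  expect_error(ensemble_pattern(list(), os, cfg), "empty")
})

test_that("a PAS orientation composes with the grid angles", {
  cfg <- cfg_default()
  st_rot <- shift_tensor(170, -80, 0.6, pas_orientation = c(0.8, 1.1, 0.3))
  p1 <- crystallite_sidebands(st_rot, 0, 0, config = cfg)
  p2 <- crystallite_sidebands(shift_tensor(170, -80, 0.6), 0.8, 1.1, 0.3,
                              config = cfg)
  expect_pattern_close(p1, p2, 1e-12)
})

test_that("the Monte-Carlo powder ensemble matches dense quadrature", {
  cfg <- cfg_default()
  st <- shift_tensor(170, -70, 0)
  os <- sample_uniform_sphere(distribution_spec(2000, 1, seed = 3))
  pe <- ensemble_pattern(st, os, cfg)
  pq <- powder_pattern(st, cfg, n_beta = 256)
  expect_pattern_close(pe, pq, 0.01)
})

test_that("rendered spectra place and conserve the sidebands", {
  cfg <- cfg_default()
  st <- shift_tensor(170, -80, 0.6)
  p <- powder_pattern(st, cfg)
  expect_equal(sideband_spacing_ppm(cfg), 2200 / 150.9)

  sp <- render_spectrum(p, linewidth_ppm = 1)
  dx <- diff(sp[1:2, 1])
  integral <- sum(sp[, 2]) * dx
  kept <- sum(p$intensity[p$intensity > 1e-8 &
                            abs(p$index) <= cfg$n_sidebands_max])
  expect_equal(integral, kept, tolerance = 2e-3)

  # stick mode: nonzero points sit one spacing apart, integral preserved
  sticks <- render_spectrum(p, linewidth_ppm = 0)
  nz <- sticks[sticks[, 2] > 0, , drop = FALSE]
  pos_diff <- diff(nz[, 1])
  expect_equal(pos_diff / sideband_spacing_ppm(cfg),
               round(pos_diff / sideband_spacing_ppm(cfg)), tolerance = 0.01)
  dx_sticks <- diff(sticks[1:2, 1])
  expect_equal(sum(sticks[, 2]) * dx_sticks, kept, tolerance = 1e-3)

  expect_warning(render_spectrum(p, 1, axis = seq(160, 180, 0.1)),
                 "truncated")
  expect_error(render_spectrum(p, -1), "linewidth")
})

test_that("sideband patterns round trip through delimited text", {
  p <- powder_pattern(carbonyl_tensor(), cfg_default())
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sideband_pattern(p, tmp)
  back <- read_sideband_pattern(tmp)
  idx <- -12:12
  expect_equal(sideband_intensity(back, idx), sideband_intensity(p, idx),
               tolerance = 1e-10)
  expect_equal(back$delta_iso, p$delta_iso)
  expect_equal(back$config$mas_rate_Hz, 2200)
})

test_that("configuration invariants are enforced", {
  expect_error(spectrometer_config(mas_rate_Hz = 0), "mas_rate")
  expect_error(spectrometer_config(larmor_MHz = -1), "larmor")
  expect_error(spectrometer_config(n_time_points = 100), "power of two")
  expect_error(spectrometer_config(n_time_points = 16), "power of two")
})
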