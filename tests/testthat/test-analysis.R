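# Composite patterns, normalization, sweeps, and the force -> stress helper.

make_three_patterns <- function(cfg = cfg_default()) {
  list(Gly = powder_pattern(shift_tensor(170.5, -74, 0.62), cfg),
       Pro = powder_pattern(shift_tensor(172.8, -78, 0.55), cfg),
       Hyp = powder_pattern(shift_tensor(172.1, -76, 0.60), cfg))
}

test_that("composite patterns reduce to their inputs in degenerate cases", {
  cfg <- cfg_default()
  p <- powder_pattern(carbonyl_tensor(), cfg)
  same <- list(Gly = p, Pro = p, Hyp = p)
  comp <- composite_pattern(same, composite_spec(normalization_mode = "none"))
  expect_pattern_close(comp, p, 1e-12)

  three <- make_three_patterns(cfg)
  only_gly <- composite_pattern(
    three, composite_spec(c(Gly = 1, Pro = 0, Hyp = 0), "none"))
  expect_pattern_close(only_gly, three$Gly, 1e-12)
})

test_that("composites equal the element-wise weighted mean", {
  three <- make_three_patterns()
  w <- c(Gly = 0.5, Pro = 0.3, Hyp = 0.2)
  comp <- composite_pattern(three, composite_spec(w, "none"))
  idx <- -8:8
  manual <- w["Gly"] * sideband_intensity(three$Gly, idx) +
    w["Pro"] * sideband_intensity(three$Pro, idx) +
    w["Hyp"] * sideband_intensity(three$Hyp, idx)
  manual <- manual / sum(w)  # inputs each sum to 1 over the full window
  expect_equal(sideband_intensity(comp, idx), manual, tolerance = 1e-9)
})

test_that("composite construction is linear in the residue weights", {
  three <- make_three_patterns()
  set.seed(30)
  idx <- -8:8
  for (i in 1:5) {
    w1 <- stats::runif(3); w2 <- stats::runif(3)
    names(w1) <- names(w2) <- names(three)
    lambda <- stats::runif(1)
    mix <- lambda * w1 + (1 - lambda) * w2
    # superposition holds for the unnormalized weighted sums
    c1 <- composite_pattern(three, composite_spec(w1 / sum(w1), "none"))
    c2 <- composite_pattern(three, composite_spec(w2 / sum(w2), "none"))
    cm <- composite_pattern(three, composite_spec(mix / sum(mix), "none"))
    lhs <- sideband_intensity(cm, idx) * sum(mix)
    rhs <- lambda * sum(w1) * sideband_intensity(c1, idx) +
      (1 - lambda) * sum(w2) * sideband_intensity(c2, idx)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("mismatched spectrometer settings cannot be combined", {
  p1 <- powder_pattern(carbonyl_tensor(), spectrometer_config())
  p2 <- powder_pattern(carbonyl_tensor(),
                       spectrometer_config(mas_rate_Hz = 3000))
  expect_error(composite_pattern(list(Gly = p1, Pro = p2),
                                 composite_spec(c(Gly = 1, Pro = 1))),
               "mix")
})

test_that("normalization modes divide by the stated reference", {
  p <- powder_pattern(carbonyl_tensor(), cfg_default())
  n_iso <- normalize_pattern(p, "isotropic")
  expect_equal(sideband_intensity(n_iso, 0L), 1)
  n_m3 <- normalize_pattern(p, "sideband:-3")
  expect_equal(sideband_intensity(n_m3, -3L), 1)
  n_max <- normalize_pattern(p, "max")
  expect_equal(max(n_max$intensity), 1)
  expect_identical(normalize_pattern(p, "none"), p)
  # a pattern with no intensity at the reference index
  p0 <- crystallite_sidebands(shift_tensor(170, 0, 0), beta = 1)
  expect_error(normalize_pattern(p0, "sideband:-3"), "sideband:-3")
  expect_error(normalize_pattern(p, "weird"), "unknown")
})

test_that("alignment sweep is self-referenced and seed-stable", {
  tensors <- collagen_carbonyl_tensors()
  sw <- alignment_sweep(tensors, c(1, 5, 10), grid_n = 800, seed = 5)
  i_ref <- which(sw$values == 1)
  expect_equal(unname(sw$ratios[i_ref, ]), rep(1, length(sw$index)))
  expect_true(all(is.finite(sw$ratios)))
  sw2 <- alignment_sweep(tensors, c(1, 5, 10), grid_n = 800, seed = 5)
  expect_identical(sw$ratios, sw2$ratios)
  expect_error(alignment_sweep(tensors, c(2, 5), grid_n = 100), "reference")
  # order parameters attached and increasing
  expect_true(all(diff(attr(sw, "order_parameters")) > -0.05))
})

test_that("a strain sweep that only moves delta_iso leaves all ratios at 1", {
  spec <- synthetic_spec(
    strain_levels = c(0, 8.6, 17), forces_pN = c(0, 100, 500),
    strain_response = list(Gly = c(delta_iso = -0.12, zeta = 0, eta = 0),
                           Pro = c(delta_iso = -0.03, zeta = 0, eta = 0),
                           Hyp = c(delta_iso = -0.04, zeta = 0, eta = 0)),
    noise_sd = 0)
  pts <- strain_points_from_table(make_strain_tensor_table(spec))
  sw <- strain_sweep(pts, grid_n = 500, seed = 9)
  expect_lt(max(abs(sw$ratios - 1)), 1e-6)
})

test_that("strain sweep ratios match a direct per-strain recomputation", {
  spec <- synthetic_spec(strain_levels = c(0, 8.6, 17),
                         forces_pN = c(0, 100, 500), noise_sd = 0)
  pts <- strain_points_from_table(make_strain_tensor_table(spec))
  cfg <- cfg_default()
  grid_n <- 400; seed <- 11; ca <- 10
  sw <- strain_sweep(pts, c_over_a = ca, grid_n = grid_n, seed = seed)
  # independent recomputation with the same shared grid
  os <- sample_ellipsoid_projected(distribution_spec(grid_n, ca, seed))
  pats <- lapply(pts, function(sp) {
    per <- lapply(sp$tensors, ensemble_pattern, orientations = os,
                  config = cfg)
    composite_pattern(per, composite_spec())
  })
  for (i in seq_along(pts)) {
    manual <- sideband_intensity(pats[[i]], sw$index) /
      sideband_intensity(pats[[1]], sw$index)
    expect_equal(unname(sw$ratios[i, ]), unname(manual), tolerance = 1e-10)
  }
  expect_error(strain_sweep(pts[-1]), "0% strain")
})

test_that("rerunning a sweep with one seed is bit-identical", {
  spec <- synthetic_spec(strain_levels = c(0, 17), forces_pN = c(0, 500))
  pts <- strain_points_from_table(make_strain_tensor_table(spec))
  s1 <- strain_sweep(pts, grid_n = 300, seed = 2)
  s2 <- strain_sweep(pts, grid_n = 300, seed = 2)
  expect_identical(s1$ratios, s2$ratios)
})

test_that("monotone_fraction summarizes ratio trends", {
  sw <- structure(list(ratios = cbind(c(1, 1.1, 1.2), c(1, 0.9, 0.95)),
                       index = c(0, 1)), class = "sweep_result")
  expect_equal(monotone_fraction(sw), 0.5)
  expect_equal(monotone_fraction(sw, tol = 0.06), 1)
})

test_that("force converts to stress on a 1.5 nm cylinder as printed", {
  expect_equal(force_to_stress(10), 5.7, tolerance = 0.01 * 5.7)
  expect_equal(force_to_stress(750), 424, tolerance = 0.01 * 424)
  expect_equal(force_to_stress(0), 0)
  # linear in force, inverse-square in diameter
  set.seed(33)
  f <- stats::runif(5, 1, 1000); d <- stats::runif(5, 0.5, 4)
  expect_equal(force_to_stress(2 * f), 2 * force_to_stress(f))
  for (i in 1:5)
    expect_equal(force_to_stress(f[i], 2 * d[i]),
                 force_to_stress(f[i], d[i]) / 4, tolerance = 1e-12)
  expect_error(force_to_stress(10, 0), "diameter")
  expect_error(force_to_stress(-1), "force")
})
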