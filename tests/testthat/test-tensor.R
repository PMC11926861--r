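# Shielding-tensor processing: diagonalization, calibration, conventions.

test_that("diagonalization handles isotropic, diagonal and rotated matrices", {
  iso <- diagonalize_shielding(diag(100, 3))
  expect_equal(iso$values, rep(100, 3))
  expect_equal(iso$sigma_iso, 100)
  expect_true(iso$degenerate)

  dg <- diagonalize_shielding(diag(c(120, 100, 80)))
  expect_equal(sort(dg$values), c(80, 100, 120))
  expect_false(dg$degenerate)
  # PAS axes aligned with the input axes (columns are +/- unit vectors)
  expect_equal(abs(dg$vectors), diag(1, 3)[, order(c(120, 100, 80),
                                                   decreasing = TRUE)],
               tolerance = 1e-12)

  # conjugation by a 30 degree rotation about z leaves principal values fixed
  R <- rotation_zyz(pi / 6, 0, 0)
  rot <- diagonalize_shielding(R %*% diag(c(120, 100, 80)) %*% t(R))
  expect_equal(sort(rot$values), c(80, 100, 120), tolerance = 1e-9)
})

test_that("trace and principal values are invariant under rotation", {
  set.seed(42)
  for (i in 1:1000) {
    m <- random_symmetric()
    dg <- diagonalize_shielding(m)
    expect_equal(dg$sigma_iso, sum(diag(m)) / 3, tolerance = 1e-9)
  }
  set.seed(43)
  for (i in 1:50) {
    m <- random_symmetric()
    R <- random_rotation()
    expect_equal(sort(diagonalize_shielding(R %*% m %*% t(R))$values),
                 sort(diagonalize_shielding(m)$values), tolerance = 1e-8)
  }
})

test_that("diagonalization rejects non-finite input and warns on large antisymmetry", {
  expect_error(diagonalize_shielding(matrix(c(1, NA, rep(1, 7)), 3, 3)),
               "non-finite")
  m <- diag(c(120, 100, 80)); m[1, 2] <- 5  # antisym norm ~3.5 ppm
  expect_warning(diagonalize_shielding(m), "antisymmetric")
})

test_that("the calibration line maps shielding to shift and back", {
  expect_equal(shielding_to_shift(0), 175.7662)
  expect_equal(shielding_to_shift(100), 78.1662)
  x <- seq(-50, 250, by = 7)
  expect_equal(shift_to_shielding(shielding_to_shift(x)), x,
               tolerance = 1e-9)
  # negative slope: strictly monotone decreasing
  expect_true(all(diff(shielding_to_shift(x)) < 0))
  expect_error(shift_calibration(slope = 0), "slope")
})

test_that("Haeberlen and IUPAC parameters follow the conventions", {
  a <- haeberlen_parameters(c(10, -5, -5))
  expect_equal(a$delta_iso, 0)
  expect_equal(a$zeta, 10)
  expect_equal(a$eta, 0)
  expect_equal(a$span_omega, 15)
  expect_equal(a$skew_kappa, -1)

  b <- haeberlen_parameters(c(30, 0, -10))
  expect_equal(b$delta_iso, 20 / 3, tolerance = 1e-9)
  expect_equal(b$zeta, 70 / 3, tolerance = 1e-9)
  expect_equal(b$eta, 3 / 7, tolerance = 1e-9)
  expect_equal(b$span_omega, 40)
  expect_equal(b$skew_kappa, -0.5, tolerance = 1e-9)

  iso <- haeberlen_parameters(c(5, 5, 5))
  expect_equal(iso$zeta, 0)
  expect_equal(iso$eta, 0)
  expect_true(iso$degenerate)
})

test_that("Haeberlen ordering satisfies its defining inequalities on random input", {
  set.seed(7)
  for (i in 1:200) {
    pv <- stats::rnorm(3, 100, 60)
    h <- haeberlen_parameters(pv)
    d <- abs(h$principal - h$delta_iso)
    expect_true(d["zz"] >= d["xx"] - 1e-12 && d["xx"] >= d["yy"] - 1e-12)
    expect_gte(h$eta, 0); expect_lte(h$eta, 1)
    expect_gte(h$span_omega, 0)
    expect_lte(abs(h$skew_kappa), 1)
    # span/skew reconstructed from (iso, zeta, eta) agree to 1e-9
    h2 <- haeberlen_parameters(haeberlen_principal(h$delta_iso, h$zeta, h$eta))
    expect_equal(h2$span_omega, h$span_omega, tolerance = 1e-9)
    expect_equal(h2$skew_kappa, h$skew_kappa, tolerance = 1e-9)
  }
})

test_that("(iso, zeta, eta) -> principal -> parameters round trips", {
  set.seed(11)
  for (i in 1:200) {
    iso <- stats::runif(1, 100, 200)
    zeta <- sample(c(-1, 1), 1) * stats::runif(1, 5, 120)
    eta <- stats::runif(1, 0, 0.99)
    h <- haeberlen_parameters(haeberlen_principal(iso, zeta, eta))
    expect_equal(h$delta_iso, iso, tolerance = 1e-9)
    expect_equal(h$zeta, zeta, tolerance = 1e-9)
    expect_equal(h$eta, eta, tolerance = 1e-9)
  }
})

test_that("the PAS orientation reconstructs the symmetrized input matrix", {
  set.seed(13)
  for (i in 1:20) {
    m <- random_symmetric()
    st <- shift_tensor_from_shielding(m, shift_calibration(1, 0))
    R <- rotation_zyz(st$pas_orientation[1], st$pas_orientation[2],
                      st$pas_orientation[3])
    rebuilt <- R %*% diag(st$principal) %*% t(R)
    expect_equal(rebuilt, (m + t(m)) / 2, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("per-component calibration scales the anisotropy by |slope| and flips its sign", {
  m <- diag(c(30, 10, -40) + 100)
  st <- shift_tensor_from_shielding(m)
  raw <- haeberlen_parameters(diag(m))
  expect_equal(st$zeta, -0.9760 * raw$zeta, tolerance = 1e-9)
  expect_equal(st$eta, raw$eta, tolerance = 1e-9)
  expect_equal(st$delta_iso, shielding_to_shift(raw$delta_iso),
               tolerance = 1e-9)
  # iso-only mode calibrates delta_iso the same way but keeps |zeta|
  st2 <- shift_tensor_from_shielding(m, per_component = FALSE)
  expect_equal(st2$delta_iso, st$delta_iso, tolerance = 1e-9)
  expect_equal(st2$zeta, -raw$zeta, tolerance = 1e-9)
})

test_that("tensor tables round trip through both schemas", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tbl <- data.frame(site_id = c("a", "b", "c"),
                    residue = c("Gly", "Pro", "Hyp"),
                    s11 = c(240, 238, 235), s22 = c(180, 182, 181),
                    s33 = c(90, 95, 93))
  class(tbl) <- c("tensor_table", "data.frame")
  write_tensor_table(tbl, tmp)
  back <- read_tensor_table(tmp)
  expect_equal(nrow(back), 3)
  expect_equal(back$s22, tbl$s22)

  # full-matrix route gives identical parameters to the principal-value route
  set.seed(5)
  pv <- c(240, 180, 90)
  R <- random_rotation()
  m <- R %*% diag(pv) %*% t(R)
  tbl_m <- data.frame(site_id = "x", residue = "Gly",
                      m11 = m[1, 1], m12 = m[1, 2], m13 = m[1, 3],
                      m21 = m[2, 1], m22 = m[2, 2], m23 = m[2, 3],
                      m31 = m[3, 1], m32 = m[3, 2], m33 = m[3, 3])
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(names(tbl_m), collapse = ","),
               paste(unlist(tbl_m), collapse = ",")), tmp2)
  p_m <- tensor_table_params(read_tensor_table(tmp2))[[1]]
  p_pv <- haeberlen_parameters(pv)
  expect_equal(p_m$zeta, p_pv$zeta, tolerance = 1e-9)
  expect_equal(p_m$eta, p_pv$eta, tolerance = 1e-9)
  expect_equal(p_m$delta_iso, p_pv$delta_iso, tolerance = 1e-9)
})

test_that("tensor table reader validates input and flags the shielding scale", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("site_id\tresidue\ts11\ts22\ts33", tmp)
  expect_warning(empty <- read_tensor_table(tmp), "no rows")
  expect_equal(nrow(empty), 0)

  writeLines(c("site_id\tresidue\ts11\ts22\ts33",
               "a\tGly\t240\toops\t90"), tmp)
  expect_error(read_tensor_table(tmp), "non-numeric.*row 1")

  writeLines(c("site_id\tresidue\ts11\ts22\ts33",
               "a\tXyz\t240\t180\t90"), tmp)
  expect_error(read_tensor_table(tmp), "unknown residue")

  writeLines(c("site_id\tresidue\ts11", "a\tGly\t240"), tmp)
  expect_error(read_tensor_table(tmp), "principal-value|matrix")

  # shielding-scale flag: values are calibrated on extraction
  writeLines(c("# scale=shielding",
               "site_id\tresidue\ts11\ts22\ts33",
               "a\tGly\t240\t180\t90"), tmp)
  tb <- read_tensor_table(tmp)
  expect_equal(attr(tb, "scale"), "shielding")
  p <- tensor_table_params(tb)[[1]]
  expect_equal(p$delta_iso, shielding_to_shift(170), tolerance = 1e-9)
})
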