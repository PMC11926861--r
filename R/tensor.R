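# Chemical-shift tensor processing: diagonalization of raw shielding
# matrices, shielding->shift calibration, and the Haeberlen / IUPAC
# parameter conventions.

#' Shielding-to-shift calibration line
#'
#' An affine map \eqn{\delta = a\,\sigma + b} converting computed isotropic
#' (or principal) magnetic shieldings \eqn{\sigma} (ppm) to chemical shifts
#' \eqn{\delta} (ppm).  The defaults are the collagen carbonyl calibration
#' obtained by regressing computed isotropic shieldings against known
#' chemical shifts: slope -0.9760, intercept 175.7662 ppm.
#'
#' @param slope Dimensionless slope; must be non-zero.  Negative for the
#'   usual shielding/shift sign convention.
#' @param intercept Intercept in ppm.
#' @return An object of class `shift_calibration`.
#' @export
shift_calibration <- function(slope = -0.9760, intercept = 175.7662) {
  if (!is.finite(slope) || !is.finite(intercept) || slope == 0)
    stop_input("calibration requires finite slope != 0 and finite intercept")
  structure(list(slope = slope, intercept = intercept),
            class = "shift_calibration")
}

#' Convert shielding to chemical shift (and back)
#'
#' Applies the affine calibration \eqn{\delta = a\sigma + b}.  The map is
#' invertible; `shift_to_shielding()` is the exact inverse.
#'
#' @param sigma Shielding value(s) in ppm.
#' @param delta Chemical shift value(s) in ppm.
#' @param calibration A [shift_calibration()] object.
#' @return Numeric vector of the same length as the input.
#' @export
shielding_to_shift <- function(sigma, calibration = shift_calibration()) {
  stopifnot(inherits(calibration, "shift_calibration"))
  calibration$slope * sigma + calibration$intercept
}

#' @rdname shielding_to_shift
#' @export
shift_to_shielding <- function(delta, calibration = shift_calibration()) {
  stopifnot(inherits(calibration, "shift_calibration"))
  (delta - calibration$intercept) / calibration$slope
}

#' Diagonalize a raw shielding matrix
#'
#' Symmetrizes the (generally non-symmetric) 3x3 shielding matrix as
#' \eqn{(M + M^T)/2} — the antisymmetric part does not contribute to the
#' observable MAS lineshape at this level of theory — and eigendecomposes
#' the symmetric part to obtain principal shielding values and the
#' principal-axis-system (PAS) orientation.
#'
#' @param matrix A 3x3 numeric matrix of shielding values (ppm).
#' @param antisym_warn_ppm Warn if the Frobenius norm of the discarded
#'   antisymmetric part exceeds this many ppm (default 1).
#' @return A list with components `values` (principal shieldings, decreasing),
#'   `vectors` (matching eigenvector columns, right-handed),
#'   `sigma_iso` (mean principal shielding = trace/3),
#'   `antisym_norm`, and `degenerate` (TRUE if all eigenvalues coincide, in
#'   which case the PAS orientation is arbitrary).
#' @export
diagonalize_shielding <- function(matrix, antisym_warn_ppm = 1) {
  m <- base::matrix(as.numeric(matrix), 3, 3)
  check_finite(m, "shielding matrix")
  sym <- (m + t(m)) / 2
  anti <- (m - t(m)) / 2
  antisym_norm <- sqrt(sum(anti^2))
  if (antisym_norm > antisym_warn_ppm)
    warning(sprintf(
      "antisymmetric part of shielding matrix discarded (norm %.3g ppm)",
      antisym_norm))
  e <- eigen(sym, symmetric = TRUE)
  vec <- e$vectors
  if (det(vec) < 0) vec[, 3] <- -vec[, 3]  # enforce right-handed PAS
  spread <- max(e$values) - min(e$values)
  list(values = e$values, vectors = vec,
       sigma_iso = mean(e$values),
       antisym_norm = antisym_norm,
       degenerate = spread <= 1e-9 * max(1, abs(mean(e$values))))
}

#' Principal shift values from Haeberlen parameters
#'
#' Reconstructs the three principal chemical-shift values
#' \eqn{(\delta_{xx}, \delta_{yy}, \delta_{zz})} from the Haeberlen triple
#' \eqn{(\delta_{iso}, \zeta, \eta)}:
#' \eqn{\delta_{zz} = \delta_{iso} + \zeta},
#' \eqn{\delta_{xx} = \delta_{iso} - \zeta(1+\eta)/2},
#' \eqn{\delta_{yy} = \delta_{iso} - \zeta(1-\eta)/2}.
#'
#' @param delta_iso Isotropic shift (ppm).
#' @param zeta Signed anisotropy \eqn{\zeta = \delta_{zz}-\delta_{iso}} (ppm).
#' @param eta Asymmetry in `[0, 1]`.
#' @return Numeric vector `c(xx, yy, zz)` in ppm.
#' @export
haeberlen_principal <- function(delta_iso, zeta, eta) {
  if (!is.finite(eta) || eta < -1e-12 || eta > 1 + 1e-12)
    stop_input("eta must lie in [0, 1], got %g", eta)
  c(xx = delta_iso - zeta * (1 + eta) / 2,
    yy = delta_iso - zeta * (1 - eta) / 2,
    zz = delta_iso + zeta)
}

#' Haeberlen and IUPAC parameters from principal shift values
#'
#' Orders three principal chemical-shift values by the Haeberlen rule
#' \eqn{|\delta_{zz}-\delta_{iso}| \ge |\delta_{xx}-\delta_{iso}| \ge
#' |\delta_{yy}-\delta_{iso}|} and returns the anisotropy
#' \eqn{\zeta = \delta_{zz}-\delta_{iso}}, asymmetry
#' \eqn{\eta = (\delta_{yy}-\delta_{xx})/\zeta \in [0,1]}, together with the
#' IUPAC span \eqn{\Omega = \delta_{11}-\delta_{33}} and skew
#' \eqn{\kappa = 3(\delta_{22}-\delta_{iso})/\Omega} for
#' \eqn{\delta_{11} \ge \delta_{22} \ge \delta_{33}}.
#'
#' An isotropic tensor (\eqn{\zeta = 0}) is returned with `eta = 0` and the
#' `degenerate` flag set, so downstream code stays total.  An exact ordering
#' tie (\eqn{\eta = 1} with either sign of \eqn{\zeta} admissible) is broken
#' deterministically towards \eqn{\zeta > 0}.
#'
#' @param principal Numeric vector of three principal shifts (ppm).
#' @param vectors Optional 3x3 matrix whose columns are the PAS axes matching
#'   `principal`; if given, columns are permuted to the Haeberlen (x, y, z)
#'   assignment and the PAS orientation is reported as ZYZ Euler angles.
#' @return An object of class `shift_tensor`: a list with `delta_iso`, `zeta`,
#'   `eta`, `span_omega`, `skew_kappa`, `principal` (named xx/yy/zz),
#'   `pas_orientation` (ZYZ angles, radians; NULL if no vectors supplied) and
#'   `degenerate`.
#' @export
haeberlen_parameters <- function(principal, vectors = NULL) {
  pv <- as.numeric(principal)
  if (length(pv) != 3) stop_input("need exactly three principal values")
  check_finite(pv, "principal values")
  iso <- mean(pv)
  d <- pv - iso
  tol <- 1e-12 * max(1, abs(iso), max(abs(d)))

  # choose zz = largest |deviation|; on an exact tie prefer zeta > 0
  ord <- order(abs(d), d, decreasing = TRUE)
  i_zz <- ord[1]
  rest <- ord[2:3]
  # among the remaining two, xx has the larger |deviation| (ties: keep order,
  # which drives eta -> 1 consistently)
  if (abs(d[rest[2]]) > abs(d[rest[1]]) + tol) rest <- rev(rest)
  i_xx <- rest[1]; i_yy <- rest[2]

  zeta <- d[i_zz]
  degenerate <- abs(zeta) <= tol
  eta <- if (degenerate) 0 else (d[i_yy] - d[i_xx]) / zeta
  eta <- max(0, min(1, eta))

  srt <- sort(pv, decreasing = TRUE)
  span <- srt[1] - srt[3]
  kappa <- if (span <= tol) 0 else 3 * (srt[2] - iso) / span
  kappa <- max(-1, min(1, kappa))

  pas <- NULL
  if (!is.null(vectors) && !degenerate) {
    v <- vectors[, c(i_xx, i_yy, i_zz), drop = FALSE]
    if (det(v) < 0) v[, 1] <- -v[, 1]
    pas <- euler_from_rotation(v)
  } else if (!is.null(vectors)) {
    pas <- c(alpha = 0, beta = 0, gamma = 0)
  }

  structure(list(delta_iso = iso,
                 zeta = if (degenerate) 0 else zeta,
                 eta = eta,
                 span_omega = span,
                 skew_kappa = kappa,
                 principal = c(xx = pv[i_xx], yy = pv[i_yy], zz = pv[i_zz]),
                 pas_orientation = pas,
                 degenerate = degenerate),
            class = "shift_tensor")
}

#' Construct a chemical-shift tensor from Haeberlen parameters
#'
#' Convenience constructor used throughout the simulation layer.
#'
#' @inheritParams haeberlen_principal
#' @param pas_orientation Optional ZYZ Euler angles (radians) of the PAS in
#'   the molecular frame; defaults to the identity.
#' @return A `shift_tensor` object (see [haeberlen_parameters()]).
#' @export
shift_tensor <- function(delta_iso, zeta, eta, pas_orientation = c(0, 0, 0)) {
  st <- haeberlen_parameters(haeberlen_principal(delta_iso, zeta, eta))
  st$pas_orientation <- c(alpha = pas_orientation[1],
                          beta = pas_orientation[2],
                          gamma = pas_orientation[3])
  st
}

#' @export
print.shift_tensor <- function(x, ...) {
  cat(sprintf(
    "Chemical-shift tensor: delta_iso = %.4f ppm, zeta = %.4f ppm, eta = %.4f\n",
    x$delta_iso, x$zeta, x$eta))
  cat(sprintf("  IUPAC: span = %.4f ppm, skew = %.4f%s\n",
              x$span_omega, x$skew_kappa,
              if (isTRUE(x$degenerate)) "  [degenerate: isotropic]" else ""))
  invisible(x)
}

#' Full shift-tensor parameters from a raw shielding matrix
#'
#' Runs the complete processing chain: symmetrize and diagonalize the
#' shielding matrix, apply the shielding-to-shift calibration, and express
#' the result in the Haeberlen and IUPAC conventions with the PAS
#' orientation.
#'
#' By default the calibration line is applied to each principal component
#' (`per_component = TRUE`), so the anisotropy scales by `|slope|` and flips
#' sign for a negative slope; this is the only reading under which calibrated
#' tensors stay internally consistent.  With `per_component = FALSE` only the
#' isotropic shift is calibrated and the shielding anisotropy is carried over
#' with its sign flipped by `sign(slope)`.
#'
#' @param matrix 3x3 shielding matrix (ppm).
#' @param calibration A [shift_calibration()].
#' @param per_component Apply the calibration per principal component
#'   (default) or to the isotropic value only.
#' @return A `shift_tensor` object.
#' @export
shift_tensor_from_shielding <- function(matrix,
                                        calibration = shift_calibration(),
                                        per_component = TRUE) {
  dg <- diagonalize_shielding(matrix)
  if (per_component) {
    pv <- shielding_to_shift(dg$values, calibration)
    haeberlen_parameters(pv, dg$vectors)
  } else {
    st <- haeberlen_parameters(dg$values, dg$vectors)
    iso <- shielding_to_shift(st$delta_iso, calibration)
    out <- shift_tensor(iso, sign(calibration$slope) * st$zeta, st$eta)
    out$pas_orientation <- st$pas_orientation
    out$degenerate <- st$degenerate
    out
  }
}

RESIDUE_VOCAB <- c("Gly", "Pro", "Hyp", "other")

#' Read a tensor table
#'
#' Reads a delimited text file (comma or tab, auto-detected) with one nucleus
#' per row.  Two schemas are accepted: principal-value columns
#' `(site_id, residue, s11, s22, s33)` or full-matrix columns
#' `(site_id, residue, m11, m12, m13, m21, m22, m23, m31, m32, m33)`.
#' Optional columns `strain_pct` and `force_pN` are carried through.
#' Leading `# key=value` comment lines are parsed; `# scale=shielding`
#' marks values on the shielding scale (they are converted to shifts with
#' `calibration` when parameters are extracted).  A header row is mandatory.
#'
#' @param path Path to the file.
#' @return A data frame of class `tensor_table` with attribute `scale`
#'   (`"shift"` or `"shielding"`).
#' @export
read_tensor_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines)
  scale <- "shift"
  if (length(meta_lines)) {
    meta <- sub("^\\s*#\\s*", "", lines[meta_lines])
    kv <- strsplit(meta, "=", fixed = TRUE)
    for (p in kv) if (length(p) == 2 && trimws(p[1]) == "scale")
      scale <- trimws(p[2])
    lines <- lines[-meta_lines]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("tensor table ", path, " is empty")
    out <- data.frame(site_id = character(), residue = character(),
                      s11 = numeric(), s22 = numeric(), s33 = numeric())
    class(out) <- c("tensor_table", "data.frame")
    attr(out, "scale") <- scale
    return(out)
  }
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0) warning("tensor table ", path, " has a header but no rows")

  pv_cols <- c("s11", "s22", "s33")
  m_cols <- paste0("m", as.vector(outer(1:3, 1:3, function(i, j) paste0(i, j))))
  has_pv <- all(pv_cols %in% names(df))
  has_m <- all(m_cols %in% names(df))
  if (!("site_id" %in% names(df)) || !("residue" %in% names(df)))
    stop_input("tensor table %s: missing site_id / residue columns", path)
  if (!has_pv && !has_m)
    stop_input(paste0("tensor table %s: need either principal-value columns ",
                      "(s11,s22,s33) or matrix columns (m11..m33)"), path)
  num_cols <- if (has_m) m_cols else pv_cols
  num_cols <- c(num_cols, intersect(c("strain_pct", "force_pN"), names(df)))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v) & !is.na(df[[cn]]) | is.na(v))
    if (length(bad))
      stop_input("tensor table %s: non-numeric value in column %s, row %d",
                 path, cn, bad[1])
    df[[cn]] <- v
  }
  bad_res <- which(!(df$residue %in% RESIDUE_VOCAB))
  if (length(bad_res))
    stop_input("tensor table %s: unknown residue '%s' in row %d (allowed: %s)",
               path, df$residue[bad_res[1]], bad_res[1],
               paste(RESIDUE_VOCAB, collapse = ", "))
  class(df) <- c("tensor_table", "data.frame")
  attr(df, "scale") <- scale
  df
}

#' Write a tensor table
#'
#' Inverse of [read_tensor_table()]; writes tab-separated text with a
#' `# scale=` comment header.
#'
#' @param table A `tensor_table` data frame.
#' @param path Output path.
#' @param scale `"shift"` (default) or `"shielding"`.
#' @return The path, invisibly.
#' @export
write_tensor_table <- function(table, path, scale = attr(table, "scale")) {
  if (is.null(scale)) scale <- "shift"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s", scale), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract shift tensors from a tensor table
#'
#' Converts every row of a tensor table into a `shift_tensor`.  Shielding-
#' scale tables are calibrated first (per principal component by default, see
#' [shift_tensor_from_shielding()]); matrix-schema rows are symmetrized and
#' diagonalized.
#'
#' @param table A `tensor_table` from [read_tensor_table()].
#' @param calibration A [shift_calibration()] used when the table is on the
#'   shielding scale.
#' @param per_component Calibration mode, see [shift_tensor_from_shielding()].
#' @return A named list of `shift_tensor` objects (names = site_id), with the
#'   row's `residue`, `strain_pct` and `force_pN` attached to each element.
#' @export
tensor_table_params <- function(table, calibration = shift_calibration(),
                                per_component = TRUE) {
  scale <- attr(table, "scale")
  if (is.null(scale)) scale <- "shift"
  has_m <- all(paste0("m", c(11, 12, 13, 21, 22, 23, 31, 32, 33)) %in%
                 names(table))
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    if (has_m) {
      m <- matrix(as.numeric(table[i, paste0(
        "m", c(11, 12, 13, 21, 22, 23, 31, 32, 33))]), 3, 3, byrow = TRUE)
      st <- if (scale == "shielding")
        shift_tensor_from_shielding(m, calibration, per_component)
      else {
        dg <- diagonalize_shielding(m)
        haeberlen_parameters(dg$values, dg$vectors)
      }
    } else {
      pv <- as.numeric(table[i, c("s11", "s22", "s33")])
      if (scale == "shielding") {
        if (per_component) pv <- shielding_to_shift(pv, calibration)
        st <- haeberlen_parameters(pv)
        if (!per_component) {
          iso_cal <- shielding_to_shift(st$delta_iso + 0, calibration)
          st <- shift_tensor(iso_cal, sign(calibration$slope) * st$zeta, st$eta)
        }
      } else st <- haeberlen_parameters(pv)
    }
    st$residue <- table$residue[i]
    if ("strain_pct" %in% names(table)) st$strain_pct <- table$strain_pct[i]
    if ("force_pN" %in% names(table)) st$force_pN <- table$force_pN[i]
    out[[i]] <- st
  }
  names(out) <- table$site_id
  out
}
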