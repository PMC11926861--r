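# Composite collagen carbonyl patterns and the two interpretation sweeps:
# sideband intensity ratios versus molecular strain at fixed alignment, and
# versus the alignment parameter c/a at fixed tensors.

#' Composite pattern specification
#'
#' @param residue_weights Named non-negative weights per residue; default the
#'   collagen model-peptide composition Gly:Pro:Hyp = 1:1:1.
#' @param normalization_mode One of `"isotropic"` (divide by the centreband,
#'   the Fig-style convention), `"sideband:<index>"` (e.g. `"sideband:-3"`),
#'   `"max"`, or `"none"`.
#' @return An object of class `composite_spec`.
#' @export
composite_spec <- function(residue_weights = c(Gly = 1, Pro = 1, Hyp = 1),
                           normalization_mode = "isotropic") {
  if (any(residue_weights < 0) || sum(residue_weights) <= 0)
    stop_input("residue weights must be non-negative and not all zero")
  if (is.null(names(residue_weights)))
    stop_input("residue_weights must be named by residue")
  ok <- normalization_mode %in% c("isotropic", "max", "none") ||
    grepl("^sideband:-?[0-9]+$", normalization_mode)
  if (!ok) stop_input("unknown normalization mode '%s'", normalization_mode)
  structure(list(residue_weights = residue_weights,
                 normalization_mode = normalization_mode),
            class = "composite_spec")
}

#' Normalize a sideband pattern
#'
#' Divides all intensities by a reference intensity: the centreband
#' (`"isotropic"`), a specific sideband (`"sideband:<index>"`), the maximum
#' (`"max"`), or leaves the pattern unchanged (`"none"`).
#'
#' @param pattern A `sideband_pattern`.
#' @param mode Normalization mode string.
#' @return A `sideband_pattern` with the mode recorded.
#' @export
normalize_pattern <- function(pattern, mode = "isotropic") {
  stopifnot(inherits(pattern, "sideband_pattern"))
  if (mode == "none") return(pattern)
  ref <- if (mode == "isotropic") sideband_intensity(pattern, 0L)
  else if (mode == "max") max(pattern$intensity)
  else if (grepl("^sideband:-?[0-9]+$", mode))
    sideband_intensity(pattern, as.integer(sub("^sideband:", "", mode)))
  else stop_input("unknown normalization mode '%s'", mode)
  if (!is.finite(ref) || ref <= 1e-12)
    stop_input("reference intensity for mode '%s' is zero or missing", mode)
  pattern$intensity <- pattern$intensity / ref
  pattern$normalization <- mode
  pattern
}

#' Composite pattern from per-residue patterns
#'
#' Weighted sum of per-residue sideband patterns (matched by sideband index),
#' renormalized to total intensity 1 and then passed through the spec's
#' normalization mode.  All patterns must share MAS rate and field.
#'
#' @param per_residue Named list of `sideband_pattern`s, names = residues.
#' @param spec A [composite_spec()].
#' @return A `sideband_pattern`.
#' @export
composite_pattern <- function(per_residue, spec = composite_spec()) {
  if (length(per_residue) == 0) stop_input("no patterns supplied")
  if (is.null(names(per_residue)))
    stop_input("per_residue patterns must be named by residue")
  miss <- setdiff(names(per_residue), names(spec$residue_weights))
  if (length(miss))
    stop_input("no composite weight for residue(s): %s",
               paste(miss, collapse = ", "))
  cfg0 <- per_residue[[1]]$config
  for (p in per_residue) {
    if (p$config$mas_rate_Hz != cfg0$mas_rate_Hz ||
        p$config$larmor_MHz != cfg0$larmor_MHz)
      stop_input("patterns mix MAS rates or fields; cannot combine")
  }
  w <- spec$residue_weights[names(per_residue)]
  w <- w / sum(w)
  index <- sort(unique(unlist(lapply(per_residue, `[[`, "index"))))
  total <- numeric(length(index))
  iso <- 0
  for (k in seq_along(per_residue)) {
    p <- per_residue[[k]]
    total <- total + w[k] * sideband_intensity(p, index)
    iso <- iso + w[k] * p$delta_iso
  }
  total <- total / sum(total)
  out <- new_sideband_pattern(index, total, iso, cfg0)
  normalize_pattern(out, spec$normalization_mode)
}

#' A strain point: force, molecular strain, and per-residue tensors
#'
#' @param strain_pct Molecular tensile strain in percent (>= 0).
#' @param tensors Named list of `shift_tensor`s per residue.
#' @param force_pN Applied force in piconewtons (>= 0), optional.
#' @return An object of class `strain_point`.
#' @export
strain_point <- function(strain_pct, tensors, force_pN = NA_real_) {
  if (strain_pct < 0) stop_input("strain_pct must be >= 0")
  if (!is.na(force_pN) && force_pN < 0) stop_input("force_pN must be >= 0")
  if (is.null(names(tensors))) stop_input("tensors must be named by residue")
  structure(list(strain_pct = strain_pct, force_pN = force_pN,
                 tensors = tensors),
            class = "strain_point")
}

#' Build strain points from a tensor table
#'
#' Groups the rows of a tensor table by `strain_pct` and residue.  With
#' several sites per residue at one strain level the first is used and a
#' warning emitted.
#'
#' @param table A `tensor_table` with a `strain_pct` column.
#' @param calibration Passed to [tensor_table_params()].
#' @return A list of `strain_point`s sorted by strain.
#' @export
strain_points_from_table <- function(table, calibration = shift_calibration()) {
  if (!("strain_pct" %in% names(table)))
    stop_input("tensor table has no strain_pct column")
  params <- tensor_table_params(table, calibration)
  levels <- sort(unique(table$strain_pct))
  lapply(levels, function(s) {
    rows <- which(table$strain_pct == s)
    res <- table$residue[rows]
    if (anyDuplicated(res)) {
      warning("multiple sites per residue at strain ", s, "%; using the first")
      rows <- rows[!duplicated(res)]
      res <- res[!duplicated(res)]
    }
    tl <- params[rows]
    names(tl) <- res
    fp <- if ("force_pN" %in% names(table)) table$force_pN[rows[1]] else NA_real_
    strain_point(s, tl, fp)
  })
}

sweep_result <- function(variable, values, index, ratios, patterns,
                         reference) {
  structure(list(sweep_variable = variable, values = values, index = index,
                 ratios = ratios, patterns = patterns, reference = reference),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sideband-ratio sweep over %s (reference: %s)\n",
              x$sweep_variable, x$reference))
  m <- round(x$ratios, 4)
  dimnames(m) <- list(format(x$values), paste0("N", x$index))
  print(m)
  invisible(x)
}

ratio_indices <- function(ref_pattern, n_max) {
  idx <- ref_pattern$index
  keep <- abs(idx) <= n_max & sideband_intensity(ref_pattern, idx) > 1e-8
  sort(idx[keep])
}

#' Alignment sweep of composite sideband ratios
#'
#' For each aspect ratio c/a, generates an orientation set (one shared seed),
#' simulates per-residue patterns, builds the normalized composite, and
#' reports each sideband intensity relative to the `c/a = 1` (uniform)
#' composite.  This is the "increasing molecular order" arm of the
#' strain-versus-alignment comparison.
#'
#' @param tensors Named list of `shift_tensor`s per residue.
#' @param c_over_a_values Aspect ratios; must contain the reference (1 by
#'   default).
#' @param spec A [composite_spec()].
#' @param config A [spectrometer_config()].
#' @param grid_n Orientations per set (default 5000).
#' @param seed RNG seed shared by all sets.
#' @param reference Reference aspect ratio (default 1).
#' @param n_max Largest |sideband index| reported (default 6).
#' @param method Sampling method, see [distribution_spec()].
#' @return A `sweep_result` with a ratio matrix (values x sideband index),
#'   the composite patterns, and per-value order parameters in
#'   `attr(, "order_parameters")`.
#' @export
alignment_sweep <- function(tensors, c_over_a_values = c(1, 2, 5, 10),
                            spec = composite_spec(),
                            config = spectrometer_config(),
                            grid_n = 5000, seed = 1, reference = 1,
                            n_max = 6, method = "random") {
  if (!(reference %in% c_over_a_values))
    stop_input("c_over_a_values must include the reference (%g)", reference)
  patterns <- list()
  p2 <- numeric(length(c_over_a_values))
  for (i in seq_along(c_over_a_values)) {
    ca <- c_over_a_values[i]
    os <- sample_ellipsoid_projected(
      distribution_spec(grid_n, ca, seed, method))
    p2[i] <- order_parameter(os)
    per_res <- lapply(tensors, ensemble_pattern, orientations = os,
                      config = config)
    patterns[[i]] <- composite_pattern(per_res, spec)
  }
  ref_pat <- patterns[[match(reference, c_over_a_values)]]
  idx <- ratio_indices(ref_pat, n_max)
  ratios <- t(vapply(patterns, function(p)
    sideband_intensity(p, idx) / sideband_intensity(ref_pat, idx),
    numeric(length(idx))))
  out <- sweep_result("c_over_a", c_over_a_values, idx, ratios, patterns,
                      sprintf("uniform orientation distribution (c/a = %g)",
                              reference))
  attr(out, "order_parameters") <- p2
  out
}

#' Strain sweep of composite sideband ratios at fixed alignment
#'
#' Simulates the composite pattern for each strain point using one
#' orientation set (fixed `c_over_a`, default 10, one seed, reused across
#' strain levels so that tensor effects are isolated), and reports sideband
#' intensities relative to the 0 %-strain composite.
#'
#' @param strain_points List of [strain_point()]s; must include 0 % strain.
#' @param c_over_a Fixed aspect ratio (default 10).
#' @param spec A [composite_spec()].
#' @param config A [spectrometer_config()].
#' @param grid_n Orientations in the shared set (default 5000).
#' @param seed RNG seed for the shared set.
#' @param n_max Largest |sideband index| reported (default 6).
#' @param method Sampling method, see [distribution_spec()].
#' @return A `sweep_result` (values = strain percentages).
#' @export
strain_sweep <- function(strain_points, c_over_a = 10,
                         spec = composite_spec(),
                         config = spectrometer_config(),
                         grid_n = 5000, seed = 1, n_max = 6,
                         method = "random") {
  strains <- vapply(strain_points, `[[`, numeric(1), "strain_pct")
  if (!any(strains == 0))
    stop_input("strain sweep needs a 0%% strain reference point")
  os <- sample_ellipsoid_projected(
    distribution_spec(grid_n, c_over_a, seed, method))
  patterns <- lapply(strain_points, function(sp) {
    per_res <- lapply(sp$tensors, ensemble_pattern, orientations = os,
                      config = config)
    composite_pattern(per_res, spec)
  })
  ref_pat <- patterns[[which(strains == 0)[1]]]
  idx <- ratio_indices(ref_pat, n_max)
  ratios <- t(vapply(patterns, function(p)
    sideband_intensity(p, idx) / sideband_intensity(ref_pat, idx),
    numeric(length(idx))))
  sweep_result("strain_pct", strains, idx, ratios, patterns,
               "0% strain condition")
}

#' Fraction of sideband orders with monotone ratio trends
#'
#' Diagnostic for the qualitative contrast between the two sweeps: over the
#' reported sideband orders, the fraction whose ratio sequence is monotone
#' (non-decreasing or non-increasing within `tol`) across the sweep values.
#'
#' @param sweep A `sweep_result`.
#' @param tol Tolerance for monotonicity violations (default 0).
#' @return A number in `[0, 1]`.
#' @export
monotone_fraction <- function(sweep, tol = 0) {
  stopifnot(inherits(sweep, "sweep_result"))
  mono <- apply(sweep$ratios, 2, function(r) {
    d <- diff(r)
    all(d >= -tol) || all(d <= tol)
  })
  mean(mono)
}

#' Convert an axial force on a molecular cylinder to stress
#'
#' \eqn{\sigma = F / (\pi (d/2)^2)} with the force in pN and the diameter in
#' nm, returned in MPa.  With the 1.5 nm diameter of a collagen triple helix,
#' 10 pN corresponds to about 5.7 MPa and 750 pN to about 424 MPa.
#'
#' @param force_pN Force in piconewtons (>= 0); vectorized.
#' @param diameter_nm Cylinder diameter in nm (> 0), default 1.5.
#' @return Stress in MPa.
#' @export
force_to_stress <- function(force_pN, diameter_nm = 1.5) {
  if (any(force_pN < 0)) stop_input("force must be >= 0")
  if (diameter_nm <= 0) stop_input("diameter must be > 0")
  area_m2 <- pi * (diameter_nm / 2 * 1e-9)^2
  force_pN * 1e-12 / area_m2 / 1e6
}
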