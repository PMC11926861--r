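# Synthetic inputs for the whole pipeline: per-strain chemical-shift tensor
# tables emulating the statistical structure of quantum-chemical output for
# strained collagen model peptides, noisy slow-MAS spectra at a stated SNR,
# and on-disk fixtures in every file schema the package reads.
#
# The baseline carbonyl parameters and linear strain responses below are
# plausible literature-scale SYNTHETIC STAND-INS, chosen so that (i) values
# sit in the backbone-carbonyl range and (ii) the glycine isotropic shift is
# the largest mover under strain, mirroring the qualitative behaviour of
# computed collagen tensors.  They are configuration, not constants of
# nature.

default_baseline <- function() list(
  Gly = c(delta_iso = 170.5, zeta = -74, eta = 0.62),
  Pro = c(delta_iso = 172.8, zeta = -78, eta = 0.55),
  Hyp = c(delta_iso = 172.1, zeta = -76, eta = 0.60))

#' Synthetic collagen carbonyl tensor set
#'
#' The package's standard synthetic stand-in for the Gly/Pro/Hyp backbone
#' carbonyl shift tensors of a collagen triple helix: the default baseline
#' Haeberlen parameters combined with a principal-axis orientation that puts
#' the most-shielded component (the peptide-plane normal) perpendicular to
#' the molecular long axis and the least-shielded in-plane component along
#' it — the geometry of peptide planes that lie parallel to the helix axis.
#' With this geometry, increasing alignment of the molecular axis with the
#' rotor axis changes the low-order sideband/centreband ratios smoothly.
#'
#' @param pas_orientation ZYZ Euler angles (radians) of each tensor's PAS in
#'   the molecular frame; the default `c(0, pi/2, 0)` is the perpendicular
#'   carbonyl geometry described above.
#' @param baseline Named list per residue of `c(delta_iso, zeta, eta)`.
#' @return Named list of `shift_tensor`s (Gly, Pro, Hyp).
#' @export
collagen_carbonyl_tensors <- function(pas_orientation = c(0, pi / 2, 0),
                                      baseline = default_baseline()) {
  lapply(baseline, function(b)
    shift_tensor(unname(b["delta_iso"]), unname(b["zeta"]),
                 unname(b["eta"]), pas_orientation = pas_orientation))
}

# per-% -strain linear coefficients (ppm/% except eta, 1/%)
default_strain_response <- function() list(
  Gly = c(delta_iso = -0.120, zeta = -0.15, eta = 0.0020),
  Pro = c(delta_iso = -0.030, zeta = -0.10, eta = 0.0010),
  Hyp = c(delta_iso = -0.040, zeta = -0.08, eta = 0.0015))

#' Collagen residue composition
#'
#' Default approximate amino-acid composition of collagen used for
#' compositional bookkeeping: Gly 33%, Pro/Hyp 21% (combined), Ala 10%,
#' Arg 5%, Glu 4.5%, Ser 4%, Lys/Hyl 3.5%.
#'
#' @param fractions Named numeric vector of fractions in `[0, 1]`.
#' @return A named numeric vector of class `residue_composition`.
#' @export
residue_composition <- function(fractions = c(Gly = 0.33, `Pro/Hyp` = 0.21,
                                              Ala = 0.10, Arg = 0.05,
                                              Glu = 0.045, Ser = 0.04,
                                              `Lys/Hyl` = 0.035)) {
  if (any(fractions < 0 | fractions > 1))
    stop_input("fractions must lie in [0, 1]")
  structure(fractions, class = "residue_composition")
}

#' Synthetic tensor-table specification
#'
#' Defines the per-strain tensor tables the generator emits: baseline
#' Haeberlen parameters per residue, a linear strain response, seeded
#' Gaussian jitter, and the strain/force ladder.  The default ladder is the
#' six-level design 0, 1.4, 3.4, 8.6, 13.1, 17 % strain at 0, 10, 50, 100,
#' 250, 500 pN.
#'
#' @param strain_levels Non-negative, sorted strain percentages.
#' @param forces_pN Forces matching `strain_levels` (same length), in pN.
#' @param residues Residue labels (subset of Gly/Pro/Hyp/other).
#' @param baseline Named list per residue of `c(delta_iso, zeta, eta)`.
#' @param strain_response Named list per residue of linear coefficients per
#'   percent strain, same component names.
#' @param noise_sd Standard deviation (ppm) of seeded jitter on `delta_iso`
#'   and `zeta` (a tenth of it on `eta`); 0 for deterministic tables.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(strain_levels = c(0, 1.4, 3.4, 8.6, 13.1, 17),
                           forces_pN = c(0, 10, 50, 100, 250, 500),
                           residues = c("Gly", "Pro", "Hyp"),
                           baseline = default_baseline(),
                           strain_response = default_strain_response(),
                           noise_sd = 0, seed = 1) {
  if (is.unsorted(strain_levels) || any(strain_levels < 0))
    stop_input("strain_levels must be non-negative and sorted")
  if (length(forces_pN) != length(strain_levels))
    stop_input("forces_pN must match strain_levels in length")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  bad <- setdiff(residues, names(baseline))
  if (length(bad))
    stop_input("no baseline parameters for residue(s): %s",
               paste(bad, collapse = ", "))
  bad <- setdiff(residues, names(strain_response))
  if (length(bad))
    stop_input("no strain response for residue(s): %s",
               paste(bad, collapse = ", "))
  structure(list(strain_levels = strain_levels, forces_pN = forces_pN,
                 residues = residues, baseline = baseline,
                 strain_response = strain_response, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a per-strain tensor table
#'
#' Emits one row per (residue, strain level) with principal shift values
#' `parameters = baseline + response * strain + jitter`, in the
#' principal-value tensor-table schema (shift scale).  With the default
#' responses the glycine isotropic shift moves more across the strain range
#' than proline or hydroxyproline.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional output path; if given the table is also written via
#'   [write_tensor_table()].
#' @return A `tensor_table` data frame.
#' @export
make_strain_tensor_table <- function(spec = synthetic_spec(), path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- with_seed(spec$seed, {
    out <- list()
    for (i in seq_along(spec$strain_levels)) {
      s <- spec$strain_levels[i]
      for (res in spec$residues) {
        b <- spec$baseline[[res]]
        r <- spec$strain_response[[res]]
        jit <- if (spec$noise_sd > 0)
          stats::rnorm(3, 0, spec$noise_sd * c(1, 1, 0.1)) else c(0, 0, 0)
        diso <- unname(b["delta_iso"] + r["delta_iso"] * s) + jit[1]
        zeta <- unname(b["zeta"] + r["zeta"] * s) + jit[2]
        eta <- max(0, min(1, unname(b["eta"] + r["eta"] * s) + jit[3]))
        pv <- unname(haeberlen_principal(diso, zeta, eta))
        out[[length(out) + 1]] <- data.frame(
          site_id = sprintf("%s_C_s%g", res, s), residue = res,
          s11 = pv[1], s22 = pv[2], s33 = pv[3],
          strain_pct = s, force_pN = spec$forces_pN[i])
      }
    }
    out
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  class(tbl) <- c("tensor_table", "data.frame")
  attr(tbl, "scale") <- "shift"
  if (!is.null(path)) write_tensor_table(tbl, path)
  tbl
}

#' Generate a noisy slow-MAS spectrum
#'
#' Renders the uniform-powder spectrum of a tensor and adds seeded white
#' Gaussian noise with standard deviation `max(signal) / snr`.
#'
#' @param params A `shift_tensor`.
#' @param config A [spectrometer_config()].
#' @param snr Signal-to-noise ratio (> 0); `Inf` for a noiseless spectrum.
#' @param linewidth_ppm Rendered linewidth (FWHM, ppm).
#' @param seed RNG seed.
#' @param axis Optional ppm axis (default 4096 points spanning the pattern).
#' @param n_beta,n_gamma Powder quadrature resolution.
#' @return A two-column matrix `(ppm, intensity)`.
#' @export
make_noisy_spectrum <- function(params, config = spectrometer_config(),
                                snr = 50, linewidth_ppm = 1.5, seed = 1,
                                axis = NULL, n_beta = 64, n_gamma = 16) {
  if (!is.numeric(snr) || snr <= 0) stop_input("snr must be > 0")
  p <- powder_pattern(params, config, n_beta = n_beta, n_gamma = n_gamma)
  spec <- render_spectrum(p, linewidth_ppm = linewidth_ppm, axis = axis)
  if (is.finite(snr)) {
    sd <- max(spec[, 2]) / snr
    spec[, 2] <- spec[, 2] +
      with_seed(seed, stats::rnorm(nrow(spec), 0, sd))
  }
  spec
}

#' Write a complete set of fixture files
#'
#' Generates one file per schema the package reads — a per-strain tensor
#' table, an orientation grid (800 points, c/a = 10: the study defaults),
#' a composite sideband pattern and a rendered spectrum — all derived from
#' one seed, and returns their paths.
#'
#' @param out_dir Writable directory (created if missing).
#' @param seed Integer seed controlling every file.
#' @return Named character vector of file paths, invisibly.
#' @export
make_fixture_files <- function(out_dir, seed = 1) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  spec <- synthetic_spec(seed = seed, noise_sd = 0.05)
  tbl_path <- file.path(out_dir, "strain_tensors.tsv")
  tbl <- make_strain_tensor_table(spec, tbl_path)

  os <- sample_ellipsoid_projected(distribution_spec(800, 10, seed))
  grid_path <- file.path(out_dir, "grid.tsv")
  write_orientation_set(os, grid_path)

  cfg <- spectrometer_config()
  pts <- strain_points_from_table(tbl)
  per_res <- lapply(pts[[1]]$tensors, ensemble_pattern, orientations = os,
                    config = cfg)
  pat <- composite_pattern(per_res, composite_spec(normalization_mode = "none"))
  pat_path <- file.path(out_dir, "pattern.tsv")
  write_sideband_pattern(pat, pat_path)

  spec_path <- file.path(out_dir, "spectrum.tsv")
  sp <- make_noisy_spectrum(pts[[1]]$tensors$Gly, cfg, snr = 50, seed = seed)
  utils::write.table(data.frame(ppm = sp[, 1], intensity = sp[, 2]),
                     spec_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(tensors = tbl_path, grid = grid_path, pattern = pat_path,
              spectrum = spec_path))
}
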