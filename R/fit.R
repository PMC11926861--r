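# Least-squares recovery of Haeberlen CSA parameters from slow-MAS
# sideband patterns or rendered 1D spectra.  The forward model is the
# package's own sideband engine under a uniform-powder quadrature (or a
# user-supplied orientation set); the optimizer is a deterministic
# multi-start over a coarse (zeta, eta) grid followed by box-constrained
# local refinement, with the overall intensity scale concentrated out
# analytically at every step.

# forward model factory: returns function(zeta, eta) -> intensities at idx
make_pattern_model <- function(idx, config, orientations, n_beta, n_gamma) {
  force(idx); force(config)
  if (!is.null(orientations)) {
    function(zeta, eta) {
      p <- ensemble_pattern(shift_tensor(0, zeta, eta), orientations, config)
      sideband_intensity(p, idx)
    }
  } else {
    function(zeta, eta) {
      p <- powder_pattern(shift_tensor(0, zeta, eta), config,
                          n_beta = n_beta, n_gamma = n_gamma)
      sideband_intensity(p, idx)
    }
  }
}

# concentrated least squares: optimal scale and RSS of y against model m
conc_ls <- function(y, m) {
  denom <- sum(m^2)
  s <- if (denom > 0) sum(y * m) / denom else 0
  r <- y - s * m
  list(scale = s, rss = sum(r^2), residuals = r)
}

# deterministic multi-start grid (zeta ppm x eta)
ZETA_STARTS <- c(-110, -80, -50, -20, 20, 50, 80, 110)
ETA_STARTS <- c(0.05, 0.5, 0.95)

# nlminb reports success through several messages ("relative convergence",
# "X-convergence", "singular convergence" at a locally flat optimum); only
# iteration/evaluation limits count as non-convergence here
nlminb_converged <- function(res) {
  res$convergence == 0 || grepl("convergence", res$message, fixed = TRUE)
}

#' Fit CSA parameters to a sideband pattern or spectrum
#'
#' Recovers the Haeberlen parameters (anisotropy \eqn{\zeta}, asymmetry
#' \eqn{\eta}), overall intensity, and — in lineshape mode — the linewidth,
#' from observed spinning-sideband data, by least squares against the
#' package's sideband engine.  A deterministic multi-start over a coarse
#' \eqn{(\zeta, \eta)} grid (\eqn{\zeta \in \{\pm 20, \pm 50, \pm 80,
#' \pm 110\}} ppm, \eqn{\eta \in \{0.05, 0.5, 0.95\}}) guards against local
#' minima and resolves the sign of \eqn{\zeta} from the sideband envelope
#' asymmetry; \eqn{\eta} is constrained to `[0, 1]`.  Standard errors come
#' from the linearized covariance at the optimum.
#'
#' @param observed Either a `sideband_pattern` (intensity-domain fit) or a
#'   two-column matrix / data frame `(ppm, intensity)` (spectrum fit, which
#'   also estimates the isotropic shift and linewidth).
#' @param config A [spectrometer_config()] with the MAS rate and field of
#'   the measurement.
#' @param assume_uniform_orientation If `TRUE` (default) the forward model
#'   is the uniform powder; supply `orientations` to fit under a known
#'   partial alignment instead.
#' @param orientations Optional `orientation_set` replacing the powder
#'   average.
#' @param init Optional named list of starting values (`zeta`, `eta`,
#'   `delta_iso`, `linewidth_ppm`); when given, the multi-start grid is
#'   seeded with it as the first candidate.
#' @param lineshape Fit the full lineshape (linewidth as a parameter)?
#'   Default `FALSE` for pattern input, `TRUE` for spectrum input.
#' @param powder_n Quadrature resolution `c(n_beta, n_gamma)` of the final
#'   forward model (default `c(64, 16)`, matching [powder_pattern()]).
#' @param coarse_n Quadrature resolution used during multi-start screening
#'   and early refinement (default `c(16, 8)`).
#' @return An object of class `csa_fit` with components `params` (a
#'   `shift_tensor`), `intensity`, `linewidth_ppm`, `residual_norm`
#'   (\eqn{\sqrt{RSS}}), `uncertainties`, `vcov`, `fitted`, `observed`,
#'   `trace` (accepted objective values, non-increasing), `converged` and
#'   `degenerate`.  Methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @export
fit_csa <- function(observed, config = spectrometer_config(),
                    assume_uniform_orientation = TRUE,
                    orientations = NULL, init = NULL, lineshape = NULL,
                    powder_n = c(64, 16), coarse_n = c(16, 8)) {
  if (!assume_uniform_orientation && is.null(orientations))
    stop_input("supply an orientation set or assume a uniform orientation")
  if (assume_uniform_orientation) orientations <- NULL
  if (inherits(observed, "sideband_pattern")) {
    if (is.null(lineshape)) lineshape <- FALSE
    if (lineshape)
      stop_input("lineshape mode needs a spectrum, not a sideband pattern")
    fit_csa_pattern(observed, config, orientations, init, powder_n, coarse_n)
  } else {
    observed <- as.matrix(observed)
    if (ncol(observed) != 2)
      stop_input("spectrum input must have two columns (ppm, intensity)")
    if (is.null(lineshape)) lineshape <- TRUE
    fit_csa_spectrum(observed, config, orientations, init, lineshape,
                     powder_n, coarse_n)
  }
}

fit_csa_pattern <- function(pattern, config, orientations, init,
                            powder_n, coarse_n) {
  idx <- pattern$index[abs(pattern$index) <= config$n_sidebands_max]
  y <- sideband_intensity(pattern, idx)
  trace <- numeric(0)

  # degenerate shortcut: all intensity in the centreband
  if (sideband_intensity(pattern, 0L) / sum(y) > 1 - 1e-9) {
    st <- shift_tensor(pattern$delta_iso, 0, 0)
    st$degenerate <- TRUE
    return(new_csa_fit(st, intensity = sum(y), linewidth = NA_real_,
                       residual = 0, unc = c(zeta = 0, eta = 0),
                       vc = NULL, fitted = y, observed = y, index = idx,
                       config = config, trace = 0, converged = TRUE,
                       degenerate = TRUE, mode = "pattern",
                       pattern = pattern))
  }
  n_obs <- sum(y > 1e-9)
  if (n_obs < 4)
    stop_input("only %d resolvable sidebands; at least 4 needed to identify (zeta, eta, intensity)",
               n_obs)

  model_coarse <- make_pattern_model(idx, config, orientations,
                                     coarse_n[1], coarse_n[2])
  model_fine <- make_pattern_model(idx, config, orientations,
                                   powder_n[1], powder_n[2])
  obj <- function(th, model) conc_ls(y, model(th[1], th[2]))$rss

  starts <- expand.grid(zeta = ZETA_STARTS, eta = ETA_STARTS)
  if (!is.null(init) && !is.null(init$zeta))
    starts <- rbind(data.frame(zeta = init$zeta,
                               eta = if (is.null(init$eta)) 0.5 else init$eta),
                    starts)
  sv <- apply(starts, 1, function(th) obj(th, model_coarse))
  best_rss <- Inf
  trace <- c(trace, cummin(sv)[length(sv)])
  ord <- order(sv)
  refine <- utils::head(ord, 3)
  best <- NULL
  for (i in refine) {
    r <- stats::nlminb(as.numeric(starts[i, ]), obj, model = model_coarse,
                       lower = c(-400, 0), upper = c(400, 1),
                       control = list(rel.tol = 1e-12))
    if (r$objective < best_rss - 1e-15 || is.null(best)) {
      if (r$objective < best_rss) trace <- c(trace, r$objective)
      best_rss <- min(best_rss, r$objective)
      if (is.null(best) || r$objective <= best$objective) best <- r
    }
  }
  # polish on the full-resolution forward model
  pol <- stats::nlminb(best$par, obj, model = model_fine,
                       lower = c(-400, 0), upper = c(400, 1),
                       control = list(rel.tol = 1e-15, abs.tol = 0,
                                      x.tol = 1e-14, iter.max = 500))
  trace <- c(trace, pol$objective)
  th <- pol$par
  m <- model_fine(th[1], th[2])
  cl <- conc_ls(y, m)

  degenerate <- abs(th[1]) < 0.5
  st <- shift_tensor(pattern$delta_iso, th[1], th[2])
  st$degenerate <- degenerate

  unc <- fit_uncertainties(y, function(p) p[3] * model_fine(p[1], p[2]),
                           c(th, cl$scale), c("zeta", "eta", "intensity"))
  new_csa_fit(st, intensity = cl$scale, linewidth = NA_real_,
              residual = sqrt(cl$rss), unc = unc$se, vc = unc$vcov,
              fitted = cl$scale * m, observed = y, index = idx,
              config = config, trace = cummin(trace),
              converged = nlminb_converged(pol), degenerate = degenerate,
              mode = "pattern", pattern = pattern)
}

fit_csa_spectrum <- function(spec, config, orientations, init, lineshape,
                             powder_n, coarse_n) {
  axis <- spec[, 1]; y <- spec[, 2]
  if (is.unsorted(axis)) { o <- order(axis); axis <- axis[o]; y <- y[o] }
  sp_ppm <- sideband_spacing_ppm(config)

  # candidate isotropic shifts: supplied, or detected spectral peaks
  cands <- if (!is.null(init) && !is.null(init$delta_iso)) init$delta_iso
  else {
    pk <- find_peaks(axis, y, min_height = 0.15 * max(y),
                     min_sep = sp_ppm / 2)
    if (length(pk) == 0) stop_input("no peaks detected in spectrum")
    utils::head(pk, 4)
  }
  lw0 <- if (!is.null(init) && !is.null(init$linewidth_ppm))
    init$linewidth_ppm else 1.5

  render_model <- function(zeta, eta, lw, diso, nb, ng_) {
    p <- if (!is.null(orientations))
      ensemble_pattern(shift_tensor(diso, zeta, eta), orientations, config)
    else powder_pattern(shift_tensor(diso, zeta, eta), config,
                        n_beta = nb, n_gamma = ng_)
    # truncation against the observed axis is expected while screening
    # displaced candidate centres; silence the render warning here
    suppressWarnings(render_spectrum(p, linewidth_ppm = lw, axis = axis))[, 2]
  }
  obj <- function(th, nb, ng_)
    conc_ls(y, render_model(th[1], th[2], th[3], th[4], nb, ng_))$rss

  starts <- expand.grid(zeta = ZETA_STARTS, eta = ETA_STARTS)
  if (!is.null(init) && !is.null(init$zeta))
    starts <- rbind(data.frame(zeta = init$zeta,
                               eta = if (is.null(init$eta)) 0.5 else init$eta),
                    starts)
  screen <- expand.grid(start = seq_len(nrow(starts)), cand = cands)
  sv <- apply(screen, 1, function(r)
    obj(c(starts$zeta[r[1]], starts$eta[r[1]], lw0, r[2]),
        coarse_n[1], coarse_n[2]))
  trace <- min(sv)
  # refine the best start of each of the leading centreband candidates, so a
  # spuriously good screen at a comb-displaced centre cannot crowd out the
  # true one before local refinement
  best_by_cand <- vapply(split(seq_along(sv), screen$cand), function(ii)
    ii[which.min(sv[ii])], integer(1))
  ord <- best_by_cand[order(sv[best_by_cand])]
  best <- NULL
  for (i in utils::head(ord, 3)) {
    th0 <- c(starts$zeta[screen$start[i]], starts$eta[screen$start[i]],
             lw0, screen$cand[i])
    lower <- c(-400, 0, 0.01, th0[4] - sp_ppm / 2)
    upper <- c(400, 1, 30, th0[4] + sp_ppm / 2)
    r <- stats::nlminb(th0, obj, nb = coarse_n[1], ng_ = coarse_n[2],
                       lower = lower, upper = upper,
                       control = list(rel.tol = 1e-10))
    if (is.null(best) || r$objective < best$objective) best <- r
    trace <- c(trace, min(trace[length(trace)], r$objective))
  }
  th0 <- best$par
  pol <- stats::nlminb(th0, obj, nb = powder_n[1], ng_ = powder_n[2],
                       lower = c(-400, 0, 0.01, th0[4] - sp_ppm / 2),
                       upper = c(400, 1, 30, th0[4] + sp_ppm / 2),
                       control = list(rel.tol = 1e-14, iter.max = 400))
  trace <- c(trace, pol$objective)
  th <- pol$par
  m <- render_model(th[1], th[2], th[3], th[4], powder_n[1], powder_n[2])
  cl <- conc_ls(y, m)

  degenerate <- abs(th[1]) < 0.5
  st <- shift_tensor(th[4], th[1], th[2])
  st$degenerate <- degenerate
  unc <- fit_uncertainties(y, function(p)
    p[5] * render_model(p[1], p[2], p[3], p[4], powder_n[1], powder_n[2]),
    c(th, cl$scale),
    c("zeta", "eta", "linewidth_ppm", "delta_iso", "intensity"))
  if (!lineshape) th[3] <- NA_real_
  new_csa_fit(st, intensity = cl$scale, linewidth = th[3],
              residual = sqrt(cl$rss), unc = unc$se, vc = unc$vcov,
              fitted = cl$scale * m, observed = y, index = NULL,
              config = config, trace = cummin(trace),
              converged = nlminb_converged(pol), degenerate = degenerate,
              mode = "spectrum", pattern = NULL, axis = axis)
}

# simple local-maximum peak picking, tallest first; maxima closer than
# min_sep are merged onto the tallest so noise ripples on one sideband do
# not produce duplicate candidates
find_peaks <- function(x, y, min_height, min_sep = 0) {
  n <- length(y)
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] >= min_height]
  i <- i[order(y[i], decreasing = TRUE)]
  if (min_sep > 0) {
    kept <- integer(0)
    for (j in i)
      if (!length(kept) || all(abs(x[j] - x[kept]) >= min_sep))
        kept <- c(kept, j)
    i <- kept
  }
  x[i]
}

# linearized covariance at the optimum (central differences)
fit_uncertainties <- function(y, model_fn, par, par_names) {
  n <- length(y); p <- length(par)
  m0 <- model_fn(par)
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-6, 1e-6 * abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (model_fn(pp) - model_fn(pm)) / (2 * h)
  }
  rss <- sum((y - m0)^2)
  sigma2 <- rss / max(1, n - p)
  vc <- tryCatch(sigma2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(par_names, par_names)
  list(se = stats::setNames(sqrt(pmax(0, diag(vc))), par_names), vcov = vc)
}

new_csa_fit <- function(params, intensity, linewidth, residual, unc, vc,
                        fitted, observed, index, config, trace, converged,
                        degenerate, mode, pattern, axis = NULL) {
  structure(list(params = params, intensity = intensity,
                 linewidth_ppm = linewidth, residual_norm = residual,
                 uncertainties = unc, vcov_ = vc, fitted_values = fitted,
                 observed = observed, index = index, config = config,
                 trace = trace, converged = converged,
                 degenerate = degenerate, mode = mode,
                 input_pattern = pattern, axis = axis,
                 call = sys.call(-1)),
            class = "csa_fit")
}

#' @export
print.csa_fit <- function(x, ...) {
  cat("CSA fit (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  delta_iso = %.3f ppm, zeta = %.3f ppm, eta = %.4f%s\n",
              x$params$delta_iso, x$params$zeta, x$params$eta,
              if (x$degenerate) "  [degenerate: ~isotropic]" else ""))
  if (!is.na(x$linewidth_ppm))
    cat(sprintf("  linewidth = %.3f ppm\n", x$linewidth_ppm))
  cat(sprintf("  intensity = %.4g, residual norm = %.3g, converged: %s\n",
              x$intensity, x$residual_norm, x$converged))
  invisible(x)
}

#' @export
coef.csa_fit <- function(object, ...) {
  c(delta_iso = object$params$delta_iso, zeta = object$params$zeta,
    eta = object$params$eta, intensity = object$intensity,
    linewidth_ppm = object$linewidth_ppm)
}

#' @export
vcov.csa_fit <- function(object, ...) object$vcov_

#' @export
fitted.csa_fit <- function(object, ...) object$fitted_values

#' @export
residuals.csa_fit <- function(object, ...) object$observed - object$fitted_values

#' @export
summary.csa_fit <- function(object, ...) {
  est <- coef(object)
  se <- object$uncertainties
  tab <- data.frame(estimate = est[names(se)], std_error = se)
  out <- list(fit = object, coefficients = tab,
              residual_norm = object$residual_norm,
              span = object$params$span_omega,
              skew = object$params$skew_kappa)
  class(out) <- "summary.csa_fit"
  out
}

#' @export
print.summary.csa_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(format(x$coefficients, digits = 5))
  cat(sprintf("\nIUPAC span = %.3f ppm, skew = %.4f\n", x$span, x$skew))
  invisible(x)
}

#' Predict from a CSA fit
#'
#' Simulates the fitted tensor forward: the sideband pattern
#' (`type = "pattern"`) or a rendered spectrum (`type = "spectrum"`).
#'
#' @param object A `csa_fit`.
#' @param type `"pattern"` or `"spectrum"`.
#' @param axis Optional ppm axis for spectrum prediction (defaults to the
#'   observed axis in spectrum mode).
#' @param linewidth_ppm Linewidth for spectrum prediction; defaults to the
#'   fitted value or 1 ppm.
#' @param ... Unused.
#' @return A `sideband_pattern` or a `(ppm, intensity)` matrix.
#' @export
predict.csa_fit <- function(object, type = c("pattern", "spectrum"),
                            axis = NULL, linewidth_ppm = NULL, ...) {
  type <- match.arg(type)
  p <- powder_pattern(object$params, object$config)
  if (type == "pattern") return(p)
  lw <- if (!is.null(linewidth_ppm)) linewidth_ppm
  else if (!is.na(object$linewidth_ppm)) object$linewidth_ppm else 1
  if (is.null(axis)) axis <- object$axis
  render_spectrum(p, linewidth_ppm = lw, axis = axis)
}

#' @export
plot.csa_fit <- function(x, ...) {
  if (x$mode == "pattern") {
    graphics::plot(x$index, x$observed, type = "h", lwd = 3,
                   xlab = "sideband index", ylab = "intensity",
                   main = "CSA fit: observed (bars) vs fitted (points)", ...)
    graphics::points(x$index, x$fitted_values, col = "red", pch = 19)
  } else {
    graphics::plot(x$axis, x$observed, type = "l",
                   xlim = rev(range(x$axis)),
                   xlab = "ppm", ylab = "intensity",
                   main = "CSA fit: observed vs fitted", ...)
    graphics::lines(x$axis, x$fitted_values, col = "red")
  }
  invisible(x)
}

#' Simulate noisy replicates from a CSA fit
#'
#' Draws spectra from the fitted tensor with additive white noise at a given
#' signal-to-noise ratio, using the synthetic-data noise model.
#'
#' @param object A `csa_fit`.
#' @param nsim Number of replicates.
#' @param seed RNG seed (replicate i uses `seed + i - 1`).
#' @param snr Signal-to-noise ratio (max signal / noise sd), default 50.
#' @param linewidth_ppm Linewidth; defaults as in [predict.csa_fit()].
#' @param ... Unused.
#' @return A list of `(ppm, intensity)` matrices.
#' @export
simulate.csa_fit <- function(object, nsim = 1, seed = 1, snr = 50,
                             linewidth_ppm = NULL, ...) {
  lw <- if (!is.null(linewidth_ppm)) linewidth_ppm
  else if (!is.na(object$linewidth_ppm)) object$linewidth_ppm else 1
  lapply(seq_len(nsim), function(i)
    make_noisy_spectrum(object$params, object$config, snr = snr,
                        linewidth_ppm = lw, seed = seed + i - 1,
                        axis = object$axis))
}
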