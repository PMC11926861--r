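# masSidebands

Simulation and analysis of slow magic-angle-spinning (MAS) ¹³C NMR
spinning-sideband patterns for partially oriented samples, built around the
problem of interpreting carbonyl sideband intensities in mechanically
strained collagen-rich tissue.

When a tendon is strained, two distinct molecular changes could alter the
carbonyl sideband envelope observed at slow MAS: a change in molecular
*conformation* (which moves the chemical-shift tensors themselves) or a
change in molecular *alignment* with the rotor axis (which moves the
orientation distribution the tensors are averaged over). The two produce
different fingerprints: conformational changes move some sideband
intensities up and others down, while increasing alignment changes most
sidebands smoothly relative to the isotropic signal — and a change that
only shifts isotropic frequencies leaves sideband intensity ratios exactly
alone. This package implements every computational stage needed to make
that comparison quantitative, for users who work with computed shielding
tensors and slow-MAS spectra.

## What it computes

**Tensor processing.** Raw 3×3 shielding matrices are symmetrized and
diagonalized; principal shieldings σ are converted to shifts with an affine
calibration (default δ = −0.9760 σ + 175.7662, a collagen carbonyl
calibration). Tensors are reported in both conventions:

- Haeberlen: δ_iso, ζ = δ_zz − δ_iso, η = (δ_yy − δ_xx)/ζ with
  |δ_zz − δ_iso| ≥ |δ_xx − δ_iso| ≥ |δ_yy − δ_iso|;
- IUPAC: span Ω = δ₁₁ − δ₃₃, skew κ = 3(δ₂₂ − δ_iso)/Ω.

**Orientation model.** Partial uniaxial alignment is generated by sampling
points uniformly by area on a prolate spheroid (a, a, c) and projecting
them radially onto the unit sphere; the aspect ratio c/a ≥ 1 is the
alignment parameter (c/a = 1 is a uniform powder). The diagnostic is the
order parameter ⟨P₂(cos β)⟩, with an analytic quadrature reference for any
c/a.

**Sideband engine.** For an isolated spin-½ with CSA under MAS, the
instantaneous shift is the two-harmonic Fourier series in rotor phase;
the periodic phase Φ(t) has a closed form, and rotor-phase-averaged
sideband intensities are I_N = |F_N|², the Fourier coefficients of
exp(iΦ) over a single rotor period. Σ_N I_N = 1 by Parseval. A brute-force
long-FID + DFT oracle (`fid_dft_sidebands()`) validates the engine to
better than 1e-6 per sideband.

**Analysis.** Composite Gly/Pro/Hyp (1:1:1) carbonyl patterns; sideband
ratio sweeps against molecular strain at fixed alignment (`strain_sweep()`,
one shared orientation grid) and against c/a at fixed tensors
(`alignment_sweep()`); normalization on the isotropic peak, a chosen
sideband, or the maximum; and the force→stress helper
σ = F/(π(d/2)²) for a molecular cylinder (d = 1.5 nm by default).

**Fitting.** `fit_csa()` recovers (δ_iso, ζ, η, intensity, linewidth) from
a sideband pattern or a rendered 1D spectrum by multi-start least squares
against the engine, and returns a classed `csa_fit` object with the usual
`print`, `summary`, `coef`, `vcov`, `predict`, `fitted`, `residuals`,
`plot` and `simulate` methods.

**Synthetic data.** `synthetic_spec()` / `make_strain_tensor_table()`
emulate per-strain tensor tables (defaults: strains 0, 1.4, 3.4, 8.6,
13.1, 17 % at 0–500 pN, with the glycine isotropic shift the largest
mover); `make_noisy_spectrum()` adds seeded white noise at a stated SNR;
`make_fixture_files()` writes every file schema the package reads.

## Worked example

```r
library(masSidebands)

cfg <- spectrometer_config()          # 150.9 MHz (14.1 T), 2.2 kHz MAS
tensors <- collagen_carbonyl_tensors()
tensors$Gly
#> Chemical-shift tensor: delta_iso = 170.5000 ppm, zeta = -74.0000 ppm, eta = 0.6200
#>   IUPAC: span = 133.9400 ppm, skew = 0.3149

# 800-point aligned orientation grid from an ellipsoid with axes (10, 1, 1)
os <- sample_ellipsoid_projected(distribution_spec(n_points = 800,
                                                   c_over_a = 10, seed = 1))
os
#> Orientation set: 800 points, c/a = 10, method = random, <P2> = 0.7326

# composite Gly/Pro/Hyp 1:1:1 pattern, normalized on the isotropic peak
pat <- composite_pattern(lapply(tensors, ensemble_pattern,
                                orientations = os, config = cfg),
                         composite_spec())
pat
#> Sideband pattern: delta_iso = 171.800 ppm, 2200 Hz MAS at 150.9 MHz (norm: isotropic)
#>      -6      -5      -4      -3      -2      -1       0       1       2       3
#> 0.01280 0.04257 0.12401 0.21276 0.51942 0.21572 1.00000 0.73670 0.51799 0.19101
#>       4       5       6
#> 0.06541 0.01491 0.00318

# how the sideband/isotropic ratios respond to increasing alignment
alignment_sweep(tensors, c(1, 2, 5, 10), grid_n = 5000, seed = 1, n_max = 3)
#> Sideband-ratio sweep over c_over_a (reference: uniform orientation distribution (c/a = 1))
#>       N-3    N-2    N-1 N0     N1     N2     N3
#>  1 1.0000 1.0000 1.0000  1 1.0000 1.0000 1.0000
#>  2 0.9194 0.9361 0.9681  1 0.9564 0.9279 0.9237
#>  5 0.5986 0.9509 0.6965  1 0.9154 0.6483 0.5858
#> 10 0.3022 0.8611 0.3670  1 0.6084 0.4421 0.3112

# recover CSA parameters from a noisy synthetic spectrum (SNR 50)
spec <- make_noisy_spectrum(shift_tensor(172, -75, 0.5), cfg,
                            snr = 50, linewidth_ppm = 1.5, seed = 42)
fit <- fit_csa(spec, cfg)
coef(fit)
#>     delta_iso          zeta           eta     intensity linewidth_ppm
#>     172.00272     -74.98777       0.49905       1.00284       1.50533

# stress on a 1.5 nm collagen triple helix
force_to_stress(c(10, 750))
#> [1]   5.658842 424.413182
```

The ratio table reads: at c/a = 10 the N = −3 sideband carries 30 % of the
intensity (relative to the isotropic peak) that it carries in a uniform
powder, and every ratio changes smoothly with alignment — the fingerprint
that distinguishes an ordering change from a conformational one. The fit
recovers the generating parameters (ζ = −75 ppm, η = 0.5, 1.5 ppm
linewidth) to a fraction of a percent at SNR 50.

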