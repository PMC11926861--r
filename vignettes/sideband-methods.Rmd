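---
title: "Models and methods: MAS sidebands for partially oriented samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: MAS sidebands for partially oriented samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masSidebands)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The physical model

The observable is the spinning-sideband intensity pattern of an isolated
spin-½ nucleus (in practice a ¹³C carbonyl) whose resonance frequency is
orientation-dependent through the chemical-shift anisotropy (CSA). Under
magic-angle spinning the instantaneous shift is the lab-frame component of
the shift tensor along the field, probed by a direction that precesses
about the rotor axis at the magic angle $\theta_m = \arccos(1/\sqrt 3)$.
Writing the tensor in the rotor-fixed frame as $A$, the shift is

$$\delta(t) = b(t)^\top A\, b(t), \qquad
b(t) = (\sin\theta_m\cos\omega_r t,\ \sin\theta_m\sin\omega_r t,\ \cos\theta_m),$$

which expands exactly into a constant term plus first and second rotor
harmonics. At the magic angle the constant term is $\mathrm{tr}(A)/3 =
\delta_{iso}$: the anisotropy is fully time-dependent, with coefficients

$$C_1 = 2\sin\theta_m\cos\theta_m\,A_{xz},\quad
S_1 = 2\sin\theta_m\cos\theta_m\,A_{yz},\quad
C_2 = \tfrac{1}{2}\sin^2\theta_m\,(A_{xx}-A_{yy}),\quad
S_2 = \sin^2\theta_m\,A_{xy}.$$

The accumulated anisotropic phase $\Phi(t)$ integrates in closed form, is
periodic with the rotor period, and the rotor-phase-averaged sideband
intensities are the squared Fourier coefficients of $e^{i\Phi(t)}$ over a
single period:

$$I_N = |F_N|^2, \qquad
F_N = \frac{1}{T_r}\int_0^{T_r} e^{i\Phi(t)}e^{-iN\omega_r t}\,dt .$$

Because $|e^{i\Phi}| = 1$, Parseval's theorem gives $\sum_N I_N = 1$
identically — the engine conserves intensity by construction rather than
by numerical accident. The coefficients are evaluated by FFT on
`n_time_points` samples per rotor period (default 128, a power of two;
the window is doubled automatically if spectral weight reaches its edge,
up to 4096).

Assumptions: a single spin with CSA only. Dipolar and J couplings,
cross-polarization dynamics, finite pulses and relaxation during
acquisition are all outside the model. A general-purpose spin-dynamics
engine working in Liouville space can include such effects; where a
measured pattern departs from this one-spin model, that discrepancy is
real physics the model does not claim.

### Frames and conventions

The frame chain is fixed: PAS → (tensor's `pas_orientation`) → molecular
frame → (grid $\alpha, \beta, \gamma$) → rotor frame → (magic angle +
spinning) → lab. All rotations are ZYZ, $R = R_z(\alpha) R_y(\beta)
R_z(\gamma)$, and $R(\alpha, \beta, 0)\,\hat z$ is the direction
$(\sin\beta\cos\alpha, \sin\beta\sin\alpha, \cos\beta)$. Two exact
symmetries are worth stating because they shape the whole design:

- rotation about the **rotor** axis ($\alpha$) is equivalent to a rotor
  phase shift, so exact rotor-phase averaging makes $I_N$ independent of
  $\alpha$ for *any* tensor;
- rotation about the **molecular** axis ($\gamma$) matters whenever the
  tensor is not axially symmetric about that axis; orientation sets store
  a uniformly drawn $\gamma$ per point for that reason.

Consequently the uniform-powder average (`powder_pattern()`) needs only a
two-angle quadrature: Gauss–Legendre in $\cos\beta$ (default 64 nodes)
crossed with an equally spaced $\gamma$ grid (default 16; reduced to one
node for tensors axial in their PAS). Positive sideband index means higher
frequency.

Tensor conventions follow the field's two standards. Haeberlen:
$|\delta_{zz}-\delta_{iso}| \ge |\delta_{xx}-\delta_{iso}| \ge
|\delta_{yy}-\delta_{iso}|$, $\zeta = \delta_{zz}-\delta_{iso}$, $\eta =
(\delta_{yy}-\delta_{xx})/\zeta \in [0,1]$; IUPAC: span $\Omega$ and skew
$\kappa$. Degenerate (isotropic) tensors get $\eta = 0$ and a flag so that
downstream code never divides by zero; an exact ordering tie (the
$\eta = 1$ case, where either sign of $\zeta$ reproduces the same tensor)
is broken deterministically towards $\zeta > 0$.

### Shielding calibration

Computed shieldings $\sigma$ are converted to shifts with the affine
calibration $\delta = -0.9760\,\sigma + 175.7662$ (slope dimensionless,
intercept ppm), obtained for collagen carbonyls by regressing computed
isotropic shieldings on known shifts. The calibration is stated for
isotropic values; this package applies it **per principal component** by
default, so that the anisotropy scales by $|a|$ and changes sign with the
negative slope. That is the only reading under which the calibrated
principal values, $\delta_{iso}$, $\zeta$ and $\Omega$ remain mutually
consistent, so it is the default; `per_component = FALSE` reproduces the
isotropic-only reading (anisotropy carried over with its sign flipped by
the slope's sign) for comparison. The antisymmetric part of a raw
shielding matrix does not contribute to the observable at this level of
theory; it is discarded by symmetrization, with a warning when its norm
exceeds 1 ppm.

## The orientation model

Partial uniaxial alignment is modelled geometrically: points are placed
uniformly *by surface area* on a prolate spheroid with semi-axes
$(a, a, c)$, $c/a \ge 1$, and projected radially onto the unit sphere.
Density then concentrates towards the poles as $c/a$ grows, i.e. towards
the rotor axis; $c/a = 1$ is the uniform powder, and the study default
emulating an aligned fibre is $c/a = 10$ (axes 10, 1, 1). All points carry
equal weight — alignment lives purely in point density. "Projection" means
radial normalization of the position vector, the geometrically simplest
reading. Oblate ($c/a < 1$) and biaxial ($a \ne b$) distributions are
deliberately out of scope: the modelled samples are axially symmetric
about the rotor axis.

Sampling is by rejection against the exact spheroid area element
$f(u) \propto \sqrt{c^2(1-u^2)/a^2 + u^2}$ in $u = \cos\theta$ of the
parameter angle, with the projected polar angle
$\cos\beta = (c/a)\,u / \sqrt{(1-u^2) + (c/a)^2 u^2}$. The same densities
integrate to an analytic quadrature value of
$\langle P_2(\cos\beta)\rangle$ (`ellipsoid_order_parameter()`), which is
the reference every sampler is tested against (and grows from 0 at
$c/a = 1$ towards 1 as $c/a \to \infty$). A deterministic quasi-uniform
mode (stratified inverse-CDF polar angles, golden-angle azimuths) is
available for low-variance sweeps; the default is random sampling because
Monte-Carlo error is then honestly visible in repeated runs.

```{r}
ellipsoid_order_parameter(10)
order_parameter(sample_ellipsoid_projected(distribution_spec(10000, 10, seed = 1)))
```

## Composite patterns and the two sweeps

Collagen's carbonyl signal is modelled as the 1:1:1 sum of Gly, Pro and
Hyp patterns (`composite_spec()`), renormalized to unit total intensity
and then normalized per the chosen mode — on the isotropic peak by
default, as ratio plots are usually drawn; normalization on a specific
sideband (e.g. index −3) or on the maximum is also provided for matching
differently normalized experimental figures.

The two interpretation arms are:

- `strain_sweep()`: tensors change with molecular strain, alignment fixed
  ($c/a = 10$), **one orientation grid reused** across strain levels so
  that every ratio difference is attributable to the tensors;
- `alignment_sweep()`: tensors fixed, one grid generated per $c/a$ from a
  shared seed, ratios referenced to the uniform ($c/a = 1$) pattern.

A key exact property connects them: sideband intensities depend only on
$(\zeta, \eta)$ and orientation, never on $\delta_{iso}$, so a strain
response that moves only isotropic shifts leaves every intensity ratio at
exactly 1. This is what lets slow-MAS sideband ratios discriminate
ordering changes from (isotropic-shift-dominated) conformational changes.

The qualitative contrast — conformational changes push some sidebands up
and others down, increasing order changes most ratios smoothly — is
summarized by `monotone_fraction()`, the fraction of reported sideband
orders whose ratio sequence is monotone across the sweep. It is a
*reported diagnostic*, not a hard invariant, because it depends on the
tensor set: for tensors whose unique axis lies along the molecular axis,
strong alignment suppresses all sidebands and low-order ratio curves can
be genuinely non-monotone.

### The synthetic collagen tensor geometry

`collagen_carbonyl_tensors()` is the package's standard synthetic
stand-in: baseline Haeberlen parameters of literature scale for backbone
carbonyls ($\delta_{iso} \approx 170\text{–}173$ ppm, $\zeta \approx
-74$ to $-78$ ppm, $\eta \approx 0.55$–0.62) combined with a PAS
orientation $(0, \pi/2, 0)$ that places the most-shielded principal axis
(the peptide-plane normal) perpendicular to the molecular long axis and
the least-shielded in-plane axis along it. That is the orientation of
peptide planes lying roughly parallel to a helix axis, and with it the
low-order sideband/centreband ratios of the composite respond smoothly to
alignment. These values are explicitly synthetic: they are chosen once for
realism of scale and geometry, are configuration rather than constants,
and are not computed tensor values for any specific structure.

## The synthetic-data generator

`synthetic_spec()` defines the emulated study: strain levels 0, 1.4, 3.4,
8.6, 13.1, 17 % (forces 0, 10, 50, 100, 250, 500 pN), residues Gly, Pro,
Hyp, a linear per-percent strain response, and seeded Gaussian jitter
(`noise_sd`, ppm, applied to $\delta_{iso}$ and $\zeta$, a tenth of it to
$\eta$). The default response makes the glycine isotropic shift the
largest mover across the strain range — the qualitative structure the
tables must reproduce — while anisotropies move a few percent. Linearity
is the simplest model consistent with monotone parameter trends; the
coefficients are configuration, not claims.

What the generator does *not* emulate: per-site scatter within one
residue type along the helix, correlated (non-Gaussian) parameter
changes, the aliphatic spectral region, temperature effects, or any
intensity non-uniformity from polarization transfer. Passing tests
therefore demonstrate correctness of the pipeline's mathematics and its
statistical behaviour under the stated noise model — not agreement with
any measured tendon spectrum.

`make_noisy_spectrum()` renders the powder spectrum (Lorentzian sticks of
area $I_N$, default FWHM 1.5 ppm on a 4096-point axis) and adds white
noise of standard deviation $\max(\text{signal})/\mathrm{SNR}$.

## CSA fitting

`fit_csa()` is intensity-domain least squares against the package's own
forward model, with the overall scale concentrated out analytically at
every objective evaluation. Design choices:

- **Multi-start**: a deterministic grid $\zeta \in \{\pm 20, \pm 50,
  \pm 80, \pm 110\}$ ppm $\times$ $\eta \in \{0.05, 0.5, 0.95\}$ guards
  against local minima and gives the optimizer both signs of $\zeta$; the
  envelope asymmetry then identifies the sign whenever the skew is
  appreciable. Screening runs on a coarse powder grid (16 × 8 nodes), the
  best basins are refined by box-constrained `nlminb`
  ($\eta \in [0, 1]$), and the winner is polished on the full grid
  (64 × 16) at tight tolerance. Identical quadrature in generation and
  fitting makes the noiseless round trip exact to numerical precision.
- **Spectrum mode** additionally estimates the isotropic shift and
  linewidth. Candidate centres are detected spectral peaks (merged within
  half a sideband spacing so noise ripples on one sideband do not spawn
  duplicates); because every sideband sits on the same frequency comb,
  the best start of *each* leading candidate is refined and the lowest
  final residual decides — this is what resolves the comb ambiguity of
  which peak is the centreband.
- **Degenerate inputs**: a pattern with effectively all intensity in the
  centreband returns $\zeta = 0$ with a flag rather than an error; fits
  with fewer than four resolvable sidebands raise an identifiability
  error (three parameters plus scale cannot be determined).
- **Uncertainties** are linearized (Gauss–Newton) standard errors from
  the numerical Jacobian at the optimum; they are asymptotic and assume
  i.i.d. noise on the fitted quantity.
- The accepted-objective trace is stored (`$trace`) and is non-increasing
  by construction.

Fitting alignment ($c/a$) jointly with the CSA from a single pattern is
not offered: without prior knowledge the two are practically degenerate,
and the package instead exposes forward simulation under a supplied
orientation set (`assume_uniform_orientation = FALSE`).

## Numerical choices and problem sizes

- Time grid 128 points/rotor period; doubling changes no intensity by
  more than 1e-6 at carbonyl-scale anisotropies and slow MAS, and an
  automatic edge check doubles the grid when needed.
- The brute-force validation oracle integrates the phase by cumulative
  trapezoids at 4096 points/period over 128 periods and reads sideband
  bins from a long-FID DFT; it shares no code path with the closed-form
  engine.
- Powder quadrature 64 × 16 (β × γ) for production and fitting; 512 β
  nodes for reference patterns in tests.
- Sweeps in the validation suite use 5000 orientations per set with 4
  replicate seeds to estimate Monte-Carlo standard errors; monotonicity
  is asserted within three standard errors, matching what sampling noise
  permits. Order-parameter checks use 10000 points against the analytic
  quadrature within 0.02.
- Fit validation uses 20 noisy spectra at SNR 50; recovery is summarized
  by RMSE of $\zeta$ (relative) and $\eta$ (absolute).

## Known limitations

- One-spin CSA only; no dipolar, J, CP or relaxation physics.
- Ensembles mixing tensors with different isotropic shifts are summed by
  sideband index; the stored $\delta_{iso}$ is the weighted mean. For the
  collagen carbonyls the residue shifts differ by ~2 ppm, far less than
  the 14.6 ppm sideband spacing at 2.2 kHz, so index-aligned summation is
  the right model of the overlapped experimental envelope.
- The ellipsoid-projection distribution is one geometric family of
  uniaxial alignment; it does not represent bimodal or biaxial order.
- The tensor-table schema carries principal values (or full matrices) but
  no per-site PAS orientation in the molecular frame; the sweep layer
  attaches the standard carbonyl geometry where orientation matters.
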