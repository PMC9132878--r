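---
title: "Methods: sensitivity analysis and inverse UQ for passive myocardium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitivity analysis and inverse UQ for passive myocardium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myouq)
```

This vignette is the package's own account of the science it implements:
the models, the numerical choices, and what the desk-scale synthetic
studies can and cannot show about image-derived cardiac models.

## The constitutive model

Passive myocardium is treated as an incompressible, hyperelastic,
orthotropic material with the Holzapfel–Ogden (H-O) strain-energy density

$$\Psi = \frac{a}{2b}\left[e^{b(I_1-3)}-1\right]
 + \sum_{i\in\{f,s\}}\frac{a_i}{2b_i}\left[e^{b_i(\max(I_{4i},1)-1)^2}-1\right]
 + \frac{a_{fs}}{2b_{fs}}\left[e^{b_{fs}I_{8fs}^2}-1\right],$$

where $I_1$ is the first invariant of $C = F^\top F$, $I_{4f}$ and
$I_{4s}$ are the squared stretches along the reference fibre and sheet
directions, and $I_{8fs}$ couples the two families.  The $\max$ switch
expresses that fibres and sheets bear load only in extension; it makes
$\Psi$ continuously differentiable but not twice so at $I_4 = 1$, and the
derivative exactly at the kink is taken on the compression branch (zero).
The Cauchy stress is the standard incompressible push-forward
$\tau = 2\Psi_1 B + 2\Psi_{4f}\, m\!\otimes\!m + 2\Psi_{4s}\, s\!\otimes\!s
+ \Psi_{8fs}(m\!\otimes\!s + s\!\otimes\!m) - p I$ with $m = Fm_0$,
$s = Fs_0$.  At the undeformed reference the stress is purely hydrostatic
($2\Psi_1 I = aI$), so the traction-free reference corresponds to the
equilibrium multiplier $p = a$; `cauchy_stress()` leaves $p$ to the
caller.  Because the exponents can reach 10 under the study priors,
every exponential is guarded: overflow raises a structured error naming
the offending energy term instead of returning `Inf`.

Stiffness constants are in kPa; cavity pressures are specified in mmHg
and converted (1 mmHg = 0.133322 kPa) only inside the forward solver, at
the boundary between clinical and constitutive units.

### Virtual uni-axial stretch

`uniaxial_stress()` simulates stretching a homogeneous myocardial strip
along the myocyte or sheet axis.  Given the axial stretch $\lambda$, the
two lateral stretches are found by a damped two-variable Newton iteration
on (log lateral stretch, pressure $p$) under the incompressibility
constraint, requiring both lateral Cauchy stresses to vanish.  The
equal-lateral isotropic solution $\lambda^{-1/2}$ seeds the iteration;
orthotropy makes the two lateral directions genuinely inequivalent, so
the full solve is kept rather than the equal-lateral shortcut.

## The forward model

The imaging-based finite-element left ventricle that motivates this
workflow is replaced by a semi-analytic stand-in: quasi-static passive
inflation of an incompressible thick-walled cylinder (inner radius
25 mm, outer 35 mm, length 80 mm; reference cavity volume
$\pi R_i^2 L \approx 157$ ml, in the adult range).  The fibre helix
angle rotates linearly across the wall from $+60^\circ$ at the
endocardium to $-90^\circ$ at the epicardium (configurable over the
study bounds), and the sheet angle from $+45^\circ$ to $-45^\circ$, the
usual rule-based architecture.  The inflation-extension deformation
field is exact for an incompressible cylinder, leaving two scalar
unknowns — the deformed inner radius and the axial stretch — determined
by radial equilibrium against the cavity pressure and the closed-tube
reduced axial balance.  Both residuals involve only stress differences,
so the Lagrange multiplier drops out; a 16-point Gauss–Legendre rule
integrates across the wall (the order is a configuration knob with a
convergence test in the suite).  Because the material is hyperelastic
and loading quasi-static, the response is path-independent: only the
end-diastolic pressure needs to be solved, which is equivalent to the
linearly ramped loading it emulates.  A Newton solve with step damping
is tried directly and falls back to pressure continuation (8, then 32
ramp stages) for very soft configurations.

Two behaviours of the finite-element original are reproduced
deliberately:

* **Failure on extreme configurations.**  Solutions whose endocardial
  stretch $r_i/R_i$ exceeds 2 (cavity volume beyond roughly 630 ml) are
  reported as structured simulation failures, the counterpart of mesh
  distortion failures in the FEM; datasets drop and log them, and a
  failure rate above 10% aborts.  Without this guard the semi-analytic
  solver happily produces litre-scale "ventricles" in the softest corner
  of the log-uniform prior, a regime no emulator should be asked to fit
  and no FEM would survive.
* **Segmental heterogeneity.**  On a perfect cylinder the 24 clinical
  wall segments (4 short-axis slices × 6 AHA segments) would be
  degenerate, so each segment carries a deterministic, seeded
  wall-thickness multiplier (±10%, mean exactly 1) and reports strains
  at its own mid-wall radius.  This keeps the 24 circumferential strain
  observations distinguishable, which the likelihood needs.

Quantities of interest follow clinical convention: cavity volume in ml,
and segmental circumferential/longitudinal/radial Green–Lagrange strains
referenced to end-diastole ($\tilde F = F^{-1}$), so a principal stretch
$\lambda$ reports $(\lambda^{-2}-1)/2$ and all strains vanish identically
at zero pressure.  Inflation therefore gives negative circumferential
and longitudinal strains and positive radial strains.

## Designs and priors

All designs come from an unscrambled Sobol sequence (Joe–Kuo direction
numbers, implemented in-package and verified against an independent
reference implementation).  The sensitivity training design of length
$n$ maps the first $n/2$ material-parameter samples linearly onto
$[0.1, 10]$ and the last $n/2$ uniformly in log space, with pressure
(4–30 mmHg) and fibre angles always linear, so one training set covers
both the uniform and log-uniform priors.  Test blocks continue the same
Sobol stream in log space.  The inverse-UQ emulator uses a 5-input
design: the four free log-material parameters plus pressure, with the
sheet/shear constants fixed at the literature values
$a_s = 0.69$ kPa, $b_s = 1.11$, $a_{fs} = 0.31$ kPa, $b_{fs} = 2.58$.

## Gaussian-process emulation

One independent zero-mean GP per scalar output, with the anisotropic
(ARD) squared-exponential kernel plus nugget.  Inputs are
log-transformed on the eight material dimensions (the response varies
much faster at low stiffness; the log makes it more stationary) and
standardized; outputs are standardized to mean 0, variance 1.
Hyperparameters maximize the log marginal likelihood via L-BFGS-B with
analytic gradients; the first start is unit amplitude/lengthscales with
nugget 0.05, further seeded restarts perturb it, and the nugget is
optimized jointly with a floor of $10^{-6}$.  The 24 strain emulators
are warm-started from the first one, since the outputs differ only by
segment geometry.  Cholesky factorizations escalate jitter before
failing.  Emulator accuracy is always validated out-of-sample with the
$Q^2$ coefficient (1 − SSE/SST about the test mean) before an emulator
is used; the study drivers refuse to proceed below a configurable gate
(default 0.9).

Joint posterior function draws over the large pick-freeze designs use
pathwise (Matheron) sampling: a random-Fourier-feature draw from the
prior corrected by the exact conditioning update.  This is linear in
the number of design rows — a dense factorization over the
$N(d+2) \approx 10^4$ rows is not practical — and is cross-checked
statistically against dense sampling on small problems.  Dense
$\mathcal N(\mu, \Sigma)$ sampling remains available (`gp_sample()`).

## Sobol sensitivity analysis

First-order indices use the Saltelli (2010) pick-freeze estimator and
total effects the Jansen estimator — the defaults of the standard SA
libraries — on designs of $N(d+2)$ rows built from a $2d$-dimensional
Sobol stream mapped through the prior inverse CDFs.  Index ensembles
are produced by evaluating the estimators on each of 250 joint GP
posterior draws, so the spread of the ensemble reflects emulator
uncertainty; negative estimates are retained in the ensembles (clipping
to $[-0.05, 1.05]$ happens only in the scalar convenience estimators).
The experiment drivers default to a base sample of $N = 2^9$, which a
doubling check shows moves ensemble mean indices by under 0.01 on these
emulators; the estimator-oracle tests run at $N = 2^{14}$ against
analytic values and a bias-corrected double-loop Monte-Carlo oracle.

The first experiment varies all eleven inputs under both priors for
four outputs (volume and the starred strains of the inferior-lateral
segment of the second slice).  The second fixes the reduced
parameterization and the fibre angles, and sweeps pressure over
5–25 mmHg in steps of 2.5, tracking the total effects of
$a, b, a_f, b_f$ on volume and circumferential strain.

## Bayesian inverse UQ

The observation model concatenates one volume measurement (Gaussian
noise, SD 5 ml — fixed during inference because a single measurement
cannot identify its own variance) and 24 circumferential strains (iid
Gaussian, SD 0.03, variance inferred).  Longitudinal and radial strains
are excluded, matching what can be measured reliably in vivo.  The
log-likelihood is the corresponding two-component Gaussian form with
emulator posterior means plugged in for the forward model (a known
source of inference bias when the emulator is imperfect; the $Q^2$
gate keeps that bias small).

Priors are uniform on the natural scales: each material parameter on
$[0.1, 10]$ and the strain-noise SD on $[10^{-4}, 0.2]$ (the material
prior follows the study bounds; the noise-SD support is a documented
package default).  Sampling runs in an unconstrained
parameterization — a logistic map from $\mathbb R$ onto the log-scale
prior box, with the exact Jacobian — because hard support walls force
gradient-based samplers into random-walk behaviour along weakly
identified directions.  The sampler is an in-package No-U-Turn sampler
(dynamic termination, multiplicative dual-averaging step-size
adaptation targeting 0.8 acceptance, and a dense mass matrix estimated
in two warmup windows with shrinkage, as in Stan's windowed adaptation).
The production path is compiled (Rcpp) with the emulator-stack gradient
fused in; a pure-R reference implementation of the same algorithm is
kept for generic targets and cross-validation.  Five chains start from
Sobol-dispersed points of the prior box; convergence is declared when
every parameter's classic Gelman–Rubin PSRF (the 1992 construction, not
the rank-normalized split variant) is below 1.01.

Practical identifiability is summarized by the inverse interquartile
range (I-IQR) of each marginal posterior on the natural scale, per test
case and pressure, with battery cases additionally binned by the
quartiles of their own noiseless 10 mmHg volumes.  Posterior parameter
draws are also pushed through the uni-axial protocol to give posterior
stress–stretch curve distributions, summarized by the stress I-IQR and
the median inverse absolute error against the ground-truth curve at
each stretch (infinite inverse errors are capped at $10^6$ and
flagged).  The default stretch grid is
$\{1.02, 1.05, 1.10, 1.15, 1.20, 1.25, 1.30\}$ with 500 draws pushed
per case.

## Problem sizes and what the tests show

The package's studies are sized for a single CPU: the showcase
convergence run trains the 25 inverse-UQ emulators on the full
2000-point design and samples 5 × (1000 + 2000) draws; the test suite
exercises the same code paths at reduced sizes (300-point emulators,
batteries of 8–20 cases, shorter chains) chosen so the full suite runs
in minutes.  The synthetic studies demonstrate that the estimators,
emulators and samplers behave correctly on a forward model with the
same constitutive law, the same loading, the same observation model and
the same parameter ranges as the imaging-based original.  They do not
reproduce that model's geometry: a cylinder has no apex or base effects,
its segments differ only through seeded thickness multipliers, and
torsion-related quantities are absent.  Numerical values of indices,
I-IQRs and $Q^2$ therefore characterize this surrogate, not any
patient-derived mesh; it is the qualitative structure — which parameters
dominate, how identifiability shifts with pressure — that transfers.

## Known limitations

No viscoelasticity, active contraction, fibre dispersion, residual
stress or model-discrepancy term; the emulator plug-in uses posterior
means only; the PSRF is the classic construction; geometric uncertainty
is out of scope.  These mirror the boundaries of the workflow the
package implements.
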