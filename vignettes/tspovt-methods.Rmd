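---
title: "Models and methods behind tspovt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tspovt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tspovt)
```

`tspovt` quantifies second-generation TSPO PET tracer binding by full
arterial kinetic modelling and relates the resulting regional total
distribution volumes (V_T) to clinical covariates. This vignette explains
the models, the assumptions they make, the defaults and why they were
chosen, and what the simulation-based tests do and do not demonstrate.

## The input function

TSPO tracers have no valid reference region, so quantification needs the
metabolite-corrected arterial plasma concentration `Cp(t)`. Three component
models turn raw blood measurements into a parametric `Cp`:

* **Whole-blood-to-plasma ratio.** The automated sampler measures whole
  blood; the quantity of interest is plasma. The ratio is modelled as a
  mono-exponential approach to an asymptote,
  `ratio(t) = r_inf + (r0 − r_inf) e^{−k_r t}`. With seven manual draws,
  three parameters are the most complex form the data can support; richer
  shapes would be under-determined.
* **Parent fraction.** Radiometabolites accumulate in plasma but do not
  cross the blood-brain barrier, so only the parent tracer drives the
  tissue signal. The Hill form
  `PF(t) = 1 − (1 − p_inf) t^h / (t^h + t50^h)` is used; it guarantees
  `PF(0) = 1` and monotone decay to `p_inf`, which any physical parent
  fraction must satisfy. Parameters: `p_inf` (asymptotic parent fraction,
  unitless in [0,1)), `h` (Hill exponent), `t50` (minutes to half of the
  asymptotic loss).
* **Plasma model.** The corrected curve is fitted by a straight line from
  zero to the empirical peak followed by three decaying exponentials, with
  continuity (`ΣA_i = c_peak`) enforced by construction: the third
  amplitude absorbs the constraint, so every candidate during optimization
  is already continuous. Levenberg–Marquardt from ten deterministic random
  starts guards against the well-known multi-modality of sums of
  exponentials; the fit is reproducible given its seed.

The metabolite correction is applied to the sampled curve *before* the
tri-exponential fit. Whether correction should precede or follow the
parametric fit is genuinely open; the alternative ordering is available via
`correct_first = FALSE`, which fits total plasma first and then projects
the corrected prediction back onto the same family. The two orderings agree
on the integral scale but not point-by-point, because total plasma (parent
plus metabolites) does not itself belong to the tri-exponential family —
this is why the package treats the ordering as an explicit, visible flag
rather than an implementation detail. No delay or dispersion correction of
the automated sampling line is applied; that is a deliberate omission, and
analyses of real data with long sampling lines should be aware of it.

Automated samples are emulated at 1 Hz over 0–360 s. Where automated and
manual series overlap in time, the manual draw wins (manual plasma is
measured directly rather than derived through the ratio model).

## Kinetics

The two-tissue-compartment model describes delivery (K1, mL·cm⁻³·min⁻¹),
efflux (k2, min⁻¹) and exchange with the specifically bound compartment
(k3, k4, min⁻¹). Its impulse response is
`h(t) = φ1 e^{−θ1 t} + φ2 e^{−θ2 t}` with macro rates the roots of
`θ² − (k2+k3+k4)θ + k2k4`, and the model curve is

```
C(t) = (1 − vB) · (h ⊗ Cp)(t) + vB · C_wb(t)
```

with the blood volume fraction fixed at `vB = 0.05`, not fitted. The
convolution with the piecewise input model is evaluated in closed form
(ramp and exponential segments each convolve analytically with an
exponential), which makes a frame-averaged model evaluation cost a few
hundred `exp` calls — the property tests verify agreement with brute-force
adaptive quadrature to better than 1e-6 relative. When the two macro rates
coincide (`θ1 ≈ θ2`, a measure-zero configuration reachable only when
`(k2+k3+k4)² = 4k2k4`), the impulse response uses the exact analytic limit,
and the convolution nudges the rates apart by one part in 10⁶ rather than
implementing the `t·e^{−θt}` convolution branch; the approximation error is
of the same order as the nudge.

The total distribution volume, the study outcome, is
`V_T = (K1/k2)(1 + k3/k4)`, and equals the integral of `h` — an identity
the acceptance suite verifies over 10⁴ random parameter draws.

Fitting minimizes frame-duration-weighted least squares over the 20 frames
of the default acquisition (1×120, 2×60, 3×120, 6×300, 8×600 s; 120 min
total). Choices a reader should know about:

* **Weights ∝ frame duration** (normalized to mean 1). Acquisition noise
  is not specified by the protocol; duration weighting is the minimal
  standard surrogate for count statistics and is configurable per TAC.
* **Bounds** `K1, k2, k3, k4 ∈ (1e-4, 2]` in their native units, `vB`
  fixed. Ten Levenberg–Marquardt starts (one physiological, nine
  log-uniform inside the bounds) with a fixed seed; the lowest-RSS
  solution wins, making fits deterministic.
* **Boundary flagging.** `k4` is weakly identified in a 120-min scan: at
  realistic noise a small fraction of replicate fits slide down the
  `k4 → 0` ridge, where V_T diverges. A fit whose parameters land within
  1% of a box bound is flagged `converged = FALSE`; replicate-level
  summaries in the tests use converged fits only (98–100 of 100 at 5% TAC
  noise), mirroring routine kinetic-analysis practice of excluding
  boundary solutions.
* **V_T standard error** by the delta method from the Jacobian-based
  covariance of the microparameters; exactly-interpolating (noiseless)
  fits legitimately report SE 0.
* **Units:** rates in min⁻¹ and times in minutes internally; frame tables
  stay in seconds at the interfaces.
* The whole-blood curve for the vascular term interpolates the automated
  segment linearly and the manual draws log-linearly, with log-linear
  extrapolation beyond the last draw (the protocol does not say how the
  vascular term is carried past 6 min; log-linear decay is the natural
  choice for a clearing tracer).

## Region-based partial-volume correction

Scanner resolution mixes signal between regions. For regional (not
voxelwise) correction the geometric transfer matrix is canonical and
exactly testable: `G[i,j]` is the mean over region `i`'s voxels of the
PSF-smoothed indicator of region `j`, so for a noiseless piecewise-constant
image `observed = G · true` holds exactly and `solve(G, observed)` recovers
the truth to linear-solver precision — the acceptance suite demonstrates
this on a two-cube phantom at 6 mm FWHM. The PSF is modelled as an
isotropic Gaussian (default FWHM 5 mm, configurable); `FWHM = 0` yields the
identity. Corrections can be applied per frame to TACs (default) or post
hoc to V_T values — both modes are exposed because either ordering is
defensible and the choice should be visible, not buried. A condition-number
guard (default 10⁶) refuses corrections on near-singular geometry. RBV or
iterative-Yang style voxelwise refinements are out of scope.

## Association statistics

Regional V_T is strictly positive and right-skewed, so each region is
modelled with a Gamma GLM and log link. Every model adjusts for TSPO
rs6971 genotype (HAB = 1 indicator): the polymorphism changes tracer
affinity and is the single largest known source of between-subject variance
in second-generation TSPO PET. Dispersion is estimated by Pearson χ²/df and
inference uses t statistics on `n − p` degrees of freedom.

Effect sizes are derived from the coefficient t statistic:
`d = 2t/√df` and `r = t/√(t² + df)`. This is one standard conversion among
several; other conventions rescale `d` by a constant, so `d` values should
be compared within, not across, conventions. Continuous predictors are
z-scored within sample by default (coefficients per predictor SD);
`raw_units = TRUE` preserves native units such as "per PCL-5 point".

Multiplicity is handled by Benjamini–Hochberg FDR within each predictor
family across the seven regions (six ROIs plus whole brain). The family
definition is configurable (`per_predictor` or `global`) because the
appropriate family genuinely depends on the analysis plan and cannot be
inferred from a results table after the fact.

## The synthetic cohort generator

The generator exists so that every stage above can be checked by parameter
recovery. It draws, per subject: PCL-5 total from a truncated normal
(mean 30, SD 18, support [0, 80]); four symptom-cluster subscales as
item-count-weighted fractions of the total (5/2/7/6 of 20 items) plus
correlated noise through a shared latent factor (ρ = 0.6 by default);
months of site exposure from a lognormal (median 10 months); genotype
MAB with probability 0.55; MCI status with probability 0.5 (a matched
design); and six standard-normal cognitive domain scores. Regional V_T
follows the same generative model the analysis fits:
`μ = exp(α_region + β_HAB·HAB + β_PCL·z(pcl) + β_months·z(months))`,
`V_T ~ Gamma(mean μ, shape κ)` with κ = 25 (≈20% CV) by default. Defaults
for the effects are `β_HAB = 0.4` (high-affinity binders bind more),
`β_PCL = 0.15` and `β_months = 0.08` per SD — magnitudes that put
single-predictor effect sizes in the |d| ≈ 0.3–0.75 range at n = 20.

Baseline regional V_T (`α_region`) is set to generic plausibility for a
second-generation TSPO tracer — about 10–12 mL/cm³, hippocampus highest —
because no per-subject V_T ranges are published for this design; nothing
downstream depends on the absolute level, only on recovery of the imposed
structure. Microparameters per subject and region hold `k2, k3, k4` at
regional base values (0.08, 0.04, 0.02 min⁻¹) and solve
`K1 = V_T · k2 / (1 + k3/k4)`; V_T is linear in K1, so the stored V_T is
exact by construction and the generator stays identifiable.

TAC noise is zero-mean Gaussian with standard deviation
`cv · activity / sqrt(duration/max duration)` — the standard surrogate for
count-limited frame statistics (short early frames are noisier). Blood
noise is multiplicative Gaussian. Both are controlled by seeds, and
identical configuration plus seed reproduces every output byte-for-byte.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: head motion, scatter and attenuation residuals,
sampler delay/dispersion, plasma free-fraction variation, non-Gaussian
frame noise, anatomically realistic region geometry (the phantom uses
cuboids), and any model misspecification (the analysis fits the same family
that generated the data, so calibration results certify the inference
machinery, not robustness to wrong models).

## Numerical choices and degenerate inputs

* Frame averages use 16-node Gauss–Legendre quadrature per frame (exact
  for polynomials to degree 31; the integrands are smooth).
* Constant ratio data yields a flat ratio model directly (the rate is not
  identifiable from constant data).
* A plasma curve with no unique maximum is rejected; fewer than five
  post-peak points triggers a flagged bi-exponential fallback.
* Simulation problem sizes in the test-suite: 100 replicate noisy kinetic
  fits; 200 replicate cohorts of n = 2000 for type-I error and of n = 200
  for CI coverage; 50 replicates for the effect-ordering check — sizes at
  which Monte-Carlo error is small relative to the stated bands.
* Non-converged Gamma GLM warnings can appear at very small n (df ≤ 2)
  with extreme V_T outliers; the pipeline surfaces them rather than hiding
  them.

## Known limitations

Logan/MA1 graphical methods and voxelwise parametric maps are not
implemented; there is no DICOM ingestion, motion correction or
segmentation (label volumes are consumed, not produced); and the effect-size
conversion ties `d` and `r` to the t statistic rather than to raw group
contrasts. The pipeline's PVC stage demonstrates GTM correction on a
synthetic demo geometry — applying it to real data requires subject-specific
label volumes and the scanner's measured PSF.
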